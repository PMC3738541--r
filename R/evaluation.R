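#' Partition labeled miRNAs into cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ
#' by at most one and the same seed always yields the same partition.
#'
#' @param labeled Character vector of labeled miRNA ids.
#' @param n_folds Number of folds, default 5.
#' @param seed Integer seed.
#' @return A tibble `mirna_id`, `fold`.
#' @export
make_folds <- function(labeled, n_folds = 5, seed = 1) {
  labeled <- unique(labeled)
  if (length(labeled) < n_folds) {
    abort(paste0("need at least ", n_folds, " labeled miRNAs, got ",
                 length(labeled)),
          class = "hdmp_insufficient_labels_error")
  }
  shuffled <- withr::with_seed(seed,
    sample(sort(labeled, method = "radix")))
  tibble(mirna_id = shuffled,
         fold = rep_len(seq_len(n_folds), length(shuffled)))
}

#' ROC curve from the ranks of held-out positives
#'
#' Sweeps the rank threshold over the whole candidate pool: at cutoff `c`,
#' sensitivity is the fraction of positives ranked at or above `c` and the
#' false-positive rate is the fraction of negatives ranked at or above `c`.
#' The area is computed by the trapezoid rule.
#'
#' @param positive_ranks Integer ranks (1 = top) of the positives within
#'   the pooled ranking.
#' @param pool_size Total number of ranked candidates.
#' @return An object of class `hdmp_roc`: list with `points` (tibble
#'   `cutoff`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(1, 2), 10)$auc  # all positives on top: 1
#' @export
roc_curve <- function(positive_ranks, pool_size) {
  if (length(positive_ranks) == 0) {
    abort("no positives: ROC curve undefined",
          class = "hdmp_undefined_curve_error")
  }
  if (any(positive_ranks < 1 | positive_ranks > pool_size) ||
      anyDuplicated(positive_ranks)) {
    abort("positive ranks must be distinct and within the pool")
  }
  n_pos <- length(positive_ranks)
  n_neg <- pool_size - n_pos
  if (n_neg == 0) abort("pool contains no negatives")
  cutoffs <- 0:pool_size
  tp <- vapply(cutoffs, function(c) sum(positive_ranks <= c), numeric(1))
  fp <- cutoffs - tp
  points <- tibble(cutoff = cutoffs, fpr = fp / n_neg, tpr = tp / n_pos)
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "hdmp_roc")
}

#' @export
print.hdmp_roc <- function(x, ...) {
  cat("<hdmp_roc> AUC = ", format(x$auc, digits = 4),
      " (", x$n_pos, " positives, ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

# Rank-based AUC on scores: fraction of positive-negative pairs ordered
# correctly, ties counted 1/2 (Mann-Whitney).
auc_from_scores <- function(pos, neg) {
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Per-disease k-fold cross-validation
#'
#' The disease's labeled miRNAs are split into folds; each fold in turn is
#' held out and the model is rebuilt from the remaining labels only: the
#' held-out associations are removed before the miRNA similarity matrix is
#' recomputed (from the cached disease similarities) and before family and
#' cluster weights are derived, so no held-out information leaks into
#' scoring. The candidate pool is the union of the never-labeled miRNAs
#' and the held-out positives; the fold AUC is the rank-based
#' (Mann-Whitney, ties 1/2) probability that a held-out positive outscores
#' an unlabeled candidate.
#'
#' @param data An [hdmp_data()] object.
#' @param disease Ontology term id or name.
#' @param n_folds Number of folds, default 5.
#' @param seed Integer seed for the fold split.
#' @param k Neighborhood size override.
#' @return A tibble `disease_id`, `fold`, `n_test`, `auc` with attribute
#'   `mean_auc`.
#' @export
evaluate_disease_cv <- function(data, disease, n_folds = 5, seed = 1,
                                k = NULL) {
  stopifnot(inherits(data, "hdmp_data"))
  if (!is.null(data$ontology)) disease <- resolve_term(data$ontology, disease)
  k <- k %||% data$config$k
  assoc <- data$associations
  labeled <- unique(assoc$mirna_id[assoc$disease_id == disease])
  folds <- make_folds(labeled, n_folds = n_folds, seed = seed)
  universe <- rownames(data$similarity)
  never_labeled <- setdiff(universe, labeled)

  res <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- folds$mirna_id[folds$fold == f]
    drop <- assoc$mirna_id %in% test & assoc$disease_id == disease
    train <- assoc[!drop, ]
    class(train) <- class(assoc)
    ms <- if (is.null(data$ds)) data$similarity else
      ms_from_disease_sets(disease_sets(train), data$ds, universe = universe)
    engine <- scoring_engine(data, disease, train, k = k, similarity = ms)
    pool <- c(never_labeled, test)
    scores <- vapply(pool, engine, numeric(1))
    res[[f]] <- tibble(
      disease_id = disease, fold = f, n_test = length(test),
      auc = auc_from_scores(scores[test], scores[never_labeled])
    )
  }
  out <- bind_rows(res)
  attr(out, "mean_auc") <- mean(out$auc)
  out
}

#' Cross-validate every eligible disease
#'
#' Runs [evaluate_disease_cv()] for each disease with at least `min_labels`
#' labeled miRNAs (and at least `n_folds`, so a split exists). Diseases
#' below the threshold are reported as skipped, not errors.
#'
#' @inheritParams evaluate_disease_cv
#' @param min_labels Eligibility threshold on the labeled-set size;
#'   default 60 (appropriate for HMDD-scale catalogs — lower it for small
#'   synthetic corpora).
#' @param diseases Optional subset of disease ids to evaluate.
#' @return An object of class `hdmp_cv`: list with `folds` (per-fold
#'   tibble), `diseases` (per-disease means and skip status) and
#'   `mean_auc` (unweighted grand mean over evaluated diseases).
#' @export
hdmp_cv <- function(data, n_folds = 5, seed = 1, min_labels = 60,
                    k = NULL, diseases = NULL) {
  stopifnot(inherits(data, "hdmp_data"))
  assoc <- data$associations
  counts <- assoc |> count(disease_id, name = "n_labeled") |>
    arrange(disease_id)
  if (!is.null(diseases)) counts <- counts[counts$disease_id %in% diseases, ]
  eligible <- counts$n_labeled >= max(min_labels, n_folds)

  fold_rows <- list()
  disease_rows <- list()
  for (i in seq_len(nrow(counts))) {
    d <- counts$disease_id[i]
    if (!eligible[i]) {
      disease_rows[[i]] <- tibble(disease_id = d,
                                  n_labeled = counts$n_labeled[i],
                                  mean_auc = NA_real_, status = "skipped")
      next
    }
    r <- evaluate_disease_cv(data, d, n_folds = n_folds, seed = seed, k = k)
    fold_rows[[i]] <- r
    disease_rows[[i]] <- tibble(disease_id = d,
                                n_labeled = counts$n_labeled[i],
                                mean_auc = attr(r, "mean_auc"),
                                status = "evaluated")
  }
  diseases_tbl <- bind_rows(disease_rows)
  structure(
    list(
      folds = bind_rows(fold_rows),
      diseases = diseases_tbl,
      mean_auc = mean(diseases_tbl$mean_auc[diseases_tbl$status == "evaluated"]),
      config = c(data$config[c("scheme", "delta", "lambda", "alpha", "beta")],
                 list(k = k %||% data$config$k, n_folds = n_folds,
                      seed = seed, min_labels = min_labels))
    ),
    class = "hdmp_cv"
  )
}

#' @export
print.hdmp_cv <- function(x, ...) {
  n_eval <- sum(x$diseases$status == "evaluated")
  cat("<hdmp_cv> ", n_eval, " disease(s) x ", x$config$n_folds,
      " folds; mean AUC = ", format(x$mean_auc, digits = 4), "\n", sep = "")
  print(x$diseases, ...)
  invisible(x)
}

#' Temporal hold-out validation against an updated association catalog
#'
#' The model is built from an older association snapshot only; for each
#' disease the positives are the miRNAs newly associated in the updated
#' snapshot, and the candidate pool is every miRNA unlabeled under the old
#' snapshot. Associations present in the old snapshot but missing from the
#' new one violate the additions-only assumption and are logged and
#' ignored. Diseases with no (usable) additions, or absent from the old
#' snapshot, are reported as skipped.
#'
#' @param data An [hdmp_data()] object built from the *old* associations.
#' @param new_associations The updated association table.
#' @param k Neighborhood size override.
#' @return An object of class `hdmp_holdout`: list with `diseases`
#'   (per-disease tibble `disease_id`, `n_old`, `n_new`, `auc`, `status`)
#'   and `mean_auc` over evaluated diseases.
#' @export
hdmp_holdout <- function(data, new_associations, k = NULL) {
  stopifnot(inherits(data, "hdmp_data"))
  old <- data$associations
  new <- as_associations(new_associations, ontology = data$ontology)
  removed <- anti_join(old, as_tibble(new), by = c("mirna_id", "disease_id"))
  if (nrow(removed) > 0) {
    inform(paste0(nrow(removed), " old association(s) missing from the ",
                  "updated catalog; ignored (additions-only assumption)"))
  }
  universe <- rownames(data$similarity)
  k <- k %||% data$config$k

  rows <- list()
  for (d in sort(unique(old$disease_id), method = "radix")) {
    old_lab <- unique(old$mirna_id[old$disease_id == d])
    new_lab <- unique(new$mirna_id[new$disease_id == d])
    additions <- intersect(setdiff(new_lab, old_lab), universe)
    if (length(additions) == 0) {
      rows[[d]] <- tibble(disease_id = d, n_old = length(old_lab),
                          n_new = 0L, auc = NA_real_, status = "skipped")
      next
    }
    pool <- setdiff(universe, old_lab)
    engine <- scoring_engine(data, d, old, k = k)
    scores <- vapply(pool, engine, numeric(1))
    rows[[d]] <- tibble(
      disease_id = d, n_old = length(old_lab), n_new = length(additions),
      auc = auc_from_scores(scores[additions],
                            scores[setdiff(pool, additions)]),
      status = "evaluated"
    )
  }
  diseases_tbl <- bind_rows(rows)
  structure(
    list(diseases = diseases_tbl,
         mean_auc = mean(diseases_tbl$auc[diseases_tbl$status == "evaluated"])),
    class = "hdmp_holdout"
  )
}

#' @export
print.hdmp_holdout <- function(x, ...) {
  cat("<hdmp_holdout> mean AUC = ", format(x$mean_auc, digits = 4),
      " over ", sum(x$diseases$status == "evaluated"), " disease(s)\n",
      sep = "")
  print(x$diseases, ...)
  invisible(x)
}

#' Sweep one tuning parameter over a grid
#'
#' Re-runs the full cross-validation for each value of `k`, `alpha` or
#' `beta`, holding everything else at the dataset configuration, and
#' reports the grand-mean AUC per value.
#'
#' @inheritParams hdmp_cv
#' @param param One of `"k"`, `"alpha"`, `"beta"`.
#' @param values Numeric grid to sweep.
#' @return A tibble `param`, `value`, `mean_auc`.
#' @export
hdmp_sweep <- function(data, param = c("k", "alpha", "beta"), values,
                       n_folds = 5, seed = 1, min_labels = 60,
                       diseases = NULL) {
  param <- match.arg(param)
  rows <- map(values, function(v) {
    d <- data
    if (param == "k") {
      cv <- hdmp_cv(d, n_folds = n_folds, seed = seed,
                    min_labels = min_labels, k = v, diseases = diseases)
    } else {
      d$config[[param]] <- v
      cv <- hdmp_cv(d, n_folds = n_folds, seed = seed,
                    min_labels = min_labels, diseases = diseases)
    }
    tibble(param = param, value = v, mean_auc = cv$mean_auc)
  })
  bind_rows(rows)
}
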