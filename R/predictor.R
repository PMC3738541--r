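#' Assemble a prediction dataset
#'
#' Bundles everything the scorer needs: the validated associations, the
#' miRNA functional-similarity matrix (computed from an ontology, or
#' supplied precomputed), family and cluster catalogs restricted to the
#' dataset miRNAs, and the tuning parameters. The pairwise disease
#' similarities are cached so cross-validation can rebuild the miRNA matrix
#' per fold cheaply.
#'
#' @param associations miRNA-disease pairs, see [as_associations()].
#' @param ontology An [as_ontology()] table; required unless `similarity`
#'   is given.
#' @param similarity Optional precomputed symmetric miRNA similarity matrix
#'   with ids as dimnames. Its rownames define the miRNA universe (so it
#'   may contain miRNAs with no association yet).
#' @param families Optional family catalog (tibble `group_id`, `mirna_id`).
#' @param loci Optional precursor coordinates; clusters are derived with
#'   [build_clusters()] when `clusters` is not given directly.
#' @param clusters Optional cluster catalog.
#' @param phenotypes,phenotype_map Optional phenotype-similarity table and
#'   term-to-phenotype mapping, see [phenotype_similarity()].
#' @param scheme Disease contribution scheme, `"ic"` (default) or `"layer"`.
#' @param delta Layer-scheme contribution factor, default 0.5.
#' @param lambda Semantic/phenotype fusion weight, default 0.5.
#' @param alpha,beta Family and cluster weight adjustment factors, default 4.
#' @param k Neighborhood size for scoring, default 20.
#' @param max_gap Cluster chaining gap in bp, default 20000.
#' @return An object of class `hdmp_data`.
#' @export
hdmp_data <- function(associations, ontology = NULL, similarity = NULL,
                      families = NULL, loci = NULL, clusters = NULL,
                      phenotypes = NULL, phenotype_map = NULL,
                      scheme = c("ic", "layer"), delta = 0.5, lambda = 0.5,
                      alpha = 4, beta = 4, k = 20, max_gap = 20000) {
  scheme <- match.arg(scheme)
  if (is.null(ontology) && is.null(similarity)) {
    abort("either `ontology` or a precomputed `similarity` matrix is required")
  }
  if (!is.null(ontology)) ontology <- as_ontology(ontology)
  associations <- as_associations(associations, ontology = ontology)

  ic <- ds <- NULL
  if (is.null(similarity)) {
    if (scheme == "ic") ic <- compute_information_content(ontology)
    ds <- disease_similarity_matrix(
      ontology, unique(associations$disease_id),
      scheme = scheme, delta = delta, ic = ic,
      phenotypes = phenotypes, mapping = phenotype_map, lambda = lambda
    )
    similarity <- ms_from_disease_sets(disease_sets(associations), ds)
  } else {
    if (is.null(dimnames(similarity)[[1]])) {
      abort("`similarity` needs miRNA ids as dimnames")
    }
    rownames(similarity) <- normalize_mirna_id(rownames(similarity))
    colnames(similarity) <- normalize_mirna_id(colnames(similarity))
    if (!isTRUE(all.equal(similarity, t(similarity), tolerance = 1e-8))) {
      abort("`similarity` must be symmetric")
    }
    orphan <- setdiff(associations$mirna_id, rownames(similarity))
    if (length(orphan) > 0) {
      abort(paste0("associations reference miRNAs absent from the ",
                   "similarity matrix: ", paste(orphan, collapse = ", ")))
    }
  }
  universe <- rownames(similarity)

  if (is.null(clusters) && !is.null(loci)) {
    clusters <- build_clusters(loci, max_gap = max_gap)
  }
  families <- unique_membership(restrict_catalog(families, universe), "family")
  clusters <- unique_membership(restrict_catalog(clusters, universe), "cluster")

  structure(
    list(
      associations = associations,
      ontology = ontology,
      similarity = similarity,
      families = families,
      clusters = clusters,
      phenotypes = phenotypes,
      phenotype_map = phenotype_map,
      ds = ds,
      ic = ic,
      config = list(scheme = scheme, delta = delta, lambda = lambda,
                    alpha = alpha, beta = beta, k = k, max_gap = max_gap)
    ),
    class = "hdmp_data"
  )
}

# enforce <=1 group per miRNA (first group in radix order wins, with a warning)
unique_membership <- function(catalog, kind) {
  if (nrow(catalog) > 0 && anyDuplicated(catalog$mirna_id)) {
    dup <- unique(catalog$mirna_id[duplicated(catalog$mirna_id)])
    warn(paste0(length(dup), " miRNA(s) in more than one ", kind,
                "; keeping the first membership each"))
    catalog <- catalog[!duplicated(catalog$mirna_id), ]
  }
  attr(catalog, "kind") <- kind
  catalog
}

#' @export
print.hdmp_data <- function(x, ...) {
  cat("<hdmp_data>\n",
      "  miRNAs:       ", nrow(x$similarity), "\n",
      "  diseases:     ", length(unique(x$associations$disease_id)), "\n",
      "  associations: ", nrow(x$associations), "\n",
      "  families:     ", length(unique(x$families$group_id)), "\n",
      "  clusters:     ", length(unique(x$clusters$group_id)), "\n",
      "  scheme:       ", x$config$scheme,
      " (delta=", x$config$delta, ", lambda=", x$config$lambda, ")\n",
      "  k=", x$config$k, ", alpha=", x$config$alpha,
      ", beta=", x$config$beta, "\n", sep = "")
  invisible(x)
}

#' The k most similar neighbors of a miRNA
#'
#' Returns the top-`k` other miRNAs by functional similarity. Ties are
#' broken by ascending miRNA id so the neighborhood is deterministic; when
#' the pool holds fewer than `k` others, all of them are returned.
#'
#' @param similarity A symmetric miRNA similarity matrix (or an
#'   [hdmp_data()] object).
#' @param u The query miRNA id.
#' @param k Neighborhood size.
#' @return A tibble `mirna_id`, `similarity` in descending similarity order.
#' @export
select_neighbors <- function(similarity, u, k) {
  if (inherits(similarity, "hdmp_data")) similarity <- similarity$similarity
  u <- normalize_mirna_id(u)
  if (!u %in% rownames(similarity)) {
    abort(paste0("unknown miRNA: '", u, "'"), class = "hdmp_lookup_error")
  }
  stopifnot(k >= 1)
  sims <- similarity[u, ]
  sims <- sims[names(sims) != u]
  ord <- order(-sims, names(sims), method = "radix")
  take <- head(ord, k)
  tibble(mirna_id = names(sims)[take], similarity = unname(sims[take]))
}

#' Subscore contributed by one neighbor
#'
#' A neighbor `v` of query miRNA `u` contributes 0 when it is not labeled
#' with the disease. When labeled, it contributes its functional similarity
#' MS(u, v), multiplied by the family weight when `u` and `v` share a
#' family and by the cluster weight when they share a cluster (both
#' boosts apply when both groups are shared).
#'
#' @param data An [hdmp_data()] object.
#' @param u,v Query and neighbor miRNA ids.
#' @param disease Ontology term id of the query disease.
#' @param labels Optional association table overriding `data$associations`
#'   (used during cross-validation to score against training labels only).
#' @return A non-negative scalar.
#' @export
neighbor_subscore <- function(data, u, v, disease, labels = NULL) {
  stopifnot(inherits(data, "hdmp_data"))
  labels <- if (is.null(labels)) data$associations else as_associations(labels)
  u <- normalize_mirna_id(u); v <- normalize_mirna_id(v)
  labeled <- any(labels$mirna_id == v & labels$disease_id == disease)
  if (!labeled) return(0)
  w <- pair_weight(data, u, v, disease, labels)
  unname(data$similarity[u, v] * w)
}

pair_weight <- function(data, u, v, disease, labels) {
  w <- 1
  fu <- data$families$group_id[match(u, data$families$mirna_id)]
  fv <- data$families$group_id[match(v, data$families$mirna_id)]
  if (!is.na(fu) && !is.na(fv) && fu == fv) {
    members <- data$families$mirna_id[data$families$group_id == fu]
    w <- w * group_weight(group_rate(members, disease, labels),
                          data$config$alpha)
  }
  cu <- data$clusters$group_id[match(u, data$clusters$mirna_id)]
  cv <- data$clusters$group_id[match(v, data$clusters$mirna_id)]
  if (!is.na(cu) && !is.na(cv) && cu == cv) {
    members <- data$clusters$mirna_id[data$clusters$group_id == cu]
    w <- w * group_weight(group_rate(members, disease, labels),
                          data$config$beta)
  }
  w
}

#' Relevance score of a candidate miRNA for a disease
#'
#' The sum of [neighbor_subscore()] over the query's k most similar
#' neighbors. Unlabeled neighbors occupy neighborhood slots but contribute
#' 0, so a candidate surrounded by labeled, highly similar miRNAs scores
#' high.
#'
#' @inheritParams neighbor_subscore
#' @param k Neighborhood size; defaults to the dataset's configured `k`.
#' @return A non-negative scalar.
#' @export
relevance_score <- function(data, u, disease, k = NULL, labels = NULL) {
  stopifnot(inherits(data, "hdmp_data"))
  k <- k %||% data$config$k
  labels <- if (is.null(labels)) data$associations else as_associations(labels)
  engine <- scoring_engine(data, disease, labels, k = k)
  unname(engine(normalize_mirna_id(u)))
}

# Closure scoring any candidate against fixed labels/weights; weights are
# computed once per (disease, labels) pair.
scoring_engine <- function(data, disease, labels, k,
                           similarity = data$similarity) {
  fam_w <- group_weight_table(data$families, disease, labels,
                              factor = data$config$alpha)
  clus_w <- group_weight_table(data$clusters, disease, labels,
                               factor = data$config$beta)
  fam_of <- setNames(data$families$group_id, data$families$mirna_id)
  clus_of <- setNames(data$clusters$group_id, data$clusters$mirna_id)
  fw <- setNames(fam_w$weight, fam_w$group_id)
  cw <- setNames(clus_w$weight, clus_w$group_id)
  labeled <- unique(labels$mirna_id[labels$disease_id == disease])

  function(u) {
    sims <- similarity[u, ]
    sims <- sims[names(sims) != u]
    ord <- order(-sims, names(sims), method = "radix")
    nb <- names(sims)[head(ord, k)]
    lab <- nb[nb %in% labeled]
    if (length(lab) == 0) return(0)
    w <- rep(1, length(lab))
    fu <- unname(fam_of[u])
    if (!is.na(fu)) {
      share <- !is.na(fam_of[lab]) & fam_of[lab] == fu
      w[share] <- w[share] * fw[fu]
    }
    cu <- unname(clus_of[u])
    if (!is.na(cu)) {
      share <- !is.na(clus_of[lab]) & clus_of[lab] == cu
      w[share] <- w[share] * cw[cu]
    }
    sum(similarity[u, lab] * w)
  }
}

#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA in the candidate pool (by default all miRNAs not yet
#' labeled with the disease) and ranks them by descending relevance score,
#' ties broken by ascending miRNA id, with dense 1-based ranks.
#'
#' @inheritParams relevance_score
#' @param disease Ontology term id (or name when the dataset carries an
#'   ontology); must have at least one labeled miRNA.
#' @param pool Optional candidate pool; defaults to the unlabeled miRNAs.
#' @param top Optionally keep only the first `top` rows.
#' @return A tibble `rank`, `mirna_id`, `score` of class `hdmp_ranking`
#'   with attributes `disease` and `k`.
#' @export
rank_candidates <- function(data, disease, k = NULL, pool = NULL,
                            labels = NULL, top = NULL) {
  stopifnot(inherits(data, "hdmp_data"))
  if (!is.null(data$ontology)) disease <- resolve_term(data$ontology, disease)
  k <- k %||% data$config$k
  labels <- if (is.null(labels)) data$associations else as_associations(labels)
  labeled <- unique(labels$mirna_id[labels$disease_id == disease])
  if (length(labeled) == 0) {
    abort(paste0("disease '", disease, "' has no labeled miRNAs"),
          class = "hdmp_no_labels_error")
  }
  universe <- rownames(data$similarity)
  pool <- if (is.null(pool)) setdiff(universe, labeled) else
    intersect(normalize_mirna_id(pool), universe)
  engine <- scoring_engine(data, disease, labels, k = k)
  scores <- vapply(pool, engine, numeric(1))
  ord <- order(-scores, pool, method = "radix")
  out <- tibble(rank = seq_along(pool), mirna_id = pool[ord],
                score = unname(scores[ord]))
  if (!is.null(top)) out <- head(out, top)
  structure(out, disease = disease, k = k,
            class = c("hdmp_ranking", class(out)))
}

#' Predict disease-miRNA candidates
#'
#' Convenience wrapper around [rank_candidates()] for prediction use: ranks
#' all currently unlabeled miRNAs for the disease.
#'
#' @inheritParams rank_candidates
#' @return See [rank_candidates()].
#' @export
hdmp_predict <- function(data, disease, k = NULL, top = NULL) {
  rank_candidates(data, disease, k = k, top = top)
}
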