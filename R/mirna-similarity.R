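#' Normalize miRNA identifiers
#'
#' Folds case (so `hsa-miR-21` and `hsa-mir-21` are one precursor-style id)
#' and trims surrounding whitespace.
#'
#' @param x Character vector of miRNA names.
#' @return Character vector of normalized ids.
#' @export
normalize_mirna_id <- function(x) {
  tolower(trimws(as.character(x)))
}

#' Construct an association set
#'
#' A set of validated (miRNA, disease) pairs, deduplicated after id
#' normalization. Diseases may be given as ontology term ids or names; when
#' an ontology is supplied, names are resolved and pairs whose disease is
#' absent from the ontology are dropped with a message reporting kept and
#' dropped counts.
#'
#' @param x A data frame whose first two columns are miRNA id and disease
#'   (columns `mirna_id`, `disease_id` are used when present).
#' @param ontology Optional [as_ontology()] table used to resolve and filter
#'   diseases.
#' @return A tibble `mirna_id`, `disease_id` of class `hdmp_associations`.
#' @export
as_associations <- function(x, ontology = NULL) {
  if (inherits(x, "hdmp_associations") && is.null(ontology)) return(x)
  x <- as_tibble(x)
  if (!all(c("mirna_id", "disease_id") %in% names(x))) {
    if (ncol(x) < 2) abort("association table needs two columns")
    names(x)[1:2] <- c("mirna_id", "disease_id")
  }
  out <- tibble(
    mirna_id = normalize_mirna_id(x$mirna_id),
    disease_id = as.character(x$disease_id)
  )
  if (!is.null(ontology)) {
    ontology <- as_ontology(ontology)
    by_name <- setNames(ontology$term_id, ontology$name)
    unresolved <- !(out$disease_id %in% ontology$term_id)
    nm <- normalize_name(out$disease_id[unresolved])
    out$disease_id[unresolved] <- unname(by_name[nm])
    drop <- is.na(out$disease_id)
    if (any(drop)) {
      inform(paste0("dropped ", sum(drop), " association(s) with diseases ",
                    "absent from the ontology; kept ", sum(!drop)))
      out <- out[!drop, ]
    }
  }
  out <- distinct(out)
  if (nrow(out) == 0) {
    abort("no associations left after filtering",
          class = "hdmp_empty_associations_error")
  }
  class(out) <- c("hdmp_associations", class(out))
  out
}

# named list: mirna_id -> character vector of disease ids
disease_sets <- function(associations) {
  split(associations$disease_id, associations$mirna_id)
}

#' Functional similarity of two miRNAs
#'
#' The functional similarity MS(u, v) is the best-match average similarity
#' between the two miRNAs' disease groups:
#' \deqn{MS(u,v) = \frac{\sum_{d \in DT_u} S(d, DT_v) + \sum_{d \in DT_v} S(d, DT_u)}{|DT_u| + |DT_v|}}
#' where `S(d, DT)` is the maximum fused disease similarity between `d` and
#' any member of `DT`. Symmetric, in \[0, 1\], and 1 when the two disease
#' groups are identical.
#'
#' @param u,v miRNA ids present in `associations`.
#' @param associations An [as_associations()] table.
#' @param ds Symmetric disease-similarity matrix (term ids as dimnames)
#'   covering every disease in the two groups, or a pairwise function; see
#'   [group_similarity()].
#' @return A scalar in \[0, 1\].
#' @export
mirna_functional_similarity <- function(u, v, associations, ds) {
  associations <- as_associations(associations)
  dt <- disease_sets(associations)
  u <- normalize_mirna_id(u); v <- normalize_mirna_id(v)
  du <- unique(dt[[u]]); dv <- unique(dt[[v]])
  if (length(du) == 0) {
    abort(paste0("miRNA '", u, "' has no associated diseases"),
          class = "hdmp_unusable_mirna_error")
  }
  if (length(dv) == 0) {
    abort(paste0("miRNA '", v, "' has no associated diseases"),
          class = "hdmp_unusable_mirna_error")
  }
  su <- vapply(du, function(d) group_similarity(d, dv, ds), numeric(1))
  sv <- vapply(dv, function(d) group_similarity(d, du, ds), numeric(1))
  (sum(su) + sum(sv)) / (length(du) + length(dv))
}

# Vectorized MS matrix from per-miRNA disease sets and a cached DS matrix.
# For each miRNA u, S(d, DT_u) over all diseases is a column of row maxima;
# then the numerator splits into two incidence-matrix products. Empty
# disease sets (possible inside CV folds) yield similarity 0.
ms_from_disease_sets <- function(dt, ds, universe = names(dt)) {
  universe <- sort(unique(universe), method = "radix")
  dt <- lapply(setNames(universe, universe), function(m) {
    unique(dt[[m]] %||% character(0))
  })
  d_ids <- rownames(ds)
  n_d <- length(d_ids)
  m <- length(universe)
  sizes <- lengths(dt)

  # smat[d, u] = S(d, DT_u) = max over DT_u of DS[d, .]; 0 for empty DT_u
  smat <- vapply(dt, function(du) {
    if (length(du) == 0) return(numeric(n_d))
    apply(ds[, du, drop = FALSE], 1, max)
  }, numeric(n_d))
  if (n_d == 1) smat <- matrix(smat, nrow = 1, dimnames = list(d_ids, universe))

  # incidence[d, u] = 1 iff d in DT_u
  inc <- matrix(0, nrow = n_d, ncol = m, dimnames = list(d_ids, universe))
  for (j in seq_len(m)) inc[dt[[j]], j] <- 1

  num <- crossprod(inc, smat)        # num[u, v] = sum_{d in DT_u} S(d, DT_v)
  denom <- outer(sizes, sizes, "+")
  ms <- (num + t(num)) / ifelse(denom == 0, 1, denom)
  ms[denom == 0] <- 0
  diag(ms) <- 1
  dimnames(ms) <- list(universe, universe)
  ms
}

#' Build the full miRNA functional-similarity matrix
#'
#' Computes MS(u, v) for every pair of miRNAs in the association set. The
#' pairwise fused disease similarities are computed once over the distinct
#' diseases and cached, so the matrix is deterministic in the inputs and
#' quadratic work happens on the (much smaller) disease set.
#'
#' @inheritParams mirna_functional_similarity
#' @param ontology An [as_ontology()] table covering the association
#'   diseases (pairs with unknown diseases are dropped with a message).
#' @param scheme,delta,lambda,phenotypes,mapping See [disease_similarity()].
#' @param ic Optional precomputed [compute_information_content()] table;
#'   computed from the ontology when the IC scheme is selected and `ic` is
#'   `NULL`.
#' @return A symmetric numeric matrix with unit diagonal and miRNA ids as
#'   dimnames.
#' @export
build_similarity_matrix <- function(associations, ontology,
                                    scheme = c("ic", "layer"), delta = 0.5,
                                    ic = NULL, phenotypes = NULL,
                                    mapping = NULL, lambda = 0.5) {
  scheme <- match.arg(scheme)
  ontology <- as_ontology(ontology)
  associations <- as_associations(associations, ontology = ontology)
  if (scheme == "ic" && is.null(ic)) {
    ic <- compute_information_content(ontology)
  }
  ds <- disease_similarity_matrix(
    ontology, unique(associations$disease_id),
    scheme = scheme, delta = delta, ic = ic,
    phenotypes = phenotypes, mapping = mapping, lambda = lambda
  )
  ms_from_disease_sets(disease_sets(associations), ds)
}
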