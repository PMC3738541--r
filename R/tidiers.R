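#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per disease and fold.
#'
#' @param x An `hdmp_cv` object.
#' @param ... Ignored.
#' @return A tibble `disease_id`, `fold`, `n_test`, `auc`.
#' @method tidy hdmp_cv
#' @export
tidy.hdmp_cv <- function(x, ...) as_tibble(x$folds)

#' One-row summary of a cross-validation result
#'
#' @param x An `hdmp_cv` object.
#' @param ... Ignored.
#' @return A tibble with `n_diseases`, `n_folds`, `mean_auc`.
#' @method glance hdmp_cv
#' @export
glance.hdmp_cv <- function(x, ...) {
  tibble(
    n_diseases = sum(x$diseases$status == "evaluated"),
    n_folds = x$config$n_folds,
    mean_auc = x$mean_auc
  )
}

#' Tidy a temporal hold-out report
#'
#' @param x An `hdmp_holdout` object.
#' @param ... Ignored.
#' @return The per-disease tibble.
#' @method tidy hdmp_holdout
#' @export
tidy.hdmp_holdout <- function(x, ...) as_tibble(x$diseases)

#' @method glance hdmp_holdout
#' @export
glance.hdmp_holdout <- function(x, ...) {
  tibble(n_diseases = sum(x$diseases$status == "evaluated"),
         mean_auc = x$mean_auc)
}

#' Tidy a ROC curve into its points
#'
#' @param x An `hdmp_roc` object.
#' @param ... Ignored.
#' @return A tibble `cutoff`, `fpr`, `tpr`.
#' @method tidy hdmp_roc
#' @export
tidy.hdmp_roc <- function(x, ...) x$points

#' @method glance hdmp_roc
#' @export
glance.hdmp_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a miRNA similarity matrix into long form
#'
#' @param x A symmetric similarity matrix with miRNA ids as dimnames.
#' @return A tibble `mirna_a`, `mirna_b`, `similarity` (upper triangle).
#' @export
similarity_long <- function(x) {
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(mirna_a = rownames(x)[idx[, 1]], mirna_b = colnames(x)[idx[, 2]],
         similarity = x[idx])
}
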