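#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_col labs theme_minimal coord_equal
NULL

#' Plot a ROC curve
#'
#' @param object An `hdmp_roc` from [roc_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot hdmp_roc
#' @export
autoplot.hdmp_roc <- function(object, ...) {
  ggplot(object$points, aes(x = fpr, y = tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#2c7fb8", linewidth = 0.8) +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Plot per-disease cross-validation AUCs
#'
#' One bar per evaluated disease plus a dashed line at the grand mean.
#'
#' @param object An `hdmp_cv` from [hdmp_cv()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot hdmp_cv
#' @export
autoplot.hdmp_cv <- function(object, ...) {
  d <- object$diseases[object$diseases$status == "evaluated", ]
  ggplot(d, aes(x = stats::reorder(disease_id, mean_auc), y = mean_auc)) +
    geom_col(fill = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = "dashed") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Mean cross-validated AUC",
         title = sprintf("Grand mean AUC = %.3f", object$mean_auc)) +
    theme_minimal()
}

#' Plot ranked candidate scores
#'
#' @param object An `hdmp_ranking` from [rank_candidates()].
#' @param top Number of top candidates to show, default 20.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot hdmp_ranking
#' @export
autoplot.hdmp_ranking <- function(object, top = 20, ...) {
  d <- head(as_tibble(object), top)
  ggplot(d, aes(x = stats::reorder(mirna_id, -rank), y = score)) +
    geom_col(fill = "#41ab5d") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Relevance score",
         title = paste0("Top candidates: ", attr(object, "disease"))) +
    theme_minimal()
}

#' Plot a parameter sweep
#'
#' @param sweep A tibble from [hdmp_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  ggplot(sweep, aes(x = value, y = mean_auc)) +
    geom_line(colour = "#2c7fb8") +
    geom_point() +
    labs(x = unique(sweep$param), y = "Mean AUC") +
    theme_minimal()
}
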