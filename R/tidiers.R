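# broom-style tidiers for the package's result objects.

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Long tibble: `repetition`, `metric`, `value`.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"repetition",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble with mean/sd of each metric, the pooled confusion counts
#'   and the run parameters.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  m <- x$metrics
  tibble(
    mean_accuracy = mean(m$accuracy), sd_accuracy = sd(m$accuracy),
    mean_sensitivity = mean(m$sensitivity), sd_sensitivity = sd(m$sensitivity),
    mean_specificity = mean(m$specificity), sd_specificity = sd(m$specificity),
    TP = x$confusion[["TP"]], FP = x$confusion[["FP"]],
    TN = x$confusion[["TN"]], FN = x$confusion[["FN"]],
    n_repetitions = x$n_repetitions, n_folds = x$n_folds, mode = x$mode
  )
}

#' Tidy a gene signature
#'
#' @param x A `gene_signature`.
#' @param ... Unused.
#' @return Tibble `gene`, `weight` (NA when weights were not computed),
#'   `rank`.
#' @method tidy gene_signature
#' @export
tidy.gene_signature <- function(x, ...) {
  weight <- if (is.null(x$weights)) {
    rep(NA_real_, length(x$genes))
  } else {
    w <- x$weights$weight[match(x$genes, x$weights$gene)]
    ifelse(is.na(w), 0, w)
  }
  tibble(gene = x$genes, weight = weight, rank = seq_along(x$genes))
}

#' @method glance gene_signature
#' @export
glance.gene_signature <- function(x, ...) {
  tibble(size = x$size, mean_accuracy = x$mean_accuracy,
         se_accuracy = x$se_accuracy,
         accuracy_threshold = x$accuracy_threshold)
}

#' Tidy an RFE trace
#'
#' @param x An `rfe_trace`.
#' @param ... Unused.
#' @return Tibble `round`, `size`, `mean_accuracy`, `se_accuracy`.
#' @method tidy rfe_trace
#' @export
tidy.rfe_trace <- function(x, ...) {
  tibble(round = x$round, size = x$size,
         mean_accuracy = x$mean_accuracy, se_accuracy = x$se_accuracy)
}

#' Tidy a PCA projection
#'
#' @param x A `pca_projection`.
#' @param ... Unused.
#' @return The coordinates tibble.
#' @method tidy pca_projection
#' @export
tidy.pca_projection <- function(x, ...) x$coordinates

#' @method glance pca_projection
#' @export
glance.pca_projection <- function(x, ...) {
  tibble(eigenvalue_1 = x$eigenvalues[1L],
         eigenvalue_2 = if (length(x$eigenvalues) > 1L) x$eigenvalues[2L] else NA_real_,
         total_variance = x$total_variance)
}
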