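# ggplot2 displays for the package's result objects.

#' Plot a cross-validated accuracy distribution
#'
#' Histogram of per-repetition CV accuracy with the mean marked by a
#' dashed line.
#'
#' @param object An `evaluation_report`.
#' @param binwidth Histogram bin width (default 0.02).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, binwidth = 0.02, ...) {
  m <- object$metrics
  ggplot2::ggplot(m, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = mean(m$accuracy), linetype = "dashed") +
    ggplot2::labs(x = sprintf("accuracy (%d x %d-fold CV)",
                              object$n_repetitions, object$n_folds),
                  y = "repetitions") +
    ggplot2::theme_minimal()
}

#' Plot classification accuracy along the RFE path
#'
#' Mean CV accuracy (with one-SE ribbon) against the number of active
#' genes in each elimination round.
#'
#' @param object An `rfe_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rfe_trace
#' @export
autoplot.rfe_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_accuracy - .data$se_accuracy,
                                      ymax = .data$mean_accuracy + .data$se_accuracy),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genes in signature", y = "mean CV accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a two-component PCA projection of samples
#'
#' @param object A `pca_projection`.
#' @param ... Unused.
#' @return A ggplot object; points coloured by disease class when
#'   available.
#' @method autoplot pca_projection
#' @export
autoplot.pca_projection <- function(object, ...) {
  df <- object$coordinates
  aes <- if ("disease_class" %in% names(df)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$disease_class)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (eigenvalue %.2f)", object$eigenvalues[1L]),
      y = sprintf("PC2 (eigenvalue %.2f)",
                  if (length(object$eigenvalues) > 1L) object$eigenvalues[2L] else NA)) +
    ggplot2::theme_minimal()
}

#' Overlay two signatures' accuracy distributions
#'
#' Side-by-side comparison of the CV accuracy distributions of two
#' signatures, each with its mean as a dashed line.
#'
#' @param a,b `evaluation_report` objects.
#' @param names Labels for the two reports.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_accuracy_comparison <- function(a, b, names = c("signature A", "signature B"),
                                     binwidth = 0.02) {
  df <- dplyr::bind_rows(
    tibble(signature = names[1L], accuracy = a$metrics$accuracy),
    tibble(signature = names[2L], accuracy = b$metrics$accuracy)
  )
  means <- dplyr::summarise(dplyr::group_by(df, .data$signature),
                            mean = mean(.data$accuracy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy, fill = .data$signature)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "identity", alpha = 0.5) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean,
                                     colour = .data$signature),
                        linetype = "dashed") +
    ggplot2::labs(x = "accuracy", y = "repetitions") +
    ggplot2::theme_minimal()
}
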