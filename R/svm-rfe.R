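# Linear soft-margin SVM, recursive feature elimination (Guyon et al. 2002
# style: rank by squared hyperplane weights), one-standard-error parsimonious
# signature selection, and resampled selection-frequency gene weights.

#' Train a linear soft-margin SVM
#'
#' Thin wrapper around [e1071::svm()] (linear kernel, no internal scaling)
#' that extracts the primal hyperplane: `w` (one weight per gene) and bias
#' `b`, oriented so that `w . x + b > 0` predicts the second factor level
#' (the case/disease class).
#'
#' @param x Samples x genes numeric matrix (genes should be standardized).
#' @param y Two-level factor, control level first.
#' @param cost Soft-margin cost parameter (default 1).
#' @return An object of class `linear_svm` with elements `w`, `b`, `cost`
#'   and `levels`.
#' @export
train_linear_svm <- function(x, y, cost = 1) {
  y <- as_two_level(y, nrow(x))
  if (length(unique(y)) < 2L) {
    abort("training labels contain a single class")
  }
  check_number(cost, "cost", lower = 1e-12)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value towards the first class it encounters;
  # normalize so positive decisions mean the second (case) level.
  f <- drop(x %*% w + b)
  agree <- mean((f > 0) == (fit$fitted == levels(y)[2L]))
  if (agree < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(w = setNames(as.numeric(w), colnames(x)), b = b,
                 cost = cost, levels = levels(y)),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  f <- drop(as.matrix(newdata)[, names(object$w), drop = FALSE] %*% object$w + object$b)
  factor(object$levels[(f > 0) + 1L], levels = object$levels)
}

#' Feature importance of a linear SVM
#'
#' RFE ranking criterion: the squared hyperplane weight of each gene.
#'
#' @param model A `linear_svm` object.
#' @return Named numeric vector of scores (higher = more important).
#' @export
rank_features <- function(model) {
  stopifnot(inherits(model, "linear_svm"))
  model$w^2
}

# Row-standardize `x` using the statistics of the columns in `train_idx`,
# applying the frozen transform to all columns (prevents train/test leakage).
standardize_by_train <- function(x, train_idx) {
  tr <- x[, train_idx, drop = FALSE]
  mu <- rowMeans(tr)
  sdev <- sqrt(rowSums((tr - mu)^2) / (ncol(tr) - 1L))
  sdev[sdev == 0] <- 1
  (x - mu) / sdev
}

# Class-stratified fold assignment; every class must have >= k samples.
stratified_folds <- function(labels, k) {
  f <- as.factor(labels)
  if (any(table(f) < k)) {
    abort(sprintf("every class needs >= %d samples for %d-fold CV; use a smaller k", k, k))
  }
  folds <- integer(length(f))
  for (lev in levels(f)) {
    idx <- which(f == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# One full repetition of stratified k-fold CV: returns pooled confusion
# counts (tp, fp, tn, fn) with the second label level as positive.
cv_one_repetition <- function(x, labels, k, cost, genes = NULL,
                              nested = FALSE, nested_args = list()) {
  folds <- stratified_folds(labels, k)
  tp <- fp <- tn <- fn <- 0L
  pos <- levels(labels)[2L]
  for (fold in seq_len(k)) {
    test_idx <- which(folds == fold)
    train_idx <- which(folds != fold)
    active <- genes %||% rownames(x)
    if (nested) {
      tr <- do.call(svm_rfe, c(list(x = x[, train_idx, drop = FALSE],
                                    labels = labels[train_idx],
                                    cost = cost, seed = NULL),
                               nested_args))
      active <- select_parsimonious_signature(tr)$genes
    }
    xs <- standardize_by_train(x[active, , drop = FALSE], train_idx)
    model <- train_linear_svm(t(xs[, train_idx, drop = FALSE]),
                              labels[train_idx], cost = cost)
    pred <- predict(model, t(xs[, test_idx, drop = FALSE]))
    truth <- labels[test_idx]
    tp <- tp + sum(pred == pos & truth == pos)
    fp <- fp + sum(pred == pos & truth != pos)
    tn <- tn + sum(pred != pos & truth != pos)
    fn <- fn + sum(pred != pos & truth == pos)
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Recursive feature elimination with a linear SVM
#'
#' In each round the classifier is trained on all pooled samples, genes are
#' ranked by squared hyperplane weight, and the lowest-ranked
#' `ceiling(drop_fraction * n)` genes are removed (minimum one; one gene at
#' a time once at most `single_step_below` genes remain), until a single
#' gene is left.  Each round's classification accuracy is estimated by
#' repeated stratified cross-validation restricted to the round's active
#' genes.  Ties in the ranking are broken by input gene order, making the
#' trace deterministic for a fixed seed.
#'
#' @param x Genes x samples log2 expression matrix.
#' @param labels Two-level factor over columns, control level first.
#' @param cost SVM soft-margin cost (default 1).
#' @param drop_fraction Fraction of active genes removed per round
#'   (default 0.1).
#' @param single_step_below Active-set size at or below which genes are
#'   removed one at a time (default 50).
#' @param cv_folds,cv_repeats Folds and repetitions of the per-round CV
#'   (defaults 5 and 10).
#' @param seed Integer seed driving all fold draws.
#' @param track_cv If `FALSE`, skip the per-round CV (used when only the
#'   elimination path is needed, e.g. for selection-frequency weights).
#' @return A tibble of class `rfe_trace`: one row per round with `round`,
#'   `size`, `genes` (list-column), `accuracy` (list-column of per-repetition
#'   accuracies), `mean_accuracy`, `se_accuracy`.
#' @export
svm_rfe <- function(x, labels, cost = 1, drop_fraction = 0.1,
                    single_step_below = 50L, cv_folds = 5L, cv_repeats = 10L,
                    seed = NULL, track_cv = TRUE) {
  if (nrow(x) < 2L) abort("RFE needs at least 2 genes")
  check_number(drop_fraction, "drop_fraction", lower = 1e-9, upper = 1)
  labels <- as_two_level(labels, ncol(x))
  gene_order <- rownames(x)
  active <- gene_order
  rounds <- list()
  round_no <- 0L
  repeat {
    round_no <- round_no + 1L
    xa <- x[active, , drop = FALSE]
    xs <- standardize_by_train(xa, seq_len(ncol(xa)))
    model <- train_linear_svm(t(xs), labels, cost = cost)
    acc <- rep(NA_real_, 0)
    if (track_cv) {
      acc <- with_local_seed(
        if (is.null(seed)) NULL else derive_seed(seed, paste0("rfe_cv_", round_no)),
        vapply(seq_len(cv_repeats), function(b) {
          cm <- cv_one_repetition(xa, labels, k = cv_folds, cost = cost)
          (cm[["tp"]] + cm[["tn"]]) / sum(cm)
        }, numeric(1))
      )
    }
    rounds[[round_no]] <- list(
      round = round_no, size = length(active), genes = active,
      accuracy = acc,
      mean_accuracy = if (track_cv) mean(acc) else NA_real_,
      se_accuracy = if (track_cv && length(acc) > 1L) sd(acc) / sqrt(length(acc)) else NA_real_
    )
    if (length(active) == 1L) break
    scores <- rank_features(model)
    n_drop <- if (length(active) <= single_step_below) 1L else {
      max(1L, ceiling(drop_fraction * length(active)))
    }
    n_drop <- min(n_drop, length(active) - 1L)
    ord <- order(scores, match(active, gene_order))
    active <- active[-ord[seq_len(n_drop)]]
    # keep original gene order within the active set for deterministic ties
    active <- gene_order[gene_order %in% active]
  }
  out <- tibble(
    round = vapply(rounds, `[[`, integer(1), "round"),
    size = vapply(rounds, `[[`, integer(1), "size"),
    genes = lapply(rounds, `[[`, "genes"),
    accuracy = lapply(rounds, `[[`, "accuracy"),
    mean_accuracy = vapply(rounds, `[[`, numeric(1), "mean_accuracy"),
    se_accuracy = vapply(rounds, `[[`, numeric(1), "se_accuracy")
  )
  attr(out, "cost") <- cost
  attr(out, "levels") <- levels(labels)
  attr(out, "x") <- x
  attr(out, "labels") <- labels
  class(out) <- c("rfe_trace", class(out))
  out
}

#' Select the parsimonious signature from an RFE trace
#'
#' One-standard-error rule: with `A*` the maximum mean CV accuracy over
#' rounds and `SE*` the standard error of that round's accuracy samples,
#' the selected signature is the smallest round whose mean accuracy is at
#' least `A* - SE*`.
#'
#' @param trace An `rfe_trace` from [svm_rfe()] with CV tracking.
#' @return An object of class `gene_signature`: `genes`, `size`, `weights`
#'   (populated later by [selection_frequency_weights()] or
#'   [discover_signature()]), the final trained `model`, and the accuracy
#'   summary of the selected round.
#' @export
select_parsimonious_signature <- function(trace) {
  stopifnot(inherits(trace, "rfe_trace"))
  if (all(is.na(trace$mean_accuracy))) {
    abort("trace has no CV accuracies; rerun svm_rfe() with track_cv = TRUE")
  }
  best <- which.max(trace$mean_accuracy)
  a_star <- trace$mean_accuracy[best]
  se_star <- trace$se_accuracy[best]
  if (is.na(se_star)) se_star <- 0
  eligible <- which(trace$mean_accuracy >= a_star - se_star)
  pick <- eligible[which.min(trace$size[eligible])]
  genes <- trace$genes[[pick]]

  x <- attr(trace, "x")
  labels <- attr(trace, "labels")
  model <- NULL
  if (!is.null(x)) {
    xs <- standardize_by_train(x[genes, , drop = FALSE], seq_len(ncol(x)))
    model <- train_linear_svm(t(xs), labels, cost = attr(trace, "cost") %||% 1)
  }
  structure(
    list(genes = genes, size = length(genes), weights = NULL, model = model,
         mean_accuracy = trace$mean_accuracy[pick],
         se_accuracy = trace$se_accuracy[pick],
         accuracy_threshold = a_star - se_star,
         levels = attr(trace, "levels")),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %d genes (round mean CV accuracy %.3f)\n",
              x$size, x$mean_accuracy))
  print(head(tidy(x), 10))
  invisible(x)
}

#' Selection-frequency gene weights
#'
#' The full RFE is re-run on stratified bootstrap resamples of the cohort;
#' a gene's weight is the fraction of resamples in which it survives to the
#' round of the target signature size.  Weights measure the stability of a
#' gene's membership in the signature.
#'
#' @param x Genes x samples matrix.
#' @param labels Two-level factor over columns.
#' @param target_size Signature size at which membership is counted.
#' @param n_resamples Number of bootstrap resamples (default 100).
#' @param cost,drop_fraction,single_step_below Passed to [svm_rfe()].
#' @param seed Integer seed.
#' @return Tibble with columns `gene` and `weight` (only genes with
#'   weight > 0), sorted by non-increasing weight.
#' @export
selection_frequency_weights <- function(x, labels, target_size,
                                        n_resamples = 100L, cost = 1,
                                        drop_fraction = 0.1,
                                        single_step_below = 50L,
                                        seed = NULL) {
  check_number(target_size, "target_size", lower = 1)
  labels <- as_two_level(labels, ncol(x))
  counts <- setNames(numeric(nrow(x)), rownames(x))
  with_local_seed(seed, {
    for (r in seq_len(n_resamples)) {
      idx <- unlist(lapply(levels(labels), function(lev) {
        pool <- which(labels == lev)
        sample(pool, length(pool), replace = TRUE)
      }), use.names = FALSE)
      tr <- svm_rfe(x[, idx, drop = FALSE], labels[idx], cost = cost,
                    drop_fraction = drop_fraction,
                    single_step_below = single_step_below,
                    track_cv = FALSE)
      ok <- which(tr$size >= target_size)
      sel <- tr$genes[[ok[length(ok)]]]
      counts[sel] <- counts[sel] + 1
    }
  })
  out <- tibble(gene = names(counts), weight = unname(counts) / n_resamples)
  out <- out[out$weight > 0, , drop = FALSE]
  out[order(-out$weight, match(out$gene, rownames(x))), ]
}

#' Discover a parsimonious gene signature for a disease contrast
#'
#' High-level wrapper: restricts the cohort to the contrast's samples (and
#' optionally to an analysis gene set), runs [svm_rfe()] on the pooled
#' samples, applies the one-standard-error parsimony rule, and attaches
#' selection-frequency weights at the selected size.
#'
#' @param x Genes x samples log2 expression matrix.
#' @param phenotypes Phenotype tibble (`sample_id`, `disease_class`,
#'   `population`).
#' @param case,control Disease classes contrasted.
#' @param genes Optional analysis gene set (e.g. the cross-population union
#'   of differentially-expressed genes); default all genes in `x`.
#' @param population Optional population filter.
#' @param cost,drop_fraction,cv_folds,cv_repeats Passed to [svm_rfe()].
#' @param n_resamples Bootstrap resamples for the weights; `0` skips them.
#' @param seed Integer seed.
#' @return A `gene_signature` with its genes ordered by non-increasing
#'   selection-frequency weight, the full resampled weight table in
#'   `$weights` (which may mention genes outside the final signature), and
#'   the `rfe_trace` attached as attribute `trace`.
#' @export
discover_signature <- function(x, phenotypes, case, control,
                               genes = NULL, population = NULL,
                               cost = 1, drop_fraction = 0.1,
                               cv_folds = 5L, cv_repeats = 10L,
                               n_resamples = 100L, seed = NULL) {
  ph <- validate_phenotypes(phenotypes)
  keep <- ph$disease_class %in% c(case, control)
  if (!is.null(population)) keep <- keep & ph$population %in% population
  ph <- ph[keep, , drop = FALSE]
  xs <- x[, ph$sample_id, drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(xs))
    if (length(missing) > 0) {
      abort(sprintf("analysis-set gene(s) absent from matrix: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    xs <- xs[genes, , drop = FALSE]
  }
  labels <- factor(ph$disease_class, levels = c(control, case))
  trace <- svm_rfe(xs, labels, cost = cost, drop_fraction = drop_fraction,
                   cv_folds = cv_folds, cv_repeats = cv_repeats,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, "rfe"))
  sig <- select_parsimonious_signature(trace)
  if (n_resamples > 0) {
    w <- selection_frequency_weights(
      xs, labels, target_size = sig$size, n_resamples = n_resamples,
      cost = cost, drop_fraction = drop_fraction,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "weights"))
    sig$weights <- w
    # signature genes ordered by non-increasing selection frequency
    wg <- w$weight[match(sig$genes, w$gene)]
    wg[is.na(wg)] <- 0
    sig$genes <- sig$genes[order(-wg, seq_along(sig$genes))]
  }
  attr(sig, "trace") <- trace
  sig
}
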