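# Repeated stratified cross-validated evaluation of a fixed gene signature,
# accuracy-distribution comparison, PCA projection and cross-cohort transfer.

#' Repeated stratified k-fold cross-validation of a gene signature
#'
#' Per repetition, a class-stratified k-fold partition is drawn; for each
#' fold a linear SVM is trained on the remaining folds restricted to the
#' signature genes (gene standardization is computed on the training folds
#' and frozen), the held-out fold is predicted, and the k folds' confusion
#' counts are pooled into one accuracy / sensitivity / specificity triple.
#' Sensitivity is `TP / (TP + FN)` with the disease (second-level) class
#' positive.
#'
#' In `"fixed"` mode the gene set never changes (classifier weights are
#' still retrained inside every training split); `"nested"` mode re-runs
#' the full RFE selection inside each training split for an honest error
#' estimate of the whole selection procedure.
#'
#' @param x Genes x samples log2 expression matrix.
#' @param labels Two-level factor over columns, control level first.
#' @param genes Signature gene symbols (default: all rows of `x`).
#' @param k Folds (default 5).  Every class must have at least `k` samples.
#' @param B Repetitions (default 1000).
#' @param seed Integer seed.
#' @param cost SVM cost.
#' @param mode `"fixed"` (default) or `"nested"`.
#' @param nested_args List of arguments passed to [svm_rfe()] in nested
#'   mode (e.g. `drop_fraction`, `cv_repeats`).
#' @return An object of class `evaluation_report`: per-repetition `metrics`
#'   tibble, pooled `confusion` counts, and the run parameters.
#' @export
repeated_stratified_cv <- function(x, labels, genes = NULL, k = 5L, B = 1000L,
                                   seed = NULL, cost = 1,
                                   mode = c("fixed", "nested"),
                                   nested_args = list()) {
  mode <- match.arg(mode)
  labels <- as_two_level(labels, ncol(x))
  check_number(k, "k", lower = 2)
  check_number(B, "B", lower = 1)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing) > 0) {
      abort(sprintf("signature gene(s) absent from matrix: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  confusions <- with_local_seed(seed, {
    lapply(seq_len(B), function(b) {
      cv_one_repetition(x, labels, k = k, cost = cost, genes = genes,
                        nested = mode == "nested", nested_args = nested_args)
    })
  })
  cm <- do.call(rbind, confusions)
  metrics <- tibble(
    repetition = seq_len(B),
    accuracy = (cm[, "tp"] + cm[, "tn"]) / rowSums(cm),
    sensitivity = cm[, "tp"] / (cm[, "tp"] + cm[, "fn"]),
    specificity = cm[, "tn"] / (cm[, "tn"] + cm[, "fp"])
  )
  structure(
    list(metrics = metrics,
         confusion = c(TP = sum(cm[, "tp"]), FP = sum(cm[, "fp"]),
                       TN = sum(cm[, "tn"]), FN = sum(cm[, "fn"])),
         n_repetitions = B, n_folds = as.integer(k), mode = mode,
         positive = levels(labels)[2L], negative = levels(labels)[1L],
         genes = genes %||% rownames(x)),
    class = "evaluation_report"
  )
}

#' Evaluate a signature on a phenotyped cohort
#'
#' Convenience wrapper around [repeated_stratified_cv()] that builds the
#' binary contrast from a phenotype table.  `case` may name several disease
#' classes (e.g. `c("US", "CS")` for all sarcoidosis versus healthy
#' controls); they are pooled into one positive class.
#'
#' @param x Genes x samples matrix.
#' @param phenotypes Phenotype tibble.
#' @param genes Signature gene symbols or a `gene_signature`.
#' @param case,control Disease class(es) for the positive and negative
#'   groups.
#' @param population Optional population filter.
#' @param ... Passed to [repeated_stratified_cv()].
#' @return An `evaluation_report`.
#' @export
evaluate_signature <- function(x, phenotypes, genes, case, control,
                               population = NULL, ...) {
  if (inherits(genes, "gene_signature")) genes <- genes$genes
  ph <- validate_phenotypes(phenotypes)
  keep <- ph$disease_class %in% c(case, control)
  if (!is.null(population)) keep <- keep & ph$population %in% population
  ph <- ph[keep, , drop = FALSE]
  labels <- factor(ifelse(ph$disease_class %in% case, "case", "control"),
                   levels = c("control", "case"))
  repeated_stratified_cv(x[, ph$sample_id, drop = FALSE], labels,
                         genes = genes, ...)
}

#' @export
print.evaluation_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<evaluation_report> %s-mode, %d x %d-fold CV (positive = %s)\n",
    x$mode, x$n_repetitions, x$n_folds, x$positive))
  cat(sprintf("  accuracy    %.3f (sd %.3f)\n", g$mean_accuracy, g$sd_accuracy))
  cat(sprintf("  sensitivity %.3f\n", g$mean_sensitivity))
  cat(sprintf("  specificity %.3f\n", g$mean_specificity))
  invisible(x)
}

#' Compare two cross-validated accuracy distributions
#'
#' Welch (unequal-variance) two-sample t-test on the per-repetition
#' accuracy vectors of two evaluation reports, the comparison used to rank
#' competing signatures.  If both distributions are degenerate (zero
#' variance) the p-value is defined as 1 when the means agree and 0
#' otherwise, with a warning.
#'
#' @param a,b `evaluation_report` objects (or numeric accuracy vectors).
#' @return One-row tibble: `t_statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `mean_difference` (a minus b).
#' @export
compare_accuracy_distributions <- function(a, b) {
  acc_a <- if (inherits(a, "evaluation_report")) a$metrics$accuracy else as.numeric(a)
  acc_b <- if (inherits(b, "evaluation_report")) b$metrics$accuracy else as.numeric(b)
  if (length(acc_a) < 2L || length(acc_b) < 2L) {
    abort("both accuracy distributions need at least 2 samples")
  }
  if (sd(acc_a) == 0 && sd(acc_b) == 0) {
    warn("both accuracy distributions are degenerate (zero variance)")
    equal <- isTRUE(all.equal(mean(acc_a), mean(acc_b)))
    return(tibble(t_statistic = if (equal) 0 else Inf,
                  p_value = if (equal) 1 else 0,
                  mean_a = mean(acc_a), mean_b = mean(acc_b),
                  mean_difference = mean(acc_a) - mean(acc_b)))
  }
  tt <- t.test(acc_a, acc_b, var.equal = FALSE)
  tibble(t_statistic = unname(tt$statistic), p_value = tt$p.value,
         mean_a = mean(acc_a), mean_b = mean(acc_b),
         mean_difference = mean(acc_a) - mean(acc_b))
}

#' Project samples onto the top two principal components of a signature
#'
#' PCA of the gene-standardized signature submatrix (samples as
#' observations).  The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making projections
#' reproducible across platforms.
#'
#' @param x Genes x samples matrix.
#' @param genes Signature genes (default all; at least 2).
#' @param phenotypes Optional phenotype tibble; adds a `disease_class`
#'   column to the coordinates for plotting.
#' @return Object of class `pca_projection`: `coordinates` tibble
#'   (`sample_id`, `PC1`, `PC2`, optional `disease_class`), `eigenvalues`
#'   (top two), `total_variance`, and gene `loadings`.
#' @export
pca_projection <- function(x, genes = NULL, phenotypes = NULL) {
  if (!is.null(genes)) {
    if (inherits(genes, "gene_signature")) genes <- genes$genes
    x <- x[intersect(genes, rownames(x)), , drop = FALSE]
  }
  if (nrow(x) < 2L) abort("PCA projection needs at least 2 genes")
  if (ncol(x) < 3L) abort("PCA projection needs at least 3 samples")
  xs <- suppressWarnings(standardize_genes(x))
  pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
  n_pc <- min(2L, ncol(pc$rotation))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  coords <- tibble(sample_id = colnames(x),
                   PC1 = scores[, 1L],
                   PC2 = if (n_pc > 1L) scores[, 2L] else 0)
  if (!is.null(phenotypes)) {
    ph <- validate_phenotypes(phenotypes)
    coords$disease_class <- ph$disease_class[match(coords$sample_id, ph$sample_id)]
  }
  eig <- pc$sdev^2
  structure(
    list(coordinates = coords,
         eigenvalues = eig[seq_len(n_pc)],
         total_variance = sum(eig),
         loadings = loadings),
    class = "pca_projection"
  )
}

#' Transfer a signature to an independent validation cohort
#'
#' Mirrors the cross-platform validation design: both cohorts are
#' restricted to the signature genes shared by symbol and gene-standardized
#' independently (removing platform location/scale differences); a
#' classifier trained on the full training cohort is stored, and the
#' signature's discriminative power in the validation cohort is measured by
#' fixed-signature repeated stratified CV within that cohort.
#'
#' @param signature A `gene_signature` or character vector of genes.
#' @param train_x,train_labels Training cohort matrix and two-level factor.
#' @param test_x,test_labels Validation cohort matrix and two-level factor.
#' @param k,B,seed,cost Passed to [repeated_stratified_cv()].
#' @return An `evaluation_report` for the validation cohort, with the
#'   training-cohort classifier and its direct transfer accuracy on the
#'   validation samples in attributes `transfer_model` and
#'   `transfer_accuracy`.
#' @export
cross_cohort_evaluate <- function(signature, train_x, train_labels,
                                  test_x, test_labels,
                                  k = 5L, B = 200L, seed = NULL, cost = 1) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  present <- intersect(genes, rownames(test_x))
  missing <- setdiff(genes, present)
  if (length(present) < length(genes) / 2) {
    abort(sprintf("validation cohort shares only %d of %d signature genes (missing: %s)",
                  length(present), length(genes),
                  paste(head(missing, 10), collapse = ", ")))
  }
  if (length(missing) > 0) {
    inform(sprintf("proceeding without %d signature gene(s) absent from the validation cohort: %s",
                   length(missing), paste(missing, collapse = ", ")))
  }
  matched <- match_genes(train_x[present, , drop = FALSE],
                         test_x[present, , drop = FALSE])
  train_s <- suppressWarnings(standardize_genes(matched$x))
  test_s <- suppressWarnings(standardize_genes(matched$y))
  train_labels <- as_two_level(train_labels, ncol(train_s))
  test_labels <- as_two_level(test_labels, ncol(test_s))
  model <- train_linear_svm(t(train_s), train_labels, cost = cost)
  pred <- predict(model, t(test_s))
  transfer_acc <- mean(as.character(pred) == as.character(test_labels))
  report <- repeated_stratified_cv(test_s, test_labels, genes = present,
                                   k = k, B = B, seed = seed, cost = cost)
  attr(report, "transfer_model") <- model
  attr(report, "transfer_accuracy") <- transfer_acc
  report
}
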