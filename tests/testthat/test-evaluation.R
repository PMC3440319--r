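test_that("confusion arithmetic matches the metric definitions", {
  # direct ratios: TP=15 FN=2 TN=10 FP=2
  tp <- 15; fn <- 2; tn <- 10; fp <- 2
  expect_equal(tp / (tp + fn), 0.882, tolerance = 1e-3)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  co <- small_cohort(55, n_genes = 50, n_signature = 5,
                     n_per_class = c(HC = 10, US = 0, CS = 10))
  keep <- co$phenotypes$disease_class %in% c("HC", "CS")
  labels <- factor(co$phenotypes$disease_class[keep], levels = c("HC", "CS"))
  rep <- repeated_stratified_cv(co$expression[, keep], labels,
                                genes = co$truth$gene, B = 20, seed = 3)
  m <- rep$metrics
  # the accuracy identity holds for every repetition (pooled fold confusion)
  n <- sum(keep)
  expect_true(all(abs(m$accuracy * n - round(m$accuracy * n)) < 1e-9))
  expect_identical(sum(rep$confusion), 20L * n)
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 1))
  expect_true(all(m$sensitivity >= 0 & m$sensitivity <= 1))
  rm(acc)
})

test_that("repeated CV is reproducible and errors on undersized classes", {
  co <- small_cohort(56, n_genes = 40, n_signature = 4,
                     n_per_class = c(HC = 8, US = 0, CS = 8))
  keep <- co$phenotypes$disease_class %in% c("HC", "CS")
  labels <- factor(co$phenotypes$disease_class[keep], levels = c("HC", "CS"))
  x <- co$expression[, keep]
  r1 <- repeated_stratified_cv(x, labels, genes = co$truth$gene, B = 10, seed = 9)
  r2 <- repeated_stratified_cv(x, labels, genes = co$truth$gene, B = 10, seed = 9)
  expect_identical(r1$metrics, r2$metrics)
  expect_error(repeated_stratified_cv(x, labels, k = 9), "smaller k")
  expect_error(repeated_stratified_cv(x, labels, genes = "NOT_A_GENE"), "absent")
})

test_that("a strongly planted signature is nearly perfect; permuted labels are at chance", {
  co <- simulate_expression_cohort(expression_sim_config(
    n_genes = 100, n_signature = 10, n_per_class = c(HC = 20, US = 0, CS = 20),
    delta = 1, additive_factor = 2, noise_sd = 0.3, pop_shift_sd = 0, seed = 6))
  keep <- co$phenotypes$disease_class %in% c("HC", "CS")
  labels <- factor(co$phenotypes$disease_class[keep], levels = c("HC", "CS"))
  x <- co$expression[, keep]
  good <- repeated_stratified_cv(x, labels, genes = co$truth$gene, B = 50, seed = 2)
  expect_gte(mean(good$metrics$accuracy), 0.99)

  # averaged over several independent label permutations: a single fixed
  # relabelling can sit noticeably away from chance at this sample size
  null_acc <- vapply(1:5, function(s) {
    set.seed(10 + s)
    perm <- sample(labels)
    mean(repeated_stratified_cv(x, perm, genes = co$truth$gene,
                                B = 40, seed = 2)$metrics$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(null_acc) - 0.5), 0.06)
})

test_that("accuracy-distribution comparison is a Welch t-test with degenerate guard", {
  a <- c(0.80, 0.82, 0.84, 0.81, 0.83)
  b <- c(0.55, 0.60, 0.58, 0.57, 0.61)
  res <- compare_accuracy_distributions(a, b)
  # hand-computed Welch statistic
  se <- sqrt(var(a) / 5 + var(b) / 5)
  expect_equal(res$t_statistic, (mean(a) - mean(b)) / se, tolerance = 1e-10)
  expect_equal(res$mean_difference, mean(a) - mean(b), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)

  same <- compare_accuracy_distributions(a, a)
  expect_equal(same$mean_difference, 0)
  expect_gt(same$p_value, 0.999)

  expect_warning(deg <- compare_accuracy_distributions(rep(0.9, 5), rep(0.9, 5)),
                 "degenerate")
  expect_equal(deg$p_value, 1)
})

test_that("PCA projection satisfies spectral invariants and separates planted classes", {
  co <- simulate_expression_cohort(expression_sim_config(
    n_genes = 100, n_signature = 10, n_per_class = c(HC = 20, US = 10, CS = 20),
    delta = 0.75, additive_factor = 2, noise_sd = 0.5, pop_shift_sd = 0, seed = 14))
  pp <- pca_projection(co$expression, co$truth$gene, co$phenotypes)
  expect_true(pp$eigenvalues[1] >= pp$eigenvalues[2])
  expect_true(all(pp$eigenvalues >= 0))
  expect_lte(sum(pp$eigenvalues), pp$total_variance + 1e-8)

  # CS and HC centroids separate along PC1 relative to within-class spread
  cc <- pp$coordinates
  cs <- cc$PC1[cc$disease_class == "CS"]
  hc <- cc$PC1[cc$disease_class == "HC"]
  pooled_sd <- sqrt((var(cs) + var(hc)) / 2)
  expect_gt(abs(mean(cs) - mean(hc)), 2 * pooled_sd)

  # duplicated samples land on identical coordinates
  x2 <- cbind(co$expression, DUP = co$expression[, 1])
  pp2 <- pca_projection(x2, co$truth$gene)
  first <- pp2$coordinates[1, c("PC1", "PC2")]
  dup <- pp2$coordinates[pp2$coordinates$sample_id == "DUP", c("PC1", "PC2")]
  expect_equal(unlist(dup), unlist(first), ignore_attr = TRUE)

  expect_error(pca_projection(co$expression[1, , drop = FALSE]), "2 genes")
})

test_that("cross-cohort transfer is invariant to per-gene affine distortion", {
  co <- simulate_expression_cohort(expression_sim_config(
    n_genes = 80, n_signature = 8, n_per_class = c(HC = 20, US = 0, CS = 20),
    delta = 0.75, additive_factor = 2, pop_shift_sd = 0, seed = 33))
  keep <- co$phenotypes$disease_class %in% c("HC", "CS")
  labels <- factor(co$phenotypes$disease_class[keep], levels = c("HC", "CS"))
  x <- co$expression[, keep]
  genes <- co$truth$gene

  within <- repeated_stratified_cv(x, labels, genes = genes, B = 50, seed = 8)
  # validation cohort = affine-distorted copy (platform shift/rescale per gene)
  set.seed(19)
  shift <- rnorm(nrow(x), 0, 3)
  scale <- runif(nrow(x), 0.5, 2)
  x_val <- x * scale + shift
  colnames(x_val) <- paste0("V", seq_len(ncol(x_val)))
  transfer <- cross_cohort_evaluate(genes, x, labels, x_val, labels,
                                    B = 50, seed = 8)
  expect_lt(abs(mean(transfer$metrics$accuracy) - mean(within$metrics$accuracy)),
            0.05)
  expect_gt(attr(transfer, "transfer_accuracy"), 0.9)

  # missing genes are tolerated up to half the signature, then error
  x_missing <- x_val[setdiff(rownames(x_val), genes[1]), ]
  expect_message(cross_cohort_evaluate(genes, x, labels, x_missing, labels,
                                       B = 5, seed = 1), "proceeding without")
  x_few <- x_val[setdiff(rownames(x_val), genes[1:5]), ]
  expect_error(cross_cohort_evaluate(genes, x, labels, x_few, labels),
               "shares only")
})

test_that("random validation labels give chance-level transfer", {
  co <- simulate_expression_cohort(expression_sim_config(
    n_genes = 60, n_signature = 6, n_per_class = c(HC = 20, US = 0, CS = 20),
    delta = 1, additive_factor = 2, pop_shift_sd = 0, seed = 44))
  keep <- co$phenotypes$disease_class %in% c("HC", "CS")
  labels <- factor(co$phenotypes$disease_class[keep], levels = c("HC", "CS"))
  x <- co$expression[, keep]
  acc <- vapply(1:4, function(s) {
    set.seed(s)
    rand_labels <- factor(sample(rep(c("HC", "CS"), each = ncol(x) / 2)),
                          levels = c("HC", "CS"))
    r <- cross_cohort_evaluate(co$truth$gene, x, labels, x, rand_labels,
                               B = 40, seed = 5)
    mean(r$metrics$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.08)
})

test_that("tidiers and autoplot methods produce the documented shapes", {
  co <- small_cohort(61, n_genes = 40, n_signature = 4,
                     n_per_class = c(HC = 8, US = 0, CS = 8))
  keep <- co$phenotypes$disease_class %in% c("HC", "CS")
  labels <- factor(co$phenotypes$disease_class[keep], levels = c("HC", "CS"))
  r <- repeated_stratified_cv(co$expression[, keep], labels,
                              genes = co$truth$gene, B = 5, seed = 1)
  long <- tidy(r)
  expect_identical(nrow(long), 15L)
  expect_identical(names(glance(r))[1], "mean_accuracy")
  expect_s3_class(autoplot(r), "ggplot")

  tr <- svm_rfe(co$expression[1:10, keep], labels, cv_repeats = 2, seed = 1)
  expect_s3_class(autoplot(tr), "ggplot")
  pp <- pca_projection(co$expression, co$truth$gene, co$phenotypes)
  expect_s3_class(autoplot(pp), "ggplot")
  expect_s3_class(plot_accuracy_comparison(r, r), "ggplot")
})
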