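# Two-class unpaired moderated d-statistic with permutation-based q-values,
# in the style of Significance Analysis of Microarrays (Tusher et al. 2001)
# with q-value FDR estimation following Storey & Tibshirani (2003).

# Per-gene mean difference and pooled standard error for one or many binary
# splits at once.  `group2` is an n x B indicator matrix of case membership;
# returns list of genes x B matrices.
sam_stats_matrix <- function(x, group2, n1, n2) {
  total <- rowSums(x)
  totsq <- rowSums(x^2)
  sum2 <- x %*% group2
  mean2 <- sum2 / n2
  mean1 <- (total - sum2) / n1
  sumsq2 <- (x^2) %*% group2
  ss2 <- sumsq2 - n2 * mean2^2
  ss1 <- (totsq - sumsq2) - n1 * mean1^2
  # numerical guard: sums of squares are non-negative by definition
  ss1[ss1 < 0] <- 0
  ss2[ss2 < 0] <- 0
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(diff = mean2 - mean1, s = s)
}

split_indicator <- function(labels) {
  f <- as_two_level(labels, length(labels))
  idx2 <- as.integer(f) == 2L
  n1 <- sum(!idx2); n2 <- sum(idx2)
  if (n1 < 2L || n2 < 2L) {
    abort("each group needs at least 2 samples for the d-statistic")
  }
  list(f = f, idx2 = idx2, n1 = n1, n2 = n2)
}

#' SAM moderated d-statistic
#'
#' For each gene, `d = (mean2 - mean1) / (s + s0)` where `s` is the pooled
#' two-sample standard error of the mean difference and `s0` a small
#' "fudge" constant that damps the statistic for genes with tiny variance.
#' Orientation is second factor level minus first (case minus control when
#' labels are `factor(..., levels = c(control, case))`).
#'
#' @param x Expression matrix (genes x samples), log2 scale.
#' @param labels Two-level factor over the columns of `x`.
#' @param s0 Non-negative fudge constant (default 0, which makes `d` the
#'   classical equal-variance two-sample t statistic).
#' @return Tibble with columns `gene`, `d`, `s`.
#' @export
sam_d_statistic <- function(x, labels, s0 = 0) {
  check_number(s0, "s0", lower = 0)
  sp <- split_indicator(labels)
  st <- sam_stats_matrix(x, matrix(as.numeric(sp$idx2), ncol = 1L), sp$n1, sp$n2)
  denom <- st$s[, 1L] + s0
  d <- st$diff[, 1L] / denom
  if (any(denom == 0)) {
    warn(sprintf("%d gene(s) with zero standard error; d set to 0", sum(denom == 0)))
    d[denom == 0] <- 0
  }
  tibble(gene = rownames(x), d = unname(d), s = unname(st$s[, 1L]))
}

#' Estimate the SAM fudge constant s0
#'
#' Follows the SAM convention: candidate values are the percentiles
#' 0, 5, ..., 100 of the per-gene standard errors; the chosen s0 minimizes
#' the coefficient of variation of the median absolute d across bins of
#' the standard error, making the d-statistic's spread independent of
#' gene-level variance.
#'
#' @param x Expression matrix (genes x samples).
#' @param labels Two-level factor over columns.
#' @param probs Candidate percentiles (default `seq(0, 1, 0.05)`).
#' @param n_bins Number of quantile bins of `s` (default 10).
#' @return The selected s0 (single number).  With fewer than 100 genes the
#'   percentile search is unstable and `median(s)` is returned with a
#'   warning.
#' @export
estimate_s0 <- function(x, labels, probs = seq(0, 1, by = 0.05), n_bins = 10L) {
  sp <- split_indicator(labels)
  st <- sam_stats_matrix(x, matrix(as.numeric(sp$idx2), ncol = 1L), sp$n1, sp$n2)
  s <- st$s[, 1L]
  diff <- st$diff[, 1L]
  if (length(s) < 100L) {
    warn("fewer than 100 genes; falling back to s0 = median(s)")
    return(unname(median(s)))
  }
  candidates <- unname(quantile(s, probs))
  bins <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(candidates, function(s0) {
    d <- diff / (s + s0)
    v <- tapply(abs(d), bins, median)
    if (mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  unname(candidates[which.min(cv)])
}

#' Permutation null distribution of the d-statistic
#'
#' Group labels are permuted uniformly at random and `d` recomputed with
#' the same s0 each round.  When the number of distinct label arrangements
#' `choose(n, n1)` does not exceed `n_permutations`, all arrangements are
#' enumerated instead (exhaustive mode), which makes small-cohort results
#' fully deterministic.
#'
#' @param x Expression matrix (genes x samples).
#' @param labels Two-level factor over columns.
#' @param n_permutations Number of random permutations (default 200).
#' @param s0 Fudge constant used for every permutation.
#' @param seed Integer seed for the random mode.
#' @return Matrix of null d values (permutations x genes) with attribute
#'   `exhaustive` (logical).
#' @export
permutation_null <- function(x, labels, n_permutations = 200L, s0 = 0, seed = NULL) {
  check_number(n_permutations, "n_permutations", lower = 1)
  sp <- split_indicator(labels)
  n <- length(sp$idx2)
  n_arrangements <- choose(n, sp$n2)
  exhaustive <- n_arrangements <= n_permutations
  group2_sets <- if (exhaustive) {
    combn(n, sp$n2, simplify = FALSE)
  } else {
    with_local_seed(seed, replicate(n_permutations, sample.int(n, sp$n2), simplify = FALSE))
  }
  m <- matrix(0, nrow = n, ncol = length(group2_sets))
  for (b in seq_along(group2_sets)) m[group2_sets[[b]], b] <- 1
  st <- sam_stats_matrix(x, m, sp$n1, sp$n2)
  denom <- st$s + s0
  d <- st$diff / denom
  d[denom == 0] <- 0
  out <- t(d)
  colnames(out) <- rownames(x)
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Permutation q-values for observed d-statistics
#'
#' For the threshold at each observed `|d|`, the false discovery rate is
#' estimated as `pi0 * V / R` where `R` is the number of observed `|d|` at
#' or above the threshold and `V` the permutation estimate of the null
#' exceedance count; the q-value of a gene is the minimum estimated FDR
#' over all thresholds at which the gene would be called (enforced
#' monotone: q is non-increasing in `|d|`).
#'
#' `counting = "mean"` averages the exceedance count over permutations
#' (the q-value-method estimator, default); `"median"` uses the SAM
#' per-permutation median count, a convention that is markedly
#' anti-conservative for the most extreme genes on complete-null data.
#' `pi0` is estimated as twice the fraction of observed d inside the
#' interquartile range of the pooled null (clipped to \[0, 1\]);
#' `pi0 = "one"` is the conservative alternative.
#'
#' @param d Observed d-statistics (one per gene).
#' @param null Null matrix from [permutation_null()] (permutations x genes).
#' @param pi0 `"estimate"` (default) or `"one"`.
#' @param counting `"mean"` (default) or `"median"`.
#' @return Numeric vector of q-values in `[0, 1]`, aligned with `d`.
#' @export
compute_q_values <- function(d, null,
                             pi0 = c("estimate", "one"),
                             counting = c("mean", "median")) {
  pi0 <- match.arg(pi0)
  counting <- match.arg(counting)
  if (!is.matrix(null) || ncol(null) != length(d)) {
    abort("null must be a permutations x genes matrix matching length(d)")
  }
  m <- length(d)
  n_perm <- nrow(null)
  abs_d <- abs(d)
  ord <- order(abs_d, seq_len(m), decreasing = TRUE)
  thresholds <- abs_d[ord]

  r_counts <- count_ge_sorted(sort(abs_d), thresholds)
  if (counting == "mean") {
    pooled <- sort(abs(as.vector(null)))
    v_counts <- count_ge_sorted(pooled, thresholds) / n_perm
  } else {
    per_perm <- vapply(seq_len(n_perm), function(b) {
      count_ge_sorted(sort(abs(null[b, ])), thresholds)
    }, numeric(m))
    v_counts <- apply(per_perm, 1L, median)
  }

  pi0_hat <- if (pi0 == "one") 1 else {
    iqr <- quantile(as.vector(null), c(0.25, 0.75))
    min(1, max(0, 2 * mean(d >= iqr[1] & d <= iqr[2])))
  }

  fdr <- pmin(1, pi0_hat * v_counts / r_counts)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Per-gene fold changes between two groups
#'
#' Ratio of group geometric means on the linear scale, case over control:
#' `2 ^ (mean2_log2 - mean1_log2)`.  Values below 1 denote down-regulation
#' in the case group.
#'
#' @param x Expression matrix (genes x samples).
#' @param labels Two-level factor over columns (control level first).
#' @param log2_scale Is `x` on the log2 scale (default `TRUE`)?  If
#'   `FALSE`, values must be positive and are log2-transformed (no offset)
#'   first.
#' @return Named numeric vector of fold changes.
#' @export
fold_changes <- function(x, labels, log2_scale = TRUE) {
  if (!log2_scale) {
    if (any(x <= 0)) abort("linear-scale fold changes require positive values")
    x <- log2(x)
  }
  f <- as_two_level(labels, ncol(x))
  idx2 <- as.integer(f) == 2L
  fc <- 2^(rowMeans(x[, idx2, drop = FALSE]) - rowMeans(x[, !idx2, drop = FALSE]))
  setNames(fc, rownames(x))
}

#' Differential expression by permutation d-statistic and q-value FDR
#'
#' Runs the full two-class unpaired analysis for one contrast: moderated
#' d-statistic (with automatic or fixed s0), permutation null, q-values,
#' fold changes, and the selection rule `q < q_threshold` and
#' `max(FC, 1/FC) > fc_threshold` (both strict).  The fold-change criterion
#' is applied symmetrically so that down-regulated genes (FC < 1) are
#' selected on the magnitude of their change.
#'
#' @param x Expression matrix (genes x samples), log2 scale.
#' @param phenotypes Phenotype tibble with `sample_id`, `disease_class`
#'   and `population` columns covering the columns of `x`.
#' @param case,control Disease classes contrasted (e.g. `"CS"` vs `"HC"`).
#' @param population Optional population filter (`"AA"` or `"EA"`).
#' @param fc_threshold Fold-change magnitude threshold (default 1.4).
#' @param q_threshold q-value threshold (default 0.05).
#' @param n_permutations Permutations for the null (default 200).
#' @param s0 `"auto"` (percentile search, default) or a fixed number.
#' @param pi0,counting Passed to [compute_q_values()].
#' @param seed Seed for the permutation stream.
#' @return A tibble of class `de_result` with columns `gene`, `d`, `s`,
#'   `fold_change`, `q_value`, `selected`, `direction`, plus attributes
#'   `s0`, `n_permutations`, `exhaustive` and `contrast`.
#' @export
differential_expression <- function(x, phenotypes, case, control,
                                    population = NULL,
                                    fc_threshold = 1.4, q_threshold = 0.05,
                                    n_permutations = 200L,
                                    s0 = "auto",
                                    pi0 = c("estimate", "one"),
                                    counting = c("mean", "median"),
                                    seed = NULL) {
  check_number(fc_threshold, "fc_threshold", lower = 1)
  check_number(q_threshold, "q_threshold", lower = 0, upper = 1)
  ph <- validate_phenotypes(phenotypes)
  keep <- ph$disease_class %in% c(case, control)
  if (!is.null(population)) keep <- keep & ph$population %in% population
  ph <- ph[keep, , drop = FALSE]
  missing <- setdiff(ph$sample_id, colnames(x))
  if (length(missing) > 0) {
    abort(sprintf("phenotype sample(s) absent from matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  xs <- x[, ph$sample_id, drop = FALSE]
  labels <- factor(ph$disease_class, levels = c(control, case))

  s0_used <- if (identical(s0, "auto")) {
    estimate_s0(xs, labels)
  } else {
    check_number(s0, "s0", lower = 0)
    s0
  }
  ds <- sam_d_statistic(xs, labels, s0 = s0_used)
  null <- permutation_null(xs, labels, n_permutations = n_permutations,
                           s0 = s0_used, seed = seed)
  q <- compute_q_values(ds$d, null, pi0 = pi0, counting = counting)
  fc <- fold_changes(xs, labels)

  out <- tibble(
    gene = ds$gene, d = ds$d, s = ds$s,
    fold_change = unname(fc),
    q_value = q,
    selected = q < q_threshold & pmax(fc, 1 / fc) > fc_threshold,
    direction = ifelse(fc >= 1, "up", "down")
  )
  attr(out, "s0") <- s0_used
  attr(out, "n_permutations") <- nrow(null)
  attr(out, "exhaustive") <- attr(null, "exhaustive")
  attr(out, "contrast") <- c(case = case, control = control,
                             population = if (is.null(population)) "all" else population)
  class(out) <- c("de_result", class(out))
  out
}

#' Genes passing the differential-expression selection rule
#'
#' @param de A `de_result` tibble from [differential_expression()].
#' @return Character vector of selected gene symbols.
#' @export
select_differential <- function(de) {
  stopifnot(is.data.frame(de), all(c("gene", "selected") %in% names(de)))
  de$gene[de$selected]
}

#' Union of gene lists in first-seen order
#'
#' Builds the cross-population analysis set: the deterministic union of
#' per-population differentially-expressed gene lists.
#'
#' @param ... Character vectors of gene symbols (or a single list of them).
#' @return Character vector, duplicates removed, first-seen order.
#' @export
union_analysis_set <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1L]]) && !is.character(lists[[1L]])) {
    lists <- lists[[1L]]
  }
  unique(unlist(lists, use.names = FALSE))
}
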