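# Shared fixtures: all synthetic, built in code at test time.

# A small three-class cohort with a planted signature.
small_cohort <- function(seed = 42, n_genes = 300, n_signature = 10,
                         n_per_class = c(HC = 14, US = 6, CS = 10), ...) {
  simulate_expression_cohort(expression_sim_config(
    n_genes = n_genes, n_signature = n_signature,
    n_per_class = n_per_class, seed = seed, ...))
}

# A tiny labelled matrix for hand-checked statistics: two groups of three.
tiny_two_group <- function() {
  x <- rbind(
    GA = c(1, 2, 3, 3, 4, 5),
    GB = c(5, 5, 5, 5, 5, 5) + c(0.1, -0.1, 0, 0.1, -0.1, 0)
  )
  colnames(x) <- paste0("S", 1:6)
  labels <- factor(rep(c("ctl", "case"), each = 3), levels = c("ctl", "case"))
  list(x = x, labels = labels)
}

# Deterministic annotation for a vector of genes.
toy_annotation <- function(genes, chrom = rep("1", length(genes)),
                           start = seq(1000, by = 10000, length.out = length(genes)),
                           width = 5000) {
  tibble::tibble(gene = genes, chrom = chrom, start = start, end = start + width)
}

write_tsv_file <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Classical pooled-variance two-sample t statistic (independent oracle).
oracle_t_stat <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / (n1 + n2 - 2)
  (mean(g2) - mean(g1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
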