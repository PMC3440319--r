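#' Configuration for a synthetic expression cohort
#'
#' Describes a three-class (HC / US / CS) two-population (AA / EA) cohort
#' with a planted gene signature.  Signature genes follow an additive
#' severity pattern on the log2 scale: uncomplicated cases (US) shift from
#' the healthy baseline by `delta` and complicated cases (CS) by
#' `additive_factor * delta`, with a configurable fraction of the signature
#' down-regulated in disease.  Remaining genes carry no class signal.
#'
#' @param n_genes Total number of genes.
#' @param n_signature Number of planted signature genes (autosomal).
#' @param n_per_class Named integer vector of sample counts for classes
#'   `HC`, `US`, `CS`.
#' @param populations Named fractions for populations `AA` and `EA`
#'   (must sum to 1); each class is split deterministically.
#' @param delta Log2 effect of US versus HC in planted genes (default 0.5,
#'   i.e. a 2-fold change for complicated cases with the default
#'   `additive_factor`, inside the fold-change range typical of reported
#'   peripheral-blood signatures).
#' @param additive_factor CS effect as a multiple of `delta` (default 2).
#' @param frac_down Fraction of signature genes down-regulated in disease
#'   (default 0.9, mirroring the predominance of down-regulation in
#'   complicated sarcoidosis).
#' @param noise_sd Residual log2 standard deviation per gene (default 0.5).
#' @param pop_shift_sd Standard deviation of per-gene population baseline
#'   shifts (default 0.3 log2 units).
#' @param frac_sex_chrom Fraction of non-signature genes placed on
#'   chromosomes X/Y so the sex-chromosome filter is exercised
#'   (default 0.05).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   log2 expression (defaults 7 and 1).
#' @param seed Integer seed; identical configurations are bit-reproducible.
#' @return A validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  n_signature = 20,
                                  n_per_class = c(HC = 35, US = 17, CS = 22),
                                  populations = c(AA = 0.5, EA = 0.5),
                                  delta = 0.5,
                                  additive_factor = 2,
                                  frac_down = 0.9,
                                  noise_sd = 0.5,
                                  pop_shift_sd = 0.3,
                                  frac_sex_chrom = 0.05,
                                  baseline_mean = 7,
                                  baseline_sd = 1,
                                  seed = 1L) {
  check_number(n_genes, "n_genes", lower = 1)
  check_number(n_signature, "n_signature", lower = 0, upper = n_genes)
  if (!all(c("HC", "US", "CS") %in% names(n_per_class))) {
    abort("n_per_class must name HC, US and CS")
  }
  if (any(n_per_class < 0)) abort("class counts must be >= 0")
  if (!all(c("AA", "EA") %in% names(populations)) ||
      abs(sum(populations) - 1) > 1e-8 || any(populations < 0)) {
    abort("populations must be non-negative AA/EA fractions summing to 1")
  }
  check_number(delta, "delta")
  check_number(additive_factor, "additive_factor")
  check_number(frac_down, "frac_down", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 1e-12)
  check_number(pop_shift_sd, "pop_shift_sd", lower = 0)
  check_number(frac_sex_chrom, "frac_sex_chrom", lower = 0, upper = 1)
  structure(
    list(n_genes = as.integer(n_genes), n_signature = as.integer(n_signature),
         n_per_class = n_per_class[c("HC", "US", "CS")],
         populations = populations[c("AA", "EA")],
         delta = delta, additive_factor = additive_factor,
         frac_down = frac_down, noise_sd = noise_sd,
         pop_shift_sd = pop_shift_sd, frac_sex_chrom = frac_sex_chrom,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         seed = as.integer(seed)),
    class = "expression_sim_config"
  )
}

#' Simulate an expression cohort with planted ground truth
#'
#' @param config An [expression_sim_config()].
#' @return A list with components `expression` (log2 genes x samples
#'   matrix), `phenotypes` (sample tibble), `annotation` (gene tibble with
#'   chrom/start/end), `truth` (per planted gene: direction and class
#'   effects) and the `config` itself.
#' @export
simulate_expression_cohort <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  cfg <- config
  if (any(cfg$n_per_class == 0)) {
    warn(sprintf("class(es) with zero samples: %s",
                 paste(names(cfg$n_per_class)[cfg$n_per_class == 0], collapse = ", ")))
  }
  with_local_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    # chromosome assignment: signature genes are autosomal by construction
    chrom <- sample(as.character(1:22), cfg$n_genes, replace = TRUE)
    autosomal <- seq_len(cfg$n_genes)
    sig_idx <- if (cfg$n_signature > 0) sort(sample(autosomal, cfg$n_signature)) else integer(0)
    non_sig <- setdiff(seq_len(cfg$n_genes), sig_idx)
    n_sex <- round(cfg$frac_sex_chrom * length(non_sig))
    if (n_sex > 0) {
      sex_idx <- sample(non_sig, n_sex)
      chrom[sex_idx] <- sample(c("X", "Y"), n_sex, replace = TRUE)
    }
    start <- sample.int(2e8, cfg$n_genes)
    width <- sample(5e3:2e5, cfg$n_genes, replace = TRUE)
    annotation <- tibble(gene = genes, chrom = chrom,
                         start = start, end = start + width)

    classes <- rep(c("HC", "US", "CS"), times = cfg$n_per_class)
    n_samples <- length(classes)
    population <- unlist(lapply(cfg$n_per_class, function(n) {
      n_aa <- round(cfg$populations[["AA"]] * n)
      rep(c("AA", "EA"), times = c(n_aa, n - n_aa))
    }), use.names = FALSE)
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    phenotypes <- tibble(sample_id = sample_ids, disease_class = classes,
                         population = population)

    baseline <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    pop_shift <- matrix(rnorm(cfg$n_genes * 2L, 0, cfg$pop_shift_sd),
                        ncol = 2L, dimnames = list(NULL, c("AA", "EA")))

    direction <- integer(cfg$n_genes)
    n_down <- round(cfg$frac_down * cfg$n_signature)
    direction[sig_idx] <- rep(c(-1L, 1L),
                              times = c(n_down, cfg$n_signature - n_down))
    class_mult <- c(HC = 0, US = 1, CS = cfg$additive_factor)[classes]
    effect <- outer(direction * cfg$delta, class_mult)  # genes x samples

    values <- baseline +
      effect +
      pop_shift[, population, drop = FALSE] +
      matrix(rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd), cfg$n_genes)
    dimnames(values) <- list(genes, sample_ids)

    sig_dir <- direction[sig_idx]
    truth <- tibble(
      gene = genes[sig_idx],
      direction = ifelse(sig_dir < 0, "down", "up"),
      effect_us = sig_dir * cfg$delta,
      effect_cs = sig_dir * cfg$additive_factor * cfg$delta
    )
    list(expression = values, phenotypes = phenotypes,
         annotation = annotation, truth = truth, config = cfg)
  })
}

#' Configuration for a synthetic case-control genotype panel
#'
#' Genotypes are minor-allele dosages drawn as Binomial(2, p) per individual
#' (Hardy-Weinberg sampling within group).  Planted SNPs differ between
#' cases and controls at a specified allelic odds ratio: given control minor
#' allele frequency p0, the case frequency is
#' `p1 = OR * p0 / (1 - p0 + OR * p0)`.
#'
#' @param n_snps Number of SNPs.
#' @param n_cases,n_controls Group sizes.
#' @param planted Tibble/data frame with columns `snp` (index in
#'   `1:n_snps`), `target_or` (> 0) and `control_maf` (in (0, 0.5]).
#' @param maf_range Range from which unplanted control MAFs are drawn.
#' @param seed Integer seed.
#' @return A validated list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_snps = 100,
                                n_cases = 500,
                                n_controls = 500,
                                planted = NULL,
                                maf_range = c(0.05, 0.5),
                                seed = 1L) {
  check_number(n_snps, "n_snps", lower = 1)
  check_number(n_cases, "n_cases", lower = 1)
  check_number(n_controls, "n_controls", lower = 1)
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    stopifnot(all(c("snp", "target_or", "control_maf") %in% names(planted)))
    if (any(planted$snp < 1 | planted$snp > n_snps)) {
      abort("planted$snp indices out of range")
    }
    if (any(planted$target_or <= 0)) abort("target_or must be > 0")
    if (any(planted$control_maf <= 0 | planted$control_maf > 0.5)) {
      abort("control_maf must lie in (0, 0.5]")
    }
  }
  structure(
    list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls), planted = planted,
         maf_range = maf_range, seed = as.integer(seed)),
    class = "genotype_sim_config"
  )
}

#' Case allele frequency implied by an allelic odds ratio
#'
#' @param p0 Control minor allele frequency.
#' @param target_or Allelic odds ratio (case vs control).
#' @return Case minor allele frequency `OR * p0 / (1 - p0 + OR * p0)`.
#' @export
case_allele_frequency <- function(p0, target_or) {
  p1 <- target_or * p0 / (1 - p0 + target_or * p0)
  if (any(p1 >= 1)) abort("implied case allele frequency >= 1; adjust OR/MAF")
  p1
}

#' Simulate a case-control genotype panel with planted associations
#'
#' @param config A [genotype_sim_config()].
#' @param positions Optional tibble with columns `snp_id`, `chrom`, `pos`
#'   (one row per SNP, in order) fixing the genomic placement, e.g. inside
#'   signature genes; random autosomal positions are generated otherwise.
#' @return List with `genotypes` (SNP x sample dosage matrix), `snp_info`
#'   (snp_id/chrom/pos tibble), `phenotypes` (sample_id/status tibble,
#'   status in {control, case}) and `truth` (planted SNPs with target OR
#'   and the implied allele frequencies).
#' @export
simulate_genotypes <- function(config, positions = NULL) {
  stopifnot(inherits(config, "genotype_sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    p0 <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
    p1 <- p0
    if (!is.null(cfg$planted)) {
      p0[cfg$planted$snp] <- cfg$planted$control_maf
      p1 <- p0
      p1[cfg$planted$snp] <- case_allele_frequency(cfg$planted$control_maf,
                                                   cfg$planted$target_or)
    }
    n <- cfg$n_cases + cfg$n_controls
    status <- rep(c("control", "case"), times = c(cfg$n_controls, cfg$n_cases))
    sample_ids <- sprintf("I%04d", seq_len(n))
    dos_ctrl <- matrix(rbinom(cfg$n_snps * cfg$n_controls, 2L, p0), nrow = cfg$n_snps)
    dos_case <- matrix(rbinom(cfg$n_snps * cfg$n_cases, 2L, p1), nrow = cfg$n_snps)
    genotypes <- cbind(dos_ctrl, dos_case)
    snp_ids <- sprintf("snp%05d", seq_len(cfg$n_snps))
    dimnames(genotypes) <- list(snp_ids, sample_ids)
    if (is.null(positions)) {
      snp_info <- tibble(snp_id = snp_ids,
                         chrom = sample(as.character(1:22), cfg$n_snps, replace = TRUE),
                         pos = sample.int(2e8, cfg$n_snps))
    } else {
      positions <- as_tibble(positions)
      stopifnot(all(c("snp_id", "chrom", "pos") %in% names(positions)),
                nrow(positions) == cfg$n_snps)
      snp_info <- positions
      dimnames(genotypes) <- list(snp_info$snp_id, sample_ids)
      snp_ids <- snp_info$snp_id
    }
    truth <- if (is.null(cfg$planted)) {
      tibble(snp_id = character(), target_or = numeric(),
             control_maf = numeric(), case_maf = numeric())
    } else {
      tibble(snp_id = snp_ids[cfg$planted$snp],
             target_or = cfg$planted$target_or,
             control_maf = cfg$planted$control_maf,
             case_maf = p1[cfg$planted$snp])
    }
    list(genotypes = genotypes, snp_info = snp_info,
         phenotypes = tibble(sample_id = sample_ids, status = status),
         truth = truth, config = cfg)
  })
}

#' Write a genotype panel to TSV
#'
#' Columns: `snp_id`, `chrom`, `pos`, then one dosage column per sample.
#'
#' @param genotypes SNP x sample dosage matrix.
#' @param snp_info Tibble with snp_id/chrom/pos.
#' @param path Output path.
#' @export
write_genotype_matrix <- function(genotypes, snp_info, path) {
  stopifnot(nrow(genotypes) == nrow(snp_info))
  df <- data.frame(snp_info[, c("snp_id", "chrom", "pos")], genotypes,
                   check.names = FALSE, row.names = NULL)
  readr::write_tsv(df, path)
  invisible(path)
}
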