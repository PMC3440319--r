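test_that("SNPs map to gene regions by containment, window and nearest gene", {
  ann <- tibble::tibble(gene = c("NOG", "FAR"), chrom = c("17", "17"),
                        start = c(100000, 500000), end = c(120000, 520000))
  snps <- tibble::tibble(
    snp_id = c("mid", "down5k", "far50k", "up2k", "otherchrom"),
    chrom = c("17", "17", "17", "17", "3"),
    pos = c(110000, 125000, 170000, 98000, 110000))
  m <- map_snps_to_genes(snps, ann, window = 10000)
  expect_identical(m$relationship,
                   c("intron", "downstream", "none", "upstream", "none"))
  expect_identical(m$gene[1:2], c("NOG", "NOG"))
  expect_true(is.na(m$gene[3]))

  # nearest gene wins when windows overlap
  ann2 <- tibble::tibble(gene = c("L", "R"), chrom = "1",
                         start = c(1000, 12000), end = c(2000, 13000))
  near <- map_snps_to_genes(tibble::tibble(snp_id = "s", chrom = "1", pos = 11000),
                            ann2, window = 10000)
  expect_identical(near$gene, "R")
})

test_that("allelic association reproduces the 2x2 odds ratio and chi-square oracle", {
  # dosage matrix engineered to give a=30 b=70 c=15 d=85
  make_geno <- function(case_minor, ctrl_minor, n_case = 50, n_ctrl = 50) {
    case <- c(rep(2, case_minor %/% 2), rep(case_minor %% 2, 1),
              rep(0, n_case - case_minor %/% 2 - 1))
    ctrl <- c(rep(2, ctrl_minor %/% 2), rep(ctrl_minor %% 2, 1),
              rep(0, n_ctrl - ctrl_minor %/% 2 - 1))
    rbind(snp1 = c(ctrl, case))
  }
  g <- make_geno(30, 15)
  colnames(g) <- sprintf("I%03d", seq_len(ncol(g)))
  status <- factor(rep(c("control", "case"), each = 50), levels = c("control", "case"))
  res <- allelic_association(g, status)
  expect_identical(c(res$a, res$b, res$c, res$d), c(30, 70, 15, 85))
  expect_equal(res$odds_ratio, 2550 / 1050, tolerance = 1e-12)
  # chi-square without continuity correction, brute-force formula oracle
  a <- 30; b <- 70; c <- 15; d <- 85; n <- a + b + c + d
  chi <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$p_value, pchisq(chi, df = 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_identical(res$test, "chisq")
})

test_that("null, zero-cell and monomorphic SNPs are handled by the documented rules", {
  status <- factor(rep(c("control", "case"), each = 40), levels = c("control", "case"))
  # identical allele frequencies: OR = 1, p ~ 1
  g_null <- rbind(s = rep(c(0, 1), 40))
  colnames(g_null) <- sprintf("I%03d", 1:80)
  res_null <- allelic_association(g_null, status)
  expect_equal(res_null$odds_ratio, 1, tolerance = 1e-12)
  expect_gt(res_null$p_value, 0.9)

  # a = 0 triggers Haldane-Anscombe: finite OR below 1
  g_zero <- rbind(s = c(rep(1, 10), rep(0, 30), rep(0, 40)))
  colnames(g_zero) <- sprintf("I%03d", 1:80)
  res_zero <- allelic_association(g_zero, status)
  expect_true(is.finite(res_zero$odds_ratio) && res_zero$odds_ratio < 1)

  # monomorphic SNP is flagged with p = 1, OR = 1
  g_mono <- rbind(s = rep(0, 80))
  colnames(g_mono) <- sprintf("I%03d", 1:80)
  res_mono <- allelic_association(g_mono, status)
  expect_true(res_mono$monomorphic)
  expect_equal(res_mono$p_value, 1)
  expect_equal(res_mono$odds_ratio, 1)

  # sparse tables fall back to Fisher's exact test
  g_sparse <- rbind(s = c(rep(0, 39), 1, rep(0, 38), 1, 1))
  colnames(g_sparse) <- sprintf("I%03d", 1:80)
  expect_identical(allelic_association(g_sparse, status)$test, "fisher")
})

test_that("significance filtering ranks by p within the threshold", {
  res <- tibble::tibble(snp_id = c("a", "b", "c"),
                        p_value = c(0.02, 0.005, 0.009))
  kept <- filter_significant(res, 0.01, contrast = "case_vs_control")
  expect_identical(kept$snp_id, c("b", "c"))
  expect_identical(unique(kept$contrast), "case_vs_control")
  none <- filter_significant(res, 0.001)
  expect_identical(nrow(none), 0L)
})

test_that("planted odds ratios are recovered and flow through the wrapper", {
  ors <- vapply(1:20, function(s) {
    g <- simulate_genotypes(genotype_sim_config(
      n_snps = 5, n_cases = 500, n_controls = 500,
      planted = tibble::tibble(snp = 1, target_or = 2.7, control_maf = 0.2),
      seed = 9000 + s))
    status <- factor(g$phenotypes$status, levels = c("control", "case"))
    allelic_association(g$genotypes, status)$odds_ratio[1]
  }, numeric(1))
  expect_lt(abs(mean(ors) - 2.7), 0.25)

  # end-to-end wrapper: planted SNP inside a gene region comes out significant
  g <- simulate_genotypes(genotype_sim_config(
    n_snps = 20, n_cases = 500, n_controls = 500,
    planted = tibble::tibble(snp = 1, target_or = 2.7, control_maf = 0.2),
    seed = 123))
  ann <- tibble::tibble(gene = "FKBP1A", chrom = g$snp_info$chrom[1],
                        start = g$snp_info$pos[1] - 500,
                        end = g$snp_info$pos[1] + 500)
  out <- associate_snps(g$genotypes, factor(g$phenotypes$status,
                                            levels = c("control", "case")),
                        g$snp_info, ann, p_threshold = 0.01)
  expect_true(g$snp_info$snp_id[1] %in% out$snp_id)
  expect_identical(out$gene[out$snp_id == g$snp_info$snp_id[1]], "FKBP1A")
})

test_that("genotype TSV and VCF readers agree on dosages", {
  g <- simulate_genotypes(genotype_sim_config(n_snps = 4, n_cases = 3,
                                              n_controls = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(g$genotypes, g$snp_info, path)
  rt <- read_genotype_matrix(path)
  expect_identical(unname(rt$genotypes), unname(g$genotypes))
  expect_identical(rt$snp_info$snp_id, g$snp_info$snp_id)

  skip_if_not_installed("vcfR")
  gt_code <- c("0/0", "0/1", "1/1")
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "I1", "I2", "I3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            gt_code[c(1, 2, 3)]), collapse = "\t"),
    paste(c("2", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            gt_code[c(3, 3, 1)]), collapse = "\t"))
  vcf_path <- write_tsv_file(vcf_lines, ext = ".vcf")
  v <- read_vcf_genotypes(vcf_path)
  expect_identical(unname(v$genotypes["rs1", ]), c(0L, 1L, 2L))
  expect_identical(unname(v$genotypes["rs2", ]), c(2L, 2L, 0L))
  expect_identical(v$snp_info$pos, c(100L, 200L))
})
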