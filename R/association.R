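# Case-control allelic association of SNPs mapped to signature-gene regions.

#' Read a genotype dosage matrix from TSV
#'
#' Columns: `snp_id`, `chrom`, `pos`, then one minor-allele dosage column
#' (0/1/2) per sample.
#'
#' @param path Path to a TSV file.
#' @return List with `genotypes` (SNP x sample integer matrix) and
#'   `snp_info` (tibble `snp_id`, `chrom`, `pos`).
#' @export
read_genotype_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("snp_id", "chrom", "pos")
  if (!all(required %in% names(df))) {
    abort("genotype TSV must start with columns snp_id, chrom, pos")
  }
  if (anyDuplicated(df$snp_id)) abort("duplicate snp_id in genotype table")
  geno <- as.matrix(df[, setdiff(names(df), required), drop = FALSE])
  rownames(geno) <- df$snp_id
  if (!all(geno %in% 0:2)) abort("dosages must be 0, 1 or 2")
  storage.mode(geno) <- "integer"
  list(genotypes = geno,
       snp_info = as_tibble(df[, required]))
}

#' Read genotype dosages from a VCF
#'
#' Minimal reader: the GT field of a diploid VCF is converted to a count of
#' alternate alleles per sample (0/1/2).  Requires the `vcfR` package.
#'
#' @param path Path to an (uncompressed) VCF file.
#' @return Same structure as [read_genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_genotypes() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(
    vapply(gsub("\\|", "/", gt), function(g) {
      if (is.na(g)) return(NA_integer_)
      sum(strsplit(g, "/", fixed = TRUE)[[1L]] != "0")
    }, integer(1)),
    nrow = nrow(gt), dimnames = dimnames(gt)
  )
  if (anyNA(dosage)) abort("missing genotypes are not supported")
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix[, "CHROM"], fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(dosage) <- ids
  list(genotypes = dosage,
       snp_info = tibble(snp_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"])))
}

#' Map SNPs to gene regions
#'
#' A SNP inside a gene span is labelled `intron` (exon structure is not
#' modelled); within `window` bp upstream of the start it is `upstream`,
#' within `window` bp downstream of the end `downstream`, otherwise `none`.
#' When several genes qualify the nearest wins (distance 0 inside a span),
#' with ties broken by gene input order.  Gene coordinates are BED-like
#' 0-based half-open; SNP positions are 1-based.
#'
#' @param snp_info Tibble with `snp_id`, `chrom`, `pos`.
#' @param annotation Gene annotation tibble (`gene`, `chrom`, `start`,
#'   `end`).
#' @param window Flanking window in bp (default 10000).
#' @return Tibble `snp_id`, `gene` (NA when unassigned), `relationship`.
#' @export
map_snps_to_genes <- function(snp_info, annotation, window = 10000) {
  check_number(window, "window", lower = 0)
  ann_chrom <- sub("^chr", "", as.character(annotation$chrom))
  snp_chrom <- sub("^chr", "", as.character(snp_info$chrom))
  map_one <- function(chrom, pos) {
    on_chrom <- which(ann_chrom == chrom)
    if (length(on_chrom) == 0L) {
      return(list(gene = NA_character_, relationship = "none"))
    }
    start1 <- annotation$start[on_chrom] + 1L  # first covered 1-based position
    end1 <- annotation$end[on_chrom]           # last covered 1-based position
    inside <- pos >= start1 & pos <= end1
    dist <- ifelse(inside, 0,
                   ifelse(pos < start1, start1 - pos, pos - end1))
    rel <- ifelse(inside, "intron",
                  ifelse(pos < start1 & start1 - pos <= window, "upstream",
                         ifelse(pos > end1 & pos - end1 <= window, "downstream",
                                "none")))
    hit <- which(rel != "none")
    if (length(hit) == 0L) {
      return(list(gene = NA_character_, relationship = "none"))
    }
    best <- hit[which.min(dist[hit])]
    list(gene = annotation$gene[on_chrom[best]], relationship = rel[best])
  }
  mapped <- purrr::map2(snp_chrom, snp_info$pos, map_one)
  tibble(snp_id = snp_info$snp_id,
         gene = purrr::map_chr(mapped, "gene"),
         relationship = purrr::map_chr(mapped, "relationship"))
}

#' Allelic case-control association per SNP
#'
#' For each SNP a 2x2 allele-count table is built (`a` = case minor
#' alleles, `b` = case major, `c` = control minor, `d` = control major;
#' allele totals are twice the sample counts).  The p-value is the 1-df
#' chi-square test without continuity correction, replaced by Fisher's
#' exact test when any expected cell count is below 5.  The odds ratio is
#' `(a d) / (b c)` with the Haldane-Anscombe +0.5 correction applied to all
#' cells when any cell is zero.  Monomorphic SNPs get `p = 1`, `OR = 1` and
#' are flagged.
#'
#' @param genotypes SNP x sample dosage matrix (0/1/2 minor-allele counts).
#' @param status Two-level factor over samples, control level first, case
#'   second.
#' @return Tibble: `snp_id`, allele counts `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `test` ("chisq", "fisher" or "monomorphic"),
#'   `monomorphic`.
#' @export
allelic_association <- function(genotypes, status) {
  status <- as_two_level(status, ncol(genotypes))
  case <- as.integer(status) == 2L
  if (sum(case) == 0L || sum(!case) == 0L) abort("both groups must be nonempty")
  a <- unname(rowSums(genotypes[, case, drop = FALSE]))
  c_ <- unname(rowSums(genotypes[, !case, drop = FALSE]))
  b <- 2 * sum(case) - a
  d <- 2 * sum(!case) - c_
  res <- purrr::pmap(list(a, b, c_, d), function(a, b, c, d) {
    tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    mono <- (a + c == 0) || (b + d == 0)
    if (mono) {
      return(list(odds_ratio = 1, p_value = 1, test = "monomorphic"))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    p <- if (any(expected < 5)) {
      fisher.test(tab)$p.value
    } else {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    if (any(tab == 0)) tab <- tab + 0.5
    list(odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
         p_value = p,
         test = if (any(expected < 5)) "fisher" else "chisq")
  })
  tibble(
    snp_id = rownames(genotypes),
    a = unname(a), b = unname(b), c = unname(c_), d = unname(d),
    odds_ratio = purrr::map_dbl(res, "odds_ratio"),
    p_value = purrr::map_dbl(res, "p_value"),
    test = purrr::map_chr(res, "test"),
    monomorphic = purrr::map_chr(res, "test") == "monomorphic"
  )
}

#' Filter and rank significant associations
#'
#' @param results Tibble from [allelic_association()], optionally joined
#'   with a gene mapping.
#' @param p_threshold Nominal p-value threshold (default 0.01; no
#'   multiple-testing correction, by design).
#' @param contrast Optional label recorded in a `contrast` column.
#' @return Rows with `p_value < p_threshold` sorted by ascending p.
#' @export
filter_significant <- function(results, p_threshold = 0.01, contrast = NULL) {
  check_number(p_threshold, "p_threshold", lower = 0, upper = 1)
  out <- results[results$p_value < p_threshold, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  if (!is.null(contrast)) out$contrast <- contrast
  as_tibble(out)
}

#' SNP association against signature-gene regions
#'
#' End-to-end wrapper: maps SNPs to gene regions, restricts to SNPs
#' assigned to a gene (optionally only signature genes), runs the allelic
#' test and returns the annotated association table.
#'
#' @param genotypes SNP x sample dosage matrix.
#' @param status Two-level factor (control, case).
#' @param snp_info Tibble `snp_id`, `chrom`, `pos`.
#' @param annotation Gene annotation tibble.
#' @param genes Optional gene subset (e.g. signature genes).
#' @param window Mapping window in bp (default 10000).
#' @param p_threshold If non-`NULL`, return only significant rows via
#'   [filter_significant()].
#' @return Association tibble with `gene` and `relationship` columns.
#' @export
associate_snps <- function(genotypes, status, snp_info, annotation,
                           genes = NULL, window = 10000, p_threshold = NULL) {
  if (!is.null(genes)) {
    annotation <- annotation[annotation$gene %in% genes, , drop = FALSE]
  }
  mapping <- map_snps_to_genes(snp_info, annotation, window = window)
  keep <- !is.na(mapping$gene)
  if (!any(keep)) abort("no SNPs map to the requested gene regions")
  res <- allelic_association(genotypes[mapping$snp_id[keep], , drop = FALSE], status)
  out <- dplyr::left_join(res, mapping[keep, ], by = "snp_id")
  out <- dplyr::relocate(out, "gene", "relationship", .after = "snp_id")
  if (!is.null(p_threshold)) out <- filter_significant(out, p_threshold)
  out
}
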