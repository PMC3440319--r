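#' Validate a gene-by-sample expression matrix
#'
#' The package represents expression data as a plain numeric matrix in log2
#' units with gene symbols as row names and sample identifiers as column
#' names, the convention used throughout differential expression and
#' classification.  This validator enforces the container's invariants.
#'
#' @param x A numeric matrix, genes in rows, samples in columns.
#' @return The validated matrix, invisibly unchanged.
#' @export
as_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("expression matrix must have gene symbols as rownames and sample ids as colnames")
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g) > 0) {
    abort(sprintf("duplicate gene symbol(s): %s", paste(head(dup_g, 5), collapse = ", ")))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s) > 0) {
    abort(sprintf("duplicate sample id(s): %s", paste(head(dup_s, 5), collapse = ", ")))
  }
  if (!all(is.finite(x))) {
    abort("expression matrix contains non-finite values; missing values are not supported")
  }
  x
}

#' Read an expression matrix from TSV
#'
#' Expects one header line (gene-column name followed by sample identifiers)
#' and one row per gene: symbol, then numeric log2 expression values.
#'
#' @param path Path to a tab-separated file.
#' @param collapse_duplicates If `TRUE`, multiple rows sharing a gene symbol
#'   (e.g. multiple probes on a different platform) are collapsed by keeping
#'   the row with the highest mean expression; if `FALSE` (default) a
#'   duplicated symbol is an error.
#' @return A validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path, collapse_duplicates = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    abort(sprintf("no data rows in '%s'", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1L]])
  if (ncols < 2L) {
    abort(sprintf("'%s': header must contain at least one sample column", path))
  }
  bad <- which(lengths(fields) != ncols)
  if (length(bad) > 0) {
    abort(sprintf("'%s': ragged row at line %d (expected %d fields, found %d)",
                  path, bad[1L], ncols, lengths(fields)[bad[1L]]))
  }
  samples <- fields[[1L]][-1L]
  body <- fields[-1L]
  genes <- vapply(body, `[[`, character(1), 1L)
  values <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(body, `[`, -1L))),
           nrow = length(body), ncol = ncols - 1L, byrow = TRUE)
  )
  non_numeric <- rowSums(is.na(values)) > 0
  if (any(non_numeric)) {
    warn(sprintf("dropped %d row(s) with non-numeric cells (first: '%s')",
                 sum(non_numeric), genes[which(non_numeric)[1L]]))
    values <- values[!non_numeric, , drop = FALSE]
    genes <- genes[!non_numeric]
  }
  if (nrow(values) == 0L) {
    abort(sprintf("no data rows in '%s'", path))
  }
  rownames(values) <- genes
  colnames(values) <- samples
  if (collapse_duplicates) {
    values <- collapse_duplicate_genes(values)
  }
  as_expression_matrix(values)
}

#' Collapse duplicated gene symbols by highest mean expression
#'
#' Standard highest-expressed-probe rule used when aligning validation
#' cohorts measured on platforms with several probes per gene.
#'
#' @param x Numeric matrix whose rownames may contain duplicates.
#' @return Matrix with one row per symbol (first-seen order).
#' @export
collapse_duplicate_genes <- function(x) {
  if (!anyDuplicated(rownames(x))) {
    return(x)
  }
  means <- rowMeans(x)
  ord <- order(match(rownames(x), unique(rownames(x))), -means)
  x <- x[ord, , drop = FALSE]
  x[!duplicated(rownames(x)), , drop = FALSE]
}

#' Write an expression matrix to TSV
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  as_expression_matrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE, row.names = NULL)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample phenotype table
#'
#' Tab-separated with columns `sample_id`, `disease_class` (one of HC, US,
#' CS for healthy control, uncomplicated and complicated sarcoidosis) and
#' `population` (AA or EA).
#'
#' @param path Path to a TSV file.
#' @return A tibble with one validated record per sample.
#' @export
read_phenotype_table <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_phenotypes(ph)
}

validate_phenotypes <- function(ph) {
  required <- c("sample_id", "disease_class", "population")
  missing <- setdiff(required, names(ph))
  if (length(missing) > 0) {
    abort(sprintf("phenotype table missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(ph$sample_id)) {
    abort("duplicate sample_id in phenotype table")
  }
  bad_class <- setdiff(unique(ph$disease_class), c("HC", "US", "CS"))
  if (length(bad_class) > 0) {
    abort(sprintf("unknown disease_class value(s): %s", paste(bad_class, collapse = ", ")))
  }
  bad_pop <- setdiff(unique(ph$population), c("AA", "EA"))
  if (length(bad_pop) > 0) {
    abort(sprintf("unknown population value(s): %s", paste(bad_pop, collapse = ", ")))
  }
  as_tibble(ph)
}

#' Read a gene annotation table
#'
#' BED-like TSV with columns `gene`, `chrom`, `start`, `end` (0-based
#' half-open coordinates).
#'
#' @param path Path to a TSV file.
#' @return Tibble with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene", "chrom", "start", "end")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    abort(sprintf("gene annotation missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(ann$gene)) {
    abort("duplicate gene symbol in annotation")
  }
  if (any(ann$end <= ann$start)) {
    abort("gene annotation has end <= start")
  }
  as_tibble(ann)
}

#' Remove genes on the sex chromosomes
#'
#' Genes annotated to chromosome X or Y are removed to avoid confounding
#' case/control contrasts by sex composition; all other genes are retained
#' in their original order.
#'
#' @param x Expression matrix (genes x samples).
#' @param annotation Tibble with columns `gene` and `chrom`.
#' @param on_missing What to do with genes absent from the annotation:
#'   `"drop"` removes them with a warning (default), `"error"` aborts.
#' @return The filtered expression matrix.
#' @export
filter_sex_chromosomes <- function(x, annotation, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  as_expression_matrix(x)
  chrom <- annotation$chrom[match(rownames(x), annotation$gene)]
  unannotated <- is.na(chrom)
  if (any(unannotated)) {
    if (on_missing == "error") {
      abort(sprintf("%d gene(s) lack annotation (first: '%s')",
                    sum(unannotated), rownames(x)[which(unannotated)[1L]]))
    }
    warn(sprintf("dropping %d unannotated gene(s)", sum(unannotated)))
  }
  sex <- sub("^chr", "", as.character(chrom)) %in% c("X", "Y")
  keep <- !unannotated & !sex
  out <- x[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warn("no genes remain after sex-chromosome filtering")
  }
  out
}

#' Log2-transform linear-scale expression values
#'
#' @param x Expression matrix on the linear scale (all values >= 0).
#' @param offset Non-negative pseudo-count added before taking log2
#'   (default 1).
#' @return Matrix of `log2(x + offset)` values.
#' @export
log2_transform <- function(x, offset = 1) {
  check_number(offset, "offset", lower = 0)
  if (any(x < 0)) {
    abort("log2_transform requires non-negative linear-scale values")
  }
  out <- log2(x + offset)
  dimnames(out) <- dimnames(x)
  out
}

#' Standardize each gene to zero mean and unit variance
#'
#' Row-wise z-scores across samples.  Constant genes map to all-zero rows
#' with a warning; they carry no class information but keeping them
#' preserves alignment with annotation and signatures.
#'
#' @param x Expression matrix with at least two samples.
#' @return Standardized matrix of the same shape.
#' @export
standardize_genes <- function(x) {
  if (ncol(x) < 2L) {
    abort("standardize_genes requires at least 2 samples")
  }
  mu <- rowMeans(x)
  sdev <- apply(x, 1L, sd)
  constant <- sdev == 0
  if (any(constant)) {
    warn(sprintf("%d constant gene(s) standardized to all-zero rows", sum(constant)))
    sdev[constant] <- 1
  }
  (x - mu) / sdev
}

#' Restrict two cohorts to their shared genes
#'
#' Cross-platform alignment by gene symbol: both matrices are restricted to
#' the intersection of their gene sets, in the order of the first matrix.
#'
#' @param x,y Expression matrices.
#' @return A list with elements `x` and `y` (aligned matrices) and
#'   `unmatched`, a named integer vector giving the number of genes dropped
#'   from each side.
#' @export
match_genes <- function(x, y) {
  as_expression_matrix(x)
  as_expression_matrix(y)
  shared <- intersect(rownames(x), rownames(y))
  if (length(shared) == 0L) {
    abort("no shared gene symbols between the two cohorts")
  }
  list(
    x = x[shared, , drop = FALSE],
    y = y[shared, , drop = FALSE],
    unmatched = c(x = nrow(x) - length(shared), y = nrow(y) - length(shared))
  )
}
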