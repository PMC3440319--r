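#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene symbols.  Duplicate members within a
#' set are removed.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors with attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0) {
    abort(sprintf("'%s': line %d has fewer than 3 fields", path, short[1L]))
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(names_[duplicated(names_)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene-set name(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "description") <- setNames(vapply(fields, `[[`, character(1), 2L), names_)
  sets
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided enrichment of a gene list within pathway sets: for each set,
#' `p = P(X >= overlap)` where `X` is hypergeometric with population size
#' `|universe|`, `|set * universe|` successes and `|list|` draws.  Sets are
#' intersected with the universe before testing; sets with empty
#' intersection are skipped with a message.  P-values are
#' Benjamini-Hochberg adjusted across the tested sets.
#'
#' @param genes Character vector, the gene list (must be a subset of
#'   `universe`).
#' @param universe Character vector of all genes eligible for selection
#'   (e.g. the analysis set after filtering).
#' @param gene_sets Named list of character vectors, e.g. from
#'   [read_gmt()].
#' @return Tibble with columns `set`, `overlap`, `set_size` (within the
#'   universe), `list_size`, `p_raw`, `p_adjusted`, sorted by adjusted p.
#' @export
hypergeometric_enrichment <- function(genes, universe, gene_sets) {
  genes <- unique(genes)
  universe <- unique(universe)
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    abort(sprintf("gene list not a subset of the universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  n_universe <- length(universe)
  n_list <- length(genes)
  in_universe <- lapply(gene_sets, intersect, universe)
  empty <- lengths(in_universe) == 0L
  if (any(empty)) {
    inform(sprintf("skipping %d set(s) with no genes in the universe: %s",
                   sum(empty), paste(head(names(gene_sets)[empty], 5), collapse = ", ")))
  }
  in_universe <- in_universe[!empty]
  overlap <- unname(vapply(in_universe, function(s) length(intersect(s, genes)), integer(1)))
  set_size <- unname(lengths(in_universe))
  # upper tail including the observed overlap: P(X >= k)
  p_raw <- phyper(overlap - 1L, set_size, n_universe - set_size, n_list,
                  lower.tail = FALSE)
  out <- tibble(
    set = names(in_universe),
    overlap = overlap,
    set_size = set_size,
    list_size = n_list,
    p_raw = unname(p_raw),
    p_adjusted = bh_adjust(unname(p_raw))
  )
  dplyr::arrange(out, .data$p_adjusted, .data$p_raw, .data$set)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical BH: sort p ascending, multiply by `m / rank`, enforce
#' monotonicity from the largest down, clip at 1, and return in the input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
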