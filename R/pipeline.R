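# End-to-end orchestration: simulate -> DE -> union analysis set ->
# signature discovery -> evaluation -> enrichment -> SNP association,
# driven by a single seeded configuration with a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param expression,phenotypes,annotation Paths to the cohort TSV files.
#' @param gene_sets Optional GMT path (enables the enrichment stage).
#' @param genotypes,genotype_status Optional genotype TSV and case/control
#'   status TSV (enable the association stage).
#' @param out_dir Output directory.
#' @param seed Global seed; per-stage seeds are derived from it so that
#'   toggling one stage leaves the others' random streams untouched.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(expression, phenotypes, annotation,
                            gene_sets = NULL, genotypes = NULL,
                            genotype_status = NULL,
                            out_dir = "results", seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    inputs = list(expression = expression, phenotypes = phenotypes,
                  annotation = annotation, gene_sets = gene_sets,
                  genotypes = genotypes, genotype_status = genotype_status),
    de = list(case = "CS", control = "HC", populations = c("AA", "EA"),
              fc_threshold = 1.4, q_threshold = 0.05, n_permutations = 200L),
    discover = list(cost = 1, drop_fraction = 0.1, cv_folds = 5L,
                    cv_repeats = 5L, n_resamples = 50L),
    evaluate = list(k = 5L, B = 100L, contrasts = list(
      list(name = "sarcoidosis_vs_hc", case = c("US", "CS"), control = "HC"),
      list(name = "cs_vs_hc", case = "CS", control = "HC"),
      list(name = "cs_vs_us", case = "CS", control = "US")
    )),
    associate = list(window = 10000, p_threshold = 0.01)
  )
}

write_stage_tsv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_tsv(df, path)
  path
}

#' Run the full discovery pipeline
#'
#' Executes the stages in dependency order: per-population differential
#' expression (CS vs HC), union analysis set, SVM-RFE signature discovery
#' on the pooled samples, repeated-CV evaluation of the signature on each
#' configured contrast (with a PCA projection per contrast), pathway
#' enrichment of the per-population DE lists, and SNP association within
#' signature-gene regions.  A failing stage aborts its dependents while
#' independent stages still run; the run fails (error) afterwards if any
#' stage failed.  All outputs are plain TSV plus a JSON manifest holding
#' the configuration, derived seeds and MD5 checksums, which together
#' fully determine the outputs.
#'
#' @param config Configuration list from [pipeline_config()] or a path to
#'   a YAML file with the same structure.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  required <- c("expression", "phenotypes", "annotation")
  for (nm in required) {
    if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]])) {
      abort(sprintf("input file for '%s' is missing: %s", nm,
                    inputs[[nm]] %||% "<unset>"))
    }
  }
  for (nm in c("gene_sets", "genotypes", "genotype_status")) {
    if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]])) {
      abort(sprintf("input file for '%s' is missing: %s", nm, inputs[[nm]]))
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  expr <- read_expression_matrix(inputs$expression)
  ph <- read_phenotype_table(inputs$phenotypes)
  ann <- read_gene_annotation(inputs$annotation)
  expr <- suppressWarnings(filter_sex_chromosomes(expr, ann))

  stage_status <- list()
  outputs <- list()
  run_stage <- function(name, depends, fun) {
    failed_dep <- depends[vapply(depends, function(d)
      !identical(stage_status[[d]], "ok"), logical(1))]
    if (length(failed_dep) > 0) {
      stage_status[[name]] <<- sprintf("skipped (failed dependency: %s)",
                                       paste(failed_dep, collapse = ", "))
      return(invisible(NULL))
    }
    res <- tryCatch({
      fun()
      stage_status[[name]] <<- "ok"
    }, error = function(e) {
      stage_status[[name]] <<- paste("failed:", conditionMessage(e))
      warn(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    invisible(res)
  }

  de_lists <- list()
  analysis_set <- NULL
  run_stage("de", character(0), function() {
    decfg <- config$de
    for (pop in decfg$populations) {
      de <- differential_expression(
        expr, ph, case = decfg$case, control = decfg$control,
        population = pop, fc_threshold = decfg$fc_threshold,
        q_threshold = decfg$q_threshold,
        n_permutations = decfg$n_permutations,
        seed = derive_seed(seed, paste0("de_", pop)))
      de_lists[[pop]] <<- select_differential(de)
      outputs[[paste0("de_", pop)]] <<- write_stage_tsv(
        dplyr::select(as_tibble(de), "gene", "d", "fold_change",
                      "q_value", "selected", "direction"),
        out_dir, sprintf("de_%s.tsv", pop))
    }
    analysis_set <<- union_analysis_set(de_lists)
    outputs[["analysis_set"]] <<- write_stage_tsv(
      tibble(gene = analysis_set), out_dir, "analysis_set.tsv")
  })

  signature <- NULL
  run_stage("discover", "de", function() {
    if (length(analysis_set) < 2L) {
      abort("analysis set has fewer than 2 genes; nothing to select from")
    }
    dcfg <- config$discover
    signature <<- discover_signature(
      expr, ph, case = config$de$case, control = config$de$control,
      genes = analysis_set, cost = dcfg$cost,
      drop_fraction = dcfg$drop_fraction, cv_folds = dcfg$cv_folds,
      cv_repeats = dcfg$cv_repeats, n_resamples = dcfg$n_resamples,
      seed = derive_seed(seed, "discover"))
    outputs[["signature"]] <<- write_stage_tsv(
      tidy(signature), out_dir, "signature.tsv")
    if (!is.null(signature$weights)) {
      outputs[["selection_weights"]] <<- write_stage_tsv(
        signature$weights, out_dir, "selection_weights.tsv")
    }
    outputs[["rfe_trace"]] <<- write_stage_tsv(
      tidy(attr(signature, "trace")), out_dir, "rfe_trace.tsv")
  })

  run_stage("evaluate", "discover", function() {
    ecfg <- config$evaluate
    summaries <- list()
    for (ct in ecfg$contrasts) {
      report <- evaluate_signature(
        expr, ph, genes = signature, case = unlist(ct$case),
        control = unlist(ct$control), k = ecfg$k, B = ecfg$B,
        seed = derive_seed(seed, paste0("evaluate_", ct$name)))
      outputs[[paste0("metrics_", ct$name)]] <<- write_stage_tsv(
        report$metrics, out_dir, sprintf("metrics_%s.tsv", ct$name))
      summaries[[ct$name]] <- dplyr::mutate(glance(report),
                                            contrast = ct$name,
                                            .before = 1L)
      keep <- ph$disease_class %in% c(unlist(ct$case), unlist(ct$control))
      pca <- pca_projection(expr[, ph$sample_id[keep], drop = FALSE],
                            genes = signature, phenotypes = ph[keep, ])
      outputs[[paste0("pca_", ct$name)]] <<- write_stage_tsv(
        tidy(pca), out_dir, sprintf("pca_%s.tsv", ct$name))
    }
    outputs[["evaluation_summary"]] <<- write_stage_tsv(
      dplyr::bind_rows(summaries), out_dir, "evaluation_summary.tsv")
  })

  run_stage("enrich", "de", function() {
    if (is.null(inputs$gene_sets)) {
      inform("no gene_sets input; skipping enrichment")
      return(invisible(NULL))
    }
    sets <- read_gmt(inputs$gene_sets)
    universe <- rownames(expr)
    for (pop in names(de_lists)) {
      enr <- hypergeometric_enrichment(de_lists[[pop]], universe, sets)
      outputs[[paste0("enrichment_", pop)]] <<- write_stage_tsv(
        enr, out_dir, sprintf("enrichment_%s.tsv", pop))
    }
  })

  run_stage("associate", "discover", function() {
    if (is.null(inputs$genotypes) || is.null(inputs$genotype_status)) {
      inform("no genotype inputs; skipping association")
      return(invisible(NULL))
    }
    g <- read_genotype_matrix(inputs$genotypes)
    status_tbl <- readr::read_tsv(inputs$genotype_status,
                                  show_col_types = FALSE, progress = FALSE)
    status <- factor(status_tbl$status[match(colnames(g$genotypes),
                                             status_tbl$sample_id)],
                     levels = c("control", "case"))
    assoc <- associate_snps(g$genotypes, status, g$snp_info, ann,
                            genes = signature$genes,
                            window = config$associate$window)
    outputs[["association"]] <<- write_stage_tsv(assoc, out_dir, "association.tsv")
    outputs[["association_significant"]] <<- write_stage_tsv(
      filter_significant(assoc, config$associate$p_threshold),
      out_dir, "association_significant.tsv")
  })

  input_files <- unlist(inputs[!vapply(inputs, is.null, logical(1))])
  manifest <- list(
    package = "sarcsig",
    version = as.character(utils::packageVersion("sarcsig")),
    seed = seed,
    derived_seeds = c(
      setNames(lapply(config$de$populations,
                      function(p) derive_seed(seed, paste0("de_", p))),
               paste0("de_", config$de$populations)),
      list(discover = derive_seed(seed, "discover"))
    ),
    config = config,
    stages = stage_status,
    inputs = as.list(tools::md5sum(input_files)),
    outputs = as.list(tools::md5sum(unlist(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  failed <- names(stage_status)[!vapply(stage_status, identical, logical(1), "ok")]
  if (length(failed) > 0) {
    abort(sprintf("pipeline finished with failed/skipped stage(s): %s (see %s)",
                  paste(failed, collapse = ", "),
                  file.path(out_dir, "manifest.json")))
  }
  invisible(manifest)
}

#' Write a self-contained synthetic demo workspace
#'
#' Generates a small synthetic cohort mirroring the structure of a
#' three-class two-population peripheral-blood study (35 HC / 17 US /
#' 22 CS by default, with a planted 20-gene signature), a case-control
#' genotype panel with SNPs planted inside signature genes at realistic
#' odds ratios, a toy GMT pathway collection containing one set enriched
#' in the planted signature, and a ready-to-run pipeline configuration.
#' All files are plain TSV/GMT/YAML; the planted ground truth is written
#' alongside as `truth_signature.tsv` and `truth_snps.tsv`.
#'
#' @param dir Target directory (created if needed).
#' @param seed Integer seed.
#' @param force Overwrite a non-empty directory (default `FALSE`).
#' @param n_genes,n_per_class Cohort dimensions passed to
#'   [expression_sim_config()].
#' @return Named list of the written file paths, invisibly.
#' @export
make_demo_workspace <- function(dir, seed = 1L, force = FALSE,
                                n_genes = 2000,
                                n_per_class = c(HC = 35, US = 17, CS = 22)) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(sprintf("directory '%s' is not empty; use force = TRUE to overwrite", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- simulate_expression_cohort(expression_sim_config(
    n_genes = n_genes, n_per_class = n_per_class,
    seed = derive_seed(seed, "expression")))
  files <- list()
  files$expression <- write_expression_matrix(cohort$expression,
                                              file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  files$phenotypes <- file.path(dir, "phenotypes.tsv")
  readr::write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  files$annotation <- file.path(dir, "annotation.tsv")
  readr::write_tsv(cohort$truth, file.path(dir, "truth_signature.tsv"))
  files$truth_signature <- file.path(dir, "truth_signature.tsv")

  # genotype panel: plant associated SNPs inside three signature genes
  sig_genes <- cohort$truth$gene
  n_snps <- 150L
  planted <- tibble(snp = 1:3, target_or = c(1.5, 2.0, 2.7),
                    control_maf = c(0.3, 0.25, 0.2))
  gcfg <- genotype_sim_config(n_snps = n_snps, n_cases = 300, n_controls = 300,
                              planted = planted,
                              seed = derive_seed(seed, "genotypes"))
  positions <- with_local_seed(derive_seed(seed, "snp_positions"), {
    ann <- cohort$annotation
    host <- ann[match(sig_genes, ann$gene), ]
    in_gene_host <- host[rep_len(seq_len(nrow(host)), 50L), ]
    width <- in_gene_host$end - in_gene_host$start
    in_gene <- tibble(
      snp_id = sprintf("snp%05d", 1:50),
      chrom = in_gene_host$chrom,
      pos = in_gene_host$start + ceiling(runif(50L) * width)
    )
    background <- tibble(
      snp_id = sprintf("snp%05d", 51:n_snps),
      chrom = sample(as.character(1:22), n_snps - 50L, replace = TRUE),
      pos = sample.int(2e8, n_snps - 50L)
    )
    dplyr::bind_rows(in_gene, background)
  })
  panel <- simulate_genotypes(gcfg, positions = positions)
  files$genotypes <- write_genotype_matrix(panel$genotypes, panel$snp_info,
                                           file.path(dir, "genotypes.tsv"))
  readr::write_tsv(panel$phenotypes, file.path(dir, "genotype_status.tsv"))
  files$genotype_status <- file.path(dir, "genotype_status.tsv")
  readr::write_tsv(panel$truth, file.path(dir, "truth_snps.tsv"))
  files$truth_snps <- file.path(dir, "truth_snps.tsv")

  # toy pathway collection: one set concentrated in the planted signature
  gmt <- with_local_seed(derive_seed(seed, "gmt"), {
    autosomal <- cohort$annotation$gene[!cohort$annotation$chrom %in% c("X", "Y")]
    other <- setdiff(autosomal, sig_genes)
    c(paste(c("PLANTED_SIGNALING", "synthetic set containing planted genes",
              c(sig_genes[1:15], sample(other, 10))), collapse = "\t"),
      vapply(1:5, function(i) {
        paste(c(sprintf("RANDOM_SET_%d", i), "synthetic background set",
                sample(other, 40)), collapse = "\t")
      }, character(1)))
  })
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  files$gene_sets <- file.path(dir, "pathways.gmt")

  cfg <- pipeline_config(
    expression = files$expression, phenotypes = files$phenotypes,
    annotation = files$annotation, gene_sets = files$gene_sets,
    genotypes = files$genotypes, genotype_status = files$genotype_status,
    out_dir = file.path(dir, "results"), seed = seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  files$config <- file.path(dir, "config.yaml")
  invisible(files)
}
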