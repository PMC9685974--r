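# End-to-end driver: cascade -> four associations -> FDR -> concordance ->
# validation candidates, with result tables and a reproducibility manifest.

#' Pipeline configuration
#'
#' Every data argument accepts either an in-memory object or a file path
#' (resolved with the package readers). Paths are validated up front; a
#' missing input aborts the run before any output is written.
#'
#' @param variants annotated variant table: [variant_records()] or a
#'   tab-delimited file with the same columns.
#' @param case discovery case cohort: [case_cohort()] or a file for
#'   [read_case_genotypes()] (`case_size` required for flat files).
#' @param case2 replication case cohort: a [case_cohort()], a
#'   [frequency_table()] (aggregate frequencies), or a file for
#'   [read_control_frequencies()] (`case2_size` required); `NULL` to run a
#'   single-case design.
#' @param controls named list of control panels, each a
#'   [frequency_table()] or a list `list(path =, n =, dialect =)`.
#' @param case_size,case2_size cohort sizes for file inputs.
#' @param evidence gene-evidence table, or `NULL` with `gene_primary` /
#'   `gene_others` file paths for [read_gene_lists()].
#' @param gene_primary,gene_others gene-list files (used when `evidence`
#'   is `NULL`).
#' @param filter a [filter_config()].
#' @param skip_cascade run associations on all input variants without
#'   filtering (for pre-prioritized variant sets).
#' @param alpha FDR level. @param family BH family definition.
#' @param or_estimator,p_rule passed to [associate()].
#' @param compute_ci compute exact confidence intervals.
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters only when inputs were simulated).
#' @return list of class `run_config`.
#' @export
run_config <- function(variants, case, controls, case2 = NULL,
                       case_size = NULL, case2_size = NULL,
                       evidence = NULL, gene_primary = NULL, gene_others = character(),
                       filter = filter_config(), skip_cascade = FALSE,
                       alpha = 0.05, family = "pooled",
                       or_estimator = "cmle", p_rule = "minlik",
                       compute_ci = TRUE, out_dir = NULL, seed = NULL) {
  structure(as.list(environment()), class = "run_config")
}

.resolve_inputs <- function(config) {
  paths <- character()
  take_path <- function(p) { paths[[length(paths) + 1L]] <<- p; p }
  need_file <- function(p, what) {
    if (!is.character(p) || length(p) != 1L || !file.exists(p))
      .stop2("configuration error: missing ", what, " file: ",
             if (is.character(p)) p else "<not a path>")
    take_path(p)
  }
  variants <- config$variants
  if (!inherits(variants, "variant_records")) {
    tab <- read.delim(need_file(variants, "variant annotation"),
                      stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character", ref = "character",
                                     alt = "character"))
    variants <- variant_records(tab)
  }
  case <- config$case
  if (!inherits(case, "case_cohort"))
    case <- read_case_genotypes(need_file(case, "case genotype"),
                                cohort_size = config$case_size, name = "cases")
  case2 <- config$case2
  if (!is.null(case2) && !inherits(case2, "freq_table") &&
      !inherits(case2, "case_cohort"))
    case2 <- read_control_frequencies(need_file(case2, "replication case"),
                                      n_individuals = config$case2_size, name = "cases2")
  controls <- lapply(names(config$controls), function(nm) {
    ctl <- config$controls[[nm]]
    if (inherits(ctl, "freq_table")) return(ctl)
    read_control_frequencies(need_file(ctl$path, paste0("control '", nm, "'")),
                             n_individuals = ctl$n, name = nm,
                             dialect = if (is.null(ctl$dialect)) "fraction" else ctl$dialect)
  })
  names(controls) <- names(config$controls)
  evidence <- config$evidence
  if (is.null(evidence) && !is.null(config$gene_primary)) {
    need_file(config$gene_primary, "primary gene list")
    for (p in config$gene_others) need_file(p, "gene list")
    evidence <- read_gene_lists(config$gene_primary, config$gene_others)
  }
  list(variants = variants, case = case, case2 = case2, controls = controls,
       evidence = evidence, input_paths = paths)
}

#' Run the full enrichment pipeline
#'
#' Executes, in order: the prioritization cascade on the discovery cohort's
#' annotated variants, exact association of every case cohort against every
#' control panel over the surviving keys, FDR adjustment, the
#' cross-comparison concordance selection, and the region-flag exclusion
#' producing validation candidates. When `out_dir` is set it writes one
#' association table per comparison, the selected and candidate key tables,
#' the cascade trace (JSON) and a manifest recording cohort sizes,
#' thresholds, package version and input file checksums. Outputs are only
#' written after the whole analysis has succeeded.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `survivors`, `trace`, `results`, `matrix`,
#'   `selected`, `candidates`, and `manifest`.
#' @export
run_full_pipeline <- function(config) {
  if (!inherits(config, "run_config")) .stop2("config must be a run_config")
  inp <- .resolve_inputs(config)
  if (config$skip_cascade) {
    survivors <- inp$variants
    trace <- NULL
  } else {
    if (is.null(inp$evidence)) .stop2("configuration error: no gene evidence supplied")
    cas <- run_cascade(inp$variants, inp$case, inp$evidence, config$filter)
    survivors <- cas$variants
    trace <- cas$trace
  }
  keys <- survivors$key
  cases <- c(list(cases = inp$case), if (!is.null(inp$case2)) list(cases2 = inp$case2))
  results <- list()
  for (ca_nm in names(cases)) for (co_nm in names(inp$controls)) {
    nm <- paste0(ca_nm, "_vs_", co_nm)
    results[[nm]] <- associate(cases[[ca_nm]], inp$controls[[co_nm]], keys,
                               or_estimator = config$or_estimator,
                               p_rule = config$p_rule, alpha = config$alpha,
                               compute_ci = config$compute_ci, comparison = nm)
  }
  results <- adjust_significance(results, family = config$family, alpha = config$alpha)
  mat <- build_matrix(results,
                      case_labels = sub("_vs_.*$", "", names(results)))
  selected <- select_consistent(mat)
  candidates <- validation_candidates(selected, inp$variants)
  manifest <- list(
    tool = "varenrich",
    version = as.character(utils::packageVersion("varenrich")),
    seed = config$seed,
    alpha = config$alpha, family = config$family,
    or_estimator = config$or_estimator, p_rule = config$p_rule,
    filter = unclass(config$filter),
    cohort_sizes = c(list(cases = inp$case$n_individuals),
                     if (!is.null(inp$case2)) list(cases2 = inp$case2$n_individuals),
                     lapply(inp$controls, function(x) x$n_individuals)),
    n_variants_in = nrow(inp$variants), n_variants_tested = length(keys),
    n_selected = length(selected), n_candidates = length(candidates),
    input_md5 = as.list(tools::md5sum(inp$input_paths)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    for (nm in names(results))
      write_association_table(results[[nm]], p(paste0("assoc_", nm, ".tsv")),
                              variants = inp$variants)
    keytab <- function(k) data.frame(
      key = k, gene = inp$variants$gene[match(k, inp$variants$key)])
    write.table(keytab(selected), p("selected.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(keytab(candidates), p("candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(trace))
      jsonlite::write_json(data.frame(stage = trace$stage, n_in = trace$n_in,
                                      n_out = trace$n_out),
                           p("trace.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(survivors = survivors, trace = trace, results = results,
                 matrix = mat, selected = selected, candidates = candidates,
                 manifest = manifest))
}
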