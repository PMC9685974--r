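#' Bundled 49-variant breast-cancer candidate table
#'
#' A packaged fixture encoding a published breast-cancer rare-variant
#' discovery table: 49 candidate variants in 37 cancer genes, with the
#' carrier counts of a 290-patient *BRCA1/2*-negative discovery cohort, and
#' the per-variant allele frequencies (as printed, percent at 2 decimal
#' places) of an external 466-patient early-onset case cohort (dbGaP
#' accession phs000822.v1.p1) and two aggregate control panels: gnomAD
#' v2.1.1 East-Asian (9,977 individuals) and SG10K_Health (9,770
#' individuals). A dash in the source table — a variant not reported in a
#' cohort — becomes `present = FALSE`.
#'
#' Genomic coordinates are not part of the published table; the fixture
#' keys use the gene's chromosome and the transcript cDNA offset as stable
#' placeholder coordinates (alleles of the two frameshift deletions and the
#' insertion are likewise placeholder-anchored). The join key is unique and
#' consistent across all five returned objects, which is all the analysis
#' requires.
#'
#' For the discovery cohort the integer carrier count is authoritative and
#' alternate-allele counts assume heterozygous carriers (the printed
#' frequencies are rounded, and several disagree with `carriers / 580` at
#' 2 decimal places — consistent with unpublished per-variant allele
#' numbers below 580; `af_discrepant` flags those rows rather than
#' resolving them). For the three aggregate cohorts alternate counts are
#' reconstructed downstream as `round_half_up(af * an)` with allele
#' numbers `2 * n` (932, 19,954, 19,540).
#'
#' @return list with elements
#'   \describe{
#'     \item{`variants`}{[variant_records()]: gene, consequence, scaled
#'       CADD, ACMG class, region flags, and the gnomAD reference MAF used
#'       by the frequency filter.}
#'     \item{`case_sg`}{[case_cohort()], n = 290, with `af_printed` and
#'       `af_discrepant` columns alongside the carrier counts.}
#'     \item{`case_dbgap`}{[frequency_table()], n = 466 (case cohort known
#'       only as frequencies).}
#'     \item{`control_gnomad`}{[frequency_table()], n = 9,977.}
#'     \item{`control_sg10k`}{[frequency_table()], n = 9,770.}
#'   }
#' @export
load_candidate_variants <- function() {
  path <- system.file("extdata", "candidate_variants_49.tsv",
                      package = "varenrich", mustWork = TRUE)
  fx <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character"))
  stopifnot(nrow(fx) == 49L)

  variants <- variant_records(data.frame(
    chrom = fx$chrom, pos = fx$pos, ref = fx$ref, alt = fx$alt,
    gene = fx$gene, hgvs = fx$hgvs, consequence = fx$consequence,
    cadd = fx$cadd, acmg = fx$acmg, region_flags = fx$region_flags,
    maf_reference = fx$af_gnomad / 100,
    qc_pass = TRUE, stringsAsFactors = FALSE))

  af_printed <- fx$af_case_sg / 100
  af_recomputed <- round(fx$n_patients / 580 * 100, 2)
  calls <- data.frame(key = variants$key, carriers = fx$n_patients,
                      alt_alleles = fx$n_patients, allele_number = 580L,
                      af_printed = af_printed,
                      af_discrepant = abs(af_recomputed - fx$af_case_sg) > 0.005,
                      stringsAsFactors = FALSE)
  case_sg <- case_cohort(calls, n_individuals = 290L, name = "sg_cases")

  ft <- function(af_percent, n, name)
    frequency_table(data.frame(key = variants$key, af = af_percent / 100,
                               stringsAsFactors = FALSE),
                    n_individuals = n, name = name)
  list(variants = variants,
       case_sg = case_sg,
       case_dbgap = ft(fx$af_case_dbgap, 466L, "dbgap_cases"),
       control_gnomad = ft(fx$af_gnomad, 9977L, "gnomad_eas"),
       control_sg10k = ft(fx$af_sg10k, 9770L, "sg10k"))
}

#' Run the four-way association analysis on the bundled candidate table
#'
#' Convenience wrapper: tests both case cohorts against both control
#' panels over all 49 bundled variants, adjusts for multiple testing and
#' returns the annotated results plus the comparison matrix, the
#' consistently enriched selection and the validation candidates.
#'
#' @param family BH family definition, see [adjust_significance()].
#' @param alpha FDR level.
#' @param compute_ci compute exact confidence intervals (default `TRUE`).
#' @return list with `results` (named list of four annotated
#'   `association_results`), `matrix`, `selected`, `candidates`, and the
#'   fixture itself as `data`.
#' @export
analyze_candidate_variants <- function(family = "pooled", alpha = 0.05,
                                       compute_ci = TRUE) {
  fx <- load_candidate_variants()
  keys <- fx$variants$key
  results <- list(
    sg_vs_gnomad    = associate(fx$case_sg, fx$control_gnomad, keys, compute_ci = compute_ci),
    sg_vs_sg10k     = associate(fx$case_sg, fx$control_sg10k, keys, compute_ci = compute_ci),
    dbgap_vs_gnomad = associate(fx$case_dbgap, fx$control_gnomad, keys, compute_ci = compute_ci),
    dbgap_vs_sg10k  = associate(fx$case_dbgap, fx$control_sg10k, keys, compute_ci = compute_ci))
  results <- adjust_significance(results, family = family, alpha = alpha)
  mat <- build_matrix(results)
  selected <- select_consistent(mat)
  candidates <- validation_candidates(selected, fx$variants)
  list(results = results, matrix = mat, selected = selected,
       candidates = candidates, data = fx)
}
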