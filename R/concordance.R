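# Cross-comparison concordance: combine the annotated association results
# of the four case/control pairs into a per-variant status matrix and apply
# the selection rule.

#' Build the per-variant comparison matrix
#'
#' @param results named list of annotated `association_results` (after
#'   [adjust_significance()]), one per comparison, all covering the same
#'   set of variant keys.
#' @param case_labels optional character vector, parallel to `results`,
#'   naming the case cohort behind each comparison (used by
#'   [concordant_in_cohort()]). Defaults to the part of each comparison
#'   name before `"_vs_"`.
#' @return data frame of class `comparison_matrix`: a `key` column plus one
#'   status column and one adjusted-p/odds-ratio column pair per comparison.
#' @export
build_matrix <- function(results, case_labels = NULL) {
  if (!length(results)) {
    out <- data.frame(key = character(), stringsAsFactors = FALSE)
    class(out) <- c("comparison_matrix", "data.frame")
    return(out)
  }
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- vapply(results, function(r) r$comparison[1], character(1))
  keys <- sort(results[[1L]]$key)
  for (r in results) {
    if (!identical(sort(r$key), keys))
      .stop2("all comparisons must cover the same variant keys")
    if (any(r$status == "testable", na.rm = TRUE))
      .stop2("results must be annotated with adjust_significance() first")
  }
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (nm in names(results)) {
    i <- match(keys, results[[nm]]$key)
    out[[paste0(nm, ".status")]] <- results[[nm]]$status[i]
    out[[paste0(nm, ".or")]] <- results[[nm]]$or[i]
  }
  if (is.null(case_labels))
    case_labels <- sub("_vs_.*$", "", names(results))
  attr(out, "comparisons") <- names(results)
  attr(out, "case_labels") <- setNames(case_labels, names(results))
  class(out) <- c("comparison_matrix", "data.frame")
  out
}

.cell_pass <- function(status, or, require_enrichment) {
  pass <- status %in% c("untestable_case_absent", "untestable_control_absent") |
    status == "significant"
  if (require_enrichment)
    pass <- pass & (status != "significant" | (!is.na(or) & or > 1))
  pass
}

#' Select consistently enriched variants
#'
#' A comparison cell passes when its variant is significant at the chosen
#' FDR level *or* is absent from either cohort of that comparison (an
#' unobserved variant cannot testify against enrichment); a variant is
#' selected when every comparison passes. Setting
#' `require_enrichment = TRUE` additionally demands an odds ratio above 1
#' in every significant cell — a stricter reading that does **not**
#' reproduce the bundled study's published selection, which retains
#' significantly *depleted* cells.
#'
#' @param matrix a [build_matrix()] result.
#' @param require_enrichment see above; default `FALSE`.
#' @return character vector of selected variant keys (sorted).
#' @export
select_consistent <- function(matrix, require_enrichment = FALSE) {
  comps <- attr(matrix, "comparisons")
  if (!length(comps) || !nrow(matrix)) return(character())
  pass <- rep(TRUE, nrow(matrix))
  for (nm in comps) {
    st <- matrix[[paste0(nm, ".status")]]
    if (any(is.na(st))) .stop2("unannotated cell in comparison ", nm)
    pass <- pass & .cell_pass(st, matrix[[paste0(nm, ".or")]], require_enrichment)
  }
  sort(matrix$key[pass])
}

#' Variants significant in both comparisons of one case cohort
#'
#' @param matrix a [build_matrix()] result.
#' @param case_label a value of the matrix's `case_labels` attribute.
#' @return character vector of keys significant in every comparison whose
#'   case cohort is `case_label`.
#' @export
concordant_in_cohort <- function(matrix, case_label) {
  labels <- attr(matrix, "case_labels")
  comps <- names(labels)[labels == case_label]
  if (!length(comps)) .stop2("unknown case cohort label: ", case_label)
  sig <- rep(TRUE, nrow(matrix))
  for (nm in comps) sig <- sig & matrix[[paste0(nm, ".status")]] == "significant"
  sort(matrix$key[sig])
}

#' Remove selected variants in sequencing-hostile regions
#'
#' Drops, from a selected key set, variants flagged as lying in highly
#' repetitive or highly polymorphic regions, where orthogonal validation
#' (e.g. Sanger sequencing) is unreliable; the survivors are the
#' validation candidates.
#'
#' @param selected character vector of selected keys.
#' @param variants a [variant_records()] table carrying `region_flags`.
#' @param exclude_flags flags that disqualify a variant.
#' @return character vector of candidate keys (sorted).
#' @export
validation_candidates <- function(selected, variants,
                                  exclude_flags = c("repetitive", "polymorphic_locus")) {
  flagged <- variants$key[has_region_flag(variants, exclude_flags)]
  sort(setdiff(selected, flagged))
}
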