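# Variant prioritization cascade. Every stage is a pure per-variant
# predicate (output is always a subset of the input), so the surviving set
# is the conjunction of the stage predicates in any order; the cascade
# fixes one order purely for the audit trail.

#' Filter cascade configuration
#'
#' @param maf_threshold reference-population MAF cutoff (fraction). A
#'   variant is retained when its reference MAF is *unreported* or strictly
#'   below the threshold; a MAF exactly at the threshold is removed.
#' @param cadd_threshold scaled CADD cutoff; nonsynonymous SNVs must score
#'   strictly above it.
#' @param min_carriers minimum number of case carrier individuals
#'   (homozygotes count once).
#' @param cadd_exempt_consequences protein-truncating classes retained
#'   regardless of CADD score.
#' @param require_review_pass when `TRUE`, variants explicitly failing
#'   manual read-level review are removed; an absent review verdict counts
#'   as a pass (loci whose alignments are too complex to review are kept).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.01, cadd_threshold = 20,
                          min_carriers = 3,
                          cadd_exempt_consequences = c("frameshift_insertion",
                                                       "frameshift_deletion",
                                                       "stopgain"),
                          require_review_pass = TRUE) {
  if (maf_threshold <= 0 || cadd_threshold <= 0) .stop2("thresholds must be strictly positive")
  if (min_carriers < 1) .stop2("min_carriers must be >= 1")
  structure(list(maf_threshold = maf_threshold, cadd_threshold = cadd_threshold,
                 min_carriers = as.integer(min_carriers),
                 cadd_exempt_consequences = cadd_exempt_consequences,
                 require_review_pass = isTRUE(require_review_pass)),
            class = "filter_config")
}

#' Cascade stages
#'
#' Each stage takes and returns a [variant_records()] table.
#' \describe{
#'   \item{`qc_filter`}{keep variants whose upstream caller QC flag is set.}
#'   \item{`frequency_filter`}{keep variants with unreported reference MAF
#'     or reference MAF strictly below `maf_threshold`.}
#'   \item{`consequence_filter`}{keep exempt protein-truncating classes
#'     unconditionally, and nonsynonymous SNVs with CADD strictly above
#'     `cadd_threshold`; every other class is removed. A non-exempt variant
#'     with a missing CADD score is an error.}
#'   \item{`gene_prioritization_filter`}{keep variants whose gene is on the
#'     primary cancer-gene list and corroborated by at least one other
#'     list (see [read_gene_lists()]).}
#'   \item{`recurrence_filter`}{keep variants carried by at least
#'     `min_carriers` case individuals.}
#'   \item{`review_filter`}{drop variants whose manual review verdict is
#'     explicitly `FALSE`; `NA` (unreviewed/unreviewable) passes.}
#' }
#'
#' @param variants a [variant_records()] table.
#' @param maf_threshold,cadd_threshold,exempt,min_carriers see
#'   [filter_config()].
#' @param evidence gene-evidence table from [read_gene_lists()].
#' @param case_cohort a [case_cohort()] supplying carrier counts.
#' @return the filtered `variant_records` table.
#' @name cascade_stages
NULL

#' @rdname cascade_stages
#' @export
qc_filter <- function(variants) {
  variants[!is.na(variants$qc_pass) & variants$qc_pass, , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
frequency_filter <- function(variants, maf_threshold = 0.01) {
  keep <- is.na(variants$maf_reference) | variants$maf_reference < maf_threshold
  variants[keep, , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
consequence_filter <- function(variants, cadd_threshold = 20,
                               exempt = c("frameshift_insertion",
                                          "frameshift_deletion", "stopgain")) {
  is_exempt <- variants$consequence %in% exempt
  if (any(!is_exempt & is.na(variants$cadd)))
    .stop2("missing CADD score on non-exempt variant(s): ",
           paste(utils::head(variants$key[!is_exempt & is.na(variants$cadd)], 5), collapse = ", "))
  keep <- is_exempt |
    (variants$consequence == "nonsynonymous_snv" & variants$cadd > cadd_threshold)
  variants[keep, , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
gene_prioritization_filter <- function(variants, evidence) {
  i <- match(toupper(variants$gene), evidence$gene)
  keep <- !is.na(i) & evidence$in_primary_list[i] & nzchar(evidence$corroborating_lists[i])
  variants[keep, , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
recurrence_filter <- function(variants, case_cohort, min_carriers = 3) {
  i <- match(variants$key, case_cohort$calls$key)
  carriers <- ifelse(is.na(i), 0L, case_cohort$calls$carriers[i])
  variants[carriers >= min_carriers, , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
review_filter <- function(variants) {
  variants[is.na(variants$review_pass) | variants$review_pass, , drop = FALSE]
}

#' Run the full prioritization cascade with an audit trail
#'
#' Applies, in order: QC, reference-frequency, consequence/CADD, gene-list
#' corroboration, carrier recurrence, and (optionally) manual-review
#' filtering. Because all stages are per-variant predicates the surviving
#' set does not depend on this order; the trace does.
#'
#' @param variants a [variant_records()] table.
#' @param case_cohort a [case_cohort()] for the recurrence stage.
#' @param evidence gene-evidence table from [read_gene_lists()].
#' @param config a [filter_config()].
#' @return list with `variants` (survivors) and `trace`, a data frame of
#'   class `filter_trace` with one row per stage: stage name, variants in,
#'   variants out, and the removed keys (list column).
#' @export
run_cascade <- function(variants, case_cohort, evidence, config = filter_config()) {
  stages <- list(
    qc          = function(v) qc_filter(v),
    frequency   = function(v) frequency_filter(v, config$maf_threshold),
    consequence = function(v) consequence_filter(v, config$cadd_threshold,
                                                 config$cadd_exempt_consequences),
    gene        = function(v) gene_prioritization_filter(v, evidence),
    recurrence  = function(v) recurrence_filter(v, case_cohort, config$min_carriers),
    review      = if (config$require_review_pass) function(v) review_filter(v)
                  else function(v) v)
  trace <- data.frame(stage = names(stages), n_in = NA_integer_,
                      n_out = NA_integer_, stringsAsFactors = FALSE)
  removed <- vector("list", length(stages))
  v <- variants
  for (s in seq_along(stages)) {
    n_in <- nrow(v)
    out <- stages[[s]](v)
    trace$n_in[s] <- n_in
    trace$n_out[s] <- nrow(out)
    removed[[s]] <- setdiff(v$key, out$key)
    v <- out
  }
  trace$removed <- I(removed)
  class(trace) <- c("filter_trace", "data.frame")
  list(variants = v, trace = trace)
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("<filter_trace>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %5d -> %5d  (-%d)\n", x$stage[i], x$n_in[i], x$n_out[i],
                x$n_in[i] - x$n_out[i]))
  invisible(x)
}
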