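#' Case cohort with per-variant carrier counts
#'
#' A diploid case cohort summarized per variant: the number of carrier
#' individuals, the number of alternate alleles they contribute, and the
#' per-variant allele number (callable alleles; at most `2 * n_individuals`,
#' reduced when genotypes are missing).
#'
#' @param calls data frame with columns `key`, `carriers`, and optionally
#'   `alt_alleles` (default: equal to `carriers`, the all-heterozygous
#'   assumption appropriate for rare variants) and `allele_number` (default
#'   `2 * n_individuals`).
#' @param n_individuals cohort size (diploid individuals).
#' @param name cohort label used in comparison names.
#' @param genotypes optional integer dosage matrix (variants x samples,
#'   rownames = keys, values 0/1/2/NA) retained when reading per-sample
#'   files; used only for carrier-matrix exports.
#' @return object of class `case_cohort`.
#' @export
case_cohort <- function(calls, n_individuals, name = "cases", genotypes = NULL) {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L) .stop2("n_individuals must be a positive count")
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (!all(c("key", "carriers") %in% names(calls))) .stop2("calls need columns key, carriers")
  if (is.null(calls$alt_alleles)) calls$alt_alleles <- calls$carriers
  if (is.null(calls$allele_number)) calls$allele_number <- 2L * n_individuals
  calls$carriers <- as.integer(calls$carriers)
  calls$alt_alleles <- as.integer(calls$alt_alleles)
  calls$allele_number <- as.integer(calls$allele_number)
  if (anyDuplicated(calls$key)) .stop2("duplicated keys in case calls")
  with(calls, {
    if (any(carriers < 0L) || any(carriers > n_individuals)) .stop2("carrier counts outside [0, n_individuals]")
    if (any(alt_alleles < 0L) || any(alt_alleles > allele_number)) .stop2("alt alleles outside [0, allele_number]")
    if (any(allele_number > 2L * n_individuals)) .stop2("allele_number exceeds 2 * n_individuals")
  })
  structure(list(name = name, n_individuals = n_individuals,
                 calls = calls, genotypes = genotypes),
            class = "case_cohort")
}

#' @export
print.case_cohort <- function(x, ...) {
  cat(sprintf("<case_cohort '%s'> %d individuals, %d variants\n",
              x$name, x$n_individuals, nrow(x$calls)))
  invisible(x)
}

#' Aggregate allele-frequency panel
#'
#' A cohort known only through per-variant allele frequencies and allele
#' numbers, the form in which population panels (gnomAD subsets, national
#' reference cohorts) and privacy-restricted case cohorts are distributed.
#' Alternate-allele counts are reconstructed as `round_half_up(af * an)`.
#'
#' @param tab data frame with columns `key`, `af` and optionally `an`
#'   (default `2 * n_individuals`) and `present` (default: `TRUE` where `af`
#'   is not `NA`). A variant with `present = FALSE` carries no frequency.
#' @param n_individuals number of diploid individuals in the panel.
#' @param name cohort label.
#' @return object of class `freq_table`.
#' @export
frequency_table <- function(tab, n_individuals, name = "controls") {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L) .stop2("n_individuals must be a positive count")
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (!all(c("key", "af") %in% names(tab))) .stop2("frequency table needs columns key, af")
  if (anyDuplicated(tab$key)) .stop2("duplicated keys in frequency table")
  if (is.null(tab$an)) tab$an <- 2L * n_individuals
  tab$an[is.na(tab$an)] <- 2L * n_individuals
  tab$an <- as.integer(tab$an)
  if (is.null(tab$present)) tab$present <- !is.na(tab$af)
  tab$af[!tab$present] <- NA_real_
  ok <- tab$present
  if (any(tab$af[ok] < 0 | tab$af[ok] > 1)) .stop2("allele frequencies must lie in [0, 1]")
  if (any(.rhu(tab$af[ok] * tab$an[ok]) > tab$an[ok])) .stop2("reconstructed allele count exceeds allele number")
  structure(list(name = name, n_individuals = n_individuals, table = tab),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table '%s'> %d individuals, %d variants (%d present)\n",
              x$name, x$n_individuals, nrow(x$table), sum(x$table$present)))
  invisible(x)
}

# per-key lookup of (alt count, allele number, present) for either cohort type
.cohort_counts <- function(x, keys) {
  if (inherits(x, "case_cohort")) {
    i <- match(keys, x$calls$key)
    data.frame(key = keys,
               alt = x$calls$alt_alleles[i],
               an = ifelse(is.na(i), 2L * x$n_individuals, x$calls$allele_number[i]),
               present = !is.na(i))
  } else if (inherits(x, "freq_table")) {
    i <- match(keys, x$table$key)
    present <- !is.na(i) & x$table$present[i]
    an <- ifelse(is.na(i), 2L * x$n_individuals, x$table$an[i])
    alt <- ifelse(present, .rhu(x$table$af[i] * x$table$an[i]), NA_real_)
    data.frame(key = keys, alt = alt, an = an, present = present)
  } else .stop2("expected a case_cohort or freq_table")
}
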