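#' Build a 2x2 allele-count table from a case count and a control frequency
#'
#' The control alternate count is reconstructed as
#' `round_half_up(control_af * control_an)`, the only reconstruction
#' possible when a panel publishes rounded frequencies rather than counts.
#'
#' @param case_alt alternate alleles observed in cases.
#' @param case_an case allele number.
#' @param control_af control alternate-allele frequency in `[0, 1]`.
#' @param control_an control allele number.
#' @return named integer vector `c(a, b, c, d)`.
#' @examples
#' build_table(28, 580, 0.0020, 19954)  # c reconstructs to 40
#' @export
build_table <- function(case_alt, case_an, control_af, control_an) {
  if (is.na(case_alt) || is.na(case_an) || case_alt < 0 || case_alt > case_an)
    .stop2("case_alt must lie in [0, case_an]")
  if (is.na(control_af) || control_af < 0 || control_af > 1)
    .stop2("control_af must lie in [0, 1]")
  cc <- .rhu(control_af * control_an)
  if (cc > control_an) .stop2("reconstructed control count exceeds control_an")
  c(a = as.integer(case_alt), b = as.integer(case_an - case_alt),
    c = as.integer(cc), d = as.integer(control_an - cc))
}

.EMPTY_ASSOC <- data.frame(
  key = character(), comparison = character(),
  a = integer(), b = integer(), c = integer(), d = integer(),
  case_af = numeric(), control_af = numeric(),
  or = numeric(), or_sample = numeric(), ci_low = numeric(), ci_high = numeric(),
  p_raw = numeric(), p_adjusted = numeric(), status = character(),
  stringsAsFactors = FALSE)

#' Exact case-control association for a set of variants
#'
#' Runs the exact 2x2 machinery for every requested key of one case cohort
#' against one aggregate control panel. Keys absent from the case side are
#' reported with status `untestable_case_absent`; keys absent from the
#' control panel get status `untestable_control_absent` but still receive
#' the conventional table against the panel's allele number with a zero
#' control count (odds ratio `Inf` when any case carrier exists, p-value
#' still computed). Only rows with status `testable` enter a p-value family
#' downstream; `p_adjusted` is left `NA` until [adjust_significance()] runs.
#'
#' @param case a [case_cohort()] (counts observed directly) or a
#'   [frequency_table()] (aggregate summary, as for an external case cohort
#'   published only as frequencies).
#' @param control a [frequency_table()].
#' @param keys variant keys to test; defaults to every key on the case side.
#' @param or_estimator `"cmle"` (conditional maximum likelihood, default) or
#'   `"sample"`; the other estimate is always kept in `or_sample`.
#' @param p_rule two-sided rule passed to [fisher_two_sided_p()].
#' @param alpha level for the exact confidence interval.
#' @param compute_ci set `FALSE` to skip interval inversion (the expensive
#'   part) in large simulation sweeps where only p-values are consumed.
#' @param compute_or set `FALSE` to also skip odds-ratio estimation.
#' @param comparison label stored with every row; defaults to
#'   `"<case>_vs_<control>"`.
#' @return data frame of class `association_results`, one row per key.
#' @export
associate <- function(case, control, keys = NULL,
                      or_estimator = c("cmle", "sample"),
                      p_rule = c("minlik", "doubled"),
                      alpha = 0.05, compute_ci = TRUE, compute_or = TRUE,
                      comparison = NULL) {
  or_estimator <- match.arg(or_estimator)
  p_rule <- match.arg(p_rule)
  if (!inherits(control, "freq_table")) .stop2("control must be a freq_table")
  if (is.null(keys)) {
    keys <- if (inherits(case, "case_cohort")) case$calls$key else case$table$key
  }
  if (is.null(comparison)) {
    case_name <- if (inherits(case, "case_cohort")) case$name else case$name
    comparison <- paste0(case_name, "_vs_", control$name)
  }
  if (!length(keys)) {
    out <- .EMPTY_ASSOC
    class(out) <- c("association_results", "data.frame")
    return(out)
  }
  ca <- .cohort_counts(case, keys)
  co <- .cohort_counts(control, keys)
  n <- length(keys)
  out <- data.frame(key = keys, comparison = comparison,
                    a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
                    case_af = NA_real_, control_af = NA_real_,
                    or = NA_real_, or_sample = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_raw = NA_real_, p_adjusted = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!ca$present[i]) { out$status[i] <- "untestable_case_absent"; next }
    a <- ca$alt[i]; an1 <- ca$an[i]
    ctrl_absent <- !co$present[i]
    cc <- if (ctrl_absent) 0L else co$alt[i]
    an2 <- co$an[i]
    tb <- c(a = a, b = an1 - a, c = cc, d = an2 - cc)
    out[i, c("a", "b", "c", "d")] <- as.list(tb)
    out$case_af[i] <- a / an1
    out$control_af[i] <- if (ctrl_absent) NA_real_ else cc / an2
    out$p_raw[i] <- fisher_two_sided_p(tb[1], tb[2], tb[3], tb[4], rule = p_rule)
    if (compute_or) {
      smp <- sample_or(tb[1], tb[2], tb[3], tb[4])
      out$or[i] <- if (or_estimator == "cmle")
        conditional_mle_or(tb[1], tb[2], tb[3], tb[4]) else smp
      out$or_sample[i] <- smp
    }
    if (compute_ci) {
      ci <- exact_or_ci(tb[1], tb[2], tb[3], tb[4], alpha = alpha)
      out$ci_low[i] <- ci[1]; out$ci_high[i] <- ci[2]
    }
    out$status[i] <- if (ctrl_absent) "untestable_control_absent" else "testable"
  }
  class(out) <- c("association_results", "data.frame")
  out
}
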