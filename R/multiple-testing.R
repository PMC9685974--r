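#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: on the sorted p-values,
#' `q_(i) = min over j >= i of min(1, m * p_(j) / j)`, mapped back to input
#' order. Delegates to [stats::p.adjust()], which implements exactly this
#' rule; inputs are validated to lie in (0, 1].
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values (q-values), same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    .stop2("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Adjust association results for multiple testing and flag significance
#'
#' Fills `p_adjusted` for every testable row and sets the final status:
#' `significant` when the adjusted p-value is strictly below `alpha`,
#' otherwise `not_significant`. Untestable rows are untouched.
#'
#' The `family` switch controls which tests share one BH family:
#' `"pooled"` (default) adjusts all testable tests of all supplied
#' comparisons together, the convention under which the bundled candidate
#' table reproduces its published adjusted p-values; `"per_comparison"`
#' adjusts each comparison independently.
#'
#' @param results a single `association_results` data frame or a (possibly
#'   named) list of them, one per comparison.
#' @param family `"pooled"` or `"per_comparison"`.
#' @param alpha FDR level; significance is strict (`p_adjusted < alpha`).
#' @return the input, same shape, with `p_adjusted` and `status` filled.
#' @export
adjust_significance <- function(results, family = c("pooled", "per_comparison"),
                                alpha = 0.05) {
  family <- match.arg(family)
  single <- is.data.frame(results)
  lst <- if (single) list(results) else results
  for (r in lst) {
    if (!is.data.frame(r) || is.null(r$p_raw) || is.null(r$status))
      .stop2("results must be association_results data frames")
  }
  testable <- lapply(lst, function(r) which(r$status == "testable")) # nolint
  if (family == "pooled") {
    all_p <- unlist(lapply(seq_along(lst), function(j) lst[[j]]$p_raw[testable[[j]]]))
    q <- bh_adjust(all_p)
    off <- 0L
    for (j in seq_along(lst)) {
      idx <- testable[[j]]
      lst[[j]]$p_adjusted[idx] <- q[off + seq_along(idx)]
      off <- off + length(idx)
    }
  } else {
    for (j in seq_along(lst)) {
      idx <- testable[[j]]
      lst[[j]]$p_adjusted[idx] <- bh_adjust(lst[[j]]$p_raw[idx])
    }
  }
  for (j in seq_along(lst)) {
    idx <- testable[[j]]
    lst[[j]]$status[idx] <- ifelse(lst[[j]]$p_adjusted[idx] < alpha,
                                   "significant", "not_significant")
  }
  if (single) lst[[1L]] else lst
}
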