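test_that("noncentral pmf reduces to the central hypergeometric at psi = 1", {
  # frozen small case: margins 5/5, column total 4
  expect_equal(nchg_pmf(2, 5, 5, 4), 120 / 252)
  set.seed(41)
  for (i in 1:25) {
    tb <- random_table(20)
    s <- tb["a"] + tb["c"]
    ks <- max(0, s - (tb["c"] + tb["d"])):min(tb["a"] + tb["b"], s)
    expect_equal(nchg_pmf(ks, tb["a"] + tb["b"], tb["c"] + tb["d"], s, psi = 1),
                 dhyper(ks, m = tb["a"] + tb["b"], n = tb["c"] + tb["d"], k = s),
                 tolerance = 1e-12)
  }
})

test_that("noncentral pmf normalizes over the support at any odds ratio", {
  for (psi in c(0.1, 1, 10)) {
    expect_equal(sum(nchg_pmf(0:10, 10, 14, 10, psi)), 1, tolerance = 1e-12)
    expect_equal(sum(nchg_pmf(0:6, 6, 600, 40, psi)), 1, tolerance = 1e-12)
  }
  # degenerate odds ratios put all mass on a support endpoint
  expect_equal(nchg_pmf(0:4, 5, 5, 4, psi = 0), c(1, 0, 0, 0, 0))
  expect_equal(nchg_pmf(0:4, 5, 5, 4, psi = Inf), c(0, 0, 0, 0, 1))
  expect_error(nchg_pmf(1, 5, 5, 4, psi = -1), "non-negative")
})

test_that("two-sided p-value equals enumeration and the stats reference", {
  expect_equal(fisher_two_sided_p(3, 2, 1, 4), 110 / 210)
  expect_equal(fisher_two_sided_p(5, 5, 5, 5), 1)
  set.seed(42)
  for (i in 1:200) {
    tb <- random_table(25)
    p <- fisher_two_sided_p(tb["a"], tb["b"], tb["c"], tb["d"])
    expect_equal(p, brute_fisher_p(tb["a"], tb["b"], tb["c"], tb["d"]),
                 tolerance = 1e-10)
    expect_equal(p, fisher.test(matrix(tb, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("two-sided p-value is invariant under table symmetries", {
  set.seed(43)
  for (i in 1:50) {
    tb <- random_table(20)
    p <- fisher_two_sided_p(tb["a"], tb["b"], tb["c"], tb["d"])
    expect_equal(fisher_two_sided_p(tb["a"], tb["c"], tb["b"], tb["d"]), p,
                 tolerance = 1e-10) # transpose
    expect_equal(fisher_two_sided_p(tb["d"], tb["c"], tb["b"], tb["a"]), p,
                 tolerance = 1e-10) # simultaneous row+column swap
  }
})

test_that("doubled-tail rule is a valid alternative two-sided definition", {
  p_min <- fisher_two_sided_p(4, 1, 2, 8)
  p_dbl <- fisher_two_sided_p(4, 1, 2, 8, rule = "doubled")
  expect_gte(p_dbl, p_min)  # doubling is never smaller here
  expect_equal(fisher_two_sided_p(5, 5, 5, 5, rule = "doubled"), 1)
})

test_that("extreme tables keep a positive p-value instead of underflowing", {
  p <- fisher_two_sided_p(166, 766, 12, 19942)
  expect_gt(p, 0)
  expect_lt(p, 1e-150)
})

test_that("conditional MLE solves the conditional score equation", {
  expect_equal(conditional_mle_or(5, 5, 5, 5), 1, tolerance = 1e-8)
  # saturated / empty alternate cells hit the 0 and Inf conventions
  expect_identical(conditional_mle_or(3, 577, 0, 19954), Inf)
  expect_identical(conditional_mle_or(0, 580, 7, 19947), 0)
  expect_true(is.nan(conditional_mle_or(0, 5, 0, 5)))  # single-point support
  # grid-search likelihood maximizer agrees
  expect_equal(conditional_mle_or(4, 1, 2, 8), grid_cmle(4, 1, 2, 8),
               tolerance = 5e-3)
  set.seed(44)
  for (i in 1:30) {
    tb <- random_table(12)
    s <- tb["a"] + tb["c"]
    kmin <- max(0, s - (tb["c"] + tb["d"])); kmax <- min(tb["a"] + tb["b"], s)
    if (tb["a"] <= kmin || tb["a"] >= kmax) next
    expect_equal(log(conditional_mle_or(tb["a"], tb["b"], tb["c"], tb["d"])),
                 log(grid_cmle(tb["a"], tb["b"], tb["c"], tb["d"])),
                 tolerance = 0.01)
  }
})

test_that("conditional MLE agrees with the stats reference implementation", {
  set.seed(45)
  for (i in 1:40) {
    tb <- random_table(25)
    s <- tb["a"] + tb["c"]
    kmin <- max(0, s - (tb["c"] + tb["d"])); kmax <- min(tb["a"] + tb["b"], s)
    if (tb["a"] <= kmin || tb["a"] >= kmax) next
    ref <- unname(fisher.test(matrix(tb, 2, 2, byrow = TRUE))$estimate)
    # the reference optimizer stops early; agreement to 0.1% is its precision
    expect_equal(conditional_mle_or(tb["a"], tb["b"], tb["c"], tb["d"]), ref,
                 tolerance = 1e-3)
  }
})

test_that("conditional MLE is strictly increasing in the case count", {
  ors <- vapply(1:9, function(a) conditional_mle_or(a, 10 - a, 5, 15), numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("exact CI inverts the conditional tail tests", {
  ci <- exact_or_ci(4, 1, 2, 8)
  # each bound pins its tail probability at alpha/2
  expect_equal(tail_ge(4, 1, 2, 8, ci[1]), 0.025, tolerance = 1e-5)
  expect_equal(tail_le(4, 1, 2, 8, ci[2]), 0.025, tolerance = 1e-5)
  ref <- fisher.test(matrix(c(4, 1, 2, 8), 2, 2, byrow = TRUE))$conf.int
  expect_equal(log(ci), log(as.numeric(ref)), tolerance = 0.01)
  # endpoint conventions
  expect_identical(exact_or_ci(0, 10, 3, 17)[1], 0)
  ci_sat <- exact_or_ci(3, 577, 0, 19954)
  expect_identical(ci_sat[2], Inf)
  expect_gt(ci_sat[1], 1)
})

test_that("exact CI brackets the estimate and widens as alpha decreases", {
  set.seed(46)
  for (i in 1:20) {
    tb <- random_table(20)
    s <- tb["a"] + tb["c"]
    kmin <- max(0, s - (tb["c"] + tb["d"])); kmax <- min(tb["a"] + tb["b"], s)
    if (tb["a"] <= kmin || tb["a"] >= kmax) next
    or <- conditional_mle_or(tb["a"], tb["b"], tb["c"], tb["d"])
    ci95 <- exact_or_ci(tb["a"], tb["b"], tb["c"], tb["d"], alpha = 0.05)
    ci99 <- exact_or_ci(tb["a"], tb["b"], tb["c"], tb["d"], alpha = 0.01)
    expect_lt(ci95[1], or); expect_gt(ci95[2], or)
    expect_lte(ci99[1], ci95[1]); expect_gte(ci99[2], ci95[2])
  }
})

test_that("sample odds ratio follows the standard zero-cell conventions", {
  expect_equal(sample_or(28, 552, 40, 19914), 28 * 19914 / (552 * 40))
  expect_identical(sample_or(3, 577, 0, 19954), Inf)
  expect_true(is.nan(sample_or(0, 5, 0, 5)))
  # near-balanced large-cell tables: sample OR tracks the conditional MLE
  expect_equal(sample_or(30, 70, 25, 80), conditional_mle_or(30, 70, 25, 80),
               tolerance = 0.01)
})
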