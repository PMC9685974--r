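test_that("generation is deterministic and extension-stable under one seed", {
  cfg <- simulation_config(seed = 31, n_variants = 80)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # adding variants never perturbs earlier per-variant draws
  big <- generate_cohort(simulation_config(seed = 31, n_variants = 160))
  expect_equal(big$truth$q[1:80], a$truth$q)
  expect_equal(big$case$calls$alt_alleles[1:80], a$case$calls$alt_alleles)
  expect_equal(big$control$table$af[1:80], a$control$table$af)
  # a different seed changes the draws
  expect_false(identical(generate_cohort(simulation_config(seed = 32, n_variants = 80))$truth$q,
                         a$truth$q))
})

test_that("emitted panel frequencies reconstruct their counts exactly", {
  sim <- generate_cohort(simulation_config(seed = 33, n_variants = 200))
  tab <- sim$control$table
  counts <- .rhu(tab$af * tab$an)
  expect_true(all(abs(tab$af * tab$an - counts) < 1e-9))  # af stores x/an exactly
  expect_true(all(counts >= 0 & counts <= tab$an))
  expect_true(all(tab$an <= 2L * sim$control$n_individuals))
})

test_that("case sampling follows the odds-ratio model", {
  # psi = 25 at q = 0.002 in a 290-case cohort: expected alternate alleles
  # 580 * 25*0.002/(0.998 + 25*0.002) = 27.66
  cfg <- simulation_config(seed = 34, n_variants = 400,
                           planted = data.frame(index = 1:400, psi = 25, q = 0.002))
  sim <- generate_cohort(cfg)
  expect_equal(mean(sim$case$calls$alt_alleles), 580 * 0.0477, tolerance = 0.05)
  # law of large numbers at a very large cohort
  cfg2 <- simulation_config(seed = 35, n_variants = 1, n_cases = 1e5,
                            planted = data.frame(index = 1, psi = 10, q = 0.005))
  sim2 <- generate_cohort(cfg2)
  r <- 10 * 0.005 / (1 - 0.005 + 10 * 0.005)
  expect_equal(sim2$case$calls$alt_alleles / (2e5), r, tolerance = 0.05)
})

test_that("planted variants are annotated to survive every filter stage", {
  cfg <- simulation_config(seed = 36, n_variants = 300,
                           planted = data.frame(index = c(5, 50, 250), psi = 30, q = 0.003))
  sim <- generate_cohort(cfg)
  planted <- sim$variants[sim$truth$planted, ]
  expect_true(all(planted$qc_pass))
  expect_true(all(planted$consequence == "nonsynonymous_snv" & planted$cadd > 20))
  expect_true(all(planted$maf_reference < 0.01))
  ev <- sim$evidence[match(planted$gene, sim$evidence$gene), ]
  expect_true(all(ev$in_primary_list & nzchar(ev$corroborating_lists)))
})

test_that("null variants keep the exact test near its nominal size", {
  # 2 x 1000 null variant-replicates; Fisher is conservative, so the raw
  # rejection rate at 0.05 stays below 6%
  rej <- 0L; tot <- 0L
  for (seed in 37:38) {
    sim <- generate_cohort(simulation_config(seed = seed, n_variants = 1000,
                                             maf_common_rate = 0))
    res <- associate(sim$case, sim$control, compute_ci = FALSE, compute_or = FALSE)
    rej <- rej + sum(res$p_raw < 0.05, na.rm = TRUE)
    tot <- tot + sum(!is.na(res$p_raw))
  }
  expect_lt(rej / tot, 0.06)
})

test_that("recovery reports score a selection against the truth", {
  truth <- data.frame(key = variant_key("s", 1:10, "A", "G"),
                      planted = c(rep(TRUE, 4), rep(FALSE, 6)))
  rep1 <- recover_planted(truth, truth$key[c(1, 2, 3, 9)])
  expect_equal(rep1$sensitivity, 0.75)
  expect_equal(rep1$fdp, 0.25)
  expect_equal(recover_planted(truth, character())$fdp, 0)
  expect_true(is.na(recover_planted(truth[truth$planted == FALSE, ], character())$sensitivity))
})

test_that("a planted variant absent from the control panels is selected via absence", {
  cfg <- simulation_config(seed = 39, n_variants = 150,
                           planted = data.frame(index = 7, psi = 30, q = 0.004))
  st <- generate_study(cfg)
  k <- st$truth$key[7]
  for (p in c("control1", "control2")) {  # force the variant out of both panels
    i <- st[[p]]$table$key == k
    st[[p]]$table$present[i] <- FALSE
    st[[p]]$table$af[i] <- NA
  }
  keys <- st$truth$key
  res <- adjust_significance(list(
    a = associate(st$case1, st$control1, keys, compute_ci = FALSE),
    b = associate(st$case1, st$control2, keys, compute_ci = FALSE),
    c = associate(st$case2, st$control1, keys, compute_ci = FALSE),
    d = associate(st$case2, st$control2, keys, compute_ci = FALSE)))
  sel <- select_consistent(build_matrix(res, case_labels = c("c1", "c1", "c2", "c2")))
  expect_true(k %in% sel)
  expect_identical(res$a$or[res$a$key == k], Inf)
  expect_equal(res$a$status[res$a$key == k], "untestable_control_absent")
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(1, baseline_range = c(0.001, 0.02)), "baseline_range")
  expect_error(simulation_config(1, planted = data.frame(index = 2000, psi = 2)),
               "out of range")
  expect_error(simulation_config(1, planted = data.frame(index = 1, psi = -1)), "psi")
  expect_error(simulation_config(1, qc_fail_rate = 1.5), "probabilities")
})
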