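toy_evidence <- function(genes, primary = genes, corroborated = genes)
  data.frame(gene = toupper(genes),
             in_primary_list = toupper(genes) %in% toupper(primary),
             corroborating_lists = ifelse(toupper(genes) %in% toupper(corroborated),
                                          "cgc", ""),
             stringsAsFactors = FALSE)

test_that("qc filter keeps exactly the passing variants", {
  v <- toy_records(10)
  v$qc_pass[4] <- FALSE
  expect_equal(nrow(qc_filter(v)), 9L)
  expect_false("t:4:A:C" %in% qc_filter(v)$key)
  expect_equal(qc_filter(toy_records(5)), toy_records(5))  # all pass: identity
})

test_that("frequency filter retains unreported and strictly-rare variants", {
  v <- toy_records(4)
  v$maf_reference <- c(0.02, NA, 0.01, 0.0099)
  out <- frequency_filter(v, 0.01)
  # > threshold removed; unreported kept; exactly-at-threshold removed (strict <)
  expect_equal(out$pos, c(2L, 4L))
})

test_that("consequence filter exempts truncating classes from the CADD cutoff", {
  v <- toy_records(4)
  v$consequence <- c("nonsynonymous_snv", "frameshift_deletion",
                     "other", "nonsynonymous_snv")
  v$cadd <- c(24.0, 2.03, 30, 20)
  out <- consequence_filter(v, 20)
  # nonsyn above cutoff kept; truncating kept despite CADD 2.03;
  # non-functional class removed; nonsyn exactly at cutoff removed (strict >)
  expect_equal(out$pos, c(1L, 2L))
  v$cadd[1] <- NA
  expect_error(consequence_filter(v), "missing CADD")
})

test_that("gene filter requires primary listing plus corroboration", {
  v <- toy_records(3)
  v$gene <- c("AAA", "BBB", "CCC")
  ev <- toy_evidence(c("AAA", "BBB", "DDD"), primary = c("AAA", "DDD"),
                     corroborated = c("AAA", "BBB"))
  out <- gene_prioritization_filter(v, ev)
  expect_equal(out$gene, "AAA")  # BBB corroborated but not primary; CCC unknown
})

test_that("recurrence filter counts carrier individuals", {
  v <- toy_records(3)
  cc <- case_cohort(data.frame(key = v$key, carriers = c(3L, 2L, 0L),
                               alt_alleles = c(4L, 2L, 0L)), 50L)
  expect_equal(recurrence_filter(v, cc, 3)$pos, 1L)
})

test_that("review filter removes only explicit failures", {
  v <- toy_records(3)
  v$review_pass <- c(FALSE, NA, TRUE)
  v$region_flags[2] <- "repetitive"  # unreviewable locus: review skipped
  expect_equal(review_filter(v)$pos, c(2L, 3L))
})

test_that("cascade survivors equal the planted pass-all set", {
  set.seed(9)
  n <- 1000L
  v <- toy_records(n)
  pass_all <- sort(sample(n, 12))
  # every null variant is made to violate at least one predicate
  for (i in setdiff(seq_len(n), pass_all)) {
    fail <- sample(5, 1)
    if (fail == 1) v$qc_pass[i] <- FALSE
    if (fail == 2) v$maf_reference[i] <- runif(1, 0.01, 0.1)
    if (fail == 3) v$cadd[i] <- runif(1, 0, 20)
    if (fail == 4) v$gene[i] <- "NOTLISTED"
    if (fail == 5) v$review_pass[i] <- FALSE
  }
  cc <- case_cohort(data.frame(key = v$key, carriers = 5L), 290L)
  ev <- toy_evidence(setdiff(unique(v$gene), "NOTLISTED"))
  out <- run_cascade(v, cc, ev)
  expect_equal(sort(out$variants$pos), pass_all)
})

test_that("cascade equals the conjunction of predicates and is idempotent", {
  cfg <- simulation_config(seed = 5, n_variants = 300,
                           planted = data.frame(index = 1:5, psi = 20, q = 0.002))
  sim <- generate_cohort(cfg)
  out <- run_cascade(sim$variants, sim$case, sim$evidence)
  # brute-force per-variant predicate evaluation, no sequencing of stages
  v <- sim$variants
  carriers <- sim$case$calls$carriers[match(v$key, sim$case$calls$key)]
  ev <- sim$evidence[match(toupper(v$gene), sim$evidence$gene), ]
  exempt <- v$consequence %in% c("frameshift_insertion", "frameshift_deletion", "stopgain")
  keep <- v$qc_pass &
    (is.na(v$maf_reference) | v$maf_reference < 0.01) &
    (exempt | (v$consequence == "nonsynonymous_snv" & v$cadd > 20)) &
    (!is.na(ev$gene) & ev$in_primary_list & nzchar(ev$corroborating_lists)) &
    carriers >= 3 &
    (is.na(v$review_pass) | v$review_pass)
  expect_equal(sort(out$variants$key), sort(v$key[keep]))
  again <- run_cascade(out$variants, sim$case, sim$evidence)
  expect_equal(again$variants$key, out$variants$key)
  expect_true(all(again$trace$n_in == again$trace$n_out))
})

test_that("trace conserves counts and an empty input yields a zero trace", {
  cfg <- simulation_config(seed = 6, n_variants = 120)
  sim <- generate_cohort(cfg)
  out <- run_cascade(sim$variants, sim$case, sim$evidence)
  expect_equal(out$trace$n_in - out$trace$n_out,
               vapply(out$trace$removed, length, integer(1)))
  expect_equal(out$trace$n_in[-1], out$trace$n_out[-nrow(out$trace)])
  empty <- run_cascade(toy_records(1)[0, ], sim$case, sim$evidence)
  expect_equal(nrow(empty$variants), 0L)
  expect_equal(nrow(empty$trace), 6L)
  expect_true(all(empty$trace$n_in == 0L & empty$trace$n_out == 0L))
})

test_that("filter configuration rejects degenerate thresholds", {
  expect_error(filter_config(maf_threshold = 0), "strictly positive")
  expect_error(filter_config(min_carriers = 0), "min_carriers")
})
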