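# Synthetic cohort generator with known ground truth. Cases are sampled
# per allele: with baseline (control) allele frequency q and true odds
# ratio psi, a case allele is alternate with probability
#   r = psi * q / (1 - q + psi * q),
# so the case/control allele odds ratio is exactly psi. At the sub-percent
# frequencies simulated here Hardy-Weinberg homozygotes are negligible and
# carrier individuals are identified with carrier alleles (capped at the
# cohort size).

#' Simulation configuration
#'
#' Defaults emulate the bundled study design: a 290-case discovery cohort
#' and a 466-case replication cohort tested against aggregate panels of
#' 9,977 and 9,770 individuals, candidate variants with baseline allele
#' frequencies below 1%, and annotation columns sufficient to exercise
#' every cascade stage.
#'
#' @param seed integer seed. Each variant draws from its own derived
#'   stream, so enlarging `n_variants` never perturbs earlier variants.
#' @param n_cases,n_cases2 sizes of the two diploid case cohorts.
#' @param n_controls,n_controls2 sizes of the two control panels.
#' @param n_variants number of simulated variants.
#' @param baseline_law `"loguniform"` (default) or `"point"`.
#' @param baseline_range allele-frequency range (log-uniform law) or a
#'   single value (point law); must lie within (0, 0.01).
#' @param planted data frame with columns `index` and `psi` (true odds
#'   ratio, > 0) and optionally `q` (baseline frequency override). Planted
#'   variants are annotated so that they pass every filter stage.
#' @param qc_fail_rate probability a null variant fails caller QC.
#' @param consequence_probs named class-mix probabilities for null variants.
#' @param cadd_range scaled-CADD range for nonsynonymous null variants
#'   (uniform law).
#' @param gene_eligible_rate probability a null variant's gene is on the
#'   primary cancer-gene list with corroboration.
#' @param region_flag_rate probability of a repetitive-region flag.
#' @param review_fail_rate probability a null variant fails manual review.
#' @param maf_common_rate probability a null variant is common (reference
#'   MAF drawn above 1%, so the frequency filter removes it).
#' @param an_dropout_max panel allele numbers are reduced by a per-variant
#'   missingness fraction drawn uniformly from `[0, an_dropout_max]`.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_cases = 290L, n_cases2 = 466L,
                              n_controls = 9977L, n_controls2 = 9770L,
                              n_variants = 1000L,
                              baseline_law = c("loguniform", "point"),
                              baseline_range = c(2e-4, 5e-3),
                              planted = NULL,
                              qc_fail_rate = 0.079,
                              consequence_probs = c(other = 0.50,
                                                    nonsynonymous_snv = 0.40,
                                                    stopgain = 0.04,
                                                    frameshift_deletion = 0.04,
                                                    frameshift_insertion = 0.02),
                              cadd_range = c(10, 40),
                              gene_eligible_rate = 0.30,
                              region_flag_rate = 0.05,
                              review_fail_rate = 0.02,
                              maf_common_rate = 0.15,
                              an_dropout_max = 0.10) {
  baseline_law <- match.arg(baseline_law)
  if (any(baseline_range <= 0) || any(baseline_range >= 0.01))
    .stop2("baseline_range must lie within (0, 0.01)")
  probs <- c(qc_fail_rate, gene_eligible_rate, region_flag_rate,
             review_fail_rate, maf_common_rate, an_dropout_max, consequence_probs)
  if (any(probs < 0 | probs > 1)) .stop2("all probabilities must lie in [0, 1]")
  if (abs(sum(consequence_probs) - 1) > 1e-8) .stop2("consequence_probs must sum to 1")
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    if (!all(c("index", "psi") %in% names(planted))) .stop2("planted needs columns index, psi")
    if (any(planted$index < 1 | planted$index > n_variants)) .stop2("planted index out of range")
    if (any(planted$psi <= 0)) .stop2("planted psi must be > 0")
  }
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_cases2 = as.integer(n_cases2), n_controls = as.integer(n_controls),
                 n_controls2 = as.integer(n_controls2), n_variants = as.integer(n_variants),
                 baseline_law = baseline_law, baseline_range = baseline_range,
                 planted = planted, qc_fail_rate = qc_fail_rate,
                 consequence_probs = consequence_probs, cadd_range = cadd_range,
                 gene_eligible_rate = gene_eligible_rate,
                 region_flag_rate = region_flag_rate, review_fail_rate = review_fail_rate,
                 maf_common_rate = maf_common_rate, an_dropout_max = an_dropout_max),
            class = "simulation_config")
}

# deterministic per-(variant, role) substream; stays well below 2^31
.vseed <- function(seed, i, role) {
  as.integer((seed %% 65011) * 32771 + i * 613 + role * 7) %% 2147483629L
}
.with_vseed <- function(seed, i, role, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(.vseed(seed, i, role))
  expr
}

.sim_truth <- function(config) {
  n <- config$n_variants
  q <- vapply(seq_len(n), function(i) .with_vseed(config$seed, i, 0L, {
    common <- runif(1) < config$maf_common_rate
    if (common) runif(1, 0.011, 0.05)
    else if (config$baseline_law == "point") config$baseline_range[1]
    else exp(runif(1, log(config$baseline_range[1]),
                   log(max(config$baseline_range))))
  }), numeric(1))
  psi <- rep(1, n)
  planted <- rep(FALSE, n)
  if (!is.null(config$planted)) {
    idx <- config$planted$index
    psi[idx] <- config$planted$psi
    planted[idx] <- TRUE
    if (!is.null(config$planted$q)) {
      oq <- config$planted$q
      q[idx] <- ifelse(is.na(oq), q[idx], oq)
    }
  }
  data.frame(key = variant_key("sim1", seq_len(n), "A", "G"),
             index = seq_len(n), q = q, psi = psi, planted = planted,
             stringsAsFactors = FALSE)
}

.sim_annotations <- function(config, truth) {
  n <- config$n_variants
  cls <- names(config$consequence_probs)
  ann <- lapply(seq_len(n), function(i) .with_vseed(config$seed, i, 1L, {
    consequence <- sample(cls, 1L, prob = config$consequence_probs)
    cadd <- round(runif(1, config$cadd_range[1], config$cadd_range[2]), 2)
    out <- list(consequence = consequence, cadd = cadd,
                qc_pass = runif(1) >= config$qc_fail_rate,
                eligible = runif(1) < config$gene_eligible_rate,
                region = if (runif(1) < config$region_flag_rate) "repetitive" else "",
                review = runif(1) >= config$review_fail_rate)
    if (truth$planted[i]) {  # planted variants must survive every stage
      out$consequence <- "nonsynonymous_snv"
      out$cadd <- round(runif(1, 25, config$cadd_range[2]), 2)
      out$qc_pass <- TRUE; out$eligible <- TRUE; out$region <- ""; out$review <- TRUE
    }
    out
  }))
  genes <- sprintf("SIMG%04d", seq_len(n))
  variants <- variant_records(data.frame(
    chrom = "sim1", pos = seq_len(n), ref = "A", alt = "G",
    gene = genes,
    consequence = vapply(ann, `[[`, "", "consequence"),
    cadd = vapply(ann, `[[`, 0, "cadd"),
    maf_reference = truth$q,
    qc_pass = vapply(ann, `[[`, TRUE, "qc_pass"),
    region_flags = vapply(ann, `[[`, "", "region"),
    review_pass = vapply(ann, `[[`, TRUE, "review"),
    stringsAsFactors = FALSE))
  eligible <- vapply(ann, `[[`, TRUE, "eligible")
  evidence <- data.frame(gene = genes, in_primary_list = eligible,
                         corroborating_lists = ifelse(eligible, "driver_db", ""),
                         stringsAsFactors = FALSE)
  list(variants = variants, evidence = evidence)
}

.sim_case <- function(config, truth, n_ind, role, name) {
  an <- 2L * n_ind
  r <- truth$psi * truth$q / (1 - truth$q + truth$psi * truth$q)
  alt <- vapply(seq_len(config$n_variants), function(i)
    .with_vseed(config$seed, i, role, rbinom(1L, an, r[i])), integer(1))
  case_cohort(data.frame(key = truth$key, carriers = pmin(alt, n_ind),
                         alt_alleles = alt, allele_number = an,
                         stringsAsFactors = FALSE),
              n_individuals = n_ind, name = name)
}

.sim_panel <- function(config, truth, n_ind, role, name) {
  res <- vapply(seq_len(config$n_variants), function(i)
    .with_vseed(config$seed, i, role, {
      drop <- runif(1, 0, config$an_dropout_max)
      an <- max(2L, .rhu(2 * n_ind * (1 - drop)))
      c(an, rbinom(1L, an, truth$q[i]))
    }), numeric(2))
  frequency_table(data.frame(key = truth$key, af = res[2, ] / res[1, ],
                             an = as.integer(res[1, ]), stringsAsFactors = FALSE),
                  n_individuals = n_ind, name = name)
}

#' Generate one case cohort and one control panel with known truth
#'
#' @param config a [simulation_config()].
#' @return list with `case` ([case_cohort()]), `control`
#'   ([frequency_table()]), `variants` ([variant_records()]), `evidence`
#'   (gene-evidence table for the cascade) and `truth` (per-variant
#'   baseline frequency `q`, true odds ratio `psi`, `planted` flag).
#'   Byte-identical under a fixed seed.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) .stop2("config must be a simulation_config")
  truth <- .sim_truth(config)
  ann <- .sim_annotations(config, truth)
  list(case = .sim_case(config, truth, config$n_cases, 2L, "sim_cases"),
       control = .sim_panel(config, truth, config$n_controls, 4L, "sim_controls"),
       variants = ann$variants, evidence = ann$evidence, truth = truth)
}

#' Generate the full two-case, two-panel study design from one truth
#'
#' Both case cohorts and both control panels are drawn independently from
#' the same per-variant truth (`q`, `psi`), mirroring a discovery cohort, a
#' replication cohort and two population panels.
#'
#' @param config a [simulation_config()].
#' @return list with `case1`, `case2`, `control1`, `control2`, `variants`,
#'   `evidence`, `truth`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "simulation_config")) .stop2("config must be a simulation_config")
  truth <- .sim_truth(config)
  ann <- .sim_annotations(config, truth)
  list(case1 = .sim_case(config, truth, config$n_cases, 2L, "sim_cases1"),
       case2 = .sim_case(config, truth, config$n_cases2, 3L, "sim_cases2"),
       control1 = .sim_panel(config, truth, config$n_controls, 4L, "sim_controls1"),
       control2 = .sim_panel(config, truth, config$n_controls2, 5L, "sim_controls2"),
       variants = ann$variants, evidence = ann$evidence, truth = truth)
}

#' Score a selection against the planted truth
#'
#' @param truth the `truth` component of a generated cohort/study.
#' @param selected_keys keys selected by the pipeline.
#' @return list with `n_planted`, `n_selected`, `true_positives`,
#'   `sensitivity` (recovered fraction of planted variants) and `fdp`
#'   (false-discovery proportion of the selection; 0 for an empty
#'   selection).
#' @export
recover_planted <- function(truth, selected_keys) {
  planted_keys <- truth$key[truth$planted]
  tp <- length(intersect(selected_keys, planted_keys))
  list(n_planted = length(planted_keys),
       n_selected = length(selected_keys),
       true_positives = tp,
       sensitivity = if (length(planted_keys)) tp / length(planted_keys) else NA_real_,
       fdp = if (length(selected_keys)) (length(selected_keys) - tp) / length(selected_keys) else 0)
}
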