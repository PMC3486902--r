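test_that("cohort generation is deterministic given config and seed", {
  cfg <- blastomere_cfg(n_cases = 5, n_control_samples = 4, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$cases$karyotype, b$cases$karyotype)
  c <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(a$samples$truth, c$samples$truth))
  # the generator restores the caller's RNG state
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(simulate_cohort(cfg))
  expect_identical(runif(1), before)
})

test_that("degenerate rates concentrate all carrier errors on involved chromosomes", {
  cfg <- sim_config(
    n_cases = 8, samples_per_case = 6, n_control_samples = 6,
    karyotype_pool = test_pool,
    baseline_rates = c(PB = 0, blastomere = 0, TE = 0),
    involved_malseg_rate = 1, ice_multiplier = 1, age_slope = 0, seed = 3
  )
  cohort <- simulate_cohort(cfg)
  carrier <- cohort$samples[cohort$samples$arm == "carrier", ]
  excl <- icecohort:::exclusion_pairs(cohort$cases)
  aberrant <- carrier[carrier$truth != "EXPECTED", ]
  on_involved <- dplyr::semi_join(aberrant, excl, by = c("case_id", "chromosome"))
  expect_equal(nrow(on_involved), nrow(aberrant))
  expect_gt(nrow(aberrant), 0)
  # non-involved tallies are error-free
  tal <- tally_samples(cohort$samples, cohort$cases, state_col = "truth")
  expect_true(all(tal$errors == 0))
})

test_that("with no inter-chromosomal effect, carrier and control rates agree", {
  cfg <- blastomere_cfg(
    n_cases = 60, samples_per_case = 10, n_control_samples = 10,
    ice_multiplier = 1, seed = 23
  )
  cohort <- simulate_cohort(cfg)
  r_carrier <- arm_rate(cohort, "carrier")
  r_control <- arm_rate(cohort, "control")
  # >= 10,000 chromosomes per arm; difference within 3 binomial SE
  tal <- tally_samples(cohort$samples, cohort$cases, state_col = "truth")
  n_chrom <- sum(tal$chromosomes_assessed[tal$arm == "carrier"])
  expect_gte(n_chrom, 10000)
  p_lab <- 2 * 0.053
  se <- sqrt(2 * p_lab * (1 - p_lab) / (n_chrom / 2)) / 2
  expect_lt(abs(r_carrier - r_control), 3 * se)
})

test_that("the cleavage-stage effect multiplies the carrier rate as configured", {
  # 50 cases x 8 blastomeres at baseline 0.053 with multiplier 1.25:
  # carrier non-involved rate should sit near 0.066
  cfg <- blastomere_cfg(
    n_cases = 50, samples_per_case = 8, n_control_samples = 5,
    ice_multiplier = 1.25, seed = 11
  )
  cohort <- simulate_cohort(cfg)
  tal <- tally_samples(cohort$samples, cohort$cases, state_col = "truth")
  carrier <- tal[tal$arm == "carrier", ]
  err <- sum(carrier$errors)
  n_chrom <- sum(carrier$chromosomes_assessed)
  rate <- err / n_chrom
  target <- 0.053 * 1.25
  p_lab <- 2 * target
  n_lab <- n_chrom / 2
  se <- sqrt(p_lab * (1 - p_lab) / n_lab) / 2
  expect_lt(abs(rate - target), 3 * se)

  # independent binomial-sampling oracle: the observed error count must sit
  # inside the bulk of Binom(n_lab, 2 * target) draws
  set.seed(99)
  oracle <- rbinom(4000, n_lab, p_lab)
  expect_gt(err, quantile(oracle, 0.0005))
  expect_lt(err, quantile(oracle, 0.9995))
})

test_that("per-(stage, age) cells recover their configured rates", {
  cfg <- sim_config(
    n_cases = 60, samples_per_case = 10, n_control_samples = 10,
    karyotype_pool = test_pool,
    stage_mix = c(PB = 0.5, blastomere = 0.5, TE = 0),
    ages = c(30, 40), age_weights = c(0.5, 0.5), age_slope = 0.12,
    ice_multiplier = 1, seed = 37
  )
  cohort <- simulate_cohort(cfg)
  ctrl <- cohort$samples[cohort$samples$arm == "control", ]
  ctrl <- dplyr::left_join(
    ctrl,
    dplyr::select(cohort$cases, case_id, maternal_age, excluded),
    by = "case_id"
  )
  excl_pairs <- icecohort:::exclusion_pairs(cohort$cases)
  ctrl <- dplyr::anti_join(ctrl, excl_pairs, by = c("case_id", "chromosome"))
  cells <- ctrl |>
    dplyr::group_by(stage, maternal_age) |>
    dplyr::summarise(
      n_lab = dplyr::n(),
      errs = sum(truth != "EXPECTED"),
      .groups = "drop"
    )
  for (i in seq_len(nrow(cells))) {
    r_cfg <- baseline_rate(cfg, cells$stage[i], cells$maternal_age[i])
    p_lab <- ifelse(cells$stage[i] == "PB", r_cfg, 2 * r_cfg)
    n_chrom <- ifelse(cells$stage[i] == "PB", cells$n_lab[i], 2 * cells$n_lab[i])
    if (n_chrom < 5000) next
    emp <- cells$errs[i] / cells$n_lab[i]
    se <- sqrt(p_lab * (1 - p_lab) / cells$n_lab[i])
    expect_lt(abs(emp - p_lab), 3 * se)
  }
  # a monotone age ramp yields monotone simulated rates at these cell sizes
  by_age <- ctrl |>
    dplyr::filter(stage == "blastomere") |>
    dplyr::group_by(maternal_age) |>
    dplyr::summarise(rate = mean(truth != "EXPECTED"), .groups = "drop") |>
    dplyr::arrange(maternal_age)
  expect_true(all(diff(by_age$rate) > 0))
})

test_that("age calibration keeps the pooled rate at the configured baseline", {
  cfg <- sim_config(
    karyotype_pool = test_pool,
    ages = 26:43, age_weights = rep(1 / 18, 18), age_slope = 0.1, seed = 1
  )
  for (st in stages()) {
    pooled <- sum(cfg$age_weights * baseline_rate(cfg, st, cfg$ages))
    expect_equal(pooled, cfg$baseline_rates[[st]], tolerance = 1e-9)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(
    sim_config(
      karyotype_pool = test_pool,
      baseline_rates = c(PB = 0.08, blastomere = 0.45, TE = 0.02),
      ice_multiplier = 1.5
    ),
    "probability.*> 1"
  )
  expect_error(
    sim_config(karyotype_pool = test_pool, involved_malseg_rate = 1.3)
  )
  expect_error(
    sim_config(karyotype_pool = test_pool, stage_mix = c(PB = 1, blastomere = 1, TE = 1))
  )
  expect_error(sim_config(karyotype_pool = "46,XX,r(13)(p11q21)"), "unsupported")
})

test_that("noise-free array profiles sit exactly at the class centres", {
  labels <- complement_labels()
  truth <- tibble::tibble(
    sample_id = "s1", chromosome = labels,
    truth = dplyr::case_when(
      labels == "13" ~ "LOSS",
      labels == "7" ~ "GAIN",
      TRUE ~ "EXPECTED"
    )
  )
  cfg <- sim_config(karyotype_pool = test_pool, ratio_noise_sd = 0, probes_per_chromosome = 20)
  prof <- simulate_acgh_profile(truth, cfg, seed = 1)
  expect_equal(nrow(prof), 23 * 20)
  expect_true(all(prof$ratio[prof$chromosome == "13"] == 0.5))
  expect_true(all(prof$ratio[prof$chromosome == "7"] == 1.5))
  expect_true(all(prof$ratio[!prof$chromosome %in% c("7", "13")] == 1.0))

  all_expected <- dplyr::mutate(truth, truth = "EXPECTED")
  flat <- simulate_acgh_profile(all_expected, cfg, seed = 1)
  expect_true(all(flat$ratio == 1.0))
})

test_that("noisy profile medians stay near their class centres", {
  cfg <- sim_config(karyotype_pool = test_pool, ratio_noise_sd = 0.1, seed = 5)
  cohort <- simulate_cohort(blastomere_cfg(
    n_cases = 10, samples_per_case = 20,
    n_control_samples = 1, seed = 5
  ))
  truth <- cohort$samples[cohort$samples$arm == "carrier", ]
  prof <- simulate_acgh_profile(truth, cfg, seed = 6)
  centers <- c(EXPECTED = 1.0, LOSS = 0.5, GAIN = 1.5)
  med <- prof |>
    dplyr::group_by(sample_id, chromosome) |>
    dplyr::summarise(m = stats::median(ratio), .groups = "drop") |>
    dplyr::left_join(truth, by = c("sample_id", "chromosome"))
  near <- abs(med$m - centers[med$truth]) < 0.05
  expect_gte(mean(near), 0.99)
})
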