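test_that("per-sample complements follow the haploid/diploid exclusion arithmetic", {
  expect_equal(per_sample_complement("PB", 2), 21L)
  expect_equal(per_sample_complement("PB", 0), 23L)
  expect_equal(per_sample_complement("blastomere", 3), 40L)
  expect_equal(per_sample_complement("TE", 1), 44L)
  # printed stage codes are accepted
  expect_equal(per_sample_complement("Bla", 2), 42L)
  expect_error(per_sample_complement("PB", 23), "not positive")
  expect_error(per_sample_complement("PB", -1))
})

test_that("every packaged case row's denominator equals samples x complement", {
  cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
  expect_equal(cases$expected_chromosomes, cases$chromosomes_assessed)
  # and the compound couple's three-chromosome exclusion is what makes its row work
  compound <- cases[cases$rearrangement_class == "compound", ]
  expect_equal(compound$n_excluded, 3L)
  expect_equal(compound$expected_chromosomes, 8L * 40L)
})

test_that("control denominators equal control samples x the matched patient's complement", {
  cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
  controls <- read_control_table(ice_example("table3_control_groups.tsv"))
  comp <- cases$complement_size[match(controls$case_id, cases$case_id)]
  expect_equal(controls$n_samples * comp, controls$chromosomes_assessed)
})

test_that("pooled carrier and control totals reproduce the reference cohort", {
  cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
  controls <- read_control_table(ice_example("table3_control_groups.tsv"))
  tal <- tally_cases(cases)
  pooled <- pool_tally(tal)
  expect_equal(pooled$chromosomes, 10837)
  expect_equal(pooled$errors, 553)
  expect_equal(sum(controls$chromosomes_assessed), 204406)
  # the control error column sums to 9598 (its printed totals row is off by one)
  expect_equal(sum(controls$errors), 9598)
})

test_that("direct tallies count non-excluded aberrations only", {
  labels <- complement_labels()
  two_samples <- tidyr::expand_grid(
    sample_id = c("b1", "b2"), chromosome = labels
  ) |>
    dplyr::mutate(
      case_id = "c1", stage = "blastomere",
      state = ifelse(sample_id == "b1" & chromosome == "21", "GAIN", "EXPECTED")
    )
  no_excl <- annotate_case_fixture("c1", "46,XX,t(9;16)(p13.1;p11.2)", "blastomere", 2)
  no_excl$excluded <- list(character(0))
  no_excl$n_excluded <- 0L
  tal <- tally_samples(two_samples, no_excl)
  expect_equal(tal$chromosomes_assessed, 92)
  expect_equal(tal$errors, 1)

  # an aberration on an excluded chromosome does not count
  one_sample <- tibble::tibble(
    sample_id = "b1", case_id = "c1", stage = "blastomere",
    chromosome = labels,
    state = ifelse(labels == "9", "LOSS", "EXPECTED")
  )
  excl_case <- annotate_case_fixture("c1", "46,XX,t(9;16)(p13.1;p11.2)", "blastomere", 1)
  expect_equal(tally_samples(one_sample, excl_case)$errors, 0)
})

test_that("tallies agree with a brute-force recount on a simulated cohort", {
  cohort <- simulate_cohort(blastomere_cfg(n_cases = 6, n_control_samples = 5, seed = 42))
  tal <- tally_samples(cohort$samples, cohort$cases, state_col = "truth")

  # independent nested-loop recount over every (sample, chromosome) pair
  brute <- list()
  for (arm in unique(cohort$samples$arm)) {
    for (cid in cohort$cases$case_id) {
      sub <- cohort$samples[cohort$samples$arm == arm & cohort$samples$case_id == cid, ]
      excl <- cohort$cases$excluded[[match(cid, cohort$cases$case_id)]]
      err <- 0L
      for (i in seq_len(nrow(sub))) {
        if (sub$truth[i] %in% c("GAIN", "LOSS") && !(sub$chromosome[i] %in% excl)) {
          err <- err + 1L
        }
      }
      brute[[paste(arm, cid)]] <- err
    }
  }
  got <- stats::setNames(tal$errors, paste(tal$arm, tal$case_id))
  expect_equal(got[names(brute)], unlist(brute))
})

test_that("stage tables reproduce the per-stage reference rates", {
  cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
  controls <- read_control_table(ice_example("table3_control_groups.tsv"))
  st <- stage_table(tally_cases(cases), controls)

  pick <- function(arm, stage) st[st$arm == arm & st$stage == stage, ]
  expect_equal(pick("carrier", "PB")$chromosomes, 1057)
  expect_equal(pick("carrier", "PB")$errors, 78)
  expect_equal(round(pick("carrier", "PB")$pct, 1), 7.4)
  expect_equal(pick("carrier", "blastomere")$chromosomes, 6158)
  expect_equal(pick("carrier", "blastomere")$errors, 404)
  expect_equal(round(pick("carrier", "blastomere")$pct, 1), 6.6)
  expect_equal(pick("carrier", "TE")$chromosomes, 3622)
  expect_equal(pick("carrier", "TE")$errors, 71)
  expect_equal(round(pick("carrier", "TE")$pct, 0), 2)
  expect_equal(pick("control", "blastomere")$chromosomes, 151644)
  expect_equal(pick("control", "blastomere")$errors, 7978)
  expect_equal(round(pick("control", "blastomere")$pct, 1), 5.3)
})

test_that("tallying with exclusions equals tallying without, minus the excluded contribution", {
  cohort <- simulate_cohort(blastomere_cfg(n_cases = 5, n_control_samples = 4, seed = 9))
  carrier <- cohort$samples[cohort$samples$arm == "carrier", ]
  with_excl <- tally_samples(carrier, cohort$cases, state_col = "truth")

  open_cases <- cohort$cases
  open_cases$excluded <- rep(list(character(0)), nrow(open_cases))
  open_cases$n_excluded <- 0L
  without <- tally_samples(carrier, open_cases, state_col = "truth")

  excl_pairs <- icecohort:::exclusion_pairs(cohort$cases)
  excl_errors <- carrier |>
    dplyr::semi_join(excl_pairs, by = c("case_id", "chromosome")) |>
    dplyr::group_by(case_id) |>
    dplyr::summarise(excl = sum(truth %in% c("GAIN", "LOSS")), .groups = "drop")

  merged <- dplyr::left_join(without, excl_errors, by = "case_id") |>
    dplyr::mutate(excl = tidyr::replace_na(excl, 0L))
  expect_equal(
    merged$errors - merged$excl,
    with_excl$errors[match(merged$case_id, with_excl$case_id)]
  )
})

test_that("missing states that are not flagged NOCALL are a data error", {
  samples <- tibble::tibble(
    sample_id = "s1", case_id = "c1", stage = "PB",
    chromosome = complement_labels(),
    state = c(NA, rep("EXPECTED", 22))
  )
  case <- annotate_case_fixture("c1", "45,XX,der(13;14)(q10;q10)", "PB", 1)
  expect_error(tally_samples(samples, case), "missing chromosome state")
  # NOCALL is tolerated and never counts as an error
  samples$state[1] <- "NOCALL"
  expect_equal(tally_samples(samples, case)$errors, 0)
})
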