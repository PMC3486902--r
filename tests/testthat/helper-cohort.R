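# Shared fixtures for the simulation-based tests: a small karyotype pool
# covering all three rearrangement classes, and compact cohort
# configurations.

test_pool <- c(
  "45,XX,der(13;14)(q10;q10)",
  "46,XY,t(9;16)(p13.1;p11.2)",
  "45,XY,der(14;21)(q10;q10)",
  "46,XX,t(1;2)(q24;p21)"
)

# blastomere-only configuration in the study's cleavage-stage rate regime
blastomere_cfg <- function(n_cases = 50, samples_per_case = 8,
                           n_control_samples = 20, ice_multiplier = 1.25,
                           seed = 11, ...) {
  sim_config(
    n_cases = n_cases, samples_per_case = samples_per_case,
    n_control_samples = n_control_samples,
    karyotype_pool = test_pool,
    stage_mix = c(PB = 0, blastomere = 1, TE = 0),
    age_slope = 0,
    ice_multiplier = ice_multiplier,
    seed = seed, ...
  )
}

# polar-body configuration with control groups matched in size to the
# patient: the weighting transform is the identity and haploid counting is
# exactly binomial, so the chi-squared variance model holds
pb_matched_cfg <- function(n_cases = 40, samples_per_case = 10,
                           ice_multiplier = 1, seed = 2) {
  sim_config(
    n_cases = n_cases, samples_per_case = samples_per_case,
    n_control_samples = samples_per_case,
    karyotype_pool = test_pool,
    stage_mix = c(PB = 1, blastomere = 0, TE = 0),
    age_slope = 0,
    ice_multiplier = ice_multiplier,
    seed = seed
  )
}

# pooled empirical error rate over non-involved chromosomes for one arm
arm_rate <- function(cohort, which_arm, state_col = "truth") {
  tal <- tally_samples(cohort$samples, cohort$cases, state_col = state_col)
  tal <- tal[tal$arm == which_arm, ]
  sum(tal$errors) / sum(tal$chromosomes_assessed)
}

# one-row annotated case table built in code
annotate_case_fixture <- function(case_id, karyotype, stage, n_samples,
                                  maternal_age = 35) {
  icecohort:::annotate_cases(tibble::tibble(
    case_id = case_id, patient_id = paste0("pat_", case_id),
    maternal_age = maternal_age, karyotype = karyotype,
    stage = stage, n_samples = as.integer(n_samples)
  ))
}

# delta-method SE of a rate ratio from label-level binomial counts
rr_se <- function(rr, p1, n1, p2, n2) {
  rr * sqrt((1 - p1) / (n1 * p1) + (1 - p2) / (n2 * p2))
}
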