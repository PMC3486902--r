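# Monte-Carlo operating characteristics of the pipeline: type-I error under
# the null (no inter-chromosomal effect) and power across effect sizes and
# cohort sizes.

#' Run the pooled carrier-vs-weighted-control test on a simulated cohort
#'
#' Convenience wrapper chaining the accounting, weighting and testing
#' stages: tallies carrier and control samples, rescales the matched
#' control tallies to each patient's chromosome count, pools, and tests.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param state_col Which state column to score (`"called"` by default;
#'   `"truth"` bypasses the call-accuracy channel).
#' @param round Passed to [weight_control()].
#' @return An [ice_test()] object for the pooled stratum.
#' @export
#' @examples
#' fit <- cohort_ice_test(simulate_cohort(sim_config(n_cases = 6, seed = 3)))
#' glance(fit)
cohort_ice_test <- function(cohort, state_col = "called", round = TRUE) {
  tallies <- tally_samples(cohort$samples, cohort$cases, state_col = state_col)
  carrier <- filter(tallies, .data$arm == "carrier")
  control <- filter(tallies, .data$arm == "control")
  weighted <- weight_control(control, carrier, round = round)
  pooled_c <- pool_tally(carrier)
  pooled_w <- pool_weighted(weighted)
  ice_test(
    pooled_c$errors, pooled_c$chromosomes,
    pooled_w$expected_errors, pooled_w$patient_chromosomes,
    stratum = "pooled simulated cohort"
  )
}

#' Monte-Carlo power of the pooled inter-chromosomal effect test
#'
#' For each combination of effect size and cohort size, simulates `reps`
#' cohorts, runs the full pipeline ([cohort_ice_test()]) on each, and
#' reports the fraction of replicates whose pooled p-value falls below
#' `alpha`. With `ice_multiplier = 1` this estimates the type-I error,
#' which should sit near `alpha`; power is monotone non-decreasing in both
#' the multiplier and the cohort size up to Monte-Carlo noise.
#'
#' @param config Base [sim_config()]; the grid overrides its
#'   `ice_multiplier` and `n_cases`.
#' @param ice_multipliers,n_cases Numeric grids.
#' @param reps Replicates per grid cell (>= 100 recommended for stable
#'   estimates).
#' @param alpha Significance level.
#' @param seed Seed for the experiment; per-replicate seeds are derived
#'   from it.
#' @param state_col Passed to [cohort_ice_test()].
#' @return A tibble: `ice_multiplier`, `n_cases`, `reps`, `alpha`, `power`,
#'   `mc_se` (binomial Monte-Carlo standard error).
#' @export
power_experiment <- function(config, ice_multipliers = c(1, 1.25, 1.5),
                             n_cases = config$n_cases, reps = 200,
                             alpha = 0.05, seed = config$seed,
                             state_col = "called") {
  stopifnot(reps >= 1, alpha > 0, alpha < 1)
  grid <- tidyr::expand_grid(ice_multiplier = ice_multipliers, n_cases = n_cases)
  purrr::pmap_dfr(grid, function(ice_multiplier, n_cases) {
    cfg <- config
    cfg$ice_multiplier <- ice_multiplier
    cfg$n_cases <- as.integer(n_cases)
    if (max_label_prob(cfg) > 1) {
      abort("ice_multiplier pushes a per-label event probability above 1")
    }
    pvals <- vapply(seq_len(reps), function(r) {
      # keep derived seeds well inside 32-bit integer range
      rep_seed <- (seed * 69069 + r * 1009 +
        round(1e4 * ice_multiplier) * 31 + n_cases) %% 2147483647L
      cohort <- simulate_cohort(cfg, seed = as.integer(rep_seed))
      cohort_ice_test(cohort, state_col = state_col)$p_value
    }, numeric(1))
    power <- mean(pvals < alpha)
    tibble(
      ice_multiplier = ice_multiplier, n_cases = n_cases, reps = reps,
      alpha = alpha, power = power,
      mc_se = sqrt(power * (1 - power) / reps)
    )
  })
}
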