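# Synthetic carrier/control cohort generator. Emulates the statistical
# structure the analysis assumes: stage- and age-dependent per-chromosome
# aneuploidy in controls, a multiplicative inter-chromosomal effect on
# non-involved chromosomes in carrier samples at configurable stages, high
# malsegregation of rearrangement-involved chromosomes, and a stage-specific
# call-accuracy channel.

# RNG hygiene: run `code` under a fixed seed, restoring the caller's RNG
# state afterwards so simulation calls do not perturb the session.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Configure the synthetic cohort generator
#'
#' Defaults reproduce the study-scale conditions of the reference cohort:
#' 54 carrier cases with karyotypes drawn from the packaged carrier pool,
#' the observed case mix over biopsy stages and maternal ages, control
#' per-chromosome aneuploidy rates of 8.0% (polar bodies), 5.3%
#' (blastomeres) and 2.0% (trophectoderm), platform call accuracies of
#' 94%/98%/95% for the three stages, and a cleavage-stage-only
#' inter-chromosomal effect.
#'
#' @param n_cases Number of carrier cases.
#' @param samples_per_case Samples with a result per carrier case.
#' @param n_control_samples Matched control samples per case.
#' @param karyotype_pool Character vector of carrier karyotypes to draw
#'   from; defaults to the packaged reference karyotypes.
#' @param stage_mix Named proportions over `stages()` for the case mix.
#' @param ages,age_weights Discrete maternal-age distribution (years).
#'   Defaults to the empirical case ages of the packaged case table.
#' @param baseline_rates Named per-chromosome aneuploidy probabilities for
#'   control samples at each stage, at the pooled (age-marginal) level.
#' @param age_slope Log-odds increase in the baseline rate per year of
#'   maternal age. The per-stage logistic intercepts are calibrated so the
#'   rate averaged over the age distribution equals `baseline_rates`; 0
#'   turns the age ramp off.
#' @param ice_multiplier Multiplicative factor (>= 0) applied to the
#'   baseline rate of non-involved chromosomes in carrier samples at the
#'   stages in `ice_stages`. 1 = no inter-chromosomal effect.
#' @param ice_stages Stages at which the effect acts (default cleavage
#'   stage only).
#' @param involved_malseg_rate Probability that a rearrangement-involved
#'   chromosome is aberrant in a carrier sample.
#' @param call_accuracy Named per-stage probability that a chromosome's
#'   state is called correctly; miscalls go to a uniformly random other
#'   state.
#' @param probes_per_chromosome,ratio_noise_sd Array-profile simulation:
#'   probes per chromosome and the standard deviation of the multiplicative
#'   (log-normal) probe noise.
#' @param seed Default seed recorded in the config and used by
#'   [simulate_cohort()] when no seed is passed.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 10, seed = 1)
#' cfg$baseline_rates
sim_config <- function(n_cases = 54,
                       samples_per_case = 5,
                       n_control_samples = 94,
                       karyotype_pool = NULL,
                       stage_mix = c(PB = 9, blastomere = 29, TE = 16) / 54,
                       ages = NULL,
                       age_weights = NULL,
                       baseline_rates = c(PB = 0.080, blastomere = 0.053, TE = 0.020),
                       age_slope = 0.1,
                       ice_multiplier = 1.25,
                       ice_stages = "blastomere",
                       involved_malseg_rate = 0.4,
                       call_accuracy = c(PB = 0.94, blastomere = 0.98, TE = 0.95),
                       probes_per_chromosome = 100,
                       ratio_noise_sd = 0.1,
                       seed = 1L) {
  if (is.null(karyotype_pool)) {
    karyotype_pool <- readr::read_tsv(
      ice_example("table1_patients.tsv"),
      col_types = readr::cols(), progress = FALSE
    )$karyotype
  }
  if (is.null(ages)) {
    case_ages <- readr::read_tsv(
      ice_example("table2_carrier_cases.tsv"),
      col_types = readr::cols(), progress = FALSE
    )$maternal_age
    tab <- table(case_ages)
    ages <- as.numeric(names(tab))
    age_weights <- as.numeric(tab) / sum(tab)
  }
  if (is.null(age_weights)) age_weights <- rep(1 / length(ages), length(ages))

  stopifnot(
    n_cases >= 1, samples_per_case >= 1, n_control_samples >= 1,
    length(karyotype_pool) >= 1,
    setequal(names(stage_mix), stages()),
    all(stage_mix >= 0), abs(sum(stage_mix) - 1) < 1e-8,
    length(ages) == length(age_weights), all(age_weights >= 0),
    setequal(names(baseline_rates), stages()),
    all(baseline_rates >= 0 & baseline_rates <= 1),
    ice_multiplier >= 0,
    involved_malseg_rate >= 0 && involved_malseg_rate <= 1,
    setequal(names(call_accuracy), stages()),
    all(call_accuracy >= 0 & call_accuracy <= 1),
    probes_per_chromosome >= 1, ratio_noise_sd >= 0
  )
  age_weights <- age_weights / sum(age_weights)
  parse_karyotype(karyotype_pool) # validates the pool

  cfg <- structure(
    list(
      n_cases = as.integer(n_cases),
      samples_per_case = as.integer(samples_per_case),
      n_control_samples = as.integer(n_control_samples),
      karyotype_pool = karyotype_pool,
      stage_mix = stage_mix[stages()],
      ages = ages,
      age_weights = age_weights,
      baseline_rates = baseline_rates[stages()],
      age_slope = age_slope,
      ice_multiplier = ice_multiplier,
      ice_stages = normalize_stage(ice_stages),
      involved_malseg_rate = involved_malseg_rate,
      call_accuracy = call_accuracy[stages()],
      probes_per_chromosome = as.integer(probes_per_chromosome),
      ratio_noise_sd = ratio_noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  cfg$age_intercepts <- calibrate_age_intercepts(cfg)

  # the effective per-label event probability (diploid stages score net
  # per-pair states, see baseline_rate()) must stay a probability
  worst <- max_label_prob(cfg)
  if (worst > 1) {
    abort(sprintf(
      "baseline_rate x ice_multiplier implies per-label event probability %.3f > 1",
      worst
    ))
  }
  cfg
}

# Solve, per stage, the logistic intercept such that the age-averaged rate
# matches the configured pooled baseline rate.
calibrate_age_intercepts <- function(cfg) {
  vapply(stages(), function(st) {
    target <- cfg$baseline_rates[[st]]
    if (target == 0 || cfg$age_slope == 0) {
      return(if (target %in% c(0, 1)) qlogis(pmin(pmax(target, 1e-12), 1 - 1e-12)) else qlogis(target))
    }
    f <- function(b0) {
      sum(cfg$age_weights * plogis(b0 + cfg$age_slope * (cfg$ages - mean_age(cfg)))) - target
    }
    uniroot(f, interval = qlogis(target) + c(-10, 10), tol = 1e-12)$root
  }, numeric(1))
}

mean_age <- function(cfg) sum(cfg$ages * cfg$age_weights)

#' Stage- and age-dependent baseline aneuploidy rate
#'
#' Per-chromosome aneuploidy probability for control samples: a logistic
#' ramp in maternal age around the cohort mean age, calibrated per stage so
#' that the rate averaged over the configured age distribution equals the
#' configured pooled rate.
#'
#' @param config A [sim_config()].
#' @param stage,age Vectors (recycled) of stage codes and maternal ages.
#' @return Numeric vector of probabilities.
#' @export
baseline_rate <- function(config, stage, age) {
  stage <- normalize_stage(stage)
  b0 <- config$age_intercepts[stage]
  r <- plogis(b0 + config$age_slope * (age - mean_age(config)))
  # exact zero must stay zero (degenerate configs)
  r[config$baseline_rates[stage] == 0] <- 0
  unname(r)
}

# Per-label event probability. Diploid (embryo) samples carry one net state
# per chromosome pair while rates are per chromosome over 46-2k
# denominators, so a per-chromosome rate r corresponds to a per-label net
# event probability of 2r; oocyte (PB-derived) complements are haploid and
# use r directly.
label_prob <- function(rate, stage) {
  ifelse(stage == "PB", rate, pmin(2 * rate, 1))
}

max_label_prob <- function(cfg) {
  worst_age <- cfg$ages[which.max(cfg$ages)]
  max(vapply(stages(), function(st) {
    r <- baseline_rate(cfg, st, worst_age) *
      ifelse(st %in% cfg$ice_stages, cfg$ice_multiplier, 1)
    ifelse(st == "PB", r, 2 * r)
  }, numeric(1)))
}

#' Print method for simulator configurations
#' @param x A `sim_config`.
#' @param ... Unused.
#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ICE cohort configuration\n")
  cat(sprintf(
    "  %d carrier cases x %d samples; %d control samples per case\n",
    x$n_cases, x$samples_per_case, x$n_control_samples
  ))
  cat(sprintf(
    "  baseline rates PB %.3f / blastomere %.3f / TE %.3f (age slope %.2f per year)\n",
    x$baseline_rates[["PB"]], x$baseline_rates[["blastomere"]],
    x$baseline_rates[["TE"]], x$age_slope
  ))
  cat(sprintf(
    "  ICE multiplier %.2f at %s; involved-chromosome malsegregation %.2f\n",
    x$ice_multiplier, paste(x$ice_stages, collapse = "+"), x$involved_malseg_rate
  ))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Simulate a carrier cohort with patient-matched controls
#'
#' Draws a cohort of carrier cases (karyotype, stage, maternal age) and, per
#' case, carrier samples plus a matched control group at the same stage and
#' age. Non-involved chromosomes are aberrant independently at the baseline
#' rate, multiplied by the configured inter-chromosomal effect for carrier
#' samples at the effect stages; rearrangement-involved chromosomes are
#' aberrant at the involved-malsegregation rate; control samples see the
#' baseline rate only. Aberrations are gains or losses with equal
#' probability. A second, `called` state column applies the stage-specific
#' call-accuracy channel (a symmetric misclassification to a uniformly
#' random other state).
#'
#' The generator is deterministic given `config` and `seed`, and restores
#' the caller's RNG state on exit.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with class `ice_cohort`: `cases` (annotated case table,
#'   one row per carrier case), `samples` (long tibble: `arm`, `sample_id`,
#'   `case_id`, `stage`, `chromosome`, `truth`, `called`), `config`, and
#'   `seed`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cases = 4, seed = 7))
#' dplyr::count(cohort$samples, arm, truth)
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_cases
    cases_raw <- tibble(
      case_id = sprintf("sim%03d", seq_len(n)),
      patient_id = sprintf("simpat%03d", seq_len(n)),
      maternal_age = sample(config$ages, n, replace = TRUE, prob = config$age_weights),
      karyotype = sample(config$karyotype_pool, n, replace = TRUE),
      stage = sample(stages(), n, replace = TRUE, prob = config$stage_mix[stages()]),
      n_samples = config$samples_per_case
    )
    cases <- annotate_cases(cases_raw, "simulated cases")

    labels <- complement_labels()
    build_arm <- function(arm, per_case_n, prefix) {
      idx <- rep(seq_len(n), each = per_case_n * length(labels))
      samp <- rep(rep(seq_len(per_case_n), each = length(labels)), times = n)
      grid <- tibble(
        arm = arm,
        sample_id = sprintf("%s%03d_%02d", prefix, idx, samp),
        case_id = cases$case_id[idx],
        stage = cases$stage[idx],
        maternal_age = cases$maternal_age[idx],
        chromosome = rep(labels, times = n * per_case_n)
      )
      excl <- mutate(exclusion_pairs(cases), involved = TRUE)
      grid <- grid %>%
        left_join(excl, by = c("case_id", "chromosome")) %>%
        mutate(involved = !is.na(.data$involved))
      base <- baseline_rate(config, grid$stage, grid$maternal_age)
      mult <- ifelse(
        arm == "carrier" & grid$stage %in% config$ice_stages,
        config$ice_multiplier, 1
      )
      p <- label_prob(base * mult, grid$stage)
      if (arm == "carrier") {
        p[grid$involved] <- config$involved_malseg_rate
      }
      aberrant <- runif(nrow(grid)) < p
      direction <- ifelse(runif(nrow(grid)) < 0.5, "LOSS", "GAIN")
      truth <- ifelse(aberrant, direction, "EXPECTED")
      # symmetric misclassification channel: with probability 1 - accuracy,
      # the call lands uniformly on one of the two states != truth
      acc <- unname(config$call_accuracy[grid$stage])
      flip <- runif(nrow(grid)) >= acc
      u <- runif(nrow(grid)) < 0.5
      other <- ifelse(truth == "EXPECTED",
        ifelse(u, "GAIN", "LOSS"),
        ifelse(u, "EXPECTED", ifelse(truth == "GAIN", "LOSS", "GAIN"))
      )
      called <- ifelse(flip, other, truth)
      grid %>%
        mutate(truth = truth, called = called) %>%
        select("arm", "sample_id", "case_id", "stage", "chromosome", "truth", "called")
    }

    samples <- bind_rows(
      build_arm("carrier", config$samples_per_case, "emb"),
      build_arm("control", config$n_control_samples, "ctrl")
    )
    structure(
      list(cases = cases, samples = samples, config = config, seed = seed),
      class = "ice_cohort"
    )
  })
}

#' @export
print.ice_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic ICE cohort: %d carrier cases, %d samples (%d carrier / %d control), seed %d\n",
    nrow(x$cases),
    dplyr::n_distinct(x$samples$sample_id),
    dplyr::n_distinct(x$samples$sample_id[x$samples$arm == "carrier"]),
    dplyr::n_distinct(x$samples$sample_id[x$samples$arm == "control"]),
    x$seed
  ))
  invisible(x)
}

#' Simulate microarray-CGH probe ratio profiles from true copy states
#'
#' For each sample and chromosome, draws `probes_per_chromosome` linear
#' test/reference fluorescence ratios around the copy-state centre — 1.0
#' for the expected state, 0.5 for a net single-copy loss, 1.5 for a net
#' single-copy gain (polar-body-derived samples use the same
#' oocyte-equivalent convention) — with multiplicative log-normal noise of
#' standard deviation `ratio_noise_sd`. With zero noise the ratios equal
#' the class centres exactly.
#'
#' @param truth Tibble of true states: columns `sample_id`, `chromosome`,
#'   and a state column `truth` (or `state`). Typically the carrier/control
#'   samples of [simulate_cohort()].
#' @param config A [sim_config()] (probe count and noise sd are read from
#'   it).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble: `sample_id`, `chromosome`, `probe_index`, `ratio`.
#' @export
#' @examples
#' truth <- tibble::tibble(
#'   sample_id = "s1", chromosome = complement_labels(),
#'   truth = c("LOSS", rep("EXPECTED", 22))
#' )
#' prof <- simulate_acgh_profile(truth, sim_config(ratio_noise_sd = 0), seed = 1)
#' unique(prof$ratio[prof$chromosome == "1"])
simulate_acgh_profile <- function(truth, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  state_col <- if ("truth" %in% names(truth)) "truth" else "state"
  states <- truth[[state_col]]
  bad <- setdiff(unique(states), c("EXPECTED", "GAIN", "LOSS"))
  if (length(bad) > 0) {
    abort(sprintf("cannot simulate probes for state '%s'", bad[[1]]))
  }
  centers <- c(EXPECTED = 1.0, LOSS = 0.5, GAIN = 1.5)
  m <- config$probes_per_chromosome
  with_seed(seed, {
    n <- nrow(truth)
    out <- tibble(
      sample_id = rep(truth$sample_id, each = m),
      chromosome = rep(truth$chromosome, each = m),
      probe_index = rep(seq_len(m), times = n),
      center = rep(unname(centers[states]), each = m)
    )
    noise <- if (config$ratio_noise_sd > 0) {
      exp(rnorm(nrow(out), mean = 0, sd = config$ratio_noise_sd))
    } else {
      1
    }
    out %>%
      mutate(ratio = .data$center * noise) %>%
      select(-"center")
  })
}
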