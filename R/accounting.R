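# Aneuploidy accounting: from per-sample copy states (or printed per-case
# tallies) to chromosomes-assessed / errors-detected tallies per case, stage
# and rearrangement class, with the rearranged chromosomes excluded.

#' Chromosomes assessed per sample after exclusions
#'
#' Polar-body (oocyte) analysis scores a haploid complement, so excluding
#' `k` distinct rearranged chromosomes leaves `23 - k` assessable
#' chromosomes per sample. Cleavage-stage and trophectoderm samples are
#' diploid, and excluding a chromosome removes both homologues: `46 - 2k`.
#'
#' @param stage Stage code(s), see [stages()] (printed codes accepted).
#' @param n_excluded Number of distinct chromosomes excluded per case.
#' @return Integer vector of per-sample assessable chromosome counts.
#' @export
#' @examples
#' per_sample_complement("PB", 2) # 21
#' per_sample_complement("blastomere", 3) # 40
#' per_sample_complement("TE", 1) # 44
per_sample_complement <- function(stage, n_excluded) {
  stage <- normalize_stage(stage)
  stopifnot(all(n_excluded >= 0))
  out <- ifelse(stage == "PB", 23L - as.integer(n_excluded),
    46L - 2L * as.integer(n_excluded)
  )
  if (any(out <= 0)) {
    abort("per-sample complement is not positive: too many excluded chromosomes")
  }
  out
}

# Long (case_id, chromosome) exclusion pairs from an annotated case table.
exclusion_pairs <- function(cases) {
  cases %>%
    select("case_id", "excluded") %>%
    tidyr::unnest(cols = "excluded") %>%
    rename(chromosome = "excluded")
}

#' Tally aneuploidies per case from per-sample copy states
#'
#' Counts, per case (and per arm if an `arm` column distinguishes carrier
#' from matched control samples), the number of (sample, chromosome) pairs
#' whose state is `GAIN` or `LOSS` on a chromosome *not* involved in the
#' case's rearrangement. The denominator is `n_samples` times the
#' stage-specific per-sample complement ([per_sample_complement()]): net
#' per-pair states are scored once per chromosome label, while diploid
#' denominators count both homologues, matching how microarray-CGH reports
#' net copy number.
#'
#' @param samples Long per-sample state tibble (columns `sample_id`,
#'   `case_id`, `stage`, `chromosome`, `state`, optionally `arm`).
#' @param cases Annotated case table ([read_case_table()] or the `cases`
#'   element of [simulate_cohort()]).
#' @param state_col Which column holds the states to score (e.g. `"truth"`
#'   or `"called"` for simulated cohorts; default `"state"`).
#' @return A tibble with one row per (arm,) case: stratum labels
#'   (`stage`, `rearrangement_class`, `carrier_sex`, `maternal_age` when
#'   available), `n_samples`, `chromosomes_assessed`, `errors`.
#' @export
tally_samples <- function(samples, cases, state_col = "state") {
  if (!state_col %in% names(samples)) {
    abort(sprintf("samples table has no '%s' column", state_col))
  }
  samples <- mutate(samples, .state = .data[[state_col]])
  if (anyNA(samples$.state)) {
    bad <- samples$sample_id[which(is.na(samples$.state))[[1]]]
    abort(sprintf(
      "sample '%s' has a missing chromosome state not flagged NOCALL", bad
    ))
  }
  if (!"arm" %in% names(samples)) samples <- mutate(samples, arm = "carrier")

  excl <- mutate(exclusion_pairs(cases), .excluded = TRUE)
  scored <- samples %>%
    left_join(excl, by = c("case_id", "chromosome")) %>%
    mutate(
      .excluded = !is.na(.data$.excluded),
      .is_err = (.data$.state == "GAIN" | .data$.state == "LOSS") & !.data$.excluded
    )

  meta_cols <- intersect(
    c("stage", "rearrangement_class", "carrier_sex", "maternal_age", "n_excluded"),
    names(cases)
  )
  n_samp <- scored %>%
    distinct(.data$arm, .data$case_id, .data$sample_id) %>%
    count(.data$arm, .data$case_id, name = "n_samples")
  errs <- scored %>%
    filter(.data$.is_err) %>%
    count(.data$arm, .data$case_id, name = "errors")
  counts <- n_samp %>%
    left_join(errs, by = c("arm", "case_id")) %>%
    mutate(errors = tidyr::replace_na(.data$errors, 0L))
  counts %>%
    left_join(select(cases, "case_id", dplyr::all_of(meta_cols)), by = "case_id") %>%
    mutate(
      chromosomes_assessed = .data$n_samples *
        per_sample_complement(.data$stage, .data$n_excluded),
      .before = "errors"
    ) %>%
    select(-dplyr::any_of("n_excluded"))
}

#' Per-case tallies from an observed case table
#'
#' For case tables that already carry observed error counts (the study-scale
#' reference tables), recomputes the chromosomes-assessed denominator from
#' the karyotype and sample count and returns a tally tibble in the same
#' shape as [tally_samples()].
#'
#' @param cases Annotated case table with an `errors` column.
#' @return A tibble with `arm = "carrier"`, stratum labels, `n_samples`,
#'   `chromosomes_assessed` (recomputed), and `errors`.
#' @export
#' @examples
#' cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
#' sum(tally_cases(cases)$chromosomes_assessed)
tally_cases <- function(cases) {
  if (!"errors" %in% names(cases)) {
    abort("case table has no 'errors' column; use tally_samples() on sample data")
  }
  if (any(cases$errors > cases$expected_chromosomes)) {
    abort("errors exceed chromosomes assessed for at least one case")
  }
  cases %>%
    mutate(
      arm = "carrier",
      chromosomes_assessed = .data$expected_chromosomes
    ) %>%
    select(
      "arm", "case_id", "stage", "rearrangement_class", "carrier_sex",
      "maternal_age", "n_samples", "chromosomes_assessed", "errors"
    )
}

#' Pool tallies into per-stage rates for both arms
#'
#' Aggregates carrier tallies and control-group tallies stage by stage, the
#' per-chromosome malsegregation rate being errors over chromosomes
#' assessed.
#'
#' @param carrier_tallies Tally tibble for carriers ([tally_cases()] or
#'   [tally_samples()] output).
#' @param control_tallies Control-group tibble with `stage`,
#'   `chromosomes_assessed`, `errors` (e.g. [read_control_table()] output),
#'   or a tally tibble from simulated control samples. Optional.
#' @return A tibble with one row per arm and stage: `chromosomes`, `errors`,
#'   `rate`, and `pct` (rate in percent).
#' @export
#' @examples
#' cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
#' controls <- read_control_table(ice_example("table3_control_groups.tsv"))
#' stage_table(tally_cases(cases), controls)
stage_table <- function(carrier_tallies, control_tallies = NULL) {
  pool_arm <- function(x, arm) {
    x %>%
      mutate(arm = if ("arm" %in% names(x)) .data$arm else arm) %>%
      group_by(.data$arm, .data$stage) %>%
      summarise(
        chromosomes = sum(.data$chromosomes_assessed),
        errors = sum(.data$errors),
        .groups = "drop"
      )
  }
  out <- pool_arm(carrier_tallies, "carrier")
  if (!is.null(control_tallies)) {
    out <- bind_rows(out, pool_arm(control_tallies, "control"))
  }
  out %>%
    mutate(
      rate = .data$errors / .data$chromosomes,
      pct = 100 * .data$rate,
      stage = factor(.data$stage, levels = stages())
    ) %>%
    arrange(.data$arm, .data$stage)
}

#' Pool a set of tallies into one total
#'
#' @param tallies Tally tibble with `chromosomes_assessed` and `errors`.
#' @return One-row tibble: `n_cases`, `n_samples` (if present),
#'   `chromosomes`, `errors`, `rate`.
#' @export
pool_tally <- function(tallies) {
  tibble(
    n_cases = nrow(tallies),
    n_samples = if ("n_samples" %in% names(tallies)) sum(tallies$n_samples) else NA_integer_,
    chromosomes = sum(tallies$chromosomes_assessed),
    errors = sum(tallies$errors),
    rate = sum(tallies$errors) / sum(tallies$chromosomes_assessed)
  )
}

#' Flag samples abnormal on non-rearranged chromosomes
#'
#' A sample counts as abnormal at the embryo level only if at least one
#' chromosome *outside* the matched rearrangement is aberrant; samples whose
#' only aneuploidies involve the rearranged chromosomes are not evidence of
#' an inter-chromosomal effect.
#'
#' @inheritParams tally_samples
#' @return A tibble with one row per (arm,) sample: `abnormal` logical.
#' @export
sample_abnormal <- function(samples, cases, state_col = "state") {
  samples <- mutate(samples, .state = .data[[state_col]])
  if (!"arm" %in% names(samples)) samples <- mutate(samples, arm = "carrier")
  excl <- mutate(exclusion_pairs(cases), .excluded = TRUE)
  samples %>%
    left_join(excl, by = c("case_id", "chromosome")) %>%
    mutate(.excluded = !is.na(.data$.excluded)) %>%
    group_by(.data$arm, .data$case_id, .data$sample_id) %>%
    summarise(
      abnormal = any(.data$.state %in% c("GAIN", "LOSS") & !.data$.excluded),
      .groups = "drop"
    )
}
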