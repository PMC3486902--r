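# Matched-control weighting: give each patient-matched control group the
# same weight as its patient by converting the control error rate into an
# expected error count at the patient's chromosome count.

#' Round half away from zero
#'
#' Rounding convention of the weighting transform: `x.5` always rounds up
#' (for non-negative input), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector (non-negative in this pipeline).
#' @return `floor(x + 0.5)`.
#' @export
#' @examples
#' round_half_up(c(1.5, 2.5, 1.49))
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Rescale matched control groups to their patients' chromosome counts
#'
#' Control groups differ widely in size, so pooling their raw tallies would
#' weight some maternal ages far more heavily than the matched patients
#' they stand for. The weighting transform fixes this: each control group's
#' per-chromosome error frequency (errors / chromosomes assessed) is
#' multiplied by the matched patient's assessed chromosome count, giving the
#' error count the control group would have shown had it comprised exactly
#' as many samples as its patient. Expected counts are rounded half-up to
#' integers by default; `round = FALSE` keeps the raw expectations for
#' sensitivity analysis (rounding then summing differs from summing then
#' rounding).
#'
#' @param controls Control-group tibble ([read_control_table()] schema, or a
#'   control-arm tally from [tally_samples()]): columns `case_id`,
#'   `chromosomes_assessed`, `errors`.
#' @param cases Annotated case table supplying each patient's assessed
#'   chromosome count (`expected_chromosomes`, or `chromosomes_assessed` for
#'   tally input), joined by `case_id`.
#' @param round Round expected counts half-up to integers (default `TRUE`).
#' @return A tibble with one row per matched case: `case_id`, `stage`,
#'   `control_rate`, `patient_chromosomes`, `expected_errors`,
#'   `expected_normal` (`patient_chromosomes - expected_errors`).
#' @export
#' @examples
#' cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
#' controls <- read_control_table(ice_example("table3_control_groups.tsv"))
#' weight_control(controls, cases)
weight_control <- function(controls, cases, round = TRUE) {
  if (any(controls$chromosomes_assessed <= 0)) {
    abort("control group with zero chromosomes assessed cannot be weighted")
  }
  pat_col <- if ("expected_chromosomes" %in% names(cases)) {
    "expected_chromosomes"
  } else {
    "chromosomes_assessed"
  }
  pat <- cases %>%
    select("case_id", patient_chromosomes = dplyr::all_of(pat_col))
  out <- controls %>%
    left_join(pat, by = "case_id")
  if (anyNA(out$patient_chromosomes)) {
    abort(sprintf(
      "no matched patient for control group(s): %s",
      paste(out$case_id[is.na(out$patient_chromosomes)], collapse = ", ")
    ))
  }
  out <- out %>%
    mutate(
      control_rate = .data$errors / .data$chromosomes_assessed,
      expected_errors = .data$control_rate * .data$patient_chromosomes
    )
  if (round) {
    out <- mutate(out, expected_errors = round_half_up(.data$expected_errors))
  }
  out %>%
    mutate(expected_normal = .data$patient_chromosomes - .data$expected_errors) %>%
    select(
      "case_id", dplyr::any_of(c("stage", "age")), "control_rate",
      "patient_chromosomes", "expected_errors", "expected_normal"
    )
}

#' Pool weighted control groups
#'
#' Sums expected error and expected normal counts over all matched control
#' groups. Control groups shared between two cases of the same patient are
#' counted once per case, exactly as each case's own weighted values — no
#' deduplication.
#'
#' @param weighted Output of [weight_control()], one row per case.
#' @return One-row tibble: `n_groups`, `expected_errors`, `expected_normal`,
#'   `patient_chromosomes`, `rate` (pooled expected error rate).
#' @export
pool_weighted <- function(weighted) {
  if (anyDuplicated(weighted$case_id)) {
    abort(sprintf(
      "duplicate case_id in weighted controls: %s",
      paste(unique(weighted$case_id[duplicated(weighted$case_id)]), collapse = ", ")
    ))
  }
  tibble(
    n_groups = nrow(weighted),
    expected_errors = sum(weighted$expected_errors),
    expected_normal = sum(weighted$expected_normal),
    patient_chromosomes = sum(weighted$patient_chromosomes),
    rate = sum(weighted$expected_errors) / sum(weighted$patient_chromosomes)
  )
}
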