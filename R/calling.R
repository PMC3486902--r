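# Whole-chromosome copy-number calling from (simulated) aCGH ratio
# profiles. The analysis unit is the whole chromosome: per chromosome the
# median probe ratio is compared with fixed linear-ratio thresholds. No
# within-chromosome segmentation.

#' Calling thresholds for whole-chromosome copy-number states
#'
#' Defaults are the midpoints between the copy-number class centres on the
#' linear ratio scale (expected 1.0, net single-copy loss 0.5, net
#' single-copy gain 1.5): below 0.75 calls a loss, above 1.25 a gain.
#'
#' @param loss_below Median linear ratio below which a chromosome is called
#'   `LOSS`.
#' @param gain_above Median ratio above which a chromosome is called
#'   `GAIN`.
#' @param min_probes Minimum probes per chromosome for a confident call;
#'   chromosomes with fewer probes are flagged `NOCALL`.
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(loss_below = 0.75, gain_above = 1.25, min_probes = 10) {
  if (!(loss_below > 0 && loss_below < 1 && gain_above > 1)) {
    abort("need 0 < loss_below < 1 < gain_above")
  }
  if (min_probes < 1) abort("min_probes must be >= 1")
  structure(
    list(
      loss_below = loss_below, gain_above = gain_above,
      min_probes = as.integer(min_probes)
    ),
    class = "call_thresholds"
  )
}

#' Call whole-chromosome copy-number states from a probe-ratio profile
#'
#' Per sample and chromosome, the median probe ratio is compared with the
#' thresholds: median below `loss_below` calls `LOSS`, above `gain_above`
#' calls `GAIN`, otherwise `EXPECTED`. Chromosomes with fewer than
#' `min_probes` probes are flagged `NOCALL` rather than guessed. The median
#' (not the mean) gives robustness to outlying probes.
#'
#' @param profile Long probe tibble: `sample_id`, `chromosome`, `ratio`
#'   (as from [simulate_acgh_profile()] or [read_profile_table()]).
#' @param thresholds A [call_thresholds()] object.
#' @return A tibble with one row per sample and chromosome: `n_probes`,
#'   `median_ratio`, `state` (provenance: called).
#' @export
#' @examples
#' truth <- tibble::tibble(
#'   sample_id = "s1", chromosome = complement_labels(),
#'   truth = ifelse(complement_labels() %in% c("1", "13"), "LOSS", "EXPECTED")
#' )
#' prof <- simulate_acgh_profile(truth, sim_config(ratio_noise_sd = 0), seed = 1)
#' dplyr::filter(call_copy_number(prof), state != "EXPECTED")
call_copy_number <- function(profile, thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  if (any(profile$ratio <= 0)) abort("probe ratios must be positive")
  profile %>%
    group_by(.data$sample_id, .data$chromosome) %>%
    summarise(
      n_probes = n(),
      median_ratio = median(.data$ratio),
      .groups = "drop"
    ) %>%
    mutate(
      state = dplyr::case_when(
        .data$n_probes < thresholds$min_probes ~ "NOCALL",
        .data$median_ratio < thresholds$loss_below ~ "LOSS",
        .data$median_ratio > thresholds$gain_above ~ "GAIN",
        TRUE ~ "EXPECTED"
      )
    )
}
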