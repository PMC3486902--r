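# Tab-separated readers and writers for the pipeline's three tables: cases,
# patient-matched control groups, and long-format per-sample copy states.
# TSV, UTF-8, header row, "." for missing.

#' Locate a packaged example table
#'
#' The package ships the study-scale reference tables as plain-text fixtures:
#' carrier karyotypes (`table1_patients.tsv`), per-case carrier tallies
#' (`table2_carrier_cases.tsv`), matched control-group tallies
#' (`table3_control_groups.tsv`), the weighted control expectations
#' (`table5_weighted_controls.tsv`), and the cleavage-stage
#' Robertsonian embryo-level counts (`embryo_level_robertsonian.tsv`).
#'
#' @param file Name of a file under `extdata`. With no argument, lists the
#'   available files.
#' @param verify If `TRUE`, check the file's MD5 checksum against the
#'   packaged manifest and fail on mismatch.
#' @return Full path to the file (or a character vector of file names).
#' @export
#' @examples
#' ice_example()
#' ice_example("table2_carrier_cases.tsv")
ice_example <- function(file = NULL, verify = TRUE) {
  dir <- system.file("extdata", package = "icecohort", mustWork = TRUE)
  if (is.null(file)) {
    return(setdiff(list.files(dir), "MANIFEST.md5"))
  }
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    abort(sprintf("no packaged file '%s'; see ice_example() for the list", file))
  }
  if (verify && file != "MANIFEST.md5") {
    manifest <- utils::read.table(
      file.path(dir, "MANIFEST.md5"),
      col.names = c("md5", "name"), stringsAsFactors = FALSE
    )
    want <- manifest$md5[manifest$name == file]
    if (length(want) == 1 && !identical(unname(tools::md5sum(path)), want)) {
      abort(sprintf("checksum mismatch for packaged file '%s'", file))
    }
  }
  path
}

read_tsv_strict <- function(path, col_types) {
  out <- readr::read_tsv(
    path,
    col_types = col_types, na = c("", "."), progress = FALSE
  )
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  missing <- setdiff(names(col_types$cols), names(out))
  if (length(missing) > 0) {
    abort(sprintf(
      "'%s' is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  out
}

#' Read a carrier case table
#'
#' One row per case (one PGD cycle of one carrier couple at one biopsy
#' stage). Requires columns `case_id`, `patient_id`, `maternal_age`,
#' `karyotype`, `stage`, `n_samples`; any further columns (e.g. observed
#' `chromosomes_assessed` and `errors`) are kept. Karyotypes are parsed on
#' read and the case is annotated with its rearrangement class, carrier sex,
#' excluded chromosomes and stage-specific per-sample complement.
#'
#' @param path Path to a TSV file. Stage codes `PB`, `Bla`/`blastomere`, and
#'   `TE` are accepted (case-insensitive).
#' @return A tibble of cases with columns `carrier_sex`,
#'   `rearrangement_class`, `excluded` (list of chromosome labels),
#'   `n_excluded`, `complement_size`, and `expected_chromosomes`
#'   (`n_samples * complement_size`) appended.
#' @export
#' @examples
#' cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
#' sum(cases$expected_chromosomes)
read_case_table <- function(path) {
  raw <- read_tsv_strict(path, readr::cols(
    case_id = readr::col_character(),
    patient_id = readr::col_character(),
    maternal_age = readr::col_double(),
    karyotype = readr::col_character(),
    stage = readr::col_character(),
    n_samples = readr::col_integer(),
    .default = readr::col_guess()
  ))
  if (anyDuplicated(raw$case_id)) {
    abort(sprintf(
      "duplicate case_id in '%s': %s",
      path, paste(unique(raw$case_id[duplicated(raw$case_id)]), collapse = ", ")
    ))
  }
  annotate_cases(raw, path)
}

# Shared case annotation; row numbers preserved for error messages. Each
# distinct karyotype is parsed exactly once.
annotate_cases <- function(raw, origin = "case table") {
  ukt <- unique(raw$karyotype)
  events <- vector("list", length(ukt))
  for (j in seq_along(ukt)) {
    ev <- tryCatch(parse_karyotype(ukt[[j]]), error = function(e) e)
    if (inherits(ev, "error")) {
      row <- which(raw$karyotype == ukt[[j]])[[1]]
      abort(sprintf("%s row %d: %s", origin, row, conditionMessage(ev)))
    }
    events[[j]] <- ev
  }
  stage_ok <- tryCatch(normalize_stage(raw$stage), error = function(e) e)
  if (inherits(stage_ok, "error")) {
    bad <- which(is.na(match(
      tolower(as.character(raw$stage)),
      c("pb", "bla", "blastomere", "te", "trophectoderm")
    )))[[1]]
    abort(sprintf("%s row %d: %s", origin, bad, conditionMessage(stage_ok)))
  }
  if (any(raw$n_samples < 0, na.rm = TRUE)) {
    abort(sprintf(
      "%s row %d: n_samples must be >= 0",
      origin, which(raw$n_samples < 0)[[1]]
    ))
  }
  sex_u <- vapply(events, function(ev) {
    s <- unique(ev$carrier_sex)
    if (length(s) > 1) "both" else s
  }, character(1))
  class_u <- vapply(events, function(ev) {
    if (nrow(ev) > 1) "compound" else ev$kind
  }, character(1))
  excl_u <- lapply(events, function(ev) {
    chroms <- unique(stats::na.omit(c(ev$chrom_1, ev$chrom_2)))
    chroms[order(match(chroms, CHROM_LABELS))]
  })
  idx <- match(raw$karyotype, ukt)
  out <- raw %>%
    mutate(
      stage = stage_ok,
      carrier_sex = sex_u[idx],
      rearrangement_class = class_u[idx],
      excluded = excl_u[idx],
      n_excluded = lengths(.data$excluded),
      complement_size = per_sample_complement(.data$stage, .data$n_excluded),
      expected_chromosomes = .data$n_samples * .data$complement_size
    )
  as_tibble(out)
}

#' Read a matched control-group table
#'
#' One row per patient-matched control group: aggregated tallies from
#' karyotypically normal patients of the same age, biopsy stage, clinic and
#' time window as the matched carrier case, with the matched patient's
#' rearranged chromosomes excluded from both denominator and error count.
#'
#' @param path Path to a TSV with columns `case_id` (the matched carrier
#'   case), `age`, `stage`, `n_patients`, `n_samples`,
#'   `chromosomes_assessed`, `errors`.
#' @return A tibble with canonical stage codes.
#' @export
read_control_table <- function(path) {
  out <- read_tsv_strict(path, readr::cols(
    case_id = readr::col_character(),
    age = readr::col_double(),
    stage = readr::col_character(),
    n_patients = readr::col_integer(),
    n_samples = readr::col_integer(),
    chromosomes_assessed = readr::col_integer(),
    errors = readr::col_integer()
  ))
  bad <- which(out$errors > out$chromosomes_assessed)
  if (length(bad) > 0) {
    abort(sprintf("'%s' row %d: errors exceed chromosomes assessed", path, bad[[1]]))
  }
  mutate(out, stage = normalize_stage(.data$stage))
}

#' Read a weighted-control reference table
#'
#' Schema of the packaged `table5_weighted_controls.tsv`: per matched case,
#' the control group's raw tally alongside its published expected error and
#' expected normal counts after rescaling to the patient's chromosome count.
#' Used to check the weighting transform row for row.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_weighted_table <- function(path) {
  read_tsv_strict(path, readr::cols(
    case_id = readr::col_character(),
    age = readr::col_double(),
    n_patient_samples = readr::col_integer(),
    n_control_samples = readr::col_integer(),
    control_chromosomes = readr::col_integer(),
    control_errors = readr::col_integer(),
    expected_errors = readr::col_integer(),
    expected_normal = readr::col_integer()
  ))
}

#' Read embryo-level abnormality counts
#'
#' Per analysis arm, the number of samples abnormal for at least one
#' chromosome outside the matched rearrangement and the total samples
#' considered; either counts or a pre-computed proportion may be given
#' (missing values as `.`).
#'
#' @param path Path to a TSV with columns `arm`, `abnormal_samples`,
#'   `total_samples`, `abnormal_proportion`.
#' @return A tibble.
#' @export
read_embryo_level_table <- function(path) {
  read_tsv_strict(path, readr::cols(
    arm = readr::col_character(),
    abnormal_samples = readr::col_integer(),
    total_samples = readr::col_integer(),
    abnormal_proportion = readr::col_double()
  ))
}

SAMPLE_STATES <- c("EXPECTED", "GAIN", "LOSS", "NOCALL")

#' Read and write long-format per-sample copy-state tables
#'
#' The sample table is the pipeline's exchange format for called (or
#' simulated) whole-chromosome copy states: one row per sample and
#' chromosome label, state one of `EXPECTED`, `GAIN`, `LOSS`, `NOCALL`.
#' `write_sample_table()` and `read_sample_table()` are loss-free inverses
#' on valid data.
#'
#' @param path Path to a TSV with columns `sample_id`, `case_id`, `stage`,
#'   `chromosome`, `state` (additional columns such as `arm` are kept).
#' @param allow_missing If `FALSE` (default), every sample must cover the
#'   full 23-label complement of [complement_labels()]; missing rows are an
#'   error naming the sample. If `TRUE`, missing labels are tolerated
#'   (treated as no-calls downstream).
#' @return A tibble of per-chromosome states.
#' @export
read_sample_table <- function(path, allow_missing = FALSE) {
  out <- read_tsv_strict(path, readr::cols(
    sample_id = readr::col_character(),
    case_id = readr::col_character(),
    stage = readr::col_character(),
    chromosome = readr::col_character(),
    state = readr::col_character(),
    .default = readr::col_guess()
  ))
  validate_sample_table(mutate(out, stage = normalize_stage(.data$stage)),
    allow_missing = allow_missing, origin = path
  )
}

validate_sample_table <- function(x, allow_missing = FALSE, origin = "sample table") {
  bad_state <- setdiff(unique(x$state), SAMPLE_STATES)
  if (length(bad_state) > 0) {
    abort(sprintf(
      "%s: invalid state '%s' (expected %s)",
      origin, bad_state[[1]], paste(SAMPLE_STATES, collapse = "/")
    ))
  }
  bad_chrom <- setdiff(unique(x$chromosome), CHROM_LABELS)
  if (length(bad_chrom) > 0) {
    abort(sprintf("%s: invalid chromosome label '%s'", origin, bad_chrom[[1]]))
  }
  dup <- x %>%
    count(.data$sample_id, .data$chromosome) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "%s: duplicate (sample, chromosome) rows, e.g. sample '%s' chromosome %s",
      origin, dup$sample_id[[1]], dup$chromosome[[1]]
    ))
  }
  if (!allow_missing) {
    cover <- x %>%
      group_by(.data$sample_id) %>%
      summarise(n_labels = dplyr::n_distinct(.data$chromosome), .groups = "drop") %>%
      filter(.data$n_labels < length(complement_labels()))
    if (nrow(cover) > 0) {
      abort(sprintf(
        "%s: sample '%s' covers only %d of %d chromosome labels",
        origin, cover$sample_id[[1]], cover$n_labels[[1]],
        length(complement_labels())
      ))
    }
  }
  x
}

#' @rdname read_sample_table
#' @param x A tibble of per-chromosome states as produced by
#'   [simulate_cohort()] or [call_copy_number()].
#' @export
write_sample_table <- function(x, path) {
  stopifnot(all(c("sample_id", "case_id", "stage", "chromosome", "state") %in% names(x)))
  readr::write_tsv(x, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Write an aCGH-like probe-ratio profile table
#'
#' Long format: one row per probe, columns `sample_id`, `chromosome`,
#' `probe_index`, `ratio` (linear test/reference fluorescence ratio).
#'
#' @param x Profile tibble from [simulate_acgh_profile()].
#' @param path Output TSV path.
#' @export
write_profile_table <- function(x, path) {
  stopifnot(all(c("sample_id", "chromosome", "probe_index", "ratio") %in% names(x)))
  readr::write_tsv(x, path, na = ".", progress = FALSE)
  invisible(path)
}

#' @rdname write_profile_table
#' @export
read_profile_table <- function(path) {
  out <- read_tsv_strict(path, readr::cols(
    sample_id = readr::col_character(),
    chromosome = readr::col_character(),
    probe_index = readr::col_integer(),
    ratio = readr::col_double()
  ))
  if (any(out$ratio <= 0, na.rm = TRUE)) {
    abort(sprintf("'%s': probe ratios must be positive", path))
  }
  out
}
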