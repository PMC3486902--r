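# Carrier vs weighted-control inference: per-chromosome malsegregation
# rates, Yates-corrected chi-squared tests on 2x2 tallies, relative risks,
# and stratified analyses by rearrangement class, biopsy stage and carrier
# sex.

#' Per-chromosome malsegregation rate
#'
#' @param errors,chromosomes Error and chromosomes-assessed counts
#'   (vectorized).
#' @return `errors / chromosomes` as a probability.
#' @export
#' @examples
#' per_chromosome_rate(553, 10837)
per_chromosome_rate <- function(errors, chromosomes) {
  if (any(chromosomes <= 0)) {
    abort("chromosomes assessed must be positive to form a rate")
  }
  if (any(errors < 0 | errors > chromosomes)) {
    abort("errors must lie in [0, chromosomes assessed]")
  }
  errors / chromosomes
}

#' Yates-corrected chi-squared test on a 2x2 table
#'
#' Continuity-corrected Pearson statistic on the 2x2 table
#' `rbind(c(a, b), c(c, d))`: expected counts from the margins, each cell
#' contributing `max(|O - E| - 0.5, 0)^2 / E`. The correction is clamped at
#' zero so a table with identical row proportions gives statistic 0 and
#' p = 1. Two-sided p-value from the upper tail of the chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param a,b,c,d Cell counts (vectorized): by convention `a` = carrier
#'   errors, `b` = carrier normal, `c` = control expected errors, `d` =
#'   control expected normal.
#' @return A tibble with columns `statistic`, `p_value`.
#' @export
#' @examples
#' yates_chi2(553, 10284, 462, 10375)
yates_chi2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    abort("2x2 cell counts must be non-negative")
  }
  n <- a + b + c + d
  if (any((a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0)) {
    abort("2x2 table has a zero margin; the test is undefined")
  }
  stat <- rep(0, length(n))
  for (cell in list(
    list(o = a, r = a + b, k = a + c),
    list(o = b, r = a + b, k = b + d),
    list(o = c, r = c + d, k = a + c),
    list(o = d, r = c + d, k = b + d)
  )) {
    e <- cell$r * cell$k / n
    stat <- stat + pmax(abs(cell$o - e) - 0.5, 0)^2 / e
  }
  tibble(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Test a carrier tally against its weighted control expectation
#'
#' Assembles the 2x2 contingency table (carrier errors / normal vs control
#' expected errors / normal), the per-chromosome rates for both arms, their
#' difference, the chromosome-level relative risk (carrier rate over control
#' rate, unrounded), and the Yates-corrected chi-squared test.
#'
#' @param carrier_errors,carrier_chromosomes Carrier error count and
#'   chromosomes assessed.
#' @param control_errors,control_chromosomes Control (typically weighted
#'   expected) error count and chromosome total.
#' @param stratum Label for the stratum tested (default `"all"`).
#' @return An object of class `ice_test`; see [tidy.ice_test()] and
#'   [glance.ice_test()] for tibble views.
#' @export
#' @examples
#' ice_test(553, 10837, 462, 10837)
ice_test <- function(carrier_errors, carrier_chromosomes,
                     control_errors, control_chromosomes,
                     stratum = "all") {
  carrier_rate <- per_chromosome_rate(carrier_errors, carrier_chromosomes)
  control_rate <- per_chromosome_rate(control_errors, control_chromosomes)
  tab <- matrix(
    c(
      carrier_errors, carrier_chromosomes - carrier_errors,
      control_errors, control_chromosomes - control_errors
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      arm = c("carrier", "control"),
      outcome = c("error", "normal")
    )
  )
  test <- yates_chi2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  structure(
    list(
      stratum = stratum,
      table = tab,
      carrier_rate = carrier_rate,
      control_rate = control_rate,
      rate_difference = carrier_rate - control_rate,
      relative_risk = if (control_rate > 0) carrier_rate / control_rate else NA_real_,
      statistic = test$statistic,
      p_value = test$p_value
    ),
    class = "ice_test"
  )
}

#' @export
print.ice_test <- function(x, ...) {
  cat("Inter-chromosomal effect test (Yates-corrected chi-squared)\n")
  cat("Stratum:", x$stratum, "\n\n")
  print(x$table)
  cat(sprintf(
    "\ncarrier rate %.4f vs control rate %.4f (difference %+.4f)\n",
    x$carrier_rate, x$control_rate, x$rate_difference
  ))
  cat(sprintf(
    "relative risk %.3f, X-squared = %.3f, df = 1, p-value = %.4g\n",
    x$relative_risk, x$statistic, x$p_value
  ))
  invisible(x)
}

#' Tidy an inter-chromosomal effect test
#'
#' @param x An [ice_test()] object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with the stratum, the four 2x2 cells,
#'   both rates, the rate difference, relative risk, statistic and p-value.
#'   `glance()`: a one-row model summary (statistic, p-value, df, total
#'   chromosomes).
#' @method tidy ice_test
#' @export
tidy.ice_test <- function(x, ...) {
  tibble(
    stratum = x$stratum,
    carrier_errors = x$table[1, 1],
    carrier_normal = x$table[1, 2],
    control_errors = x$table[2, 1],
    control_normal = x$table[2, 2],
    carrier_rate = x$carrier_rate,
    control_rate = x$control_rate,
    rate_difference = x$rate_difference,
    relative_risk = x$relative_risk,
    statistic = x$statistic,
    p_value = x$p_value
  )
}

#' @rdname tidy.ice_test
#' @method glance ice_test
#' @export
glance.ice_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    df = 1L,
    n_chromosomes = sum(x$table)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Embryo-level abnormality comparison
#'
#' Compares the proportion of samples abnormal for at least one chromosome
#' outside the rearrangement between carriers and controls, and their ratio
#' (the relative risk of a carrier producing an abnormal embryo through
#' errors unrelated to the constitutional rearrangement). Because embryos
#' frequently carry several aneuploidies, this embryo-level risk is diluted
#' relative to the chromosome-level risk: extra aneuploidies often land in
#' embryos that were already abnormal.
#'
#' Counts may be given directly, as a data frame in the schema of
#' [read_embryo_level_table()], or as pre-computed proportions where counts
#' are unavailable.
#'
#' @param data Optional tibble with columns `arm` (`"carrier"`/`"control"`),
#'   `abnormal_samples`, `total_samples`, `abnormal_proportion`. When given,
#'   the remaining arguments are ignored.
#' @param carrier_abnormal,carrier_total,control_abnormal,control_total
#'   Abnormal and total sample counts per arm.
#' @param carrier_proportion,control_proportion Alternative to the counts.
#' @return One-row tibble: the counts used (NA when a proportion was
#'   supplied), `carrier_proportion`, `control_proportion`,
#'   `relative_risk`.
#' @export
#' @examples
#' embryo_level_comparison(
#'   read_embryo_level_table(ice_example("embryo_level_robertsonian.tsv"))
#' )
embryo_level_comparison <- function(data = NULL,
                                    carrier_abnormal = NULL, carrier_total = NULL,
                                    control_abnormal = NULL, control_total = NULL,
                                    carrier_proportion = NULL,
                                    control_proportion = NULL) {
  pick <- function(arm, col) {
    v <- data[[col]][data$arm == arm]
    if (length(v) != 1) {
      abort(sprintf("embryo-level table needs exactly one '%s' row", arm))
    }
    if (is.na(v)) NULL else v
  }
  if (!is.null(data)) {
    carrier_abnormal <- pick("carrier", "abnormal_samples")
    carrier_total <- pick("carrier", "total_samples")
    control_abnormal <- pick("control", "abnormal_samples")
    control_total <- pick("control", "total_samples")
    carrier_proportion <- pick("carrier", "abnormal_proportion")
    control_proportion <- pick("control", "abnormal_proportion")
  }
  prop <- function(abnormal, total, given, arm) {
    if (!is.null(abnormal) && !is.null(total)) {
      if (total <= 0) abort(sprintf("%s total samples must be positive", arm))
      if (abnormal < 0 || abnormal > total) {
        abort(sprintf("%s abnormal count must lie in [0, total]", arm))
      }
      abnormal / total
    } else if (!is.null(given)) {
      if (given < 0 || given > 1) abort(sprintf("%s proportion must be in [0,1]", arm))
      given
    } else {
      abort(sprintf("supply either counts or a proportion for the %s arm", arm))
    }
  }
  p_carrier <- prop(carrier_abnormal, carrier_total, carrier_proportion, "carrier")
  p_control <- prop(control_abnormal, control_total, control_proportion, "control")
  if (p_control == 0) {
    abort("control abnormal proportion is zero; relative risk undefined")
  }
  tibble(
    carrier_abnormal = carrier_abnormal %||% NA_integer_,
    carrier_total = carrier_total %||% NA_integer_,
    control_abnormal = control_abnormal %||% NA_integer_,
    control_total = control_total %||% NA_integer_,
    carrier_proportion = p_carrier,
    control_proportion = p_control,
    relative_risk = p_carrier / p_control
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified inter-chromosomal effect analysis
#'
#' Runs the full comparison — weight each matched control group to its
#' patient's chromosome count, pool carrier and weighted-control counts
#' within each stratum, test with [ice_test()] — for every stratum defined
#' by the requested variables.
#'
#' @param cases Annotated case table with observed `errors`
#'   ([read_case_table()]), or a carrier tally from [tally_samples()].
#' @param controls Control-group tibble ([read_control_table()] schema or a
#'   control-arm tally).
#' @param by Stratifying variables, any of `"class"` (rearrangement class),
#'   `"stage"`, `"sex"` (carrier sex). Empty (`character()`) pools
#'   everything into a single `"all"` stratum.
#' @param include_compound Keep the compound (two-rearrangement couple) case
#'   in the analysis? Defaults to `FALSE`: the compound case is part of
#'   stage-level accounting but excluded from stratified inference. Cases
#'   with carrier sex `"both"` are likewise dropped whenever `"sex"` is a
#'   stratifier.
#' @param min_chromosomes Strata whose carrier arm has fewer assessed
#'   chromosomes than this are flagged `underpowered` (default 1000).
#' @param round Passed to [weight_control()].
#' @return A tibble of class `ice_strata`: one row per non-empty stratum
#'   with the stratum labels, `n_cases`, the [tidy.ice_test()] columns and
#'   an `underpowered` flag. Empty strata are skipped with a message.
#' @export
#' @examples
#' cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
#' controls <- read_control_table(ice_example("table3_control_groups.tsv"))
#' stratified_ice(cases, controls, by = "class")
stratified_ice <- function(cases, controls, by = c("class", "stage"),
                           include_compound = FALSE,
                           min_chromosomes = 1000, round = TRUE) {
  var_map <- c(
    class = "rearrangement_class", stage = "stage",
    sex = "carrier_sex"
  )
  bad <- setdiff(by, names(var_map))
  if (length(bad) > 0) {
    abort(sprintf("unknown stratifier '%s' (use class/stage/sex)", bad[[1]]))
  }
  strat_vars <- unname(var_map[by])

  tallies <- if ("errors" %in% names(cases) && !"arm" %in% names(cases)) {
    tally_cases(cases)
  } else {
    cases
  }
  if (!include_compound) {
    tallies <- filter(tallies, .data$rearrangement_class != "compound")
  }
  if ("carrier_sex" %in% strat_vars) {
    tallies <- filter(tallies, .data$carrier_sex %in% c("male", "female"))
  }
  weighted <- controls %>%
    filter(.data$case_id %in% tallies$case_id) %>%
    weight_control(cases, round = round)

  joined <- tallies %>%
    left_join(
      select(weighted, "case_id", "expected_errors", "patient_chromosomes"),
      by = "case_id"
    )
  if (anyNA(joined$expected_errors)) {
    missing <- joined$case_id[is.na(joined$expected_errors)]
    message(
      "skipping case(s) without a matched control group: ",
      paste(missing, collapse = ", ")
    )
    joined <- filter(joined, !is.na(.data$expected_errors))
  }
  if (nrow(joined) == 0) {
    abort("no cases left to stratify")
  }

  grouped <- if (length(strat_vars) > 0) {
    group_by(joined, dplyr::across(dplyr::all_of(strat_vars)))
  } else {
    group_by(joined, stratum = "all")
  }
  pooled <- grouped %>%
    summarise(
      n_cases = n(),
      carrier_errors = sum(.data$errors),
      carrier_chromosomes = sum(.data$chromosomes_assessed),
      control_errors = sum(.data$expected_errors),
      control_chromosomes = sum(.data$patient_chromosomes),
      .groups = "drop"
    )

  label_cols <- if (length(strat_vars) > 0) strat_vars else "stratum"
  results <- purrr::pmap_dfr(pooled, function(...) {
    row <- list(...)
    label <- paste(unlist(row[label_cols]), collapse = " / ")
    fit <- ice_test(
      row$carrier_errors, row$carrier_chromosomes,
      row$control_errors, row$control_chromosomes,
      stratum = label
    )
    dplyr::bind_cols(
      tibble(
        !!!row[setdiff(label_cols, "stratum")],
        stratum = label,
        n_cases = row$n_cases
      ),
      tidy(fit)[, -1]
    )
  })
  out <- results %>%
    mutate(underpowered = (.data$carrier_errors + .data$carrier_normal) < min_chromosomes)
  class(out) <- c("ice_strata", class(out))
  out
}
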