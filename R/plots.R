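# ggplot2 views of the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot carrier vs control rates for one test
#'
#' @param object An [ice_test()] result.
#' @param ... Unused.
#' @return A ggplot: per-chromosome malsegregation rate by arm, annotated
#'   with the error/total counts.
#' @method autoplot ice_test
#' @export
autoplot.ice_test <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(
      c("carrier_rate", "control_rate"),
      names_to = "arm", values_to = "rate"
    ) %>%
    mutate(
      arm = sub("_rate", "", .data$arm),
      label = ifelse(.data$arm == "carrier",
        sprintf("%d / %d", .data$carrier_errors, .data$carrier_errors + .data$carrier_normal),
        sprintf("%d / %d", .data$control_errors, .data$control_errors + .data$control_normal)
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$rate, fill = .data$arm)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.1f%%", 100 * x)) +
    ggplot2::labs(
      title = sprintf("Malsegregation of structurally normal chromosomes (%s)", object$stratum),
      subtitle = sprintf(
        "RR %.3f, Yates X² = %.2f, p = %.3g",
        object$relative_risk, object$statistic, object$p_value
      ),
      x = NULL, y = "per-chromosome rate"
    ) +
    ggplot2::theme_minimal()
}

#' Plot relative risks across strata
#'
#' @param object An `ice_strata` tibble from [stratified_ice()].
#' @param ... Unused.
#' @return A ggplot: chromosome-level relative risk per stratum, with
#'   under-powered strata hollow and the null (RR = 1) marked.
#' @method autoplot ice_strata
#' @export
autoplot.ice_strata <- function(object, ...) {
  df <- mutate(as_tibble(object),
    stratum = factor(.data$stratum, levels = rev(.data$stratum))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relative_risk, y = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$underpowered), size = 3) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 1),
      labels = c(`FALSE` = "adequate", `TRUE` = "under-powered"),
      name = "chromosome count"
    ) +
    ggplot2::labs(
      x = "chromosome-level relative risk (carrier / weighted control)",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-stage malsegregation rates for both arms
#'
#' @param x A stage table from [stage_table()].
#' @return A ggplot: grouped bars of the per-chromosome rate by biopsy
#'   stage and arm.
#' @export
plot_stage_rates <- function(x) {
  ggplot2::ggplot(
    x,
    ggplot2::aes(x = .data$stage, y = .data$rate, fill = .data$arm)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.7), width = 0.6) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
      position = ggplot2::position_dodge(width = 0.7), vjust = -0.4, size = 3
    ) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "biopsy stage", y = "per-chromosome malsegregation rate", fill = NULL) +
    ggplot2::theme_minimal()
}
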