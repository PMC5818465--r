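#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a thermal accumulation
#'
#' @param object Result of [accumulate_thermal()].
#' @param ... Unused.
#' @return A ggplot of the running total over time.
#' @export
autoplot.thermal_accumulation <- function(object, ...) {
  model <- attr(object, "model")
  lab <- if (identical(model, "chill")) {
    "cumulative chill units (CU)"
  } else {
    "cumulative growing degree hours (GDH)"
  }
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$timestamp, y = .data$cumulative)
  ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a forcing-test break determination
#'
#' @param object Result of [estimate_break_date()].
#' @param ... Unused.
#' @return A ggplot of the forced/field weight ratio per test date, with
#'   the classification threshold and the dated break.
#' @export
autoplot.break_determination <- function(object, ...) {
  thr <- 1 + object$threshold_pct / 100
  p <- ggplot2::ggplot(
    object$ratios,
    ggplot2::aes(x = .data$date, y = .data$ratio)
  ) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$broken), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "royalblue"),
      guide = "none"
    ) +
    ggplot2::labs(x = NULL, y = "forced / field weight ratio") +
    ggplot2::theme_minimal()
  if (!is.na(object$break_date)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$break_date,
      linetype = 3, colour = "royalblue"
    )
  }
  p
}

#' Plot Duncan letter groups
#'
#' @param object A [duncan_mrt()] result.
#' @param ... Unused.
#' @return A ggplot of group means with letter annotations.
#' @export
autoplot.duncan_mrt <- function(object, ...) {
  d <- object$means
  d$group <- factor(d$group, levels = d$group)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sd,
        ymax = .data$mean + .data$sd
      ),
      width = 0.2
    ) +
    ggplot2::geom_text(
      ggplot2::aes(
        y = .data$mean + .data$sd,
        label = .data$letters
      ),
      vjust = -0.6
    ) +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}

#' Seasonal starch and chill overview
#'
#' Per-date starch (mean with SD bars over ovaries) overlaid on the
#' chill-unit accumulation, with the break of endodormancy marked.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return A ggplot.
#' @export
plot_starch_season <- function(report) {
  stopifnot(inherits(report, "run_report"))
  sbd <- dplyr::summarise(
    dplyr::group_by(report$starch, .data$date),
    starch = mean(.data$ovary_value), sd = stats::sd(.data$ovary_value),
    .groups = "drop"
  )
  cu <- report$chill
  scale_f <- max(sbd$starch + sbd$sd, na.rm = TRUE) /
    max(cu$cumulative, 1)
  ggplot2::ggplot(sbd, ggplot2::aes(x = .data$date, y = .data$starch)) +
    ggplot2::geom_line(
      data = cu,
      ggplot2::aes(
        x = as.Date(.data$timestamp),
        y = .data$cumulative * scale_f
      ),
      colour = "steelblue"
    ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$starch - .data$sd,
      ymax = .data$starch + .data$sd
    )) +
    ggplot2::geom_vline(
      xintercept = report$break_date, linetype = 3,
      colour = "royalblue"
    ) +
    ggplot2::scale_y_continuous(
      name = "ovary starch (summed OD / frame mean)",
      sec.axis = ggplot2::sec_axis(~ . / scale_f, name = "chill units (CU)")
    ) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}
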