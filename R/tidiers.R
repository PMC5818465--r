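#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a one-way ANOVA
#'
#' @param x A `oneway_anova`.
#' @param ... Unused.
#' @return One row per term (`between`, `within`) with `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value`.
#' @export
tidy.oneway_anova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$mse),
    statistic = c(x$f, NA_real_),
    p.value = c(x$p, NA_real_)
  )
}

#' @rdname tidy.oneway_anova
#' @export
glance.oneway_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$f, df_between = x$df_between,
    df_within = x$df_within, p.value = x$p, mse = x$mse,
    degenerate = x$degenerate
  )
}

#' Tidy a Duncan multiple-range result
#'
#' @param x A `duncan_mrt`.
#' @param ... Unused.
#' @return Per-group tibble ordered by descending mean, with the letter
#'   display.
#' @export
tidy.duncan_mrt <- function(x, ...) {
  x$means
}

#' @rdname tidy.duncan_mrt
#' @export
glance.duncan_mrt <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, mse = x$mse, df_within = x$df_within,
    n_effective = x$n_effective, n_groups = nrow(x$means),
    n_letters = length(unique(unlist(strsplit(x$means$letters, "")))),
    gated = x$gated, method = x$method
  )
}

#' Tidy a Pearson correlation
#'
#' @param x A `pearson_cor`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `p.value`, `n`, `stars`,
#'   `window`.
#' @export
tidy.pearson_cor <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, p.value = x$p, n = x$n, stars = x$stars,
    window = x$window
  )
}

#' Tidy a break determination
#'
#' @param x A `break_determination`.
#' @param ... Unused.
#' @return The per-date ratio tibble with `broken` flags.
#' @export
tidy.break_determination <- function(x, ...) {
  x$ratios
}

#' @rdname tidy.break_determination
#' @export
glance.break_determination <- function(x, ...) {
  tibble::tibble(
    break_date = x$break_date, threshold_pct = x$threshold_pct,
    chilling_requirement = x$chilling_requirement,
    n_tests = nrow(x$ratios)
  )
}

#' Tidy a starch measurement
#'
#' @param x A `starch_measurement`.
#' @param ... Unused.
#' @return One-row tibble with per-frame sums and the ovary value.
#' @export
tidy.starch_measurement <- function(x, ...) {
  tibble::tibble(
    ovary_id = x$ovary_id, date = x$date,
    frame_1 = x$per_frame[1], frame_2 = x$per_frame[2],
    frame_3 = x$per_frame[3], frame_4 = x$per_frame[4],
    ovary_value = x$ovary_value, mask_area_um2 = x$mask_area
  )
}

#' Tidy a pipeline run report
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return The windowed-correlation tibble of the run.
#' @export
tidy.run_report <- function(x, ...) {
  x$correlations
}

#' @rdname tidy.run_report
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    cultivar = x$cultivar, year = x$year,
    break_date = x$break_date,
    chilling_requirement = x$chilling_requirement,
    heat_total = x$heat_total,
    n_sections = nrow(x$starch),
    n_dates = length(unique(x$starch$date)),
    n_warnings = length(x$warnings)
  )
}
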