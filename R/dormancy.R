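#' Classify a single forcing test
#'
#' A forcing test compares the fresh weight of flower buds sampled directly
#' in the field with buds from shoots kept a week in a warm growth chamber.
#' Endodormancy is considered broken when the forced mean weight is at
#' least `threshold_pct` percent above the field mean (boundary inclusive).
#'
#' @param field_weights,forced_weights Bud fresh weights (mg), at least two
#'   positive values each.
#' @param threshold_pct Required percentage increase (default 30).
#' @return A one-row tibble with `broken`, `ratio` (forced mean / field
#'   mean), `field_mean`, `forced_mean`, `n_field`, `n_forced`.
#' @examples
#' classify_break(rep(60, 10), rep(78, 10))
#' @export
classify_break <- function(field_weights, forced_weights, threshold_pct = 30) {
  check_weights(field_weights, "field_weights")
  check_weights(forced_weights, "forced_weights")
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1 ||
    !is.finite(threshold_pct) || threshold_pct < 0) {
    stop("`threshold_pct` must be a single non-negative number", call. = FALSE)
  }
  fm <- mean(field_weights)
  om <- mean(forced_weights)
  ratio <- om / fm
  tibble::tibble(
    broken = ratio >= 1 + threshold_pct / 100, ratio = ratio,
    field_mean = fm, forced_mean = om,
    n_field = length(field_weights), n_forced = length(forced_weights)
  )
}

check_weights <- function(w, what) {
  if (!is.numeric(w) || length(w) < 2) {
    stop(sprintf("`%s` needs at least 2 weights", what), call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop(sprintf("`%s` must be positive and finite", what), call. = FALSE)
  }
  invisible(w)
}

#' Date the break of endodormancy from a series of forcing tests
#'
#' @param tests Data frame with one row per bud: `date` (Date or string),
#'   `condition` (`"field"` or `"forced"`) and `weight_mg`. Test dates must
#'   appear in strictly increasing order.
#' @param threshold_pct Required percentage weight increase (default 30).
#' @return A `break_determination` object: list with `break_date` (Date or
#'   `NA` if no test qualifies), `ratios` (per-date tibble with `ratio` and
#'   `broken`), `threshold_pct`, and `chilling_requirement` (`NA` until
#'   filled by [chilling_requirement()]).
#' @examples
#' tests <- tidyr::expand_grid(
#'   date = as.Date("2016-01-05") + c(0, 7, 14), bud_id = 1:5,
#'   condition = c("field", "forced")
#' )
#' tests$weight_mg <- ifelse(tests$condition == "field", 60,
#'   60 * c(1.1, 1.2, 1.5)[match(tests$date, unique(tests$date))]
#' )
#' estimate_break_date(tests)
#' @export
estimate_break_date <- function(tests, threshold_pct = 30) {
  if (!is.data.frame(tests) ||
    !all(c("date", "condition", "weight_mg") %in% names(tests))) {
    stop("`tests` needs columns `date`, `condition`, `weight_mg`",
      call. = FALSE
    )
  }
  tests <- dplyr::mutate(tests, date = as.Date(.data$date))
  bad <- setdiff(unique(tests$condition), c("field", "forced"))
  if (length(bad)) {
    stop("`condition` must be 'field' or 'forced'; found: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  first_seen <- tests$date[!duplicated(tests$date)]
  if (is.unsorted(first_seen, strictly = TRUE)) {
    stop("forcing tests must be ordered by strictly increasing date",
      call. = FALSE
    )
  }
  ratios <- purrr::map_dfr(split(tests, tests$date), function(d) {
    cls <- classify_break(
      d$weight_mg[d$condition == "field"],
      d$weight_mg[d$condition == "forced"],
      threshold_pct = threshold_pct
    )
    dplyr::bind_cols(tibble::tibble(date = d$date[1]), cls)
  })
  ratios <- dplyr::arrange(ratios, .data$date)
  break_date <- if (any(ratios$broken)) {
    ratios$date[which(ratios$broken)[1]]
  } else {
    as.Date(NA)
  }
  structure(
    list(
      break_date = break_date, ratios = ratios,
      threshold_pct = threshold_pct, chilling_requirement = NA_real_
    ),
    class = "break_determination"
  )
}

#' @export
print.break_determination <- function(x, ...) {
  cat("Endodormancy break determination\n")
  cat(sprintf(
    "  threshold: +%g%% forced over field (inclusive)\n",
    x$threshold_pct
  ))
  if (is.na(x$break_date)) {
    cat("  break date: none of the tests qualified\n")
  } else {
    cat(sprintf(
      "  break date: %s (ratio %.3f)\n", format(x$break_date),
      x$ratios$ratio[x$ratios$date == x$break_date]
    ))
  }
  if (!is.na(x$chilling_requirement)) {
    cat(sprintf("  chilling requirement: %.1f CU\n", x$chilling_requirement))
  }
  invisible(x)
}

#' Chilling requirement implied by a break determination
#'
#' Chill units accumulated from the start of the season to the dated break
#' of endodormancy.
#'
#' @param temps Hourly temperature series (see [accumulate_thermal()]).
#' @param break_date A `break_determination` from [estimate_break_date()],
#'   or a Date.
#' @param season_start Start of chill accumulation. Defaults to September
#'   21 of the series' first year.
#' @param ... Passed to [accumulate_thermal()] (e.g. `chill_table`,
#'   `floor_at_zero`).
#' @return Chill units (scalar). If `break_date` is a `break_determination`
#'   the value is also stored in its `chilling_requirement` field via the
#'   returned attribute `determination`.
#' @export
chilling_requirement <- function(temps, break_date, season_start = NULL, ...) {
  det <- NULL
  if (inherits(break_date, "break_determination")) {
    det <- break_date
    break_date <- det$break_date
  }
  if (is.na(break_date)) {
    stop("no break date: endodormancy release was not observed", call. = FALSE)
  }
  break_date <- as.Date(break_date)
  temps <- check_temperature_series(temps)
  if (is.null(season_start)) {
    season_start <- default_season_start(temps$timestamp[1])
  }
  season_start <- as.Date(as_hour_time(season_start, "season_start"),
    tz = "UTC"
  )
  if (break_date <= season_start) {
    stop("break date precedes the season start", call. = FALSE)
  }
  # hours strictly before the break date's midnight: whole days accumulate
  # 24 contributions each
  window_end <- as.POSIXct(paste(format(break_date), "00:00:00"),
    tz = "UTC"
  ) - 3600
  acc <- accumulate_thermal(temps, season_start, window_end,
    model = "chill", ...
  )
  cu <- total_accumulation(acc)
  if (!is.null(det)) {
    det$chilling_requirement <- cu
    attr(cu, "determination") <- det
  }
  cu
}

default_season_start <- function(first_timestamp) {
  y <- as.integer(format(first_timestamp, "%Y"))
  candidate <- as.Date(sprintf("%d-09-21", y))
  if (candidate < as.Date(first_timestamp, tz = "UTC")) {
    candidate <- as.Date(first_timestamp, tz = "UTC")
  }
  candidate
}
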