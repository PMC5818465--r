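#' Utah model chill-unit table
#'
#' Hourly chilling effectiveness by temperature band under the Utah model.
#' Bands are half-open with an inclusive lower bound: a temperature `t`
#' falls in row `i` when `lower[i] <= t < lower[i + 1]` (the last band is
#' unbounded above). Alternative weighting tables with the same two-column
#' layout can be passed to [chill_units_hourly()] and
#' [accumulate_thermal()].
#'
#' @return A tibble with columns `lower` (band lower bound, degrees C) and
#'   `cu` (chill units contributed per hour in that band).
#' @examples
#' utah_chill_table()
#' @export
utah_chill_table <- function() {
  tibble::tibble(
    lower = c(-Inf, 1.5, 2.5, 9.2, 12.5, 16, 18),
    cu = c(0, 0.5, 1, 0.5, 0, -0.5, -1)
  )
}

check_chill_table <- function(table) {
  if (!is.data.frame(table) || !all(c("lower", "cu") %in% names(table))) {
    stop("`table` must be a data frame with columns `lower` and `cu`",
      call. = FALSE
    )
  }
  if (is.unsorted(table$lower, strictly = TRUE)) {
    stop("chill table `lower` bounds must be strictly increasing",
      call. = FALSE
    )
  }
  invisible(table)
}

#' Hourly chill-unit contribution (Utah model)
#'
#' Piecewise-constant chilling contribution of a single hour at temperature
#' `temp`. Contributions can be negative at warm temperatures.
#'
#' @param temp Hourly mean temperature(s), degrees C. Must be finite.
#' @param table Chill weighting table, see [utah_chill_table()].
#' @return Numeric vector of chill units (dimensionless), same length as
#'   `temp`.
#' @examples
#' chill_units_hourly(c(0, 5, 20))
#' @export
chill_units_hourly <- function(temp, table = utah_chill_table()) {
  if (!is.numeric(temp)) stop("`temp` must be numeric", call. = FALSE)
  if (length(temp) && any(!is.finite(temp))) {
    stop("`temp` must be finite", call. = FALSE)
  }
  check_chill_table(table)
  idx <- findInterval(temp, table$lower[-1]) + 1L
  table$cu[idx]
}

#' Hourly growing-degree-hour contribution
#'
#' Heat accumulated in one hour at temperature `temp`: zero below the
#' `lower` threshold, `temp - base` between `lower` and `upper`, and capped
#' at `upper - base` above `upper`.
#'
#' @param temp Hourly mean temperature(s), degrees C. Must be finite.
#' @param base Base temperature subtracted from each hour (degrees C).
#' @param lower Lower threshold below which no heat accumulates (degrees C).
#' @param upper Cap temperature (degrees C); hours warmer than this count as
#'   `upper`.
#' @return Numeric vector of growing degree hours (degree C hours, >= 0).
#' @examples
#' gdh_hourly(c(4, 10, 30))
#' @export
gdh_hourly <- function(temp, base = 4.5, lower = 6, upper = 25) {
  if (!is.numeric(temp)) stop("`temp` must be numeric", call. = FALSE)
  if (length(temp) && any(!is.finite(temp))) {
    stop("`temp` must be finite", call. = FALSE)
  }
  out <- pmin(temp, upper) - base
  out[temp < lower] <- 0
  out
}

as_hour_time <- function(x, what = "time") {
  if (inherits(x, "POSIXct")) {
    return(lubridate_floor_hour(x))
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(paste(format(x), "00:00:00"), tz = "UTC"))
  }
  if (is.character(x)) {
    out <- suppressWarnings(as.POSIXct(x,
      tz = "UTC",
      tryFormats = c(
        "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
        "%Y-%m-%d %H:%M", "%Y-%m-%d"
      )
    ))
    if (any(is.na(out))) {
      stop(sprintf("cannot parse %s: %s", what, x[which(is.na(out))[1]]),
        call. = FALSE
      )
    }
    return(out)
  }
  stop(sprintf("`%s` must be a POSIXct, Date or ISO-8601 string", what),
    call. = FALSE
  )
}

lubridate_floor_hour <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 3600) * 3600,
    origin = "1970-01-01", tz = "UTC"
  )
}

check_temperature_series <- function(temps) {
  if (!is.data.frame(temps) || !all(c("timestamp", "temp_c") %in% names(temps))) {
    stop("temperature series needs columns `timestamp` and `temp_c`",
      call. = FALSE
    )
  }
  ts <- as_hour_time(temps$timestamp, "timestamp")
  if (anyDuplicated(ts)) stop("duplicated timestamps", call. = FALSE)
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(temps$temp_c))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  tibble::tibble(timestamp = ts, temp_c = as.numeric(temps$temp_c))
}

#' Accumulate chill units or growing degree hours over a window
#'
#' Running sum of hourly chill-unit or GDH contributions over `[start,
#' end]` (both inclusive). The window is laid out on a full hourly grid;
#' gaps of at most `max_gap_hours` consecutive missing hours are filled by
#' linear interpolation, longer gaps contribute nothing, and a window with
#' more than 5% missing hours carries a coverage warning (also stored in
#' the result attributes).
#'
#' @param temps Data frame with columns `timestamp` (POSIXct or ISO-8601
#'   string) and `temp_c`; one row per hour, strictly increasing.
#' @param start,end Window bounds (Date, POSIXct or parseable string),
#'   within the series extent.
#' @param model `"chill"` (Utah chill units) or `"heat"` (GDH).
#' @param chill_table Chill weighting table for `model = "chill"`.
#' @param gdh_base,gdh_lower,gdh_upper GDH parameters for `model = "heat"`,
#'   see [gdh_hourly()].
#' @param floor_at_zero For chill accumulation only: if `TRUE` the running
#'   total never drops below zero (reset-at-zero variant); default `FALSE`,
#'   a plain signed sum.
#' @param max_gap_hours Longest run of missing hours filled by linear
#'   interpolation.
#' @return A tibble (class `thermal_accumulation`) with columns
#'   `timestamp`, `temp_c`, `hourly` (contribution of that hour) and
#'   `cumulative`. Attributes: `model`, `n_hours`, `n_missing`, `coverage`.
#' @examples
#' temps <- tibble::tibble(
#'   timestamp = seq(as.POSIXct("2015-11-01", tz = "UTC"),
#'     by = "hour", length.out = 48
#'   ),
#'   temp_c = 5
#' )
#' acc <- accumulate_thermal(temps, "2015-11-01", "2015-11-02 23:00")
#' total_accumulation(acc)
#' @export
accumulate_thermal <- function(temps, start, end,
                               model = c("chill", "heat"),
                               chill_table = utah_chill_table(),
                               gdh_base = 4.5, gdh_lower = 6, gdh_upper = 25,
                               floor_at_zero = FALSE, max_gap_hours = 3) {
  model <- match.arg(model)
  temps <- check_temperature_series(temps)
  start <- as_hour_time(start, "start")
  end <- as_hour_time(end, "end")
  if (start >= end) stop("window `start` must precede `end`", call. = FALSE)
  if (start < temps$timestamp[1] || end > temps$timestamp[nrow(temps)]) {
    stop("window lies outside the series extent", call. = FALSE)
  }
  grid <- seq(start, end, by = "hour")
  if (!length(grid)) stop("empty accumulation window", call. = FALSE)
  temp <- temps$temp_c[match(as.numeric(grid), as.numeric(temps$timestamp))]
  n_missing_raw <- sum(is.na(temp))
  if (n_missing_raw > 0) {
    temp <- as.numeric(zoo::na.approx(temp,
      x = as.numeric(grid),
      maxgap = max_gap_hours, na.rm = FALSE
    ))
  }
  still_na <- is.na(temp)
  coverage <- 1 - n_missing_raw / length(grid)
  hourly <- numeric(length(grid))
  filled <- !still_na
  hourly[filled] <- switch(model,
    chill = chill_units_hourly(temp[filled], table = chill_table),
    heat = gdh_hourly(temp[filled],
      base = gdh_base, lower = gdh_lower,
      upper = gdh_upper
    )
  )
  if (model == "chill" && floor_at_zero) {
    cumulative <- Reduce(function(acc, x) max(0, acc + x), hourly,
      init = 0, accumulate = TRUE
    )[-1]
  } else {
    cumulative <- cumsum(hourly)
  }
  out <- tibble::tibble(
    timestamp = grid, temp_c = temp,
    hourly = hourly, cumulative = cumulative
  )
  attr(out, "model") <- model
  attr(out, "n_hours") <- length(grid)
  attr(out, "n_missing") <- n_missing_raw
  attr(out, "coverage") <- coverage
  class(out) <- c("thermal_accumulation", class(out))
  if (coverage < 0.95) {
    warning(sprintf(
      "only %.1f%% of hours in the window are observed; missing hours contribute 0",
      100 * coverage
    ), call. = FALSE)
  }
  out
}

#' Total of a thermal accumulation
#'
#' @param acc Result of [accumulate_thermal()].
#' @return Final cumulative value (CU or GDH).
#' @export
total_accumulation <- function(acc) {
  stopifnot(is.data.frame(acc), "cumulative" %in% names(acc))
  acc$cumulative[nrow(acc)]
}

#' Daily chill and heat summary
#'
#' Collapses an hourly temperature series into a per-day table of chill
#' units and growing degree hours with running totals, the layout written
#' by the pipeline as `cu_gdh_daily.tsv`.
#'
#' @inheritParams accumulate_thermal
#' @return A tibble with columns `date`, `cu_daily`, `cu_cumulative`,
#'   `gdh_daily`, `gdh_cumulative`.
#' @export
thermal_daily_summary <- function(temps, start = NULL, end = NULL,
                                  chill_table = utah_chill_table()) {
  temps <- check_temperature_series(temps)
  if (is.null(start)) start <- temps$timestamp[1]
  if (is.null(end)) end <- temps$timestamp[nrow(temps)]
  chill <- accumulate_thermal(temps, start, end,
    model = "chill",
    chill_table = chill_table
  )
  heat <- accumulate_thermal(temps, start, end, model = "heat")
  daily <- dplyr::tibble(
    date = as.Date(chill$timestamp, tz = "UTC"),
    cu = chill$hourly, gdh = heat$hourly
  )
  daily <- dplyr::summarise(dplyr::group_by(daily, date),
    cu_daily = sum(.data$cu), gdh_daily = sum(.data$gdh),
    .groups = "drop"
  )
  dplyr::mutate(daily,
    cu_cumulative = cumsum(.data$cu_daily),
    gdh_cumulative = cumsum(.data$gdh_daily)
  )[, c("date", "cu_daily", "cu_cumulative", "gdh_daily", "gdh_cumulative")]
}
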