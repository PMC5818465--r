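#' One-way fixed-effects ANOVA across groups
#'
#' Classical one-way decomposition used to compare starch content (or
#' cell-layer counts) across collection dates.
#'
#' @param data Data frame with one observation per row.
#' @param value,group Columns holding the response and the grouping
#'   label (tidy-eval).
#' @return A `oneway_anova` object: `f`, `df_between`, `df_within`, `p`,
#'   `mse` (within-group mean square), `group_stats` (per-group n, mean,
#'   sd), `degenerate` (`TRUE` when the within-group variance is zero and
#'   F is reported as `Inf`).
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = rnorm(12))
#' one_way_anova(d, y, g)
#' @export
one_way_anova <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  ns <- table(g)
  if (length(ns) < 2) stop("ANOVA needs at least 2 groups", call. = FALSE)
  if (any(ns < 2)) stop("every group needs at least 2 observations", call. = FALSE)
  if (length(unique(v)) == 1) {
    stop("all observations identical: F is undefined", call. = FALSE)
  }
  fit <- stats::lm(v ~ g)
  at <- suppressWarnings(stats::anova(fit)) # degenerate fits handled below
  ss <- at[["Sum Sq"]]
  df <- at[["Df"]]
  msb <- ss[1] / df[1]
  msw <- ss[2] / df[2]
  degenerate <- isTRUE(all.equal(msw, 0)) ||
    msw < .Machine$double.eps * 100 * msb
  f <- if (degenerate) Inf else msb / msw
  p <- if (degenerate) 0 else stats::pf(f, df[1], df[2], lower.tail = FALSE)
  group_stats <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = g, value = v), group),
    n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
    .groups = "drop"
  )
  structure(
    list(
      f = f, df_between = df[1], df_within = df[2], p = p, mse = msw,
      ss_between = ss[1], ss_within = ss[2],
      group_stats = group_stats, degenerate = degenerate
    ),
    class = "oneway_anova"
  )
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
    x$df_between, x$df_within, x$f, x$p,
    if (x$degenerate) " [degenerate: zero within-group variance]" else ""
  ))
  invisible(x)
}

duncan_critical_ranges <- function(k, df_within, mse, n, alpha) {
  p <- 2:k
  q <- stats::qtukey((1 - alpha)^(p - 1), p, df_within)
  tibble::tibble(span = p, r_crit = q * sqrt(mse / n))
}

#' Duncan's multiple-range test
#'
#' Post-ANOVA mean separation: two means `p` ranks apart in the ordered
#' list differ when their difference exceeds `R_p = q(gamma_p; p, df) *
#' sqrt(MSE / n)`, where `gamma_p = (1 - alpha)^(p - 1)` is Duncan's
#' protection level and `q` the studentized-range quantile. Letters mark
#' maximal runs of mutually non-significant means, so groups sharing a
#' letter do not differ under the procedure. Unbalanced designs use the
#' harmonic mean of the group sizes in `R_p`.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level (default 0.05).
#' @param gate If `TRUE` (default) the test is only applied when the
#'   ANOVA F is significant at `alpha`; otherwise all groups share one
#'   letter and the result is flagged `gated`.
#' @return A `duncan_mrt` object with `means` (per-group tibble ordered
#'   by descending mean, with `letters`), `critical_ranges`, `alpha`,
#'   `mse`, `df_within`, `n_effective`, `gated`, and the `anova` fit.
#' @examples
#' d <- data.frame(
#'   g = rep(c("a", "b", "c"), each = 5),
#'   y = rep(c(0, 0, 8), each = 5) + rnorm(15)
#' )
#' duncan_mrt(d, y, g)
#' @export
duncan_mrt <- function(data, value, group, alpha = 0.05, gate = TRUE) {
  fit <- one_way_anova(data, {{ value }}, {{ group }})
  if (fit$df_within < 1) stop("df_within must be >= 1", call. = FALSE)
  gs <- dplyr::arrange(fit$group_stats, dplyr::desc(.data$mean))
  k <- nrow(gs)
  n_eff <- k / sum(1 / gs$n) # harmonic mean group size
  gated <- gate && !fit$degenerate && fit$p > alpha
  if (gated) {
    gs$letters <- rep("a", k)
    crit <- duncan_critical_ranges(k, fit$df_within, fit$mse, n_eff, alpha)
  } else {
    crit <- duncan_critical_ranges(k, fit$df_within, fit$mse, n_eff, alpha)
    r_of_span <- c(0, crit$r_crit) # index by span
    ns <- matrix(TRUE, k, k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        ns[i, j] <- ns[j, i] <-
          (gs$mean[i] - gs$mean[j]) <= r_of_span[j - i + 1]
      }
    }
    gs$letters <- letters_from_ns(ns)
  }
  structure(
    list(
      means = gs, critical_ranges = crit, alpha = alpha, mse = fit$mse,
      df_within = fit$df_within, n_effective = n_eff, gated = gated,
      anova = fit,
      method = "studentized-range quantiles via stats::qtukey"
    ),
    class = "duncan_mrt"
  )
}

# letters for maximal intervals of mutually non-significant ordered means
letters_from_ns <- function(ns) {
  k <- nrow(ns)
  reach <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(ns[i:j, j + 1])) j <- j + 1
    reach[i] <- j
  }
  lab <- 0
  assign <- vector("list", k)
  lastmax <- 0
  for (i in seq_len(k)) {
    if (reach[i] > lastmax || lastmax == 0) {
      lab <- lab + 1
      for (j in i:reach[i]) assign[[j]] <- c(assign[[j]], lab)
      lastmax <- reach[i]
    }
  }
  vapply(assign, function(a) paste(make_letter_labels(lab)[a], collapse = ""),
    character(1)
  )
}

make_letter_labels <- function(n) {
  if (n <= 26) {
    return(letters[seq_len(n)])
  }
  paste0(
    letters[(seq_len(n) - 1) %/% 26 + 1],
    letters[(seq_len(n) - 1) %% 26 + 1]
  )
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf(
    "Duncan's multiple-range test (alpha = %g%s)\n", x$alpha,
    if (x$gated) ", gated: ANOVA F not significant" else ""
  ))
  print(x$means)
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @param window Optional label (`"pre_fulfillment"` /
#'   `"post_fulfillment"`) carried into the result.
#' @return A `pearson_cor` object: `r`, `p`, `n`, `stars` (`"**"` for
#'   p < 0.01, `"*"` for p < 0.05), `window`.
#' @examples
#' pearson_correlation(1:10, 2 * (1:10) + rnorm(10))
#' @export
pearson_correlation <- function(x, y, window = NA_character_) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("`x` and `y` must be numeric vectors of equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(
      r = unname(ct$estimate), p = ct$p.value, n = length(x),
      stars = significance_stars(ct$p.value), window = window
    ),
    class = "pearson_cor"
  )
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat(sprintf(
    "Pearson r = %.4f%s (p = %.4g, n = %d%s)\n", x$r, x$stars, x$p, x$n,
    if (is.na(x$window)) "" else paste0(", ", x$window)
  ))
  invisible(x)
}

lookup_cumulative <- function(acc, dates) {
  # cumulative value at each date's midnight (last hour <= the date)
  xout <- as.numeric(as.POSIXct(paste(format(as.Date(dates)), "00:00:00"),
    tz = "UTC"
  ))
  stats::approx(as.numeric(acc$timestamp), acc$cumulative,
    xout = xout,
    method = "constant", f = 0, rule = 2
  )$y
}

#' Starch correlations in the chilling and forcing windows
#'
#' Before chilling fulfillment, per-date starch is paired with cumulative
#' chill units; from the break of endodormancy onward it is paired with
#' cumulative growing degree hours. A window with fewer than 3 dates is
#' skipped with a warning; an undefined correlation (constant values) is
#' reported as such.
#'
#' @param starch_by_date Data frame with columns `date` and `starch`
#'   (per-date values; replicate rows per date are averaged).
#' @param chill_acc,heat_acc Accumulations from [accumulate_thermal()]
#'   (heat typically accumulated from the break date).
#' @param break_date Date of endodormancy release.
#' @return A tibble with one row per window: `window`, `n`, `r`, `p`,
#'   `stars`, `note` (`NA` when the correlation was computed).
#' @export
windowed_correlations <- function(starch_by_date, chill_acc, heat_acc,
                                  break_date) {
  stopifnot(all(c("date", "starch") %in% names(starch_by_date)))
  break_date <- as.Date(break_date)
  sbd <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(starch_by_date, date = as.Date(.data$date)),
      date
    ),
    starch = mean(.data$starch), .groups = "drop"
  )
  one_window <- function(dat, x, label) {
    if (nrow(dat) < 3) {
      warning(sprintf("%s window skipped: fewer than 3 dates", label),
        call. = FALSE
      )
      return(tibble::tibble(
        window = label, n = nrow(dat), r = NA_real_, p = NA_real_,
        stars = NA_character_, note = "skipped: fewer than 3 dates"
      ))
    }
    res <- tryCatch(pearson_correlation(x, dat$starch, window = label),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("%s window: %s", label, conditionMessage(res)),
        call. = FALSE
      )
      return(tibble::tibble(
        window = label, n = nrow(dat), r = NA_real_, p = NA_real_,
        stars = NA_character_, note = conditionMessage(res)
      ))
    }
    tibble::tibble(
      window = label, n = res$n, r = res$r, p = res$p,
      stars = res$stars, note = NA_character_
    )
  }
  pre <- dplyr::filter(sbd, .data$date <= break_date)
  post <- dplyr::filter(sbd, .data$date > break_date)
  dplyr::bind_rows(
    one_window(pre, lookup_cumulative(chill_acc, pre$date), "pre_fulfillment"),
    one_window(post, lookup_cumulative(heat_acc, post$date), "post_fulfillment")
  )
}
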