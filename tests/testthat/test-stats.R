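test_that("one-way ANOVA matches the two-pass sum-of-squares computation", {
  set.seed(41)
  for (i in 1:10) {
    d <- data.frame(
      g = rep(letters[1:4], each = 6),
      y = rnorm(24, rep(runif(4, 0, 3), each = 6))
    )
    fit <- one_way_anova(d, y, g)
    oracle <- oracle_anova_f(d$y, d$g)
    expect_equal(fit$f, oracle$f, tolerance = 1e-10)
    expect_equal(fit$mse, oracle$mse, tolerance = 1e-10)
    expect_equal(fit$df_between, 3)
    expect_equal(fit$df_within, 20)
    # F invariant to adding a constant
    shifted <- one_way_anova(transform(d, y = y + 17.3), y, g)
    expect_equal(shifted$f, fit$f, tolerance = 1e-8)
  }
})

test_that("ANOVA edge cases: equal means, zero within-variance, degenerate input", {
  eq <- one_way_anova(
    data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2)),
    y, g
  )
  expect_equal(eq$f, 0)

  deg <- one_way_anova(
    data.frame(g = rep(c("a", "b"), each = 2), y = c(0, 0, 10, 10)),
    y, g
  )
  expect_true(deg$degenerate)
  expect_identical(deg$f, Inf)

  expect_error(
    one_way_anova(data.frame(g = rep("a", 4), y = rnorm(4)), y, g),
    "2 groups"
  )
  expect_error(
    one_way_anova(data.frame(g = c("a", "a", "b"), y = c(1, 2, 3)), y, g),
    "at least 2 observations"
  )
  expect_error(
    one_way_anova(data.frame(g = rep(c("a", "b"), 3), y = rep(5, 6)), y, g),
    "identical"
  )
})

test_that("Duncan letters: separation, sharing, and the F gate", {
  set.seed(42)
  far <- data.frame(
    g = rep(c("lo", "hi"), each = 6),
    y = rep(c(0, 50), each = 6) + rnorm(12)
  )
  dm <- duncan_mrt(far, y, g)
  expect_equal(sort(dm$means$letters), c("a", "b"))

  same <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = rep(1:4, 3))
  dm2 <- duncan_mrt(same, y, g, gate = FALSE)
  expect_equal(dm2$means$letters, rep("a", 3))
  dm3 <- duncan_mrt(same, y, g, gate = TRUE)
  expect_true(dm3$gated)
  expect_equal(dm3$means$letters, rep("a", 3))
})

test_that("Duncan with two groups reduces to the R_2 boundary", {
  set.seed(43)
  for (i in 1:20) {
    d <- data.frame(
      g = rep(c("a", "b"), each = 5),
      y = rnorm(10, rep(c(0, runif(1, 0, 2)), each = 5))
    )
    dm <- duncan_mrt(d, y, g, gate = FALSE)
    r2 <- stats::qtukey(0.95, 2, dm$df_within) * sqrt(dm$mse / 5)
    diff_means <- abs(diff(dm$means$mean))
    distinct <- length(unique(dm$means$letters)) == 2
    expect_equal(distinct, diff_means > r2)
    expect_equal(dm$critical_ranges$r_crit, r2)
  }
})

test_that("Duncan partition equals the exhaustive pairwise oracle", {
  set.seed(44)
  for (i in 1:20) {
    d <- data.frame(
      g = rep(paste0("g", 1:5), each = 6),
      y = rnorm(30, rep(runif(5, 0, 3), each = 6))
    )
    dm <- duncan_mrt(d, y, g, gate = FALSE)
    expect_identical(
      letter_sets(dm),
      sort_partition(oracle_duncan_partition(d$y, d$g))
    )
    # letters form contiguous runs over the ordered means
    for (l in unique(unlist(strsplit(dm$means$letters, "")))) {
      idx <- which(grepl(l, dm$means$letters, fixed = TRUE))
      expect_identical(idx, idx[1]:idx[length(idx)])
    }
  }
})

test_that("Pearson correlation and its t-based p-value", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  set.seed(45)
  y <- rnorm(12)
  z <- 0.5 * y + rnorm(12)
  pc <- pearson_correlation(y, z)
  tt <- pc$r * sqrt((12 - 2) / (1 - pc$r^2))
  expect_equal(pc$p, 2 * stats::pt(-abs(tt), 10), tolerance = 1e-12)

  # affine invariance, sign follows the slope
  pc2 <- pearson_correlation(3 * y - 2, -0.5 * z + 4)
  expect_equal(pc2$r, -pc$r, tolerance = 1e-12)
  expect_equal(pc2$p, pc$p, tolerance = 1e-12)

  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_equal(pearson_correlation(x, 2 * x + rnorm(10, 0, 0.1))$stars, "**")
})

test_that("windowed correlations pair starch with CU then GDH", {
  temps <- make_temps(rep(5, 24 * 100), start = "2015-10-01")
  chill <- accumulate_thermal(temps, "2015-10-01", temps$timestamp[nrow(temps)],
    model = "chill"
  )
  heat_temps <- make_temps(rep(10, 24 * 100), start = "2015-10-01")
  heat <- accumulate_thermal(heat_temps, "2015-10-01",
    heat_temps$timestamp[nrow(heat_temps)],
    model = "heat"
  )
  dates <- as.Date("2015-10-10") + 10 * (0:7)
  break_date <- dates[4]
  starch <- tibble::tibble(
    date = dates,
    starch = c(1, 2, 3, 4, 3.5, 2.5, 1.5, 0.5) # rises then falls
  )
  wc <- windowed_correlations(starch, chill, heat, break_date)
  expect_equal(wc$window, c("pre_fulfillment", "post_fulfillment"))
  expect_equal(wc$n, c(4, 4))
  expect_equal(wc$r, c(1, -1), tolerance = 1e-10)
  expect_equal(wc$stars, c("**", "**"))

  # short pre window: skipped with warning
  expect_warning(
    wc2 <- windowed_correlations(starch[3:8, ], chill, heat, break_date),
    "fewer than 3"
  )
  expect_true(is.na(wc2$r[1]))
  expect_match(wc2$note[1], "skipped")

  # constant starch: undefined correlation surfaced per window
  flat <- tibble::tibble(date = dates, starch = rep(2, 8))
  w <- testthat::capture_warnings(
    wc3 <- windowed_correlations(flat, chill, heat, break_date)
  )
  expect_match(w, "constant", all = TRUE)
  expect_length(w, 2)
  expect_true(all(is.na(wc3$r)))
  expect_match(wc3$note, "constant", all = TRUE)
})
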