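test_that("generators are bit-reproducible for a fixed seed", {
  sp <- season_spec("cold", seed = 9)
  expect_identical(gen_temperature_series(sp), gen_temperature_series(sp))
  t1 <- gen_temperature_series(sp)
  expect_identical(
    gen_forcing_tests(t1, sp),
    gen_forcing_tests(t1, sp)
  )
  g1 <- gen_section_image(0.1, seed = 5)
  g2 <- gen_section_image(0.1, seed = 5)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$mask, g2$mask)
  expect_false(identical(
    g1$image$pixels,
    gen_section_image(0.1, seed = 6)$image$pixels
  ))
})

test_that("noise-free series equals the closed-form sinusoid sum", {
  sp <- season_spec("cold", noise_sd = 0, seed = 1)
  temps <- gen_temperature_series(sp)
  d <- as.numeric(difftime(temps$timestamp, temps$timestamp[1],
    units = "days"
  ))
  hour <- as.numeric(format(temps$timestamp, "%H"))
  expected <- 12 - 11 * cos(2 * pi * (d - 136) / 365.25) +
    4 * sin(2 * pi * (hour - 9) / 24)
  expect_equal(temps$temp_c, expected)
})

test_that("mild winters start chilling about the onset shift later", {
  cold <- gen_temperature_series(season_spec("cold", noise_sd = 0, seed = 1))
  mild <- gen_temperature_series(season_spec("mild", noise_sd = 0, seed = 1))
  cross100 <- function(temps) {
    acc <- accumulate_thermal(temps, "2015-09-21",
      temps$timestamp[nrow(temps)],
      model = "chill"
    )
    as.Date(acc$timestamp[which(acc$cumulative >= 100)[1]], tz = "UTC")
  }
  diff_days <- as.numeric(cross100(mild) - cross100(cold))
  expect_lte(abs(diff_days - 20), 4)
})

test_that("forcing tests cross the criterion once the planted requirement is met", {
  sp <- season_spec("cold", seed = 13)
  temps <- gen_temperature_series(sp)
  tests <- gen_forcing_tests(temps, sp)
  det <- estimate_break_date(tests)
  chill <- accumulate_thermal(temps, "2015-09-21",
    temps$timestamp[nrow(temps)],
    model = "chill"
  )
  dates_u <- unique(tests$date)
  cu_at <- vapply(dates_u, function(d) {
    chill$cumulative[max(which(as.Date(chill$timestamp, tz = "UTC") < d))]
  }, numeric(1))
  first_met <- dates_u[which(cu_at >= sp$planted_cu_requirement)[1]]
  expect_lte(abs(as.numeric(det$break_date - first_met)), 7)

  # ratio ceiling below the criterion: no break at 30%
  capped <- gen_forcing_tests(temps, sp, ratio_max = 1.2)
  expect_true(is.na(estimate_break_date(capped)$break_date))

  # single bud per condition is rejected downstream
  lone <- gen_forcing_tests(temps, sp, n_buds = 1)
  expect_error(estimate_break_date(lone), "at least 2")
})

test_that("section images hit the requested starch fraction", {
  for (theta in c(0, 0.05, 0.2, 0.4)) {
    g <- gen_section_image(theta, seed = 800 + round(theta * 100))
    expect_lte(abs(g$theta_achieved - theta), 0.02)
  }
  g0 <- gen_section_image(0, seed = 801)
  expect_false(any(g0$mask))
  expect_error(gen_section_image(0.7), "0, 0.5")
})

test_that("season bundle writes every pipeline input plus ground truth", {
  out <- withr::local_tempdir()
  dates <- as.Date("2015-11-01") + 30 * (0:3)
  bundle <- gen_season_dataset(season_spec("cold", seed = 3),
    out_dir = out,
    dates = dates, n_ovaries = 2
  )
  for (p in bundle$paths[c(
    "temperature", "forcing", "annotations",
    "ground_truth", "config"
  )]) {
    expect_true(file.exists(p))
  }
  expect_length(list.files(bundle$paths$image_dir, pattern = "\\.png$"), 8)
  truth <- jsonlite::read_json(bundle$paths$ground_truth,
    simplifyVector = TRUE
  )
  expect_true(all(c(
    "planted_cu_requirement", "fulfillment_date", "theta_by_date",
    "theta_by_ovary", "granule_band", "seed"
  ) %in% names(truth)))
  expect_equal(nrow(truth$theta_by_date), 4)
  expect_equal(nrow(truth$theta_by_ovary), 8)
  # trajectory peaks at fulfillment and declines with heat afterwards
  tb <- truth$theta_by_date
  expect_true(all(diff(tb$theta[tb$gdh_since_break == 0]) >= 0))
  post <- tb[tb$gdh_since_break > 0, ]
  if (nrow(post) > 1) expect_true(all(diff(post$theta) <= 0))
})
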