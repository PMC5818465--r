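test_that("hourly chill units follow the Utah bands", {
  expect_equal(chill_units_hourly(5), 1)
  expect_equal(chill_units_hourly(20), -1)
  expect_equal(chill_units_hourly(0), 0)
  expect_equal(
    chill_units_hourly(c(1.5, 2.4, 2.5, 9.1, 9.2, 12.4, 12.5, 16, 17.9)),
    c(0.5, 0.5, 1, 1, 0.5, 0.5, 0, -0.5, -0.5)
  )
  # piecewise constant against an independent literal lookup
  temps <- seq(-10, 35, by = 0.13)
  expect_equal(
    chill_units_hourly(temps),
    vapply(temps, oracle_chill_unit, numeric(1))
  )
  expect_error(chill_units_hourly(NA_real_), "finite")
  expect_error(chill_units_hourly(Inf), "finite")
})

test_that("hourly GDH is zero below 6, linear to 25, capped above", {
  expect_equal(gdh_hourly(10), 5.5)
  expect_equal(gdh_hourly(30), 20.5)
  expect_equal(gdh_hourly(4), 0)
  expect_equal(gdh_hourly(5.999), 0)
  expect_equal(gdh_hourly(6), 1.5)
  expect_equal(gdh_hourly(25), 20.5)
  # linear with slope 1 on [6, 25]
  x <- seq(6, 25, by = 0.25)
  expect_equal(diff(gdh_hourly(x)), rep(0.25, length(x) - 1))
  # constant above the cap, never negative
  expect_equal(gdh_hourly(c(25.1, 28, 40)), rep(20.5, 3))
  expect_true(all(gdh_hourly(seq(-20, 45, by = 0.5)) >= 0))
  expect_error(gdh_hourly(NaN), "finite")
})

test_that("accumulation equals the explicit hour-by-hour sum", {
  temps <- make_temps(rep(5, 100))
  acc <- accumulate_thermal(temps, temps$timestamp[1], temps$timestamp[100],
    model = "chill"
  )
  expect_equal(total_accumulation(acc), 100)
  expect_equal(acc$cumulative[1], acc$hourly[1]) # first value = first hour

  heat <- accumulate_thermal(make_temps(rep(25, 10)),
    "2015-11-01", "2015-11-01 09:00",
    model = "heat"
  )
  expect_equal(total_accumulation(heat), 205)

  alt <- make_temps(rep(c(0, 5), 24))
  acc_alt <- accumulate_thermal(alt, alt$timestamp[1], alt$timestamp[48],
    model = "chill"
  )
  expect_equal(total_accumulation(acc_alt), 24)

  set.seed(11)
  rnd <- make_temps(runif(2000, -10, 35))
  for (model in c("chill", "heat")) {
    fun <- if (model == "chill") oracle_chill_unit else oracle_gdh
    acc <- accumulate_thermal(rnd, rnd$timestamp[1], rnd$timestamp[2000],
      model = model
    )
    expect_identical(acc$cumulative, oracle_accumulate(rnd$temp_c, fun))
  }
})

test_that("heat accumulation is monotone and chill totals are order-independent", {
  set.seed(21)
  for (i in 1:5) {
    x <- runif(500, -5, 30)
    temps <- make_temps(x)
    heat <- accumulate_thermal(temps, temps$timestamp[1], temps$timestamp[500],
      model = "heat"
    )
    expect_true(all(diff(heat$cumulative) >= 0))
    expect_true(all(heat$cumulative >= 0))
    chill <- accumulate_thermal(temps, temps$timestamp[1],
      temps$timestamp[500],
      model = "chill"
    )
    perm <- make_temps(sample(x))
    chill_p <- accumulate_thermal(perm, perm$timestamp[1],
      perm$timestamp[500],
      model = "chill"
    )
    expect_equal(total_accumulation(chill), total_accumulation(chill_p))
  }
})

test_that("window validation and gap handling behave as documented", {
  temps <- make_temps(rep(5, 100))
  expect_error(
    accumulate_thermal(temps, temps$timestamp[10], temps$timestamp[10]),
    "precede"
  )
  expect_error(
    accumulate_thermal(
      temps, temps$timestamp[1] - 3600,
      temps$timestamp[50]
    ),
    "outside"
  )
  expect_error(
    accumulate_thermal(temps[c(1:10, 10), ], temps$timestamp[1],
      temps$timestamp[9]),
    "duplicated|increasing"
  )

  # short gap: linear interpolation across <= 3 missing hours
  gap <- make_temps(seq(0, 9.9, by = 0.1))[-(41:42), ]
  acc <- accumulate_thermal(gap, gap$timestamp[1],
    gap$timestamp[nrow(gap)],
    model = "heat"
  )
  expect_equal(acc$temp_c[41:42], c(4.0, 4.1), tolerance = 1e-12)
  expect_equal(attr(acc, "n_missing"), 2L)

  # long gap: hours contribute 0 and coverage warning fires (> 5% missing)
  long_gap <- make_temps(rep(5, 100))[-(20:29), ]
  expect_warning(
    acc2 <- accumulate_thermal(long_gap, long_gap$timestamp[1],
      long_gap$timestamp[nrow(long_gap)],
      model = "chill"
    ),
    "missing hours"
  )
  expect_equal(attr(acc2, "coverage"), 0.9)
  expect_equal(total_accumulation(acc2), 90)
})

test_that("floor_at_zero clamps the running chill total", {
  temps <- make_temps(c(rep(20, 10), rep(5, 10))) # -1/h then +1/h
  plain <- accumulate_thermal(temps, temps$timestamp[1], temps$timestamp[20],
    model = "chill"
  )
  expect_equal(total_accumulation(plain), 0)
  expect_equal(min(plain$cumulative), -10)
  floored <- accumulate_thermal(temps, temps$timestamp[1],
    temps$timestamp[20],
    model = "chill", floor_at_zero = TRUE
  )
  expect_equal(total_accumulation(floored), 10)
  expect_true(all(floored$cumulative >= 0))
})

test_that("daily summary aggregates hourly contributions", {
  temps <- make_temps(rep(c(5, 10), 24)) # 48 h = 2 days
  daily <- thermal_daily_summary(temps)
  expect_equal(nrow(daily), 2)
  expect_equal(daily$cu_daily, c(12 * 1 + 12 * 0.5, 18))
  expect_equal(daily$gdh_daily, c(12 * 5.5, 12 * 5.5))
  expect_equal(daily$cu_cumulative, cumsum(daily$cu_daily))
  expect_equal(daily$gdh_cumulative, cumsum(daily$gdh_daily))
})
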