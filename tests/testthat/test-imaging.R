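test_that("colour-threshold segmentation matches its definition", {
  bg <- flat_image(c(220, 210, 200))
  band <- threshold_spec(red = c(40, 90), green = c(30, 70), blue = c(60, 110))
  expect_false(any(segment_starch(bg, band))) # background outside bounds

  # one painted granule of exactly 50 px
  img <- flat_image(c(220, 210, 200))
  sel <- cbind(
    rep(3:12, each = 5),
    rep(3:7, times = 10)
  )
  for (ch in 1:3) {
    p <- img$pixels[, , ch]
    p[sel] <- c(60, 50, 80)[ch]
    img$pixels[, , ch] <- p
  }
  m <- segment_starch(img, band)
  expect_equal(sum(m), 50)
  expect_true(all(m[sel]))

  expect_equal(sum(segment_starch(img, threshold_spec())), 400) # identity
  expect_error(threshold_spec(red = c(90, 40)), "min <= max")
  expect_error(section_image(array(300, c(4, 4, 3)), 1), "\\[0, 255\\]")
})

test_that("optical density follows log10(255 / I) with luma greyscale", {
  white <- flat_image(c(255, 255, 255), h = 2, w = 2)
  expect_equal(optical_density(white), matrix(0, 2, 2))
  gray <- flat_image(c(25.5, 25.5, 25.5), h = 2, w = 2)
  expect_equal(optical_density(gray), matrix(1, 2, 2))
  black <- flat_image(c(0, 0, 0), h = 2, w = 2)
  expect_equal(optical_density(black), matrix(log10(255), 2, 2))
  # luma weighting
  mixed <- flat_image(c(100, 50, 200), h = 2, w = 2)
  I <- 0.299 * 100 + 0.587 * 50 + 0.114 * 200
  expect_equal(optical_density(mixed)[1, 1], log10(255 / I))
})

test_that("summed starch content is additive and monotone over masks", {
  img <- flat_image(c(255, 255, 255), h = 60, w = 60)
  # paint k black pixels inside the central frame
  k <- 7
  sel <- cbind(28:(27 + k), 28:(27 + k))
  for (ch in 1:3) {
    p <- img$pixels[, , ch]
    p[sel] <- 0
    img$pixels[, , ch] <- p
  }
  fr <- measurement_frame(30, 30, area = 1337) # side 37 at 1 um/px
  empty <- matrix(FALSE, 60, 60)
  expect_equal(starch_content(img, empty, fr), 0)
  full <- matrix(TRUE, 60, 60)
  expect_equal(starch_content(img, full, fr), k * log10(255))

  m1 <- empty
  m1[sel[1:3, ]] <- TRUE
  m2 <- empty
  m2[sel[4:k, ]] <- TRUE
  expect_equal(
    starch_content(img, m1 | m2, fr),
    starch_content(img, m1, fr) + starch_content(img, m2, fr)
  )
  expect_gte(starch_content(img, m1 | m2, fr), starch_content(img, m1, fr))

  expect_error(starch_content(img, full, measurement_frame(5, 5, 1337)),
    "outside"
  )
  expect_error(measurement_frame(5, 5, -1), "positive")
})

test_that("ovary measurement averages four frames", {
  g <- gen_section_image(0.12, seed = 401)
  band <- do.call(threshold_spec, default_granule_band())
  m <- measure_ovary(g$image, band, g$frames)
  expect_length(m$per_frame, 4)
  expect_equal(m$ovary_value, mean(m$per_frame))
  expect_true(all(m$per_frame >= 0))
  expect_error(measure_ovary(g$image, band, g$frames[1:3]), "exactly 4")
  expect_s3_class(
    measure_ovary(g$image, band, g$frames[1:3], allow_any_frames = TRUE),
    "starch_measurement"
  )

  blank <- gen_section_image(0, seed = 402)
  expect_equal(measure_ovary(blank$image, band, blank$frames)$ovary_value, 0)
  expect_false(any(blank$mask))

  # measured value strictly increasing in the planted starch fraction
  thetas <- seq(0, 0.2, by = 0.05)
  vals <- vapply(seq_along(thetas), function(i) {
    gi <- gen_section_image(thetas[i], seed = 500 + i)
    measure_ovary(gi$image, band, gi$frames)$ovary_value
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("threshold calibration at a coarse grid equals the exhaustive oracle", {
  set.seed(77)
  px <- array(round(runif(18 * 18 * 3, 120, 255)), c(18, 18, 3))
  ref <- matrix(FALSE, 18, 18)
  ref[4:9, 5:13] <- TRUE
  for (ch in 1:3) {
    p <- px[, , ch]
    p[ref] <- round(runif(sum(ref), 40, 110))
    px[, , ch] <- p
  }
  img <- section_image(px, 1)
  cal <- calibrate_threshold(img, ref, step = 64)
  expect_identical(attr(cal, "method"), "exhaustive")

  grid <- sort(unique(c(seq(0, 255, by = 64), 255)))
  pl <- list()
  for (i in seq_along(grid)) {
    for (j in i:length(grid)) pl[[length(pl) + 1]] <- c(grid[i], grid[j])
  }
  best <- list(iou = -1, rng = Inf, lo = c(Inf, Inf, Inf))
  for (b1 in pl) {
    for (b2 in pl) {
      for (b3 in pl) {
        m <- px[, , 1] >= b1[1] & px[, , 1] <= b1[2] &
          px[, , 2] >= b2[1] & px[, , 2] <= b2[2] &
          px[, , 3] >= b3[1] & px[, , 3] <= b3[2]
        iou <- sum(m & ref) / sum(m | ref)
        rng <- (b1[2] - b1[1]) + (b2[2] - b2[1]) + (b3[2] - b3[1])
        lo <- c(b1[1], b2[1], b3[1])
        better <- iou > best$iou ||
          (iou == best$iou && rng < best$rng) ||
          (iou == best$iou && rng == best$rng && {
            cmp <- lo - best$lo
            nz <- which(cmp != 0)
            length(nz) > 0 && cmp[nz[1]] < 0
          })
        if (better) {
          best <- list(iou = iou, rng = rng, lo = lo, bounds = list(b1, b2, b3))
        }
      }
    }
  }
  expect_identical(list(cal$red, cal$green, cal$blue), best$bounds)
  expect_equal(attr(cal, "iou"), best$iou)
})

test_that("calibration handles trivial and degenerate references", {
  # image spanning the full intensity range: full-image reference recovers
  # the identity threshold
  px <- array(round(runif(12 * 12 * 3, 1, 254)), c(12, 12, 3))
  px[1, 1, ] <- 0
  px[12, 12, ] <- 255
  img <- section_image(px, 1)
  cal <- calibrate_threshold(img, matrix(TRUE, 12, 12), step = 5)
  expect_equal(cal$red, c(0, 255))
  expect_equal(cal$green, c(0, 255))
  expect_equal(cal$blue, c(0, 255))
  expect_equal(attr(cal, "iou"), 1)

  expect_error(calibrate_threshold(img, matrix(FALSE, 12, 12)), "empty")

  # unreachable reference: best-effort spec with reported IoU
  amb <- flat_image(c(100, 100, 100), h = 10, w = 10)
  ref <- matrix(FALSE, 10, 10)
  ref[1, 1] <- TRUE
  cal2 <- calibrate_threshold(amb, ref, step = 51)
  expect_s3_class(cal2, "threshold_spec")
  expect_true(is.finite(attr(cal2, "iou")))
  expect_lte(attr(cal2, "iou"), 1)
})

test_that("cell layers are wall peaks minus one", {
  # synthetic profile image: 15 bright ticks -> 14 layers
  img <- flat_image(c(200, 200, 200), h = 40, w = 200)
  ticks <- round(seq(20, 180, length.out = 15))
  for (w in ticks) img$pixels[18:22, w, ] <- 255
  tr <- transect_segment(10, 20, 190, 20)
  expect_equal(count_cell_layers(img, tr), 14L)

  flat <- flat_image(c(180, 180, 180), h = 40, w = 200)
  expect_equal(count_cell_layers(flat, tr), 0L)

  expect_error(
    count_cell_layers(img, transect_segment(10, 20, 14, 20)),
    "shorter"
  )
  expect_error(
    count_cell_layers(img, transect_segment(10, 20, 500, 20)),
    "outside"
  )

  # generator ground truth recovered within one layer
  g <- gen_section_image(0.1, seed = 601, n_layers = 13)
  expect_lte(abs(count_cell_layers(g$image, g$transect) - 13L), 1L)
})

test_that("ovary diameter is the scaled transect length", {
  expect_equal(ovary_diameter(transect_segment(0, 0, 0, 100), 1), 100)
  expect_equal(ovary_diameter(transect_segment(0, 0, 3, 4), 10), 50)
  expect_error(ovary_diameter(transect_segment(5, 5, 5, 5), 1), "zero-length")
})

test_that("PNG round trip preserves pixels", {
  g <- gen_section_image(0.1, seed = 701)
  path <- withr::local_tempfile(fileext = ".png")
  write_section_image(g$image, path)
  back <- read_section_image(path, pixel_size = 1)
  expect_equal(back$pixels, g$image$pixels)
})
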