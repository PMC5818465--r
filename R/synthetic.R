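#' Specification of a synthetic winter season
#'
#' Defines the climate of one simulated season (September 1 to April 30).
#' A mild winter is modelled as the cold-year climatology delayed by
#' `chill_onset_shift` days, so chilling starts to accumulate about that
#' much later.
#'
#' @param year_type `"cold"` or `"mild"`.
#' @param chill_onset_shift Days by which winter cooling is delayed;
#'   defaults to 0 (cold) or 20 (mild).
#' @param planted_cu_requirement Ground-truth chilling requirement (CU)
#'   used by the forcing-test generator.
#' @param ar_coef,noise_sd AR(1) coefficient (0 <= phi < 1) and marginal
#'   standard deviation (degrees C) of the hourly temperature noise.
#' @param start_year Calendar year of the September the season starts in.
#' @param seed Integer seed; all generators are bit-reproducible for a
#'   fixed seed and parameter set.
#' @return A `season_spec` object (list).
#' @export
season_spec <- function(year_type = c("cold", "mild"),
                        chill_onset_shift = NULL,
                        planted_cu_requirement = 1000,
                        ar_coef = 0.7, noise_sd = 1.5,
                        start_year = 2015, seed = 1L) {
  year_type <- match.arg(year_type)
  if (is.null(chill_onset_shift)) {
    chill_onset_shift <- if (year_type == "cold") 0 else 20
  }
  if (planted_cu_requirement <= 0) {
    stop("`planted_cu_requirement` must be positive", call. = FALSE)
  }
  if (ar_coef < 0 || ar_coef >= 1) {
    stop("`ar_coef` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      year_type = year_type, chill_onset_shift = chill_onset_shift,
      planted_cu_requirement = planted_cu_requirement,
      ar_coef = ar_coef, noise_sd = noise_sd,
      start_year = as.integer(start_year), seed = as.integer(seed)
    ),
    class = "season_spec"
  )
}

#' Specification of the planted starch trajectory
#'
#' Ground truth for the synthetic season: the ovary starch area fraction
#' rises linearly with cumulative chill units up to the planted chilling
#' requirement (peaking at `theta_max` at fulfillment) and then falls
#' linearly with cumulative growing degree hours, vanishing after
#' `gdh_depletion` GDH.
#'
#' @param theta_max Peak starch area fraction (0 < theta_max <= 0.5).
#' @param gdh_depletion GDH after fulfillment at which starch reaches
#'   zero. The default (600 GDH) makes starch vanish by late
#'   February/early March of the default cold season, i.e. during
#'   ecodormancy in the weeks before bud burst.
#' @param noise_sd Per-ovary standard deviation of the area fraction;
#'   defaults to 10% of `theta_max`.
#' @return A `starch_trajectory_spec` object.
#' @export
starch_trajectory_spec <- function(theta_max = 0.25, gdh_depletion = 600,
                                   noise_sd = 0.1 * theta_max) {
  if (theta_max < 0 || theta_max > 0.5) {
    stop("`theta_max` must lie in [0, 0.5]", call. = FALSE)
  }
  structure(
    list(
      theta_max = theta_max, gdh_depletion = gdh_depletion,
      noise_sd = noise_sd
    ),
    class = "starch_trajectory_spec"
  )
}

#' Generate an hourly winter temperature series
#'
#' Annual sinusoid (coldest around mid-January, shifted later for mild
#' winters) plus a diurnal sinusoid and AR(1) noise, hourly from
#' September 1 to April 30. Deterministic for a fixed spec.
#'
#' @param spec A [season_spec()].
#' @return Tibble with `timestamp` (UTC POSIXct) and `temp_c`.
#' @examples
#' temps <- gen_temperature_series(season_spec("cold", seed = 7))
#' @export
gen_temperature_series <- function(spec) {
  stopifnot(inherits(spec, "season_spec"))
  y <- spec$start_year
  ts <- seq(
    ISOdatetime(y, 9, 1, 0, 0, 0, tz = "UTC"),
    ISOdatetime(y + 1, 4, 30, 23, 0, 0, tz = "UTC"),
    by = "hour"
  )
  d <- as.numeric(difftime(ts, ts[1], units = "days"))
  hour <- as.numeric(format(ts, "%H"))
  # annual sinusoid 12 +/- 11 C, coldest mid-January. The onset shift is
  # applied only once autumn cooling reaches the chill-neutral level
  # (~13.9 C daily mean, day ~34.6: daily Utah CU sums to ~0 there given
  # the +/-4 C diurnal cycle), so a mild winter holds at that level for
  # `chill_onset_shift` days and chilling starts that much later.
  d_onset <- 34.6
  eff <- ifelse(d <= d_onset, d,
    pmax(d_onset, d - spec$chill_onset_shift)
  )
  seasonal <- 12 - 11 * cos(2 * pi * (eff - 136) / 365.25)
  diurnal <- 4 * sin(2 * pi * (hour - 9) / 24)
  noise <- withr::with_seed(spec$seed, {
    if (spec$noise_sd == 0) {
      numeric(length(ts))
    } else {
      innov_sd <- spec$noise_sd * sqrt(1 - spec$ar_coef^2)
      as.numeric(stats::filter(stats::rnorm(length(ts), 0, innov_sd),
        spec$ar_coef,
        method = "recursive",
        init = stats::rnorm(1, 0, spec$noise_sd)
      ))
    }
  })
  tibble::tibble(timestamp = ts, temp_c = seasonal + diurnal + noise)
}

#' Generate weekly forcing tests with a planted chilling requirement
#'
#' Field bud weights drift slowly upward over the season; the expected
#' forced/field weight ratio sits near `ratio_base` while the planted
#' chilling requirement is unmet and rises logistically to `ratio_max`
#' once cumulative chill units pass it, so the 30% criterion is crossed
#' at (to within hours) the first test date at or beyond fulfillment.
#'
#' @param temps Hourly temperature series (typically from
#'   [gen_temperature_series()]).
#' @param spec The [season_spec()] that produced `temps` (supplies the
#'   planted requirement and seed).
#' @param cadence Days between forcing tests (default 7).
#' @param n_buds Buds weighed per condition and date (default 10).
#' @param start_month_day Month-day (`"MM-DD"`) of the first test
#'   (default `"11-30"`).
#' @param end_date Last possible test date; defaults to March 31.
#' @param ratio_base,ratio_max,logistic_scale Expected ratio before
#'   fulfillment, its ceiling after, and the logistic width in CU.
#' @param field_mean0,field_slope Field mean weight (mg) at the first
#'   test and its increase per day.
#' @param bud_sd Per-bud weight standard deviation (mg).
#' @param season_start Start of chill accumulation (defaults as in
#'   [chilling_requirement()]).
#' @return Tibble with `date`, `condition`, `bud_id`, `weight_mg`.
#' @export
gen_forcing_tests <- function(temps, spec, cadence = 7, n_buds = 10,
                              start_month_day = "11-30", end_date = NULL,
                              ratio_base = 1.05, ratio_max = 1.6,
                              logistic_scale = 25,
                              field_mean0 = 55, field_slope = 0.05,
                              bud_sd = 3, season_start = NULL) {
  stopifnot(inherits(spec, "season_spec"))
  if (cadence < 1) stop("`cadence` must be >= 1 day", call. = FALSE)
  temps <- check_temperature_series(temps)
  y <- as.integer(format(temps$timestamp[1], "%Y"))
  first <- as.Date(sprintf("%d-%s", y, start_month_day))
  if (is.null(end_date)) end_date <- as.Date(sprintf("%d-03-31", y + 1))
  last_obs <- as.Date(temps$timestamp[nrow(temps)], tz = "UTC")
  dates <- seq(first, min(as.Date(end_date), last_obs), by = cadence)
  if (is.null(season_start)) {
    season_start <- default_season_start(temps$timestamp[1])
  }
  chill <- accumulate_thermal(temps, season_start,
    temps$timestamp[nrow(temps)],
    model = "chill"
  )
  cu_at <- lookup_cumulative(chill, dates)
  req <- spec$planted_cu_requirement
  ratio_exp <- ratio_base + (ratio_max - ratio_base) *
    stats::plogis((cu_at - req) / logistic_scale)
  days_in <- as.numeric(dates - first)
  field_mu <- field_mean0 + field_slope * days_in
  withr::with_seed(spec$seed + 1L, {
    purrr::map_dfr(seq_along(dates), function(i) {
      field <- stats::rnorm(n_buds, field_mu[i], bud_sd)
      forced <- stats::rnorm(n_buds, field_mu[i] * ratio_exp[i], bud_sd)
      tibble::tibble(
        date = dates[i],
        condition = rep(c("field", "forced"), each = n_buds),
        bud_id = rep(seq_len(n_buds), 2),
        weight_mg = pmax(c(field, forced), 1)
      )
    })
  })
}

#' Colour band of synthetic starch granules
#'
#' The dark blue-black RGB band the generator paints granules in,
#' chosen to be separable from the pale tissue background; stored in
#' every bundle's ground truth so calibration tests are self-contained.
#'
#' @return List with `red`, `green`, `blue` ranges.
#' @export
default_granule_band <- function() {
  list(red = c(40, 90), green = c(30, 70), blue = c(60, 110))
}

quadrant_frames <- function(width, height, frame_area, pixel_size) {
  qx <- round(c(width * 0.28, width * 0.72))
  qy <- round(c(height * 0.28, height * 0.72))
  list(
    measurement_frame(qx[1], qy[1], frame_area),
    measurement_frame(qx[2], qy[1], frame_area),
    measurement_frame(qx[1], qy[2], frame_area),
    measurement_frame(qx[2], qy[2], frame_area)
  )
}

#' Generate a synthetic stained ovary section
#'
#' Pale tissue background with faint cell-outline texture; starch drawn
#' as dark blue-black elliptical granules whose colours fall in a
#' distinct RGB band, covering a fraction `theta` (within 2 percentage
#' points) of the region spanned by the four measurement frames. When
#' `n_layers` is given, a horizontal transect band with `n_layers + 1`
#' bright cell-wall ticks is drawn for layer counting, spanning
#' `diameter_um`.
#'
#' @param theta Target starch area fraction of the frame region
#'   (0 <= theta <= 0.5).
#' @param width,height Image size in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed (bit-reproducible output).
#' @param n_layers Optional ground-truth number of cell layers.
#' @param diameter_um Ovary diameter represented by the transect.
#' @param granule_band RGB colour band of the granules (list with `red`,
#'   `green`, `blue` ranges).
#' @param frame_area Frame area in square micrometres.
#' @return List with `image` (a `section_image`), `mask` (ground-truth
#'   granule mask), `frames` (4 [measurement_frame()]s), `transect`
#'   (or `NULL`), `theta_achieved` (granule fraction of the frame
#'   region).
#' @export
gen_section_image <- function(theta, width = 160, height = 160,
                              pixel_size = 1, seed = 1L, n_layers = NULL,
                              diameter_um = 130,
                              granule_band = default_granule_band(),
                              frame_area = 1337) {
  if (theta < 0 || theta > 0.5) {
    stop("`theta` must lie in [0, 0.5]", call. = FALSE)
  }
  frames <- quadrant_frames(width, height, frame_area, pixel_size)
  withr::with_seed(as.integer(seed), {
    px <- array(0, c(height, width, 3))
    base_col <- c(225, 215, 200)
    for (ch in 1:3) {
      px[, , ch] <- base_col[ch] + stats::rnorm(height * width, 0, 4)
    }
    # faint cell-outline grid
    outline <- c(188, 178, 162)
    rows_g <- which(seq_len(height) %% 13 == 0)
    cols_g <- which(seq_len(width) %% 13 == 0)
    for (ch in 1:3) {
      px[rows_g, , ch] <- outline[ch] + stats::rnorm(length(rows_g) * width, 0, 3)
      px[, cols_g, ch] <- outline[ch] + stats::rnorm(height * length(cols_g), 0, 3)
    }
    transect <- NULL
    if (!is.null(n_layers)) {
      mid <- round(height / 2)
      band <- max(1, mid - 5):min(height, mid + 5)
      for (ch in 1:3) px[band, , ch] <- c(205, 200, 190)[ch]
      dpx <- diameter_um / pixel_size
      cx <- width / 2
      x1 <- cx - dpx / 2
      x2 <- cx + dpx / 2
      if (x1 < 8 || x2 > width - 7) {
        stop("`diameter_um` too large for the image", call. = FALSE)
      }
      walls <- round(seq(x1, x2, length.out = n_layers + 1))
      tick_rows <- max(1, mid - 2):min(height, mid + 2)
      for (w in walls) px[tick_rows, w, ] <- 252
      transect <- transect_segment(x1 - 6, mid, x2 + 6, mid)
    }
    # granules inside the union of the four frames
    mask <- matrix(FALSE, height, width)
    frame_region <- matrix(FALSE, height, width)
    tmp_img <- section_image(
      array(pmin(pmax(px, 0), 255), dim(px)),
      pixel_size
    )
    ix_list <- lapply(frames, frame_indices, image = tmp_img)
    for (ix in ix_list) frame_region[ix$rows, ix$cols] <- TRUE
    target <- theta * sum(frame_region)
    guard <- 0
    while (sum(mask & frame_region) < target && guard < 5000) {
      guard <- guard + 1
      ix <- ix_list[[sample.int(4, 1)]]
      cy <- sample(ix$rows, 1)
      cx_g <- sample(ix$cols, 1)
      a <- stats::runif(1, 2, 5)
      b <- stats::runif(1, 2, 5)
      ang <- stats::runif(1, 0, pi)
      rr <- max(1, floor(cy - 6)):min(height, ceiling(cy + 6))
      cc <- max(1, floor(cx_g - 6)):min(width, ceiling(cx_g + 6))
      gy <- outer(rr - cy, rep(1, length(cc)))
      gx <- outer(rep(1, length(rr)), cc - cx_g)
      u <- gx * cos(ang) + gy * sin(ang)
      v <- -gx * sin(ang) + gy * cos(ang)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      col <- c(
        stats::runif(1, granule_band$red[1], granule_band$red[2]),
        stats::runif(1, granule_band$green[1], granule_band$green[2]),
        stats::runif(1, granule_band$blue[1], granule_band$blue[2])
      )
      for (ch in 1:3) {
        plane <- px[rr, cc, ch]
        plane[inside] <- col[ch] + stats::rnorm(sum(inside), 0, 2)
        px[rr, cc, ch] <- plane
      }
      mask[rr, cc][inside] <- TRUE
    }
    # clamp granule noise back into the band so the mask stays exact
    for (ch in 1:3) {
      band_ch <- granule_band[[ch]]
      plane <- px[, , ch]
      plane[mask] <- pmin(pmax(plane[mask], band_ch[1]), band_ch[2])
      plane[!mask] <- pmin(pmax(plane[!mask], 150), 255)
      px[, , ch] <- plane
    }
    px <- round(pmin(pmax(px, 0), 255))
    list(
      image = section_image(px, pixel_size),
      mask = mask, frames = frames, transect = transect,
      theta_achieved = sum(mask & frame_region) / sum(frame_region)
    )
  })
}

planted_theta <- function(cu, gdh_since_break, traj, requirement) {
  pre <- pmin(pmax(cu, 0) / requirement, 1)
  post_scale <- pmax(0, 1 - gdh_since_break / traj$gdh_depletion)
  ifelse(gdh_since_break <= 0, traj$theta_max * pre,
    traj$theta_max * post_scale
  )
}

#' Generate a full synthetic cultivar-year bundle
#'
#' Writes every input the pipeline consumes for one cultivar-year:
#' hourly temperature CSV, forcing-test CSV, one stained-section image
#' per ovary and collection date (6 ovaries per date, 4 frames each,
#' collections every 14 days by default), an annotation JSON, a pipeline
#' `config.json`, and `ground_truth.json` holding the planted chilling
#' requirement, fulfillment date, per-date starch fractions and ovary
#' growth schedule. The starch trajectory is driven by the season's own
#' chill and heat accumulation, so the correlation structure the
#' analysis tests for is planted by construction.
#'
#' @param season A [season_spec()].
#' @param traj A [starch_trajectory_spec()].
#' @param out_dir Output directory (created if needed).
#' @param dates Optional explicit collection dates; default every 14
#'   days from September 15 to March 31.
#' @param n_ovaries Ovaries sectioned per collection date.
#' @param image_width,image_height,pixel_size Image geometry.
#' @param write_images If `FALSE`, only tables and ground truth are
#'   written (fast mode for temperature/forcing work).
#' @return Invisibly, a list with `paths` (all files written), `truth`
#'   (ground-truth list) and `config` (pipeline configuration list).
#' @export
gen_season_dataset <- function(season, traj = starch_trajectory_spec(),
                               out_dir, dates = NULL, n_ovaries = 6,
                               image_width = 160, image_height = 160,
                               pixel_size = 1, write_images = TRUE) {
  stopifnot(
    inherits(season, "season_spec"),
    inherits(traj, "starch_trajectory_spec")
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  temps <- gen_temperature_series(season)
  y <- season$start_year
  if (is.null(dates)) {
    dates <- seq(as.Date(sprintf("%d-09-15", y)),
      as.Date(sprintf("%d-03-31", y + 1)),
      by = 14
    )
  }
  season_start <- default_season_start(temps$timestamp[1])
  chill <- accumulate_thermal(temps, season_start,
    temps$timestamp[nrow(temps)],
    model = "chill"
  )
  req <- season$planted_cu_requirement
  hit <- which(chill$cumulative >= req)
  if (!length(hit)) {
    stop("planted chilling requirement is never fulfilled in this season",
      call. = FALSE
    )
  }
  fulfillment <- as.Date(chill$timestamp[hit[1]], tz = "UTC")
  heat <- accumulate_thermal(temps, fulfillment,
    temps$timestamp[nrow(temps)],
    model = "heat"
  )
  cu_at <- lookup_cumulative(chill, dates)
  gdh_since <- ifelse(dates > fulfillment, lookup_cumulative(heat, dates), 0)
  theta_dates <- planted_theta(cu_at, gdh_since, traj, req)
  post_frac <- pmin(gdh_since / traj$gdh_depletion, 1)
  layers_dates <- ifelse(dates <= fulfillment, 13L,
    13L + as.integer(round(7 * post_frac))
  )
  diameter_dates <- 90 + 40 * post_frac
  forcing <- gen_forcing_tests(temps, season)

  temp_path <- file.path(out_dir, "temperature.csv")
  readr::write_csv(
    dplyr::mutate(temps,
      timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S")
    ),
    temp_path
  )
  forcing_path <- file.path(out_dir, "forcing.csv")
  readr::write_csv(forcing, forcing_path)

  img_dir <- file.path(out_dir, "images")
  annotations <- list()
  theta_ovary <- list()
  if (write_images) {
    dir.create(img_dir, showWarnings = FALSE)
    counter <- 0
    for (i in seq_along(dates)) {
      for (ov in seq_len(n_ovaries)) {
        counter <- counter + 1
        img_seed <- (season$seed * 131071L + counter * 7919L) %% 2147483647L
        th <- withr::with_seed(
          img_seed,
          min(
            0.5,
            max(0, theta_dates[i] + stats::rnorm(1, 0, traj$noise_sd))
          )
        )
        gen <- gen_section_image(th,
          width = image_width, height = image_height,
          pixel_size = pixel_size, seed = img_seed + 1L,
          n_layers = layers_dates[i], diameter_um = diameter_dates[i]
        )
        fname <- sprintf("%s_ovary%d.png", format(dates[i]), ov)
        write_section_image(gen$image, file.path(img_dir, fname))
        annotations[[fname]] <- list(
          file = fname, date = format(dates[i]), ovary_id = ov,
          pixel_size_um = pixel_size,
          frames = lapply(gen$frames, function(f) list(x = f$x, y = f$y)),
          frame_area_um2 = 1337,
          transect = if (is.null(gen$transect)) {
            NULL
          } else {
            list(
              x1 = gen$transect$x1, y1 = gen$transect$y1,
              x2 = gen$transect$x2, y2 = gen$transect$y2
            )
          }
        )
        theta_ovary[[length(theta_ovary) + 1]] <- tibble::tibble(
          date = dates[i], ovary_id = ov, theta = th
        )
      }
    }
  }
  annot_path <- file.path(out_dir, "annotations.json")
  jsonlite::write_json(unname(annotations), annot_path,
    auto_unbox = TRUE,
    digits = NA
  )
  truth <- list(
    planted_cu_requirement = req,
    fulfillment_date = format(fulfillment),
    season_start = format(season_start),
    chill_onset_shift = season$chill_onset_shift,
    year_type = season$year_type,
    theta_by_date = data.frame(
      date = format(dates), cu = cu_at, gdh_since_break = gdh_since,
      theta = theta_dates, n_layers = layers_dates,
      diameter_um = diameter_dates
    ),
    theta_by_ovary = if (length(theta_ovary)) {
      as.data.frame(dplyr::mutate(dplyr::bind_rows(theta_ovary),
        date = format(.data$date)
      ))
    } else {
      NULL
    },
    granule_band = default_granule_band(),
    theta_max = traj$theta_max, gdh_depletion = traj$gdh_depletion,
    ovary_noise_sd = traj$noise_sd, seed = season$seed
  )
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  config <- list(
    paths = list(
      temperature = temp_path, forcing = forcing_path,
      image_dir = img_dir, annotations = annot_path
    ),
    season_start = format(season_start),
    break_threshold_pct = 30, frame_area_um2 = 1337,
    alpha = c(0.05, 0.01),
    threshold = default_granule_band(),
    cultivar = "synthetic", year = season$start_year,
    seed = season$seed
  )
  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA)
  invisible(list(
    paths = list(
      temperature = temp_path, forcing = forcing_path,
      image_dir = img_dir, annotations = annot_path,
      ground_truth = truth_path, config = config_path
    ),
    truth = truth, config = config
  ))
}
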