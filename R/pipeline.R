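#' Build a pipeline run configuration
#'
#' @param temperature,forcing,image_dir,annotations Input paths: hourly
#'   temperature CSV (`timestamp`, `temp_c`), forcing CSV (`date`,
#'   `condition`, `bud_id`, `weight_mg`), section-image directory, and
#'   the annotation JSON pairing images with frames/transects.
#' @param season_start Start of chill accumulation (`NULL` = September
#'   21 of the series' first year).
#' @param break_threshold_pct Forcing-test weight-increase criterion.
#' @param frame_area_um2 Measurement-frame area.
#' @param alpha Significance levels (mean separation, correlation).
#' @param threshold Starch colour threshold: a [threshold_spec()] or a
#'   list with `red`, `green`, `blue` ranges.
#' @param bloom_date Optional end of the heat-accumulation window;
#'   default: last sampled date.
#' @param cultivar,year Labels carried into outputs.
#' @param seed Integer recorded in the report provenance.
#' @return A `run_config` list.
#' @export
run_config <- function(temperature, forcing, image_dir, annotations,
                       season_start = NULL, break_threshold_pct = 30,
                       frame_area_um2 = 1337, alpha = c(0.05, 0.01),
                       threshold = NULL, bloom_date = NULL,
                       cultivar = "unknown", year = NA, seed = 1L) {
  structure(
    list(
      paths = list(
        temperature = temperature, forcing = forcing,
        image_dir = image_dir, annotations = annotations
      ),
      season_start = season_start,
      break_threshold_pct = break_threshold_pct,
      frame_area_um2 = frame_area_um2, alpha = alpha,
      threshold = threshold, bloom_date = bloom_date,
      cultivar = cultivar, year = year, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()] (relative
#'   input paths are resolved against the JSON's directory).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) {
      return(p)
    }
    file.path(base, p)
  }
  cfg <- run_config(
    temperature = resolve(raw$paths$temperature),
    forcing = resolve(raw$paths$forcing),
    image_dir = resolve(raw$paths$image_dir),
    annotations = resolve(raw$paths$annotations),
    season_start = raw$season_start,
    break_threshold_pct = raw$break_threshold_pct %||% 30,
    frame_area_um2 = raw$frame_area_um2 %||% 1337,
    alpha = raw$alpha %||% c(0.05, 0.01),
    threshold = raw$threshold,
    bloom_date = raw$bloom_date,
    cultivar = raw$cultivar %||% "unknown",
    year = raw$year %||% NA,
    seed = raw$seed %||% 1L
  )
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_stop <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}

read_annotations <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map(ann, function(a) {
    a$date <- as.Date(a$date)
    a
  })
}

#' Validate pipeline inputs
#'
#' Schema and consistency checks on every input named by the
#' configuration; failures are listed, never thrown.
#'
#' @param config A [run_config()] (or path to a config JSON).
#' @return A tibble with columns `check`, `ok`, `detail`; zero rows with
#'   `ok == FALSE` means a well-formed bundle.
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  res <- list()
  add <- function(check, ok, detail = "") {
    res[[length(res) + 1]] <<- tibble::tibble(
      check = check, ok = ok,
      detail = detail
    )
  }
  p <- config$paths
  for (nm in c("temperature", "forcing", "annotations")) {
    ok <- !is.null(p[[nm]]) && file.exists(p[[nm]])
    add(paste0(nm, "_exists"), ok, if (ok) "" else paste("missing:", p[[nm]]))
  }
  ok_dir <- !is.null(p$image_dir) && dir.exists(p$image_dir)
  add("image_dir_exists", ok_dir, if (ok_dir) "" else paste("missing:", p$image_dir))

  if (!is.null(p$temperature) && file.exists(p$temperature)) {
    temps <- tryCatch(
      readr::read_csv(p$temperature, show_col_types = FALSE),
      error = function(e) e
    )
    if (inherits(temps, "error")) {
      add("temperature_parses", FALSE, conditionMessage(temps))
    } else if (!all(c("timestamp", "temp_c") %in% names(temps))) {
      add("temperature_schema", FALSE, "needs columns timestamp, temp_c")
    } else {
      chk <- tryCatch(check_temperature_series(temps), error = function(e) e)
      if (inherits(chk, "error")) {
        add("temperature_series_valid", FALSE, conditionMessage(chk))
      } else {
        add("temperature_series_valid", TRUE)
        gaps <- diff(as.numeric(chk$timestamp)) / 3600
        n_gap <- sum(gaps > 1)
        add(
          "temperature_hour_coverage", n_gap == 0,
          if (n_gap) sprintf("%d gaps longer than 1 h", n_gap) else ""
        )
      }
    }
  }
  if (!is.null(p$forcing) && file.exists(p$forcing)) {
    forcing <- tryCatch(readr::read_csv(p$forcing, show_col_types = FALSE),
      error = function(e) e
    )
    if (inherits(forcing, "error")) {
      add("forcing_parses", FALSE, conditionMessage(forcing))
    } else {
      need <- c("date", "condition", "weight_mg")
      ok <- all(need %in% names(forcing))
      add(
        "forcing_schema", ok,
        if (ok) "" else paste("needs columns", paste(need, collapse = ", "))
      )
      if (ok) {
        bad <- setdiff(unique(forcing$condition), c("field", "forced"))
        add(
          "forcing_conditions", length(bad) == 0,
          if (length(bad)) paste("unknown condition:", paste(bad, collapse = ",")) else ""
        )
      }
    }
  }
  if (!is.null(p$annotations) && file.exists(p$annotations) && ok_dir) {
    ann <- tryCatch(read_annotations(p$annotations), error = function(e) e)
    if (inherits(ann, "error")) {
      add("annotations_parse", FALSE, conditionMessage(ann))
    } else {
      missing_imgs <- character()
      bad_frames <- character()
      for (a in ann) {
        img_path <- file.path(p$image_dir, a$file)
        if (!file.exists(img_path)) {
          missing_imgs <- c(missing_imgs, a$file)
          next
        }
        img <- tryCatch(
          read_section_image(img_path, pixel_size = a$pixel_size_um),
          error = function(e) NULL
        )
        if (is.null(img)) {
          missing_imgs <- c(missing_imgs, a$file)
          next
        }
        for (fr in a$frames) {
          f <- measurement_frame(fr$x, fr$y,
            area = a$frame_area_um2 %||% config$frame_area_um2
          )
          ok_f <- !inherits(
            tryCatch(frame_indices(f, img), error = function(e) e),
            "error"
          )
          if (!ok_f) bad_frames <- c(bad_frames, a$file)
        }
      }
      add(
        "images_paired", length(missing_imgs) == 0,
        if (length(missing_imgs)) {
          paste("unreadable/missing:", paste(unique(missing_imgs), collapse = ", "))
        } else {
          ""
        }
      )
      add(
        "frames_inside_images", length(bad_frames) == 0,
        if (length(bad_frames)) {
          paste("frame outside image:", paste(unique(bad_frames), collapse = ", "))
        } else {
          ""
        }
      )
    }
  }
  dplyr::bind_rows(res)
}

#' Run the full cultivar-year analysis
#'
#' Orchestrates the stages in order: chill accumulation from the season
#' start, forcing-test break dating and the derived chilling
#' requirement, heat accumulation from the break, starch densitometry
#' and ovary growth measurement on every annotated section, one-way
#' ANOVA with Duncan letters across collection dates, and windowed
#' starch-vs-chill / starch-vs-heat correlations. Deterministic given
#' inputs and configuration.
#'
#' @param config A [run_config()] or path to a config JSON.
#' @param out_dir Optional directory; when given, the fixed-schema TSV
#'   outputs (`cu_gdh_daily.tsv`, `break_dates.tsv`,
#'   `starch_by_date.tsv`, `ovary_growth.tsv`, `anova_groups.tsv`,
#'   `correlations.tsv`) and `report.json` are written there.
#' @return A `run_report` list: `chilling_requirement`, `break_date`,
#'   `determination`, `chill`, `heat`, `starch` (per-ovary tibble),
#'   `growth`, `anova`, `duncan`, `correlations`, `daily`, `warnings`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  warn_log <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  p <- config$paths

  message("stage thermal_models: reading temperature record")
  if (is.null(p$temperature) || !file.exists(p$temperature)) {
    stage_stop("thermal_models", paste("temperature CSV not found:", p$temperature))
  }
  temps <- readr::read_csv(p$temperature, show_col_types = FALSE)
  temps <- check_temperature_series(temps)
  season_start <- if (is.null(config$season_start)) {
    default_season_start(temps$timestamp[1])
  } else {
    as.Date(config$season_start)
  }
  last_ts <- temps$timestamp[nrow(temps)]
  chill <- collect(accumulate_thermal(temps, season_start, last_ts,
    model = "chill"
  ))
  daily <- collect(thermal_daily_summary(temps,
    start = season_start,
    end = last_ts
  ))
  message(sprintf(
    "stage thermal_models: %d hours, %.0f CU total",
    nrow(chill), total_accumulation(chill)
  ))

  message("stage dormancy_break: forcing tests")
  if (is.null(p$forcing) || !file.exists(p$forcing)) {
    stage_stop("dormancy_break", paste("forcing CSV not found:", p$forcing))
  }
  forcing <- readr::read_csv(p$forcing, show_col_types = FALSE)
  det <- estimate_break_date(forcing,
    threshold_pct = config$break_threshold_pct
  )
  if (is.na(det$break_date)) {
    stage_stop("dormancy_break", "no forcing test met the break criterion")
  }
  cu_req <- collect(chilling_requirement(temps, det,
    season_start = season_start
  ))
  det$chilling_requirement <- as.numeric(cu_req)
  heat_end <- if (is.null(config$bloom_date)) {
    last_ts
  } else {
    as.Date(config$bloom_date)
  }
  heat <- collect(accumulate_thermal(temps, det$break_date, heat_end,
    model = "heat"
  ))
  message(sprintf(
    "stage dormancy_break: break %s, requirement %.0f CU",
    format(det$break_date), det$chilling_requirement
  ))

  message("stage starch_imaging: measuring sections")
  if (is.null(p$annotations) || !file.exists(p$annotations)) {
    stage_stop("starch_imaging", paste("annotation JSON not found:", p$annotations))
  }
  if (is.null(p$image_dir) || !dir.exists(p$image_dir)) {
    stage_stop("starch_imaging", paste("image directory not found:", p$image_dir))
  }
  ann <- read_annotations(p$annotations)
  if (!length(ann)) stage_stop("starch_imaging", "no annotated images")
  thr <- config$threshold
  if (is.null(thr)) {
    stage_stop("starch_imaging", "no colour threshold in config")
  }
  if (!inherits(thr, "threshold_spec")) {
    thr <- threshold_spec(
      red = unlist(thr$red), green = unlist(thr$green),
      blue = unlist(thr$blue)
    )
  }
  starch_rows <- list()
  growth_rows <- list()
  for (a in ann) {
    img_path <- file.path(p$image_dir, a$file)
    if (!file.exists(img_path)) {
      stage_stop("starch_imaging", paste("image not found:", a$file))
    }
    img <- read_section_image(img_path,
      pixel_size = a$pixel_size_um,
      ovary_id = a$ovary_id, date = a$date
    )
    frames <- lapply(a$frames, function(fr) {
      measurement_frame(fr$x, fr$y,
        area = a$frame_area_um2 %||% config$frame_area_um2
      )
    })
    m <- measure_ovary(img, thr, frames)
    starch_rows[[length(starch_rows) + 1]] <- tibble::tibble(
      cultivar = config$cultivar, year = config$year,
      date = a$date, ovary_id = a$ovary_id,
      frame_1 = m$per_frame[1], frame_2 = m$per_frame[2],
      frame_3 = m$per_frame[3], frame_4 = m$per_frame[4],
      ovary_value = m$ovary_value
    )
    if (!is.null(a$transect)) {
      tr <- transect_segment(
        a$transect$x1, a$transect$y1,
        a$transect$x2, a$transect$y2
      )
      growth_rows[[length(growth_rows) + 1]] <- tibble::tibble(
        date = a$date, ovary_id = a$ovary_id,
        cell_layers = collect(count_cell_layers(img, tr)),
        diameter_um = ovary_diameter(tr, img$pixel_size)
      )
    }
  }
  starch <- dplyr::arrange(
    dplyr::bind_rows(starch_rows), .data$date,
    .data$ovary_id
  )
  growth <- if (length(growth_rows)) {
    dplyr::arrange(dplyr::bind_rows(growth_rows), .data$date, .data$ovary_id)
  } else {
    tibble::tibble()
  }
  message(sprintf("stage starch_imaging: %d sections measured", nrow(starch)))

  message("stage stats_inference")
  anova_fit <- NULL
  duncan <- NULL
  anova_note <- NA_character_
  if (length(unique(starch$ovary_value)) > 1) {
    anova_fit <- one_way_anova(starch, "ovary_value", "date")
    duncan <- duncan_mrt(starch, "ovary_value", "date",
      alpha = config$alpha[1]
    )
  } else {
    anova_note <- "ANOVA skipped: all starch values identical"
    warn_log <- c(warn_log, anova_note)
  }
  sbd <- dplyr::transmute(starch,
    date = .data$date,
    starch = .data$ovary_value
  )
  correlations <- collect(windowed_correlations(sbd, chill, heat,
    break_date = det$break_date
  ))
  correlations <- dplyr::mutate(correlations,
    cultivar = config$cultivar,
    year = config$year, .before = 1
  )

  report <- structure(
    list(
      cultivar = config$cultivar, year = config$year,
      chilling_requirement = det$chilling_requirement,
      break_date = det$break_date,
      ratio_at_break = det$ratios$ratio[det$ratios$date == det$break_date],
      heat_total = total_accumulation(heat),
      determination = det, chill = chill, heat = heat, daily = daily,
      starch = starch, growth = growth, anova = anova_fit,
      duncan = duncan, anova_note = anova_note,
      correlations = correlations, warnings = unique(warn_log),
      provenance = list(
        config_hash = rlang::hash(unclass(config)), seed = config$seed,
        package_version = as.character(utils::packageVersion("budstarch")),
        schema_version = "1.0"
      )
    ),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_report_outputs(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Cultivar-year run: %s %s\n", x$cultivar, x$year))
  cat(sprintf(
    "  break of endodormancy: %s (ratio %.3f)\n",
    format(x$break_date), x$ratio_at_break
  ))
  cat(sprintf("  chilling requirement: %.0f CU\n", x$chilling_requirement))
  cat(sprintf("  heat accumulated after break: %.0f GDH\n", x$heat_total))
  cat(sprintf(
    "  sections measured: %d over %d dates\n", nrow(x$starch),
    length(unique(x$starch$date))
  ))
  print(x$correlations[, c("window", "n", "r", "p", "stars")])
  invisible(x)
}

write_report_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$daily, file.path(out_dir, "cu_gdh_daily.tsv"))
  readr::write_tsv(
    tibble::tibble(
      cultivar = report$cultivar, year = report$year,
      break_date = format(report$break_date),
      ratio_at_break = report$ratio_at_break,
      chilling_requirement_CU = report$chilling_requirement
    ),
    file.path(out_dir, "break_dates.tsv")
  )
  readr::write_tsv(report$starch, file.path(out_dir, "starch_by_date.tsv"))
  if (nrow(report$growth)) {
    readr::write_tsv(report$growth, file.path(out_dir, "ovary_growth.tsv"))
  }
  if (!is.null(report$duncan)) {
    groups <- dplyr::transmute(report$duncan$means,
      date = .data$group, mean = .data$mean, sd = .data$sd,
      n = .data$n, letters = .data$letters
    )
    readr::write_tsv(groups, file.path(out_dir, "anova_groups.tsv"))
  }
  readr::write_tsv(report$correlations, file.path(out_dir, "correlations.tsv"))
  json_report <- list(
    cultivar = report$cultivar, year = report$year,
    break_date = format(report$break_date),
    ratio_at_break = report$ratio_at_break,
    chilling_requirement_CU = report$chilling_requirement,
    heat_total_GDH = report$heat_total,
    anova = if (is.null(report$anova)) {
      report$anova_note
    } else {
      list(
        f = report$anova$f, df_between = report$anova$df_between,
        df_within = report$anova$df_within, p = report$anova$p,
        mse = report$anova$mse
      )
    },
    correlations = as.data.frame(report$correlations),
    warnings = report$warnings,
    provenance = report$provenance
  )
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(out_dir)
}
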