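#' Construct a stained-section image
#'
#' Sections stained with the iodine (I2KI) reaction are photographed as
#' 8-bit RGB rasters; starch granules appear as dark blue-black regions.
#' The physical pixel size calibrates area and length measurements.
#'
#' @param pixels Numeric array `height x width x 3`, intensities in
#'   0..255.
#' @param pixel_size Physical size of a pixel (micrometres per pixel).
#' @param ovary_id,date Optional metadata carried through measurements.
#' @return A `section_image` object.
#' @export
section_image <- function(pixels, pixel_size, ovary_id = NA, date = NA) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels, pixel_size = pixel_size,
      ovary_id = ovary_id, date = date
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "section_image %d x %d px (%.3g um/px)\n", d[1], d[2],
    x$pixel_size
  ))
  invisible(x)
}

#' Read a section image from PNG or TIFF
#'
#' Intensities are rescaled to 0..255; 16-bit TIFF input is linearly
#' rescaled with a warning. Greyscale files are replicated across the
#' three channels.
#'
#' @param path PNG or TIFF file.
#' @inheritParams section_image
#' @return A `section_image`.
#' @export
read_section_image <- function(path, pixel_size, ovary_id = NA, date = NA) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (!is.null(bits) && isTRUE(bits > 8)) {
      warning("16-bit image linearly rescaled to 8-bit range", call. = FALSE)
    }
  } else {
    raw <- png::readPNG(path)
  }
  if (length(dim(raw)) == 2) raw <- array(raw, c(dim(raw), 3))
  raw <- raw[, , 1:3, drop = FALSE] # drop alpha if present
  section_image(round(raw * 255),
    pixel_size = pixel_size,
    ovary_id = ovary_id, date = date
  )
}

#' Write a section image as PNG
#'
#' @param image A `section_image`.
#' @param path Output PNG path.
#' @export
write_section_image <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Per-channel colour threshold defining "starch"
#'
#' The imaging system identifies a colour as a combination of red, green
#' and blue detection ranges; a pixel counts as starch when every channel
#' lies within its inclusive `[min, max]` bounds.
#'
#' @param red,green,blue Length-2 numeric `(min, max)`, each within
#'   0..255 and `min <= max`.
#' @return A `threshold_spec` object.
#' @examples
#' threshold_spec(red = c(40, 90), green = c(30, 70), blue = c(60, 110))
#' @export
threshold_spec <- function(red = c(0, 255), green = c(0, 255),
                           blue = c(0, 255)) {
  chk <- function(b, nm) {
    if (!is.numeric(b) || length(b) != 2 || any(!is.finite(b)) ||
      b[1] > b[2] || b[1] < 0 || b[2] > 255) {
      stop(sprintf("invalid threshold for %s: need 0 <= min <= max <= 255", nm),
        call. = FALSE
      )
    }
    as.numeric(b)
  }
  structure(
    list(
      red = chk(red, "red"), green = chk(green, "green"),
      blue = chk(blue, "blue")
    ),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "threshold_spec R[%g,%g] G[%g,%g] B[%g,%g]\n",
    x$red[1], x$red[2], x$green[1], x$green[2], x$blue[1], x$blue[2]
  ))
  if (!is.null(attr(x, "iou"))) {
    cat(sprintf(
      "  calibration IoU %.3f (%s)\n", attr(x, "iou"),
      attr(x, "method")
    ))
  }
  invisible(x)
}

#' Segment starch by colour threshold
#'
#' @param image A `section_image`.
#' @param thr A `threshold_spec`.
#' @return Logical matrix (`TRUE` = starch) of the image's height x width.
#' @export
segment_starch <- function(image, thr) {
  stopifnot(inherits(image, "section_image"))
  if (!inherits(thr, "threshold_spec")) {
    thr <- do.call(threshold_spec, thr)
  }
  px <- image$pixels
  px[, , 1] >= thr$red[1] & px[, , 1] <= thr$red[2] &
    px[, , 2] >= thr$green[1] & px[, , 2] <= thr$green[2] &
    px[, , 3] >= thr$blue[1] & px[, , 3] <= thr$blue[2]
}

#' Calibrate colour thresholds against a reference mask
#'
#' Emulates the interactive procedure of raising detection levels until
#' the binary image matches the visually identified granules, but
#' deterministically: bounds are restricted to a quantisation grid
#' (multiples of `step`, plus 255) and chosen to maximise
#' intersection-over-union (IoU) with `reference_mask`. Ties are broken
#' toward the tightest bounds (smallest total range), then smallest lower
#' bounds.
#'
#' When the grid is coarse enough, all candidate boxes are searched
#' exhaustively; otherwise a deterministic coordinate ascent (exact 1-D
#' scans per channel from a full-range start) is used.
#'
#' @param image A `section_image`.
#' @param reference_mask Non-empty logical matrix matching the image.
#' @param step Grid step for candidate bounds (default 5 intensity
#'   levels).
#' @param exhaustive_limit Maximum number of candidate boxes for the
#'   exhaustive route.
#' @return A `threshold_spec` with attributes `iou` (achieved IoU) and
#'   `method` (`"exhaustive"` or `"coordinate_ascent"`).
#' @export
calibrate_threshold <- function(image, reference_mask, step = 5,
                                exhaustive_limit = 1e5) {
  stopifnot(inherits(image, "section_image"))
  d <- dim(image$pixels)
  if (!is.logical(reference_mask) || !all(dim(reference_mask) == d[1:2])) {
    stop("`reference_mask` must be a logical matrix matching the image",
      call. = FALSE
    )
  }
  if (!any(reference_mask)) {
    stop("`reference_mask` is empty", call. = FALSE)
  }
  grid <- sort(unique(c(seq(0, 255, by = step), 255)))
  k <- length(grid)
  npairs <- k * (k + 1) / 2
  chans <- lapply(1:3, function(i) as.integer(round(image$pixels[, , i])))
  ref <- as.vector(reference_mask)
  n_ref <- sum(ref)
  if (npairs^3 <= exhaustive_limit) {
    res <- calibrate_exhaustive(chans, ref, n_ref, grid)
  } else {
    res <- calibrate_ascent(chans, ref, n_ref, grid)
  }
  spec <- threshold_spec(
    red = res$bounds[[1]], green = res$bounds[[2]],
    blue = res$bounds[[3]]
  )
  attr(spec, "iou") <- res$iou
  attr(spec, "method") <- res$method
  spec
}

# refined bins: grid values get their own bin, gaps between grid values
# another, so inclusive [grid_a, grid_b] boxes sum exactly
refined_bin <- function(v, grid) {
  j <- findInterval(v, grid)
  ifelse(v == grid[j], 2L * j - 1L, 2L * j)
}

cumsum3 <- function(a) {
  a <- apply(a, c(2, 3), cumsum) # along dim 1
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3)) # along dim 2
  aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1)) # along dim 3
}

calibrate_exhaustive <- function(chans, ref, n_ref, grid) {
  k <- length(grid)
  nb <- 2L * k - 1L
  b1 <- refined_bin(chans[[1]], grid)
  b2 <- refined_bin(chans[[2]], grid)
  b3 <- refined_bin(chans[[3]], grid)
  key <- (b3 - 1L) * nb * nb + (b2 - 1L) * nb + b1 # [b1, b2, b3] layout
  cnt_ref <- array(tabulate(key[ref], nbins = nb^3), dim = c(nb, nb, nb))
  cnt_all <- array(tabulate(key, nbins = nb^3), dim = c(nb, nb, nb))
  Cref <- cumsum3(cnt_ref)
  Call <- cumsum3(cnt_all)
  box_sum <- function(C, a1, z1, a2, z2, a3, z3) {
    g <- function(i, j, l) {
      if (i < 1 || j < 1 || l < 1) {
        return(0)
      }
      C[i, j, l]
    }
    g(z1, z2, z3) - g(a1 - 1, z2, z3) - g(z1, a2 - 1, z3) -
      g(z1, z2, a3 - 1) + g(a1 - 1, a2 - 1, z3) + g(a1 - 1, z2, a3 - 1) +
      g(z1, a2 - 1, a3 - 1) - g(a1 - 1, a2 - 1, a3 - 1)
  }
  pair_lo <- rep(seq_len(k), times = k - seq_len(k) + 1)
  pair_hi <- unlist(lapply(seq_len(k), function(i) i:k))
  best <- list(iou = -1, range = Inf, lo = c(Inf, Inf, Inf), bounds = NULL)
  for (p1 in seq_along(pair_lo)) {
    a1 <- pair_lo[p1]
    z1 <- pair_hi[p1]
    for (p2 in seq_along(pair_lo)) {
      a2 <- pair_lo[p2]
      z2 <- pair_hi[p2]
      for (p3 in seq_along(pair_lo)) {
        a3 <- pair_lo[p3]
        z3 <- pair_hi[p3]
        tp <- box_sum(
          Cref, 2 * a1 - 1, 2 * z1 - 1, 2 * a2 - 1, 2 * z2 - 1,
          2 * a3 - 1, 2 * z3 - 1
        )
        all_in <- box_sum(
          Call, 2 * a1 - 1, 2 * z1 - 1, 2 * a2 - 1, 2 * z2 - 1,
          2 * a3 - 1, 2 * z3 - 1
        )
        iou <- tp / (n_ref + (all_in - tp))
        rng <- (grid[z1] - grid[a1]) + (grid[z2] - grid[a2]) +
          (grid[z3] - grid[a3])
        lo <- c(grid[a1], grid[a2], grid[a3])
        if (better_candidate(iou, rng, lo, best)) {
          best <- list(
            iou = iou, range = rng, lo = lo,
            bounds = list(
              c(grid[a1], grid[z1]), c(grid[a2], grid[z2]),
              c(grid[a3], grid[z3])
            )
          )
        }
      }
    }
  }
  best$method <- "exhaustive"
  best
}

better_candidate <- function(iou, rng, lo, best) {
  if (iou > best$iou) return(TRUE)
  if (iou < best$iou) return(FALSE)
  if (rng < best$range) return(TRUE)
  if (rng > best$range) return(FALSE)
  cmp <- lo - best$lo
  nz <- which(cmp != 0)
  length(nz) > 0 && cmp[nz[1]] < 0
}

calibrate_ascent <- function(chans, ref, n_ref, grid, max_sweeps = 20) {
  k <- length(grid)
  bounds <- rep(list(c(grid[1], grid[k])), 3)
  # candidate (lo, hi) grid pairs, ordered: keeps tie-breaks deterministic
  pair_lo <- grid[rep(seq_len(k), times = k - seq_len(k) + 1)]
  pair_hi <- grid[unlist(lapply(seq_len(k), function(i) i:k))]
  pair_rng <- pair_hi - pair_lo
  ord <- order(pair_rng, pair_lo) # tightest first, then lowest
  pair_lo <- pair_lo[ord]; pair_hi <- pair_hi[ord]; pair_rng <- pair_rng[ord]
  current_iou <- -1
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (ch in 1:3) {
      others <- setdiff(1:3, ch)
      keep <- chans[[others[1]]] >= bounds[[others[1]]][1] &
        chans[[others[1]]] <= bounds[[others[1]]][2] &
        chans[[others[2]]] >= bounds[[others[2]]][1] &
        chans[[others[2]]] <= bounds[[others[2]]][2]
      v <- chans[[ch]][keep]
      r <- ref[keep]
      cnt_ref <- tabulate(v[r] + 1L, 256)
      cnt_all <- tabulate(v + 1L, 256)
      cref <- c(0, cumsum(cnt_ref))
      call_ <- c(0, cumsum(cnt_all))
      tp <- cref[pair_hi + 2] - cref[pair_lo + 1]
      fp <- (call_[pair_hi + 2] - call_[pair_lo + 1]) - tp
      iou <- tp / (n_ref + fp)
      # candidates are pre-sorted tightest/lowest first, so the first
      # maximum realises the tie-break
      b <- which.max(iou)
      new_bounds <- c(pair_lo[b], pair_hi[b])
      if (iou[b] > current_iou + 1e-15 ||
        (iou[b] >= current_iou && !identical(new_bounds, bounds[[ch]]) &&
          diff(new_bounds) < diff(bounds[[ch]]))) {
        if (!identical(new_bounds, bounds[[ch]])) changed <- TRUE
        bounds[[ch]] <- new_bounds
        current_iou <- iou[b]
      }
    }
    if (!changed) break
  }
  list(
    iou = current_iou, bounds = bounds, method = "coordinate_ascent"
  )
}

#' Optical density of a section image
#'
#' Transmitted-light densitometry on the greyscale (luma) version of the
#' image: `OD = log10(255 / max(I, 1))`, so a pure-white pixel has OD 0
#' and OD is bounded by `log10(255)`.
#'
#' @param image A `section_image`.
#' @return Numeric matrix of per-pixel optical density.
#' @export
optical_density <- function(image) {
  stopifnot(inherits(image, "section_image"))
  od_from_luma(luma(image$pixels))
}

luma <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

od_from_luma <- function(I) log10(255 / pmax(I, 1))

#' Fixed-area measurement frame
#'
#' @param x,y Pixel coordinates of the frame centre (x = column,
#'   y = row).
#' @param area Frame area in square micrometres (default 1337).
#' @return A `measurement_frame` object.
#' @export
measurement_frame <- function(x, y, area = 1337) {
  if (!is.numeric(area) || length(area) != 1 || area <= 0) {
    stop("frame `area` must be a single positive number", call. = FALSE)
  }
  structure(list(x = x, y = y, area = area), class = "measurement_frame")
}

frame_indices <- function(frame, image) {
  d <- dim(image$pixels)
  side <- round(sqrt(frame$area) / image$pixel_size)
  if (side < 1) stop("frame smaller than one pixel", call. = FALSE)
  row0 <- floor(frame$y - side / 2) + 1
  col0 <- floor(frame$x - side / 2) + 1
  rows <- row0:(row0 + side - 1)
  cols <- col0:(col0 + side - 1)
  if (rows[1] < 1 || cols[1] < 1 || rows[side] > d[1] || cols[side] > d[2]) {
    stop("measurement frame lies outside the image", call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

#' Summed optical density of starch within a frame
#'
#' Sums the optical density of every pixel that is both inside the square
#' frame (side `round(sqrt(area) / pixel_size)` pixels, centred on the
#' anchor) and flagged as starch by the mask.
#'
#' @param image A `section_image`.
#' @param mask Logical starch mask (from [segment_starch()]).
#' @param frame A [measurement_frame()].
#' @return Summed OD (dimensionless OD x pixel, >= 0).
#' @export
starch_content <- function(image, mask, frame) {
  stopifnot(inherits(image, "section_image"), inherits(frame, "measurement_frame"))
  d <- dim(image$pixels)
  if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    stop("`mask` must be a logical matrix matching the image", call. = FALSE)
  }
  ix <- frame_indices(frame, image)
  sub_mask <- mask[ix$rows, ix$cols, drop = FALSE]
  if (!any(sub_mask)) {
    return(0)
  }
  od <- od_from_luma(luma(image$pixels[ix$rows, ix$cols, , drop = FALSE]))
  sum(od[sub_mask])
}

#' Measure starch in one ovary section
#'
#' Segments starch with the stored colour thresholds and sums optical
#' density in each of the four fixed-area frames; the ovary value is the
#' mean of the four frames.
#'
#' @param image A `section_image`.
#' @param thr A `threshold_spec`.
#' @param frames List of exactly 4 [measurement_frame()]s (override with
#'   `allow_any_frames`).
#' @param allow_any_frames Permit a frame count other than four.
#' @return A `starch_measurement`: list with `per_frame` (numeric),
#'   `ovary_value` (mean of frames), `mask_area` (total segmented area,
#'   square micrometres), `ovary_id`, `date`.
#' @export
measure_ovary <- function(image, thr, frames, allow_any_frames = FALSE) {
  stopifnot(inherits(image, "section_image"))
  if (inherits(frames, "measurement_frame")) frames <- list(frames)
  if (length(frames) != 4 && !allow_any_frames) {
    stop("exactly 4 measurement frames are expected per section",
      call. = FALSE
    )
  }
  mask <- segment_starch(image, thr)
  per_frame <- vapply(frames, function(f) starch_content(image, mask, f),
    numeric(1)
  )
  structure(
    list(
      per_frame = per_frame, ovary_value = mean(per_frame),
      mask_area = sum(mask) * image$pixel_size^2,
      ovary_id = image$ovary_id, date = image$date
    ),
    class = "starch_measurement"
  )
}

#' @export
print.starch_measurement <- function(x, ...) {
  cat(sprintf(
    "starch_measurement: ovary value %.2f OD.px (frames: %s)\n",
    x$ovary_value, paste(sprintf("%.2f", x$per_frame), collapse = ", ")
  ))
  invisible(x)
}

#' Straight transect across an ovary section
#'
#' @param x1,y1,x2,y2 Endpoint pixel coordinates.
#' @return A `transect_segment` object.
#' @export
transect_segment <- function(x1, y1, x2, y2) {
  structure(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2),
    class = "transect_segment"
  )
}

transect_length_px <- function(tr) {
  sqrt((tr$x2 - tr$x1)^2 + (tr$y2 - tr$y1)^2)
}

#' Ovary diameter along a transect
#'
#' @param transect A [transect_segment()].
#' @param pixel_size Micrometres per pixel.
#' @return Diameter in micrometres.
#' @examples
#' ovary_diameter(transect_segment(0, 0, 3, 4), pixel_size = 10)
#' @export
ovary_diameter <- function(transect, pixel_size) {
  stopifnot(inherits(transect, "transect_segment"))
  len <- transect_length_px(transect)
  if (len == 0) stop("zero-length transect", call. = FALSE)
  len * pixel_size
}

#' Count cell layers along a transect
#'
#' Cell walls stained for cellulose appear as bright peaks along a
#' cross-section profile; the number of cell layers is the number of wall
#' peaks minus one. The intensity profile is sampled at roughly one-pixel
#' steps with bilinear interpolation.
#'
#' @param image A `section_image`.
#' @param transect A [transect_segment()] inside the image.
#' @param min_peak_distance Minimum distance between wall peaks
#'   (micrometres).
#' @param peak_threshold Minimum peak height as a fraction of the
#'   profile's intensity range (0..1).
#' @return Integer number of cell layers (0 for a flat profile).
#' @export
count_cell_layers <- function(image, transect, min_peak_distance = 3,
                              peak_threshold = 0.3) {
  stopifnot(
    inherits(image, "section_image"),
    inherits(transect, "transect_segment")
  )
  d <- dim(image$pixels)
  for (pt in list(
    c(transect$x1, transect$y1),
    c(transect$x2, transect$y2)
  )) {
    if (pt[1] < 1 || pt[1] > d[2] || pt[2] < 1 || pt[2] > d[1]) {
      stop("transect endpoint outside the image", call. = FALSE)
    }
  }
  len_px <- transect_length_px(transect)
  if (len_px * image$pixel_size < 2 * min_peak_distance) {
    stop("transect shorter than twice `min_peak_distance`", call. = FALSE)
  }
  I <- luma(image$pixels)
  n <- max(2L, ceiling(len_px)) + 1L
  t <- seq(0, 1, length.out = n)
  xs <- transect$x1 + t * (transect$x2 - transect$x1)
  ys <- transect$y1 + t * (transect$y2 - transect$y1)
  profile <- bilinear_sample(I, xs, ys)
  rng <- diff(range(profile))
  if (rng == 0) {
    return(0L)
  }
  step_px <- len_px / (n - 1)
  min_dist_samples <- max(1, floor(min_peak_distance /
    (image$pixel_size * step_px)))
  pk <- pracma::findpeaks(profile,
    minpeakheight = min(profile) + peak_threshold * rng,
    minpeakdistance = min_dist_samples
  )
  n_peaks <- if (is.null(pk)) 0L else nrow(pk)
  max(0L, n_peaks - 1L)
}

bilinear_sample <- function(I, xs, ys) {
  h <- nrow(I)
  w <- ncol(I)
  x0 <- pmin(pmax(floor(xs), 1), w - 1)
  y0 <- pmin(pmax(floor(ys), 1), h - 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  i00 <- I[cbind(y0, x0)]
  i01 <- I[cbind(y0, x0 + 1)]
  i10 <- I[cbind(y0 + 1, x0)]
  i11 <- I[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}
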