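# Independent oracles and small fixture builders used across the suite.

# hourly temperature tibble starting at a fixed instant
make_temps <- function(temp_c, start = "2015-11-01") {
  tibble::tibble(
    timestamp = seq(as.POSIXct(start, tz = "UTC"),
      by = "hour",
      length.out = length(temp_c)
    ),
    temp_c = temp_c
  )
}

# literal Utah band lookup, written independently of the package's table
oracle_chill_unit <- function(t) {
  if (t < 1.5) {
    0
  } else if (t < 2.5) {
    0.5
  } else if (t < 9.2) {
    1
  } else if (t < 12.5) {
    0.5
  } else if (t < 16) {
    0
  } else if (t < 18) {
    -0.5
  } else {
    -1
  }
}

oracle_gdh <- function(t) {
  if (t < 6) 0 else if (t > 25) 25 - 4.5 else t - 4.5
}

# explicit hour-by-hour running sum
oracle_accumulate <- function(temp_c, fun) {
  out <- numeric(length(temp_c))
  s <- 0
  for (i in seq_along(temp_c)) {
    s <- s + fun(temp_c[i])
    out[i] <- s
  }
  out
}

# two-pass sum-of-squares one-way ANOVA
oracle_anova_f <- function(values, groups) {
  groups <- as.character(groups)
  m <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in unique(groups)) {
    x <- values[groups == g]
    ssb <- ssb + length(x) * (mean(x) - m)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  k <- length(unique(groups))
  n <- length(values)
  list(
    f = (ssb / (k - 1)) / (ssw / (n - k)),
    mse = ssw / (n - k), df_within = n - k
  )
}

# Duncan partition by literal pairwise R_p comparison on every ordered
# pair, then maximal all-pairs-non-significant intervals, letters in order
oracle_duncan_partition <- function(values, groups, alpha = 0.05) {
  oa <- oracle_anova_f(values, groups)
  labs <- unique(as.character(groups))
  means <- vapply(labs, function(g) mean(values[groups == g]), numeric(1))
  ns_per_group <- vapply(labs, function(g) sum(groups == g), numeric(1))
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]
  labs <- labs[ord]
  k <- length(labs)
  n_h <- k / sum(1 / ns_per_group)
  rp <- function(span) {
    stats::qtukey((1 - alpha)^(span - 1), span, oa$df_within) *
      sqrt(oa$mse / n_h)
  }
  nonsig <- function(i, j) abs(means[i] - means[j]) <= rp(abs(j - i) + 1)
  intervals <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- TRUE
      if (j > i) {
        for (a in i:(j - 1)) {
          for (b in (a + 1):j) if (!nonsig(a, b)) ok <- FALSE
        }
      }
      if (ok) intervals[[length(intervals) + 1]] <- c(i, j)
    }
  }
  maximal <- Filter(function(iv) {
    !any(vapply(intervals, function(other) {
      (other[1] < iv[1] && other[2] >= iv[2]) ||
        (other[1] <= iv[1] && other[2] > iv[2])
    }, logical(1)))
  }, intervals)
  # partition: per interval, the set of group labels sharing that letter
  lapply(maximal, function(iv) sort(labs[iv[1]:iv[2]]))
}

# letter groups of a duncan_mrt result as comparable sets of labels
letter_sets <- function(dm) {
  letts <- unique(unlist(strsplit(dm$means$letters, "")))
  out <- lapply(letts, function(l) {
    sort(as.character(dm$means$group[grepl(l, dm$means$letters,
      fixed = TRUE
    )]))
  })
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

sort_partition <- function(p) {
  p[order(vapply(p, paste, character(1), collapse = "|"))]
}

# uniform-colour test image
flat_image <- function(col, h = 20, w = 20, pixel_size = 1) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- col[ch]
  section_image(px, pixel_size)
}

# forcing-test table with constant weights per condition and date
make_tests <- function(dates, field_mean, forced_means, n = 10) {
  purrr::map_dfr(seq_along(dates), function(i) {
    tibble::tibble(
      date = as.Date(dates[i]),
      condition = rep(c("field", "forced"), each = n),
      bud_id = rep(seq_len(n), 2),
      weight_mg = c(rep(field_mean, n), rep(forced_means[i], n))
    )
  })
}
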