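#' Construct a single-channel chromatogram
#'
#' Carrier for one detector channel's sampled signal plus acquisition
#' metadata. Times must be strictly increasing and match the signal length.
#'
#' @param times Sample times in minutes, strictly increasing, length >= 2.
#' @param signal Detector response, same length as `times`.
#' @param wavelength Detection wavelength, nm.
#' @param injection_volume Injected volume, uL.
#' @param sample_id Identifier for the acquisition.
#' @param truth Optional list of per-analyte ground truth (simulator only).
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(times, signal, wavelength = NA_real_,
                         injection_volume = NA_real_,
                         sample_id = "sample", truth = NULL) {
  if (length(times) != length(signal) || length(times) < 2L)
    stop("times and signal must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 wavelength = wavelength,
                 injection_volume = injection_volume,
                 sample_id = sample_id, truth = truth),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s | %s nm | %d points | %.1f-%.1f min\n",
              x$sample_id, format(x$wavelength), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

# Baseline estimate: wide running median, robust to peaks narrower than the
# window and able to follow slow linear drift.
estimate_baseline <- function(chrom, halfwidth = 1) {
  n <- length(chrom$times)
  dt <- stats::median(diff(chrom$times))
  k <- max(3L, as.integer(2 * halfwidth / dt) %/% 2L * 2L + 1L)
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  stats::runmed(chrom$signal, k, endrule = "median")
}

# s.d. of the baseline-corrected signal over a peak-free window (minutes).
estimate_noise <- function(chrom, noise_window = c(0, 0.5),
                           corrected = NULL) {
  idx <- chrom$times >= noise_window[1] & chrom$times <= noise_window[2]
  if (sum(idx) < 3L) stop("noise window contains fewer than 3 samples")
  y <- if (is.null(corrected)) chrom$signal else corrected
  stats::sd(y[idx])
}

#' Detect chromatographic peaks
#'
#' Subtracts a running-median baseline, estimates noise from a peak-free
#' window, and returns every local maximum that exceeds
#' `min_snr x noise` and is wider than `min_width` at half height.
#' Shoulder maxima that are not separated from a taller neighbour by a real
#' valley (a dip of at least three noise s.d.) are merged into it. Peak
#' bounds are placed at the enclosing baseline crossings, or at the valley
#' between overlapping neighbours.
#'
#' A flat (or peak-free) trace yields an empty table, not an error.
#'
#' @param chrom A [chromatogram()].
#' @param min_snr Minimum apex signal-to-noise ratio; must be positive.
#'   The default of 10 matches the quantification-limit criterion: apexes
#'   below it are indistinguishable from baseline excursions and, worse,
#'   a spurious noise apex next to a real peak steals part of its tail.
#' @param min_width Minimum half-height width in minutes.
#' @param noise_window Peak-free time interval (minutes) used for the noise
#'   estimate.
#' @param baseline_halfwidth Half-width (minutes) of the running-median
#'   baseline window.
#' @return A data.frame of class `peak_table`, one row per peak sorted by
#'   apex time, with columns `apex_time`, `area` (response x seconds),
#'   `height`, `width_half` (minutes), `start`, `end`, `snr`.
#' @export
detect_peaks <- function(chrom, min_snr = 10, min_width = 0.02,
                         noise_window = c(0, 0.5),
                         baseline_halfwidth = 1) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (min_snr <= 0) stop("min_snr must be > 0")
  t <- chrom$times
  base <- estimate_baseline(chrom, baseline_halfwidth)
  yc <- chrom$signal - base
  noise <- estimate_noise(chrom, noise_window, corrected = yc)
  ymax <- max(yc)
  thr <- max(min_snr * noise, ymax * 1e-9)
  if (ymax <= thr || ymax <= 0) return(empty_peak_table())

  # light smoothing so sample-level noise does not split an apex
  ys <- stats::runmed(yc, 5L, endrule = "median")
  n <- length(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] >= ys[1:(n - 2)] &
                     ys[2:(n - 1)] > ys[3:n], FALSE) & yc > thr
  cand <- which(is_max)
  if (!length(cand)) return(empty_peak_table())

  # merge shoulders: keep a candidate only if a genuine valley separates it
  # from every taller accepted apex
  cand <- cand[order(yc[cand], decreasing = TRUE)]
  accepted <- integer(0)
  dip <- max(3 * noise, ymax * 1e-6)
  for (i in cand) {
    keep <- TRUE
    for (j in accepted) {
      rng <- if (i < j) i:j else j:i
      if (min(yc[rng]) > yc[i] - dip) { keep <- FALSE; break }
    }
    if (keep) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)

  rows <- lapply(seq_along(accepted), function(k) {
    i <- accepted[k]
    h <- yc[i]
    half <- h / 2
    lo <- max(2 * noise, h * 1e-4)     # baseline-crossing threshold
    left_lim <- if (k > 1) accepted[k - 1] else 1L
    right_lim <- if (k < length(accepted)) accepted[k + 1] else n

    li <- i
    while (li > left_lim && yc[li] > lo) li <- li - 1L
    left_is_crossing <- li > left_lim
    start <- if (left_is_crossing) t[li] else {
      rng <- left_lim:i                 # overlapping: valley minimum
      t[rng[which.min(yc[rng])]]
    }
    ri <- i
    while (ri < right_lim && yc[ri] > lo) ri <- ri + 1L
    right_is_crossing <- ri < right_lim
    end <- if (right_is_crossing) t[ri] else {
      rng <- i:right_lim
      t[rng[which.min(yc[rng])]]
    }
    # final bounds: at least apex +/- 3 half-widths (about +/- 7 sigma for
    # a Gaussian, stable against noise in the crossing search), extended
    # past a baseline crossing but never past a valley shared with an
    # overlapping neighbour
    wh <- half_width(t, yc, i, half)
    if (is.finite(wh)) {
      if (left_is_crossing)
        start <- max(min(start, t[i] - 3 * wh), t[1],
                     if (k > 1) (start + t[accepted[k - 1]]) / 2 else -Inf)
      if (right_is_crossing)
        end <- min(max(end, t[i] + 3 * wh), t[n],
                   if (k < length(accepted)) (end + t[accepted[k + 1]]) / 2
                   else Inf)
    }
    data.frame(apex_time = t[i], area = NA_real_, height = h,
               width_half = wh, start = start, end = end,
               snr = if (noise > 0) h / noise else Inf)
  })
  pk <- do.call(rbind, rows)
  pk <- pk[!is.na(pk$width_half) & pk$width_half >= min_width, ,
           drop = FALSE]
  if (!nrow(pk)) return(empty_peak_table())
  # integrate on the baseline-corrected trace: the running-median baseline
  # is a far less noisy anchor for the chord than single raw samples
  chrom_corr <- chromatogram(t, yc, wavelength = chrom$wavelength,
                             injection_volume = chrom$injection_volume,
                             sample_id = chrom$sample_id)
  for (r in seq_len(nrow(pk)))
    pk$area[r] <- integrate_peak(chrom_corr, c(pk$start[r], pk$end[r]))
  pk <- pk[order(pk$apex_time), , drop = FALSE]
  rownames(pk) <- NULL
  class(pk) <- c("peak_table", "data.frame")
  pk
}

empty_peak_table <- function() {
  pk <- data.frame(apex_time = numeric(0), area = numeric(0),
                   height = numeric(0), width_half = numeric(0),
                   start = numeric(0), end = numeric(0), snr = numeric(0))
  class(pk) <- c("peak_table", "data.frame")
  pk
}

# Interpolated full width at half the apex height.
half_width <- function(t, y, apex_idx, half) {
  n <- length(y)
  li <- apex_idx
  while (li > 1L && y[li] > half) li <- li - 1L
  ri <- apex_idx
  while (ri < n && y[ri] > half) ri <- ri + 1L
  if (y[li] > half || y[ri] > half) return(NA_real_)
  xl <- interp_crossing(t[li], y[li], t[li + 1L], y[li + 1L], half)
  xr <- interp_crossing(t[ri - 1L], y[ri - 1L], t[ri], y[ri], half)
  xr - xl
}

interp_crossing <- function(t1, y1, t2, y2, level) {
  if (y2 == y1) return((t1 + t2) / 2)
  t1 + (level - y1) / (y2 - y1) * (t2 - t1)
}

#' Integrate a peak over given bounds with chord baseline correction
#'
#' Trapezoidal integral of the signal minus the straight chord joining the
#' baseline levels at the two bounds, converted to response x seconds.
#' Each chord endpoint is the median of the signal within
#' `endpoint_halfwidth` minutes of its bound, so the baseline is not
#' anchored on a single noisy sample (set `endpoint_halfwidth = 0` for the
#' raw interpolated endpoint values). A negative result (possible on pure
#' noise) is clipped to zero and flagged via the `"clipped"` attribute.
#'
#' @param chrom A [chromatogram()].
#' @param bounds Numeric length-2 vector `c(start, end)` in minutes,
#'   `start < end`, within the acquired time range.
#' @param endpoint_halfwidth Half-width (minutes) of the window used to
#'   estimate the baseline level at each bound.
#' @return Peak area in response x seconds.
#' @export
integrate_peak <- function(chrom, bounds, endpoint_halfwidth = 0.1) {
  stopifnot(inherits(chrom, "chromatogram"), length(bounds) == 2L)
  if (bounds[1] >= bounds[2]) stop("inverted bounds: start must be < end")
  t <- chrom$times
  if (bounds[1] < t[1] || bounds[2] > t[length(t)])
    stop("bounds outside acquired time range")
  inside <- t > bounds[1] & t < bounds[2]
  y_ends <- vapply(bounds, function(b) {
    w <- abs(t - b) <= endpoint_halfwidth
    if (sum(w) >= 3L) stats::median(chrom$signal[w])
    else stats::approx(t, chrom$signal, xout = b)$y
  }, numeric(1))
  tt <- c(bounds[1], t[inside], bounds[2])
  yy <- c(y_ends[1], chrom$signal[inside], y_ends[2])
  chord <- y_ends[1] + (tt - bounds[1]) / diff(bounds) * diff(y_ends)
  yb <- yy - chord
  area_min <- sum(diff(tt) * (yb[-1] + yb[-length(yb)]) / 2)
  area <- area_min * 60
  if (area < 0) {
    area <- 0
    attr(area, "clipped") <- TRUE
  }
  area
}

#' Signal-to-noise ratio of a peak
#'
#' Peak height divided by the standard deviation of the signal inside a
#' peak-free noise window. A degenerate noiseless window is an error.
#'
#' @param chrom A [chromatogram()].
#' @param peak One row of a [detect_peaks()] table (or any list with a
#'   `height` element).
#' @param noise_window Peak-free time interval, minutes.
#' @return Dimensionless S/N.
#' @export
signal_to_noise <- function(chrom, peak, noise_window = c(0, 0.5)) {
  noise <- estimate_noise(chrom, noise_window)
  if (noise == 0) stop("noise s.d. is zero in the given window")
  peak$height / noise
}

#' Column efficiency as theoretical plate number
#'
#' Half-height formula `N = 5.54 (t_R / W_1/2)^2`, the usual pharmacopoeial
#' variant. Vectorised over the rows of a peak table.
#'
#' @param peak A peak-table row (or whole table); needs `apex_time` and
#'   `width_half`.
#' @return Plate number(s), dimensionless.
#' @export
theoretical_plates <- function(peak) {
  if (any(peak$width_half <= 0)) stop("width_half must be > 0")
  5.54 * (peak$apex_time / peak$width_half)^2
}

#' Resolution between two adjacent peaks
#'
#' `Rs = 2 (t2 - t1) / (w1 + w2)` with base widths taken as
#' `1.699 x width_half` (exact for Gaussian peaks). Co-eluting peaks give 0.
#'
#' @param p1,p2 Peak-table rows with `p1$apex_time < p2$apex_time` (equal
#'   apexes allowed, returning 0).
#' @return Dimensionless resolution.
#' @export
resolution <- function(p1, p2) {
  if (p1$apex_time > p2$apex_time)
    stop("p1 must elute before p2")
  if (p1$apex_time == p2$apex_time) return(0)
  w1 <- 1.699 * p1$width_half
  w2 <- 1.699 * p2$width_half
  2 * (p2$apex_time - p1$apex_time) / (w1 + w2)
}

#' Write a peak table to CSV
#'
#' Columns: `sample_id,wavelength,apex_min,area,height,width_half_min,snr`.
#'
#' @param peaks A `peak_table`.
#' @param chrom The source [chromatogram()] (for id and wavelength).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, chrom, path) {
  out <- data.frame(sample_id = chrom$sample_id,
                    wavelength = chrom$wavelength,
                    apex_min = peaks$apex_time, area = peaks$area,
                    height = peaks$height,
                    width_half_min = peaks$width_half, snr = peaks$snr)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
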