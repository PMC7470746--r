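#' Locate local extrema of a sampled signal
#'
#' Strict neighbor comparison with plateau handling: a run of equal values
#' strictly above (below) both flanking runs is a local maximum (minimum),
#' and its center index represents it. Boundary runs are never extrema.
#'
#' @param y Numeric signal.
#' @param type `"max"` or `"min"`.
#' @return Integer vector of extremum indices (possibly empty).
#' @keywords internal
local_extrema <- function(y, type = c("max", "min")) {
  type <- match.arg(type)
  r <- rle(y)
  n_runs <- length(r$values)
  if (n_runs < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- integer(0)
  for (j in 2:(n_runs - 1)) {
    v <- r$values[j]
    is_ext <- if (type == "max") {
      v > r$values[j - 1] && v > r$values[j + 1]
    } else {
      v < r$values[j - 1] && v < r$values[j + 1]
    }
    if (is_ext) {
      idx <- c(idx, starts[j] + (r$lengths[j] - 1) %/% 2)
    }
  }
  idx
}

#' Pick the analyte peak in a retention-time window
#'
#' Scans the half-open window `[window[1], window[2])` for the global
#' maximum of the signal that is also a local maximum of the trace (the
#' derivatized-glutathione analysis uses 6.5-8 min, where the analyte elutes
#' near 7 min). Returns `NA` (no-peak flag) when the window maximum is not a
#' local maximum, e.g. a flat trace or a maximum sitting on the window edge.
#' Ties between equal-height maxima resolve to the earliest retention time.
#'
#' @param chrom A chromatogram data frame with columns `rt_min` (strictly
#'   increasing) and `signal`.
#' @param window Length-2 numeric, min; half-open `[lo, hi)`.
#' @return Integer index into `chrom`, or `NA_integer_` when no peak is
#'   found.
#' @examples
#' ch <- gen_chromatogram(chromatogram_spec())
#' pick_peak(ch)
#' @export
pick_peak <- function(chrom, window = c(6.5, 8)) {
  check_columns(chrom, c("rt_min", "signal"), "chromatogram")
  if (nrow(chrom) < 3 || any(diff(chrom$rt_min) <= 0)) {
    abort("chromatogram needs >= 3 points with strictly increasing rt_min")
  }
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("window must be an increasing interval")
  }
  in_win <- which(chrom$rt_min >= window[1] & chrom$rt_min < window[2])
  if (length(in_win) < 3) {
    abort("window contains fewer than 3 samples")
  }
  imax <- in_win[which.max(chrom$signal[in_win])]
  if (imax == in_win[1] || imax == in_win[length(in_win)]) {
    return(NA_integer_)
  }
  maxima <- local_extrema(chrom$signal, "max")
  # the plateau-center convention may shift the representative index by a
  # few samples; accept any local maximum whose plateau contains imax
  if (!imax %in% maxima) {
    if (!(chrom$signal[imax] > min(chrom$signal[in_win]) &&
          any(maxima %in% in_win &
              chrom$signal[maxima] == chrom$signal[imax]))) {
      return(NA_integer_)
    }
    imax <- maxima[maxima %in% in_win &
                     chrom$signal[maxima] == chrom$signal[imax]][1]
  }
  imax
}

#' Local-minima linear baseline correction around a peak
#'
#' Finds the nearest local minimum on each side of the peak, draws the
#' straight line connecting the two (y = m x + b on the retention-time
#' axis), and subtracts it from the signal over the enclosed segment. The
#' corrected value at both endpoints is exactly zero. When a side has no
#' local minimum before the data boundary, the boundary point is used and a
#' warning flag recorded.
#'
#' @param chrom A chromatogram data frame (`rt_min`, `signal`).
#' @param peak_index Index of the peak, e.g. from [pick_peak()].
#' @return A list of class `hplc_baseline` with elements `segment` (tibble:
#'   `rt_min`, `signal`, `corrected`), `baseline_slope`,
#'   `baseline_intercept`, `left_min_rt`, `right_min_rt`, `peak_rt`, and
#'   `flags` (character vector, possibly empty).
#' @export
correct_baseline <- function(chrom, peak_index) {
  check_columns(chrom, c("rt_min", "signal"), "chromatogram")
  if (is.na(peak_index)) abort("peak_index is NA (no peak found upstream)")
  n <- nrow(chrom)
  if (peak_index < 1 || peak_index > n) abort("peak_index out of range")
  minima <- local_extrema(chrom$signal, "min")
  flags <- character(0)
  left <- minima[minima < peak_index]
  if (length(left)) {
    left <- max(left)
  } else {
    left <- 1L
    flags <- c(flags, "left_boundary")
  }
  right <- minima[minima > peak_index]
  if (length(right)) {
    right <- min(right)
  } else {
    right <- n
    flags <- c(flags, "right_boundary")
  }
  x1 <- chrom$rt_min[left]; y1 <- chrom$signal[left]
  x2 <- chrom$rt_min[right]; y2 <- chrom$signal[right]
  m <- (y2 - y1) / (x2 - x1)
  b <- y1 - m * x1
  seg <- chrom[left:right, c("rt_min", "signal")]
  seg <- tibble(rt_min = seg$rt_min, signal = seg$signal,
                corrected = seg$signal - (m * seg$rt_min + b))
  if (any(seg$corrected < 0)) flags <- c(flags, "negative_corrected")
  structure(list(segment = seg, baseline_slope = m, baseline_intercept = b,
                 left_min_rt = x1, right_min_rt = x2,
                 peak_rt = chrom$rt_min[peak_index], flags = flags),
            class = "hplc_baseline")
}

#' Trapezoidal peak area
#'
#' Integrates the baseline-corrected signal over the segment by the
#' trapezoid rule. Negative corrected samples are kept (they cancel in the
#' integral); clipping is left to the caller.
#'
#' @param segment A data frame with `rt_min` and `corrected` columns (as in
#'   the `segment` element of [correct_baseline()]), or an `hplc_baseline`
#'   object.
#' @return Area, signal units x min.
#' @export
integrate_area <- function(segment) {
  if (inherits(segment, "hplc_baseline")) segment <- segment$segment
  check_columns(segment, c("rt_min", "corrected"), "segment")
  if (nrow(segment) < 2) abort("segment needs >= 2 points")
  pracma::trapz(segment$rt_min, segment$corrected)
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of detector response against known
#' concentration, response = slope * conc + intercept, over all calibration
#' points (replicates included). The validity range is the span of the
#' calibration concentrations; for the glutathione HPLC assay the working
#' dynamic range is 0.03-1 uM.
#'
#' @param points A data frame with columns `conc` (uM) and `response` (peak
#'   area or OD). At least 2 distinct concentrations are required.
#' @param valid_range Optional length-2 override of the validity range, uM.
#' @param detection_floor Optional response-level detection floor.
#' @return An object of class `standard_curve`: list with `model` (the lm
#'   fit), `slope`, `intercept`, `valid_range`, `detection_floor`, `points`.
#' @examples
#' fit_standard_curve(data.frame(conc = c(0.03, 0.1, 0.3, 1),
#'                               response = c(0.06, 0.2, 0.6, 2)))
#' @export
fit_standard_curve <- function(points, valid_range = NULL,
                               detection_floor = NULL) {
  check_columns(points, c("conc", "response"), "calibration points")
  if (length(unique(points$conc)) < 2) {
    abort("calibration requires >= 2 distinct concentrations")
  }
  fit <- lm(response ~ conc, data = points)
  if (is.null(valid_range)) valid_range <- range(points$conc)
  structure(list(model = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 valid_range = valid_range,
                 detection_floor = detection_floor,
                 points = as_tibble(points)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>\n")
  cat(sprintf("  response = %.6g * conc + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  valid range: %.4g to %.4g uM (%d calibration points)\n",
              x$valid_range[1], x$valid_range[2], nrow(x$points)))
  if (!is.null(x$detection_floor)) {
    cat(sprintf("  detection floor: %.4g (response units)\n",
                x$detection_floor))
  }
  invisible(x)
}

#' @describeIn fit_standard_curve Coefficient table of the fitted line.
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  cs <- coef(summary(x$model))
  tibble(term = rownames(cs), estimate = unname(cs[, 1]),
         std.error = unname(cs[, 2]), statistic = unname(cs[, 3]),
         p.value = unname(cs[, 4]))
}

#' @describeIn fit_standard_curve One-row fit summary.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         n = nrow(x$points),
         range_min = x$valid_range[1], range_max = x$valid_range[2],
         detection_floor = x$detection_floor %||% NA_real_)
}

#' Back-calculate concentration from a response via a standard curve
#'
#' Inverts the linear calibration: conc = (response - intercept) / slope.
#' Estimates outside the curve's validity range keep their point estimate
#' but carry a `below_range` or `above_range` flag.
#'
#' @param response Measured response (peak area or OD); vectorized.
#' @param curve A [fit_standard_curve()] object.
#' @return A tibble with columns `response`, `conc_uM`, `flag`
#'   (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
quantify <- function(response, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) abort("calibration slope is zero")
  conc <- (response - curve$intercept) / curve$slope
  flag <- dplyr::case_when(
    conc < curve$valid_range[1] ~ "below_range",
    conc > curve$valid_range[2] ~ "above_range",
    TRUE ~ "ok"
  )
  tibble(response = response, conc_uM = conc, flag = flag)
}

#' Quantify one chromatogram end to end
#'
#' Convenience chain: [pick_peak()] in the analyte window, local-minima
#' baseline correction, trapezoidal area, back-calculation through the
#' standard curve.
#'
#' @param chrom A chromatogram data frame (`rt_min`, `signal`).
#' @param curve A [fit_standard_curve()] object calibrated on peak areas.
#' @param window Retention-time window, min (half-open).
#' @return A one-row tibble: `peak_rt`, `area`, `conc_uM`, `flag`.
#' @export
quantify_chromatogram <- function(chrom, curve, window = c(6.5, 8)) {
  idx <- pick_peak(chrom, window)
  if (is.na(idx)) {
    return(tibble(peak_rt = NA_real_, area = NA_real_, conc_uM = NA_real_,
                  flag = "no_peak"))
  }
  bl <- correct_baseline(chrom, idx)
  area <- integrate_area(bl)
  q <- quantify(area, curve)
  tibble(peak_rt = bl$peak_rt, area = area, conc_uM = q$conc_uM,
         flag = q$flag)
}

#' Internal-standard (isotope-dilution) quantification
#'
#' Mass-spectrometric quantification by comparing the analyte peak area to
#' that of a co-injected labelled internal standard:
#' conc = (area_analyte / area_is) * is_amount / sample_volume. With the
#' amount in pmole and the volume in uL the result is in uM
#' (pmole/uL = umol/L).
#'
#' @param area_analyte Analyte peak area; >= 0.
#' @param area_is Internal-standard peak area; must be > 0.
#' @param is_amount Amount of internal standard spiked in, pmole.
#' @param sample_volume Sample volume the standard was spiked into, uL.
#' @return Concentration, uM.
#' @examples
#' internal_standard_quantify(1, 1, is_amount = 50, sample_volume = 30)
#' @export
internal_standard_quantify <- function(area_analyte, area_is, is_amount,
                                       sample_volume) {
  if (any(area_is <= 0)) abort("internal-standard area must be > 0")
  if (any(sample_volume <= 0) || any(is_amount < 0)) {
    abort("is_amount must be >= 0 and sample_volume > 0")
  }
  if (any(area_analyte < 0)) abort("analyte area must be >= 0")
  (area_analyte / area_is) * is_amount / sample_volume
}
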