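test_that("peak picking finds the analyte and flags peakless windows", {
  ch <- gen_chromatogram(chromatogram_spec(peaks = data.frame(
    rt_min = 7, amplitude = 50, width_sigma = 0.05)))
  idx <- pick_peak(ch)
  expect_equal(ch$rt_min[idx], 7, tolerance = 0.006)
  # flat zero trace: no local maximum
  flat <- tibble::tibble(rt_min = seq(6, 9, by = 0.01), signal = 0)
  expect_true(is.na(pick_peak(flat)))
  # two peaks in window: the taller (earlier) one wins
  two <- gen_chromatogram(chromatogram_spec(peaks = data.frame(
    rt_min = c(6.8, 7.5), amplitude = c(90, 40), width_sigma = c(0.05, 0.05))))
  expect_equal(two$rt_min[pick_peak(two)], 6.8, tolerance = 0.006)
  # monotone ramp: window max sits on the edge
  ramp <- tibble::tibble(rt_min = seq(6, 9, by = 0.01),
                         signal = seq(6, 9, by = 0.01))
  expect_true(is.na(pick_peak(ramp)))
  expect_error(pick_peak(ch, window = c(8, 6.5)), "increasing")
  expect_error(pick_peak(ch, window = c(1, 2)), "3 samples")
})

test_that("plateau maxima are handled deterministically", {
  y <- c(0, 1, 2, 3, 3, 3, 2, 1, 0)
  rt <- seq(6.6, 7.4, by = 0.1)
  ch <- tibble::tibble(rt_min = rt, signal = y)
  idx <- pick_peak(ch)
  expect_false(is.na(idx))
  expect_equal(ch$signal[idx], 3)
})

test_that("baseline correction connects flanking local minima exactly", {
  # Gaussian on a linear ramp: the line through the flanking minima is the
  # ramp itself, so correction recovers the closed-form Gaussian area
  spec <- chromatogram_spec(peaks = data.frame(rt_min = 7, amplitude = 60,
                                               width_sigma = 0.05),
                            baseline_slope = 5, baseline_intercept = 10,
                            sampling_interval = 0.002)
  ch <- gen_chromatogram(spec)
  idx <- pick_peak(ch)
  bl <- correct_baseline(ch, idx)
  expect_equal(integrate_area(bl), 60 * 0.05 * sqrt(2 * pi),
               tolerance = 0.02)
  # corrected endpoints are exactly zero
  expect_equal(bl$segment$corrected[1], 0)
  expect_equal(tail(bl$segment$corrected, 1), 0)
  expect_true(bl$left_min_rt < bl$peak_rt & bl$peak_rt < bl$right_min_rt)
})

test_that("zero-baseline Gaussian is returned unchanged by correction", {
  ch <- gen_chromatogram(chromatogram_spec(peaks = data.frame(
    rt_min = 7, amplitude = 40, width_sigma = 0.05)))
  bl <- correct_baseline(ch, pick_peak(ch))
  inside <- abs(bl$segment$rt_min - 7) < 0.15
  expect_equal(bl$segment$corrected[inside], bl$segment$signal[inside],
               tolerance = 1e-6)
})

test_that("missing flanking minima fall back to the data boundary with a flag", {
  # half Gaussian: no local minimum to the left of the peak
  rt <- seq(6.9, 8, by = 0.01)
  ch <- tibble::tibble(rt_min = rt,
                       signal = exp(-(rt - 7)^2 / (2 * 0.05^2)))
  idx <- pick_peak(ch, window = c(6.9, 8))
  bl <- correct_baseline(ch, idx)
  expect_true("left_boundary" %in% bl$flags)
  expect_equal(bl$left_min_rt, 6.9)
  expect_error(correct_baseline(ch, NA_integer_), "no peak")
})

test_that("trapezoidal area matches simple closed forms", {
  zero <- tibble::tibble(rt_min = 0:5, corrected = 0)
  expect_equal(integrate_area(zero), 0)
  rect <- tibble::tibble(rt_min = c(0, 1), corrected = c(1, 1))
  expect_equal(integrate_area(rect), 1)
  rt <- seq(-1, 1, by = 1e-4)
  gauss <- tibble::tibble(rt_min = rt,
                          corrected = exp(-rt^2 / (2 * 0.1^2)))
  expect_equal(integrate_area(gauss), 0.1 * sqrt(2 * pi), tolerance = 1e-3)
  expect_error(integrate_area(rect[1, ]), ">= 2")
})

test_that("standard-curve fitting is ordinary least squares on all points", {
  pts <- data.frame(conc = c(0.03, 0.1, 0.3, 1), response = NA)
  pts$response <- 2 * pts$conc
  curve <- fit_standard_curve(pts)
  expect_equal(curve$slope, 2)
  expect_equal(curve$intercept, 0, tolerance = 1e-12)
  expect_equal(curve$valid_range, c(0.03, 1))
  # replicates at a concentration all enter the fit
  dup <- rbind(pts, data.frame(conc = 0.3, response = 0.7))
  curve2 <- fit_standard_curve(dup)
  expect_equal(curve2$slope, unname(coef(lm(response ~ conc, dup))[2]))
  expect_error(fit_standard_curve(data.frame(conc = c(1, 1),
                                             response = c(1, 2))),
               "distinct")
  # summary.lm warns on an exactly collinear fit; the estimates are exact
  td <- suppressWarnings(tidy(curve))
  expect_equal(td$estimate[td$term == "conc"], 2)
  expect_gt(suppressWarnings(glance(curve))$r.squared, 0.999)
})

test_that("back-calculation inverts the curve and flags the dynamic range", {
  curve <- fit_standard_curve(data.frame(conc = c(0.03, 0.1, 0.3, 1),
                                         response = c(0.06, 0.2, 0.6, 2)))
  q <- quantify(c(curve$intercept, 0.4, 4), curve)
  expect_equal(q$conc_uM, c(0, 0.2, 2), tolerance = 1e-9)
  expect_equal(q$flag, c("below_range", "ok", "above_range"))
  # identity on calibration points
  back <- quantify(curve$points$response, curve)
  expect_equal(back$conc_uM, curve$points$conc, tolerance = 1e-9)
  zero <- curve; zero$slope <- 0
  expect_error(quantify(1, zero), "slope")
})

test_that("end-to-end spike recovery is within 2% at zero noise", {
  # calibration: chromatograms whose peak amplitude is proportional to
  # concentration, quantified exactly like samples
  area_of <- function(conc) {
    ch <- gen_chromatogram(chromatogram_spec(peaks = data.frame(
      rt_min = 7, amplitude = 100 * conc, width_sigma = 0.05),
      baseline_slope = 2, baseline_intercept = 5))
    integrate_area(correct_baseline(ch, pick_peak(ch)))
  }
  concs <- c(0.03, 0.1, 0.3, 1)
  curve <- fit_standard_curve(data.frame(conc = concs,
                                         response = vapply(concs, area_of,
                                                           numeric(1))))
  spike <- 0.42
  ch <- gen_chromatogram(chromatogram_spec(peaks = data.frame(
    rt_min = 7.05, amplitude = 100 * spike, width_sigma = 0.05),
    baseline_slope = 2, baseline_intercept = 5))
  q <- quantify_chromatogram(ch, curve)
  expect_equal(q$conc_uM, spike, tolerance = 0.02)
  expect_equal(q$flag, "ok")
  # flat sample propagates the no-peak flag
  flat <- tibble::tibble(rt_min = seq(6, 9, 0.01), signal = 1)
  expect_equal(quantify_chromatogram(flat, curve)$flag, "no_peak")
})

test_that("recovery degrades monotonically but stays usable under noise", {
  area_of <- function(conc, sd) {
    ch <- gen_chromatogram(chromatogram_spec(peaks = data.frame(
      rt_min = 7, amplitude = 100 * conc, width_sigma = 0.05)),
      noise_spec(additive_sd = sd, seed = 5))
    integrate_area(correct_baseline(ch, pick_peak(ch)))
  }
  concs <- c(0.1, 0.3, 1)
  errs <- vapply(c(0, 0.5), function(sd) {
    curve <- fit_standard_curve(data.frame(
      conc = concs, response = vapply(concs, area_of, numeric(1), sd = sd)))
    abs(quantify(area_of(0.5, sd), curve)$conc_uM - 0.5) / 0.5
  }, numeric(1))
  expect_lte(errs[1], errs[2] + 1e-9)
  expect_lt(errs[2], 0.25)
})

test_that("internal-standard quantification follows the area-ratio formula", {
  expect_equal(internal_standard_quantify(0, 1, 50, 30), 0)
  # equal areas with 50 pmole in 30 uL -> 1.667 uM
  expect_equal(internal_standard_quantify(1, 1, 50, 30), 5 / 3,
               tolerance = 1e-9)
  expect_equal(internal_standard_quantify(0.5, 1, 50, 30),
               internal_standard_quantify(1, 1, 50, 30) / 2)
  expect_error(internal_standard_quantify(1, 0, 50, 30), "internal-standard")
})
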