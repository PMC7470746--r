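test_that("all generators are bit-reproducible under a fixed seed", {
  p <- study_params()
  n <- noise_spec(relative_sd = 0.05, additive_sd = 0.5, seed = 42)
  expect_identical(gen_chemostat_series(p, duration = 20, step = 1, noise = n),
                   gen_chemostat_series(p, duration = 20, step = 1, noise = n))
  expect_identical(gen_chromatogram(chromatogram_spec(), n),
                   gen_chromatogram(chromatogram_spec(), n))
  expect_identical(gen_bioassay_plate(noise = n),
                   gen_bioassay_plate(noise = n))
  expect_identical(gen_competition(p, 0.5, 10, noise = n),
                   gen_competition(p, 0.5, 10, noise = n))
  expect_identical(gen_fluorescence_series(noise = n),
                   gen_fluorescence_series(noise = n))
  # and the caller's RNG stream is not consumed
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(gen_bioassay_plate(noise = n)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noise spec validates its fields", {
  expect_error(noise_spec(relative_sd = -0.1), ">= 0")
  expect_error(noise_spec(additive_sd = -1), ">= 0")
})

test_that("noise-free chemostat reaches the nutrient-yield steady state", {
  p <- study_params()
  s <- gen_chemostat_series(p, reservoir_conc = 21, duration = 400, step = 1,
                            yield_cells_per_uM = 7e6 / 21)
  # closed form: N* = Y (L_res - L*), L* = K dil / (gmax - dil)
  L_star <- 1 * p$dil / (0.45 - p$dil)
  N_star <- (7e6 / 21) * (21 - L_star)
  expect_equal(tail(s$live_per_ml, 1), N_star, tolerance = 1e-3)
  # the study's target density, ~7e6 cells/mL
  expect_equal(tail(s$live_per_ml, 1), 7e6, tolerance = 0.02)
  # metabolite plateau r N* / dil
  expect_equal(tail(s$metabolite_fmole_per_ml, 1), p$r * N_star / p$dil,
               tolerance = 1e-3)
})

test_that("metabolite stays at zero when nothing is released", {
  p <- ecology_params(r = 0, g = log(2) / 8)
  s <- gen_chemostat_series(p, duration = 50, step = 1)
  expect_true(all(s$metabolite_fmole_per_ml == 0))
})

test_that("metabolite plateau matches the closed-form r N / dil example", {
  # r = 0.02, dil = ln2/8, live steady state 3e6 -> plateau ~6.93e5 fmole/mL
  p <- ecology_params(r = 0.02, g = log(2) / 8)
  s <- gen_chemostat_series(p, reservoir_conc = 9, duration = 400, step = 1,
                            yield_cells_per_uM = 3e6 / 9, gmax_releaser = 2,
                            K_lys = 0.01)
  expect_equal(tail(s$metabolite_fmole_per_ml, 1), 6.93e5, tolerance = 5e-3)
})

test_that("dead cells accumulate under a death fraction and wash out", {
  p <- study_params()
  s <- gen_chemostat_series(p, duration = 400, step = 1, death_rate = 0.01)
  # steady state: D* = death * N* / dil
  expect_equal(tail(s$dead_per_ml, 1),
               0.01 * tail(s$live_per_ml, 1) / p$dil, tolerance = 1e-3)
  s0 <- gen_chemostat_series(p, duration = 50, step = 1)
  expect_true(all(s0$dead_per_ml == 0))
})

test_that("chemostat generator rejects non-positive step and duration", {
  p <- study_params()
  expect_error(gen_chemostat_series(p, duration = 0), "positive")
  expect_error(gen_chemostat_series(p, duration = 10, step = -1), "positive")
})

test_that("chromatogram generator reproduces its closed forms", {
  # no peaks, zero noise, zero baseline: all-zero trace
  flat <- gen_chromatogram(chromatogram_spec(peaks = data.frame(
    rt_min = numeric(0), amplitude = numeric(0), width_sigma = numeric(0))))
  expect_true(all(flat$signal == 0))
  # single Gaussian: numeric integral equals A sigma sqrt(2 pi) within 0.1%
  spec <- chromatogram_spec(peaks = data.frame(rt_min = 7, amplitude = 80,
                                               width_sigma = 0.06))
  ch <- gen_chromatogram(spec)
  expect_equal(pracma::trapz(ch$rt_min, ch$signal),
               80 * 0.06 * sqrt(2 * pi), tolerance = 1e-3)
  # strictly increasing time axis
  expect_true(all(diff(ch$rt_min) > 0))
})

test_that("chromatogram spec validates geometry", {
  expect_error(chromatogram_spec(time_range = c(8, 6)), "increasing")
  expect_error(chromatogram_spec(sampling_interval = 0), "sampling_interval")
  expect_error(
    chromatogram_spec(peaks = data.frame(rt_min = 7, amplitude = 1,
                                         width_sigma = 0.5),
                      time_range = c(6.5, 7.5)),
    "4 sigma")
})

test_that("bioassay plate embodies blank, saturation and the GS-SG factor", {
  plate <- gen_bioassay_plate(curve_slope = 0.2, blank_od = 0.02,
                              saturation_od = 0.6,
                              concs = c(0, 0.5, 1), replicates = 1)
  blanks <- plate$od600[plate$conc_uM == 0]
  expect_true(all(blanks == 0.02))
  gsh <- plate[plate$compound == "GSH" & plate$conc_uM == 0.5, ]
  gssg <- plate[plate$compound == "GSSG" & plate$conc_uM == 0.5, ]
  expect_equal((gssg$od600 - 0.02) / (gsh$od600 - 0.02), 2)
  # saturation clips
  high <- gen_bioassay_plate(concs = 10, replicates = 1)
  expect_true(all(high$od600 <= 0.6))
  expect_error(gen_bioassay_plate(concs = -1), "non-negative")
  expect_error(gen_bioassay_plate(replicates = 0), "replicates")
})

test_that("zero-noise plate round-trips through the yield bioassay", {
  plate <- gen_bioassay_plate(curve_slope = 0.2, blank_od = 0.02,
                              concs = c(0, 0.25, 0.5, 1, 2),
                              replicates = 3, compounds = "GSH")
  curve <- fit_yield_curve(plate)
  target <- 0.75
  od <- 0.02 + 0.2 * target
  est <- infer_gsh_equivalents(od, curve)
  expect_equal(est$estimate_uM, target, tolerance = 1e-9)
})

test_that("competition generator respects the fixed point and its basins", {
  p <- study_params()
  rho <- true_fixed_ratio(p, 3e6)
  at_fp <- gen_competition(p, init_ratio = rho, n_generations = 20)
  r_at <- at_fp$count_a / at_fp$count_b
  expect_lt(max(abs(r_at / rho - 1)), 1e-3)
  above <- gen_competition(p, init_ratio = 10 * rho, n_generations = 20)
  expect_true(all(diff(above$count_a / above$count_b) < 0))
  below <- gen_competition(p, init_ratio = rho / 100, n_generations = 20)
  r_below <- below$count_a / below$count_b
  expect_true(all(diff(r_below[1:10]) > 0))
})

test_that("competition generator validates arguments", {
  p <- study_params()
  expect_error(gen_competition(p, init_ratio = 0), "init_ratio")
  expect_error(gen_competition(p, 1, n_generations = 2), "n_generations")
  expect_error(gen_competition(p, 1, 10, sampling_counts = 0),
               "sampling_counts")
})

test_that("fluorescence generator follows grow-then-die closed forms", {
  const <- gen_fluorescence_series(0, 0, switch_time = 10, duration = 20)
  expect_true(all(const$norm_intensity == 1))
  # pure growth at 0.2/h recovered by the window estimator to 1e-6
  grow <- gen_fluorescence_series(0.2, 0, switch_time = Inf, duration = 30)
  expect_equal(max_growth_rate(grow), 0.2, tolerance = 1e-6)
  # endpoint-to-peak fold change after the switch
  s <- gen_fluorescence_series(0.2, 0.05, switch_time = 24, duration = 48)
  peak <- max(s$norm_intensity)
  expect_equal(tail(s$norm_intensity, 1) / peak, exp(-0.05 * (48 - 24)),
               tolerance = 1e-8)
  expect_equal(s$norm_intensity[1], 1)
  expect_error(gen_fluorescence_series(duration = 0), "positive")
})
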