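#' Measurement-noise specification for the synthetic generators
#'
#' Each generator perturbs its noise-free signal according to a `noise_spec`:
#' positive-valued measurements (cell densities, optical densities,
#' metabolite concentrations) receive multiplicative log-normal noise with
#' `sdlog = relative_sd`, while detector traces (chromatogram signal) receive
#' additive Gaussian noise with standard deviation `additive_sd`. A fixed
#' `seed` makes the generator output bit-identical across calls; the caller's
#' RNG state is left untouched.
#'
#' @param relative_sd Relative (log-scale) standard deviation, dimensionless,
#'   >= 0.
#' @param additive_sd Additive standard deviation in the units of the signal
#'   it perturbs, >= 0.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(0.05, seed = 1)
#' @export
noise_spec <- function(relative_sd = 0, additive_sd = 0, seed = NULL) {
  if (!is.numeric(relative_sd) || relative_sd < 0 ||
      !is.numeric(additive_sd) || additive_sd < 0) {
    abort("noise standard deviations must be >= 0")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(relative_sd = relative_sd, additive_sd = additive_sd,
                 seed = seed),
            class = "noise_spec")
}

#' Is a noise spec effectively noise-free?
#' @noRd
is_noiseless <- function(noise) {
  noise$relative_sd == 0 && noise$additive_sd == 0
}

mult_noise <- function(x, noise) {
  if (noise$relative_sd == 0) return(x)
  x * stats::rlnorm(length(x), meanlog = 0, sdlog = noise$relative_sd)
}

add_noise <- function(x, noise) {
  if (noise$additive_sd == 0) return(x)
  x + stats::rnorm(length(x), sd = noise$additive_sd)
}

#' Synthetic chromatogram layout
#'
#' Describes a fluorescence chromatogram as a sum of Gaussian peaks on a
#' linear (possibly drifting) baseline. The default emulates a derivatized
#' glutathione trace: a single peak eluting near 7 minutes.
#'
#' @param peaks A data frame with columns `rt_min` (peak center, min),
#'   `amplitude` (signal units) and `width_sigma` (Gaussian sigma, min).
#' @param baseline_slope Baseline drift, signal units per minute.
#' @param baseline_intercept Baseline level at time zero, signal units.
#' @param sampling_interval Sampling step, min; must be > 0.
#' @param time_range Length-2 numeric, min; must cover every peak center
#'   +/- 4 sigma.
#' @return An object of class `chromatogram_spec`.
#' @examples
#' chromatogram_spec()
#' @export
chromatogram_spec <- function(peaks = data.frame(rt_min = 7, amplitude = 100,
                                                 width_sigma = 0.05),
                              baseline_slope = 0, baseline_intercept = 0,
                              sampling_interval = 0.005,
                              time_range = c(6, 9)) {
  if (nrow(peaks)) {
    check_columns(peaks, c("rt_min", "amplitude", "width_sigma"), "peaks")
    if (any(peaks$width_sigma <= 0)) abort("peak widths must be > 0")
  }
  if (sampling_interval <= 0) abort("sampling_interval must be > 0")
  if (length(time_range) != 2 || diff(time_range) <= 0) {
    abort("time_range must be an increasing interval")
  }
  if (nrow(peaks)) {
    lo <- peaks$rt_min - 4 * peaks$width_sigma
    hi <- peaks$rt_min + 4 * peaks$width_sigma
    if (any(lo < time_range[1]) || any(hi > time_range[2])) {
      abort("time_range must cover all peak centers +/- 4 sigma")
    }
  }
  structure(list(peaks = peaks, baseline_slope = baseline_slope,
                 baseline_intercept = baseline_intercept,
                 sampling_interval = sampling_interval,
                 time_range = time_range),
            class = "chromatogram_spec")
}

#' Generate a nutrient-limited chemostat time series
#'
#' Simulates a single releaser population growing on a limiting nutrient
#' (lysine, Monod kinetics) in a chemostat, accumulating a released
#' metabolite, and emits the tidy culture-series table the measurement stack
#' consumes. The noise-free dynamics are
#' \deqn{dL/dt = dil (L_{res} - L) - g_N(L) N / Y}
#' \deqn{dN/dt = (g_N(L) - d - dil) N, \quad dD/dt = d N - dil D}
#' \deqn{dO/dt = r N - dil O}
#' with \eqn{g_N(L) = g_{max} L/(K_L + L)}. The default yield constant
#' 7e6/21 cells/mL per uM makes a 21 uM reservoir support a steady-state
#' live density near 7e6 cells/mL (the study condition); at steady state the
#' metabolite plateaus at r N_ss / dil. Multiplicative log-normal noise is
#' applied per sample to densities and concentration.
#'
#' @param params An [ecology_params()] object (supplies `r` and `dil`).
#' @param reservoir_conc Limiting nutrient in the reservoir, uM.
#' @param duration Simulated duration, h; must be > 0.
#' @param step Sampling step, h; must be > 0.
#' @param noise A [noise_spec()].
#' @param death_rate Per-capita death rate, per hour. Presets mirroring the
#'   contrast between improper and proper nutrient limitation are available
#'   via `chemostat_death_preset()`.
#' @param yield_cells_per_uM Cells produced per uM of limiting nutrient,
#'   cells/mL/uM.
#' @param gmax_releaser Maximal releaser growth rate on the limiting
#'   nutrient, per hour.
#' @param K_lys Half-saturation of releaser growth, uM.
#' @param inoculum Initial live density, cells/mL.
#' @return A tibble with columns `time_h`, `live_per_ml`, `dead_per_ml`,
#'   `metabolite_fmole_per_ml`.
#' @examples
#' s <- gen_chemostat_series(ecology_params(), duration = 100, step = 1)
#' tail(s)
#' @export
gen_chemostat_series <- function(params, reservoir_conc = 21,
                                 duration = 100, step = 0.5,
                                 noise = noise_spec(),
                                 death_rate = 0,
                                 yield_cells_per_uM = 7e6 / 21,
                                 gmax_releaser = 0.45, K_lys = 1,
                                 inoculum = 1e5) {
  stopifnot(inherits(params, "ecology_params"), inherits(noise, "noise_spec"))
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(step) || step <= 0) {
    abort("duration and step must be positive")
  }
  if (death_rate < 0) abort("death_rate must be >= 0")
  dil <- params$dil
  rhs <- function(t, y, p) {
    gN <- gmax_releaser * y["L"] / (K_lys + y["L"])
    dL <- dil * (reservoir_conc - y["L"]) - gN * y["N"] / yield_cells_per_uM
    dN <- (gN - death_rate - dil) * y["N"]
    dD <- death_rate * y["N"] - dil * y["D"]
    dO <- params$r * y["N"] - dil * y["O"]
    list(c(dL, dN, dD, dO))
  }
  y0 <- c(L = reservoir_conc, N = inoculum, D = 0, O = 0)
  times <- seq(0, duration, by = step)
  sol <- as.data.frame(
    deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-8, atol = 1e-8)
  )
  out <- with_noise_seed(noise, tibble(
    time_h = sol$time,
    live_per_ml = mult_noise(pmax(sol$N, 0), noise),
    dead_per_ml = mult_noise(pmax(sol$D, 0), noise),
    metabolite_fmole_per_ml = mult_noise(pmax(sol$O, 0), noise)
  ))
  out
}

#' Death-rate presets for the chemostat generator
#'
#' Constant per-capita death fractions mirroring the contrast between
#' improper (lysine-limited) and proper (glucose-limited) nutrient
#' limitation. The values are presets for generating plausible test data,
#' not measured rates.
#'
#' @param limitation `"lysine"` or `"glucose"`.
#' @return Death rate, per hour.
#' @export
chemostat_death_preset <- function(limitation = c("lysine", "glucose")) {
  switch(match.arg(limitation), lysine = 0.10, glucose = 0.01)
}

#' Generate a synthetic chromatogram
#'
#' Emits signal(t) = sum of Gaussian peaks + linear baseline + additive
#' Gaussian noise on a strictly increasing retention-time axis.
#'
#' @param spec A [chromatogram_spec()].
#' @param noise A [noise_spec()]; `additive_sd` applies.
#' @return A tibble with columns `rt_min`, `signal`.
#' @examples
#' gen_chromatogram(chromatogram_spec())
#' @export
gen_chromatogram <- function(spec = chromatogram_spec(), noise = noise_spec()) {
  stopifnot(inherits(spec, "chromatogram_spec"), inherits(noise, "noise_spec"))
  rt <- seq(spec$time_range[1], spec$time_range[2],
            by = spec$sampling_interval)
  if (length(rt) < 3) abort("time range yields fewer than 3 samples")
  signal <- spec$baseline_intercept + spec$baseline_slope * rt
  if (nrow(spec$peaks)) {
    for (i in seq_len(nrow(spec$peaks))) {
      pk <- spec$peaks[i, ]
      signal <- signal +
        pk$amplitude * exp(-(rt - pk$rt_min)^2 / (2 * pk$width_sigma^2))
    }
  }
  with_noise_seed(noise, tibble(rt_min = rt,
                                signal = add_noise(signal, noise)))
}

#' Generate a yield-bioassay plate
#'
#' Emulates the tester-strain plate that calibrates final turbidity against
#' organosulfur concentration: final OD = min(blank + slope * conc,
#' saturation), with oxidized-glutathione (GS-SG) wells responding at twice
#' the equimolar GSH response because reduction of one GS-SG yields two GSH.
#' Multiplicative log-normal noise is applied per well.
#'
#' @param curve_slope OD per uM GSH-equivalent in the linear range.
#' @param blank_od Blank (zero-concentration) OD.
#' @param saturation_od OD ceiling of the assay.
#' @param concs Standard concentrations, uM; must be non-negative.
#' @param replicates Wells per concentration; >= 1.
#' @param noise A [noise_spec()]; `relative_sd` applies to OD.
#' @param compounds Compounds to plate; `"GSH"` responds at face value,
#'   `"GSSG"` at 2x.
#' @return A tibble with columns `compound`, `conc_uM`, `od600`, `replicate`.
#' @examples
#' gen_bioassay_plate(concs = c(0, 0.5, 1, 2))
#' @export
gen_bioassay_plate <- function(curve_slope = 0.2, blank_od = 0.02,
                               saturation_od = 0.6,
                               concs = c(0, 0.25, 0.5, 1, 2),
                               replicates = 3, noise = noise_spec(),
                               compounds = c("GSH", "GSSG")) {
  stopifnot(inherits(noise, "noise_spec"))
  if (any(concs < 0)) abort("concentrations must be non-negative")
  if (replicates < 1) abort("replicates must be >= 1")
  equiv_factor <- c(GSH = 1, GSSG = 2)
  compounds <- match.arg(compounds, several.ok = TRUE)
  grid <- tidyr::expand_grid(compound = compounds, conc_uM = concs,
                             replicate = seq_len(replicates))
  od <- pmin(blank_od + curve_slope * equiv_factor[grid$compound] *
               grid$conc_uM, saturation_od)
  with_noise_seed(noise, tibble(
    compound = grid$compound,
    conc_uM = grid$conc_uM,
    od600 = mult_noise(unname(od), noise),
    replicate = grid$replicate
  ))
}

#' Generate a two-genotype competition trajectory
#'
#' Runs [simulate_coculture()] from an initial consumer/releaser ratio and
#' samples the deterministic frequency trajectory at a generation grid. With
#' a non-zero noise spec, counts at each time point are binomial draws of
#' `sampling_counts` events at the true consumer frequency (flow-cytometry
#' counting statistics); with a zero noise spec the expected counts are
#' returned so the trajectory is exactly the deterministic one.
#'
#' @param params An [ecology_params()] object.
#' @param init_ratio Initial consumer-to-releaser ratio; > 0.
#' @param n_generations Number of generations to simulate; >= 3.
#' @param sampling_counts Events counted per time point; >= 1.
#' @param noise A [noise_spec()]; any non-zero field switches on binomial
#'   sampling, and `seed` fixes the draws.
#' @param total_density Total cell density held constant in serial mode,
#'   cells/mL.
#' @param points_per_generation Sampling resolution of the output grid.
#' @return A tibble with columns `generation`, `count_a` (consumer),
#'   `count_b` (releaser).
#' @examples
#' gen_competition(ecology_params(), init_ratio = 1, n_generations = 10)
#' @export
gen_competition <- function(params, init_ratio, n_generations = 30,
                            sampling_counts = 10000, noise = noise_spec(),
                            total_density = 3e6, points_per_generation = 1) {
  stopifnot(inherits(params, "ecology_params"), inherits(noise, "noise_spec"))
  if (!is.numeric(init_ratio) || init_ratio <= 0) {
    abort("init_ratio must be > 0")
  }
  if (n_generations < 3) abort("n_generations must be >= 3")
  if (sampling_counts < 1) abort("sampling_counts must be >= 1")
  R0 <- total_density / (1 + init_ratio)
  C0 <- total_density - R0
  O0 <- params$K_half * params$g /
    max(params$gmax_consumer - params$g, .Machine$double.eps)
  sim <- simulate_coculture(params, init = c(R = R0, C = C0, O = O0),
                            duration = n_generations,
                            step = 1 / points_per_generation,
                            mode = "serial", time_unit = "generations")
  freq <- sim$C / (sim$C + sim$R)
  counts <- if (is_noiseless(noise)) {
    tibble(count_a = sampling_counts * freq,
           count_b = sampling_counts * (1 - freq))
  } else {
    with_noise_seed(noise, {
      a <- stats::rbinom(length(freq), sampling_counts, freq)
      tibble(count_a = a, count_b = sampling_counts - a)
    })
  }
  tibble(generation = sim$generation, count_a = counts$count_a,
         count_b = counts$count_b)
}

#' Generate a grow-then-die fluorescence time course
#'
#' Normalized total fluorescence (a live-biomass proxy) grows exponentially
#' at `growth_rate` until `switch_time`, then declines exponentially at
#' `death_rate`; intensity at time zero is 1 after normalization.
#'
#' @param growth_rate Exponential growth rate, per hour.
#' @param death_rate Exponential decline rate after the switch, per hour.
#' @param switch_time Time of the growth-to-death switch, h.
#' @param duration Total duration, h; must be > 0.
#' @param step Sampling step, h.
#' @param noise A [noise_spec()]; `relative_sd` applies multiplicatively,
#'   after which the series is renormalized to its first point.
#' @return A tibble with columns `time_h`, `norm_intensity`.
#' @examples
#' gen_fluorescence_series(0.2, 0.05, switch_time = 24, duration = 48)
#' @export
gen_fluorescence_series <- function(growth_rate = 0.2, death_rate = 0.05,
                                    switch_time = 24, duration = 48,
                                    step = 1, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  if (duration <= 0 || step <= 0) abort("duration and step must be positive")
  t <- seq(0, duration, by = step)
  peak <- exp(growth_rate * min(switch_time, duration))
  y <- ifelse(t <= switch_time,
              exp(growth_rate * t),
              peak * exp(-death_rate * (t - switch_time)))
  y <- with_noise_seed(noise, mult_noise(y, noise))
  tibble(time_h = t, norm_intensity = y / y[1])
}
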