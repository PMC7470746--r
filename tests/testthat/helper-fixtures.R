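# Shared fixtures and independent oracles used across test files.

# Study-condition parameter set: release 0.02 fmole/cell/h, consumption
# 2 fmole/birth, growth = dilution = ln2/8 per hour.
study_params <- function() {
  ecology_params(r = 0.02, c_per_birth = 2, g = log(2) / 8,
                 gmax_consumer = 0.35, K_half = 1e5)
}

# Closed-form fixed point of the full closed model (Monod uptake + washout
# of the resource at the effective dilution rate), at constant total density
# `total`. Derivation: at coexistence g_C(O*) = g gives O* = K g/(gmax - g);
# the resource balance r R = c g C + g O* with R = total/(1 + rho) then
# yields rho (1 + O*/(c total)) = r/(c g) - O*/(c total).
true_fixed_ratio <- function(params, total = 3e6) {
  O_star <- params$K_half * params$g / (params$gmax_consumer - params$g)
  w <- O_star / (params$c_per_birth * total)
  (params$r / (params$c_per_birth * params$g) - w) / (1 + w)
}

# Brute-force window-slope oracles, independent of the package's internals:
# plain lm() over every eligible window.
brute_max_growth_rate <- function(series, cutoff = 0.25) {
  y <- series$norm_intensity
  t <- series$time_h
  cut_val <- cutoff * max(y)
  best <- -Inf
  for (i in seq_len(length(y) - 3)) {
    idx <- i:(i + 3)
    if (y[idx[4]] <= cut_val) {
      best <- max(best, unname(coef(lm(log(y[idx]) ~ t[idx]))[2]))
    }
  }
  best
}

brute_competition_fitness <- function(traj) {
  best <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(nrow(traj) - 2)) {
    idx <- i:(i + 2)
    a <- traj$count_a[idx]
    b <- traj$count_b[idx]
    if (all(a > 0) && all(b > 0)) {
      s <- unname(coef(lm(log(a / b) ~ traj$generation[idx]))[2])
      if (s > best) {
        best <- s
        best_i <- i
      }
    }
  }
  list(fitness = best / log(2), window_start = best_i)
}
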