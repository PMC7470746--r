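#' Maximal growth rate from a sliding 4-point window
#'
#' For every window of 4 consecutive time points, fits the least-squares
#' slope of ln(normalized intensity) against time and returns the steepest
#' slope. To avoid estimating where some other nutrient may already be
#' limiting, only windows whose last point sits at or below 25% of the
#' series maximum are eligible (leaving at least two doublings of headroom).
#' When no window satisfies the restriction (e.g. a flat series), the
#' estimator falls back to all windows with a warning.
#'
#' @param series A data frame with columns `time_h` (strictly increasing)
#'   and `norm_intensity` (>= 0, normalized to the first point).
#' @param intensity_cutoff Fraction of the series maximum bounding the last
#'   point of eligible windows. Default 0.25.
#' @return Maximal growth rate, per hour.
#' @examples
#' s <- gen_fluorescence_series(0.2, 0, switch_time = Inf, duration = 30)
#' max_growth_rate(s)
#' @export
max_growth_rate <- function(series, intensity_cutoff = 0.25) {
  check_columns(series, c("time_h", "norm_intensity"), "fluorescence series")
  keep <- is.finite(series$norm_intensity) & series$norm_intensity > 0
  if (!all(keep)) {
    warn("non-positive intensities excluded from growth-rate estimation")
    series <- series[keep, ]
  }
  n <- nrow(series)
  if (n < 4) abort("growth-rate estimation needs >= 4 positive points")
  t <- series$time_h
  ly <- log(series$norm_intensity)
  cutoff <- intensity_cutoff * max(series$norm_intensity)
  starts <- seq_len(n - 3)
  eligible <- series$norm_intensity[starts + 3] <= cutoff
  if (!any(eligible)) {
    warn("no window below the intensity cutoff; using all windows")
    eligible <- rep(TRUE, length(starts))
  }
  slopes <- vapply(starts[eligible], function(i) {
    ols_slope(t[i:(i + 3)], ly[i:(i + 3)])
  }, numeric(1))
  max(slopes)
}

#' Survival and death-rate metrics from a fluorescence time course
#'
#' Endpoint survival is the last normalized intensity divided by the first.
#' The death rate is minus the least-squares slope of ln(intensity) over the
#' declining segment after the global maximum (earliest maximum on ties).
#' A series that never declines reports rate 0 with flag `"no_decline"`.
#'
#' @param series A data frame with columns `time_h`, `norm_intensity`.
#' @return A one-row tibble: `endpoint_survival`, `death_rate` (h^-1),
#'   `flag`.
#' @examples
#' s <- gen_fluorescence_series(0.2, 0.05, switch_time = 24, duration = 110)
#' death_metrics(s)
#' @export
death_metrics <- function(series) {
  check_columns(series, c("time_h", "norm_intensity"), "fluorescence series")
  n <- nrow(series)
  if (n < 2) abort("death metrics need >= 2 points")
  survival <- series$norm_intensity[n] / series$norm_intensity[1]
  peak <- which.max(series$norm_intensity)
  if (peak >= n) {
    return(tibble(endpoint_survival = survival, death_rate = 0,
                  flag = "no_decline"))
  }
  seg <- series[peak:n, ]
  if (any(seg$norm_intensity <= 0)) {
    warn("non-positive intensities excluded from death-rate fit")
    seg <- seg[seg$norm_intensity > 0, ]
    if (nrow(seg) < 2) {
      return(tibble(endpoint_survival = survival, death_rate = 0,
                    flag = "no_decline"))
    }
  }
  rate <- -ols_slope(seg$time_h, log(seg$norm_intensity))
  flag <- if (rate <= 0) "no_decline" else "ok"
  tibble(endpoint_survival = survival, death_rate = max(rate, 0),
         flag = flag)
}

#' Competition fitness from the steepest 3-point log-ratio slope
#'
#' For every window of 3 consecutive time points, fits the least-squares
#' slope of ln(count_a / count_b) against generations; the relative fitness
#' is the steepest such slope divided by ln 2 (so that a ratio doubling each
#' generation scores exactly 1). The starting fraction
#' count_a / (count_a + count_b) at the first point of the chosen window is
#' recorded for frequency-dependence analysis. Windows containing a zero
#' count in either channel are skipped; ties between equally steep windows
#' resolve to the earliest.
#'
#' @param traj A data frame with columns `generation` (monotone increasing),
#'   `count_a` (focal/consumer genotype), `count_b` (reference genotype).
#' @return A one-row tibble of class `fitness_result`: `relative_fitness`,
#'   `window_start_index`, `start_fraction`, `n_windows_used`.
#' @examples
#' traj <- tibble::tibble(generation = 0:5,
#'                        count_a = 100 * 2^(0:5), count_b = 100)
#' competition_fitness(traj)
#' @export
competition_fitness <- function(traj) {
  check_columns(traj, c("generation", "count_a", "count_b"), "trajectory")
  n <- nrow(traj)
  if (n < 3) abort("competition fitness needs >= 3 time points")
  if (any(diff(traj$generation) <= 0)) {
    abort("generation axis must be strictly increasing")
  }
  starts <- seq_len(n - 2)
  ok <- vapply(starts, function(i) {
    all(traj$count_a[i:(i + 2)] > 0) && all(traj$count_b[i:(i + 2)] > 0)
  }, logical(1))
  if (!any(ok)) abort("no 3-point window with positive counts in both channels")
  slopes <- vapply(starts[ok], function(i) {
    idx <- i:(i + 2)
    ols_slope(traj$generation[idx],
              log(traj$count_a[idx] / traj$count_b[idx]))
  }, numeric(1))
  best <- which.max(slopes) # earliest wins on ties
  i0 <- starts[ok][best]
  out <- tibble(
    relative_fitness = slopes[best] / log(2),
    window_start_index = i0,
    start_fraction = traj$count_a[i0] /
      (traj$count_a[i0] + traj$count_b[i0]),
    n_windows_used = sum(ok)
  )
  structure(out, class = c("fitness_result", class(out)))
}

#' Frequency dependence of relative fitness
#'
#' Pairs each fitness estimate with the genotype fraction at the start of
#' its steepest window and summarises the trend by the sign of the Spearman
#' rank correlation. Under negative frequency-dependent selection the
#' correlation is negative: the advantage shrinks as the genotype becomes
#' common.
#'
#' @param results A list of [competition_fitness()] results, or a data frame
#'   already holding `start_fraction` and `relative_fitness` columns.
#' @return A tibble of class `frequency_dependence`, sorted by
#'   `start_fraction`, with attributes `rank_correlation` and
#'   `correlation_sign` (`"negative"`, `"positive"`, `"zero"` or
#'   `"undefined"`); retrieve them via [glance()].
#' @export
frequency_dependence <- function(results) {
  if (is.data.frame(results)) {
    tbl <- as_tibble(results)
  } else {
    tbl <- dplyr::bind_rows(results)
  }
  check_columns(tbl, c("start_fraction", "relative_fitness"),
                "fitness results")
  if (nrow(tbl) < 1) abort("at least one fitness result is required")
  tbl <- dplyr::arrange(tbl, .data$start_fraction)
  rho <- if (nrow(tbl) >= 2 && sd(tbl$relative_fitness) > 0 &&
             sd(tbl$start_fraction) > 0) {
    cor(tbl$start_fraction, tbl$relative_fitness, method = "spearman")
  } else {
    NA_real_
  }
  sign_lab <- if (is.na(rho)) "undefined" else if (rho < 0) "negative"
              else if (rho > 0) "positive" else "zero"
  structure(tbl, class = c("frequency_dependence", class(tbl)),
            rank_correlation = rho, correlation_sign = sign_lab)
}

#' @describeIn frequency_dependence One-row summary with the rank
#'   correlation and its sign.
#' @param x A `frequency_dependence` object.
#' @param ... Unused.
#' @method glance frequency_dependence
#' @export
glance.frequency_dependence <- function(x, ...) {
  tibble(n = nrow(x),
         rank_correlation = attr(x, "rank_correlation"),
         correlation_sign = attr(x, "correlation_sign"))
}

#' Colony-size-weighted auxotroph frequency
#'
#' Population auxotroph frequency from a colony screen stratified by colony
#' size class: the fraction of all counted colonies falling in each class,
#' multiplied by the fraction of screened colonies in that class scoring as
#' auxotrophic, summed over classes.
#'
#' @param screen A data frame with one row per size class and columns
#'   `colonies_counted`, `screened`, `auxotrophs_found` (optionally
#'   `size_class`).
#' @return Estimated auxotroph frequency, dimensionless in `[0, 1]`.
#' @examples
#' auxotroph_frequency(tibble::tibble(
#'   size_class = c("large", "small"),
#'   colonies_counted = c(90, 10), screened = c(20, 20),
#'   auxotrophs_found = c(10, 0)
#' ))
#' @export
auxotroph_frequency <- function(screen) {
  check_columns(screen, c("colonies_counted", "screened", "auxotrophs_found"),
                "colony screen")
  if (any(screen$colonies_counted < 0) || any(screen$screened < 0) ||
      any(screen$auxotrophs_found < 0)) {
    abort("counts must be non-negative")
  }
  if (any(screen$auxotrophs_found > screen$screened)) {
    abort("auxotrophs_found cannot exceed screened")
  }
  total <- sum(screen$colonies_counted)
  if (total <= 0) abort("no colonies counted")
  active <- screen$colonies_counted > 0
  if (any(active & screen$screened == 0)) {
    abort("a size class with colonies has zero screened colonies")
  }
  sum((screen$colonies_counted[active] / total) *
        (screen$auxotrophs_found[active] / screen$screened[active]))
}
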