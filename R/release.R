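#' Estimate the per-cell metabolite release rate from a chemostat steady state
#'
#' At steady state the resource balance dO/dt = r N - dil O = 0 gives
#' r = dil * O_ss / N_ss, so the release rate per live cell is the dilution
#' rate times the steady-state supernatant concentration divided by the
#' steady-state live-cell density. Means are taken over a user-designated
#' steady-state window (default: the last 25% of the series).
#'
#' @param series A culture-series data frame with columns `time_h`,
#'   `live_per_ml` and `metabolite_fmole_per_ml` (the schema written by
#'   [gen_chemostat_series()]).
#' @param dil Dilution rate, per hour.
#' @param steady_window Length-2 numeric `(start_h, end_h)` selecting the
#'   steady-state window; `NULL` uses the last 25% of the time span.
#' @return Release rate, fmole per cell per hour.
#' @examples
#' p <- ecology_params()
#' s <- gen_chemostat_series(p, duration = 200, step = 1)
#' estimate_release_rate(s, dil = p$dil)
#' @export
estimate_release_rate <- function(series, dil, steady_window = NULL) {
  check_columns(series, c("time_h", "live_per_ml", "metabolite_fmole_per_ml"),
                "culture series")
  if (!is.numeric(dil) || dil < 0) abort("dil must be a non-negative number")
  tspan <- range(series$time_h)
  if (is.null(steady_window)) {
    steady_window <- c(tspan[1] + 0.75 * diff(tspan), tspan[2])
  }
  if (steady_window[1] < tspan[1] || steady_window[2] > tspan[2] ||
      steady_window[1] >= steady_window[2]) {
    abort("steady_window must be an increasing interval inside the series")
  }
  w <- series$time_h >= steady_window[1] & series$time_h <= steady_window[2]
  if (!any(w)) abort("steady_window contains no samples")
  live <- mean(series$live_per_ml[w])
  if (live <= 0) abort("live-cell density is zero in the steady-state window")
  dil * mean(series$metabolite_fmole_per_ml[w]) / live
}

#' Average metabolite content per cell
#'
#' @param total_metabolite Total extracted metabolite, fmole.
#' @param total_cells Number of cells extracted; must be positive.
#' @return fmole per cell.
#' @examples
#' per_cell_content(6e6, 3e6) # 2 fmole/cell
#' @export
per_cell_content <- function(total_metabolite, total_cells) {
  if (!is.numeric(total_cells) || any(total_cells <= 0)) {
    abort("total_cells must be positive")
  }
  if (!is.numeric(total_metabolite) || any(total_metabolite < 0)) {
    abort("total_metabolite must be non-negative")
  }
  total_metabolite / total_cells
}

#' Upper bound on supernatant metabolite attributable to dead-cell lysis
#'
#' Multiplies the dead-cell density by the average per-cell metabolite
#' content: the maximum supernatant concentration that complete lysis of all
#' dead cells could explain.
#'
#' @param dead_density Dead-cell density, cells per mL; non-negative.
#' @param content Average metabolite content, fmole per cell; non-negative.
#' @return fmole per mL.
#' @seealso [attribute_live_release()]
#' @export
dead_release_bound <- function(dead_density, content) {
  if (!is.numeric(dead_density) || any(dead_density < 0) ||
      !is.numeric(content) || any(content < 0)) {
    abort("dead_density and content must be non-negative")
  }
  dead_density * content
}

#' Attribute supernatant metabolite to live-cell release or dead-cell lysis
#'
#' Compares a measured supernatant concentration against the dead-cell lysis
#' bound. When the measurement exceeds what lysis of every dead cell could
#' supply, the excess must have been released by live cells.
#'
#' @param measured Measured supernatant concentration, fmole per mL.
#' @param dead_density Dead-cell density, cells per mL.
#' @param content Average metabolite content, fmole per cell.
#' @return A tibble with `measured`, `dead_bound`, `excess` and `source`
#'   (`"live"` when measured exceeds the bound, else `"indeterminate"`).
#' @export
attribute_live_release <- function(measured, dead_density, content) {
  bound <- dead_release_bound(dead_density, content)
  tibble(
    measured = measured,
    dead_bound = bound,
    excess = pmax(measured - bound, 0),
    source = ifelse(measured > bound, "live", "indeterminate")
  )
}
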