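#' Parameters of the releaser-consumer organosulfur model
#'
#' Bundles the constants of the cross-feeding model in which a releaser
#' population R exports an organosulfur resource (in glutathione, GSH,
#' equivalents) that a consumer population C requires. The resource balance
#' is dO/dt = r R - c g_C(O) C (minus washout where the culture is diluted),
#' where `r` is the per-cell release rate, `c` the amount consumed per
#' consumer birth, and g_C the consumer growth rate. At coexistence both
#' populations grow at the shared rate `g` and the consumer-to-releaser
#' ratio settles at C/R = r / (c g).
#'
#' @param r Release rate, fmole GSH-equivalent per cell per hour.
#' @param c_per_birth Organosulfur consumed per consumer birth, fmole per cell.
#' @param g Shared growth rate at steady state (equals the dilution rate in a
#'   chemostat), per hour.
#' @param dil Dilution rate of the culture vessel, per hour. Defaults to `g`.
#' @param gmax_consumer Maximal consumer growth rate, per hour. Model-closure
#'   parameter: must exceed `g` for a coexistence steady state to exist.
#' @param K_half Organosulfur half-saturation constant of consumer growth,
#'   fmole per mL. Model-closure parameter.
#'
#' @return An object of class `ecology_params` (a named list).
#' @examples
#' p <- ecology_params(r = 0.02, c_per_birth = 2, g = log(2) / 8)
#' predict_steady_ratio(p)
#' @export
ecology_params <- function(r = 0.02, c_per_birth = 2, g = log(2) / 8,
                           dil = g, gmax_consumer = 0.35, K_half = 1e5) {
  p <- list(r = r, c_per_birth = c_per_birth, g = g, dil = dil,
            gmax_consumer = gmax_consumer, K_half = K_half)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                            is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) {
    abort(paste0("ecology_params fields must be single non-negative numbers: ",
                 paste(bad, collapse = ", ")))
  }
  structure(p, class = "ecology_params")
}

#' @export
print.ecology_params <- function(x, ...) {
  cat("<ecology_params>\n")
  cat(sprintf("  r             %.4g fmole/cell/h (release rate)\n", x$r))
  cat(sprintf("  c_per_birth   %.4g fmole/cell (consumption per birth)\n",
              x$c_per_birth))
  cat(sprintf("  g             %.4g /h (shared growth rate)\n", x$g))
  cat(sprintf("  dil           %.4g /h (dilution rate)\n", x$dil))
  cat(sprintf("  gmax_consumer %.4g /h, K_half %.4g fmole/mL\n",
              x$gmax_consumer, x$K_half))
  invisible(x)
}

#' Predicted steady-state consumer-to-releaser ratio
#'
#' Closed-form fixed point of the organosulfur balance dO/dt = r R - c g C:
#' setting it to zero at shared growth rate g gives C/R = r / (c g).
#'
#' @param params An [ecology_params()] object.
#' @return The dimensionless ratio C/R.
#' @examples
#' # 0.02 / (2 * log(2)/8) is approximately 0.1
#' predict_steady_ratio(ecology_params(0.02, 2, log(2) / 8))
#' @export
predict_steady_ratio <- function(params) {
  stopifnot(inherits(params, "ecology_params"))
  if (params$c_per_birth <= 0 || params$g <= 0) {
    abort("predict_steady_ratio requires c_per_birth > 0 and g > 0")
  }
  params$r / (params$c_per_birth * params$g)
}

#' Consumer Monod growth rate on the organosulfur resource
#' @param O Organosulfur concentration, fmole/mL.
#' @param params An [ecology_params()] object.
#' @return Growth rate, per hour.
#' @keywords internal
consumer_growth_rate <- function(O, params) {
  params$gmax_consumer * O / (params$K_half + O)
}

#' Simulate releaser-consumer coculture dynamics
#'
#' Integrates the closed model
#' \deqn{dO/dt = r R - c\, g_C(O)\, C - d_{eff} O}
#' \deqn{dR/dt = (g - d_{eff}) R, \qquad dC/dt = (g_C(O) - d_{eff}) C}
#' with Monod consumer uptake \eqn{g_C(O) = g_{max} O / (K + O)}. The
#' effective dilution rate depends on `mode`:
#' \describe{
#'   \item{serial}{\eqn{d_{eff}} is the density-weighted mean growth rate, so
#'     total cell density R + C is held constant, mimicking serial-dilution
#'     batch competition at roughly constant density.}
#'   \item{chemostat}{\eqn{d_{eff} = dil} from the parameter set.}
#'   \item{batch}{no dilution (\eqn{d_{eff} = 0}); useful for mass-budget
#'     checks.}
#' }
#' Cumulative release (\eqn{\int r R\,dt}) and cumulative consumer births
#' (\eqn{\int g_C C\,dt}) are carried as auxiliary states so the organosulfur
#' budget can be audited.
#'
#' @param params An [ecology_params()] object.
#' @param init Named numeric vector or list with elements `R`, `C` (cells/mL)
#'   and `O` (fmole/mL); all non-negative.
#' @param duration Simulated time. Hours unless `time_unit = "generations"`,
#'   in which case it is converted via t = generations * ln2 / g.
#' @param step Output reporting step, same unit as `duration`. The integrator
#'   itself is adaptive (lsoda, rtol 1e-8); `step` only sets the output grid.
#' @param mode One of `"serial"`, `"chemostat"`, `"batch"`.
#' @param time_unit `"hours"` or `"generations"`.
#' @return A tibble of class `coculture_sim` with columns `time_h`,
#'   `generation`, `R`, `C`, `O`, `ratio` (C/R), `cum_release`, `cum_births`.
#' @examples
#' p <- ecology_params()
#' sim <- simulate_coculture(p, init = c(R = 3e6 / 1.1, C = 3e5 / 1.1, O = 0),
#'                           duration = 60, time_unit = "generations")
#' tail(sim$ratio, 1)
#' @export
simulate_coculture <- function(params, init, duration, step = duration / 400,
                               mode = c("serial", "chemostat", "batch"),
                               time_unit = c("hours", "generations")) {
  stopifnot(inherits(params, "ecology_params"))
  mode <- match.arg(mode)
  time_unit <- match.arg(time_unit)
  init <- as.list(init)
  if (!all(c("R", "C", "O") %in% names(init))) {
    abort("init must provide R, C and O")
  }
  y0 <- c(R = init$R, C = init$C, O = init$O, cumR = 0, cumB = 0)
  if (any(!is.finite(unlist(y0))) || any(unlist(y0) < 0)) {
    abort("initial state must be finite and non-negative")
  }
  if (!is.numeric(duration) || duration <= 0 || step <= 0) {
    abort("duration and step must be positive")
  }
  if (time_unit == "generations") {
    if (params$g <= 0) abort("generation time undefined when g = 0")
    duration <- duration * log(2) / params$g
    step <- step * log(2) / params$g
  }

  rhs <- function(t, y, p) {
    gC <- consumer_growth_rate(max(y["O"], 0), p)
    d_eff <- switch(mode,
      serial = {
        tot <- y["R"] + y["C"]
        if (tot > 0) (p$g * y["R"] + gC * y["C"]) / tot else 0
      },
      chemostat = p$dil,
      batch = 0
    )
    dR <- (p$g - d_eff) * y["R"]
    dC <- (gC - d_eff) * y["C"]
    dO <- p$r * y["R"] - p$c_per_birth * gC * y["C"] - d_eff * y["O"]
    list(c(dR, dC, dO, p$r * y["R"], gC * y["C"]))
  }

  times <- seq(0, duration, by = step)
  if (times[length(times)] < duration) times <- c(times, duration)
  sol <- deSolve::lsoda(y0, times, rhs, params, rtol = 1e-8, atol = 1e-6)
  if (attr(sol, "istate")[1] < 0) {
    abort("coculture integration failed to converge; see deSolve diagnostics")
  }
  sol <- as.data.frame(sol)
  neg_tol <- -1e-6 * max(abs(unlist(y0)), 1)
  if (any(sol$R < neg_tol | sol$C < neg_tol | sol$O < neg_tol)) {
    abort("integration produced negative states beyond tolerance")
  }
  out <- tibble(
    time_h = sol$time,
    generation = sol$time * params$g / log(2),
    R = pmax(sol$R, 0),
    C = pmax(sol$C, 0),
    O = pmax(sol$O, 0),
    ratio = ifelse(sol$R > 0, sol$C / sol$R, NA_real_),
    cum_release = sol$cumR,
    cum_births = sol$cumB
  )
  structure(out, class = c("coculture_sim", class(out)),
            params = params, mode = mode)
}

#' @describeIn simulate_coculture One-row summary: final state, final ratio,
#'   and the closed-form predicted ratio.
#' @param x A `coculture_sim` object.
#' @param ... Unused.
#' @method glance coculture_sim
#' @export
glance.coculture_sim <- function(x, ...) {
  params <- attr(x, "params")
  last <- x[nrow(x), ]
  tibble(
    final_ratio = last$ratio,
    predicted_ratio = predict_steady_ratio(params),
    final_R = last$R, final_C = last$C, final_O = last$O,
    generations = last$generation,
    mode = attr(x, "mode")
  )
}
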