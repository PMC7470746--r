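#' Continuous-culture device configuration
#'
#' @param vessel_volume Vessel running volume, mL.
#' @param doubling_time Target population doubling time, h.
#' @param reservoir_conc Limiting-nutrient concentration in the reservoir, uM.
#' @param mode `"chemostat"` (constant flow rate) or `"turbidostat"`
#'   (dilute-to-setpoint).
#' @param od_setpoint Optical-density set point; turbidostat mode only.
#' @return An object of class `culture_config`.
#' @examples
#' culture_config(43, 7)
#' @export
culture_config <- function(vessel_volume = 43, doubling_time = 8,
                           reservoir_conc = 21,
                           mode = c("chemostat", "turbidostat"),
                           od_setpoint = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(vessel_volume) || vessel_volume <= 0) {
    abort("vessel_volume must be > 0")
  }
  if (!is.numeric(doubling_time) || doubling_time <= 0) {
    abort("doubling_time must be > 0")
  }
  if (mode == "turbidostat" && is.null(od_setpoint)) {
    abort("turbidostat mode requires an od_setpoint")
  }
  structure(list(vessel_volume = vessel_volume, doubling_time = doubling_time,
                 reservoir_conc = reservoir_conc, mode = mode,
                 od_setpoint = od_setpoint),
            class = "culture_config")
}

#' Chemostat flow rate for a target doubling time
#'
#' f = ln(2) * V / T_D: the medium inflow that replaces one vessel volume per
#' doubling time worth of exponential dilution, so that at steady state the
#' population doubles every `doubling_time` hours.
#'
#' @param config A [culture_config()] object, or a vessel volume in mL when
#'   `doubling_time` is also given.
#' @param doubling_time Doubling time in hours (when `config` is a number).
#' @return Flow rate, mL per hour.
#' @examples
#' flow_rate(43, 7) # ~4.26 mL/h
#' @export
flow_rate <- function(config, doubling_time = NULL) {
  if (inherits(config, "culture_config")) {
    V <- config$vessel_volume
    TD <- config$doubling_time
  } else {
    V <- config
    TD <- doubling_time
  }
  if (!is.numeric(V) || !is.numeric(TD) || V <= 0 || TD <= 0) {
    abort("flow_rate requires positive vessel volume and doubling time")
  }
  log(2) * V / TD
}

#' Dilution rate for a doubling time
#'
#' dil = ln(2) / T_D, the fractional volume replacement per hour that holds a
#' chemostat population at the given doubling time.
#'
#' @param doubling_time Doubling time, hours; must be positive.
#' @return Dilution rate, per hour.
#' @examples
#' dilution_rate(8)
#' @export
dilution_rate <- function(doubling_time) {
  if (!is.numeric(doubling_time) || any(doubling_time <= 0)) {
    abort("doubling_time must be positive")
  }
  log(2) / doubling_time
}

#' Optical density from detector light intensity
#'
#' The culturing device stores a blank intensity `I0` at channel start and
#' converts each subsequent reading `I` as OD = log10(I / I0). Note this
#' device convention yields negative values as the culture thickens (I drops
#' below I0); set `conventional = TRUE` for the usual -log10(I / I0).
#'
#' @param I Measured light intensity, detector units; must be positive.
#' @param I0 Blank intensity, detector units; must be positive.
#' @param conventional If `TRUE`, return -log10(I / I0) instead.
#' @return Optical density (dimensionless).
#' @examples
#' od_from_intensity(10, 1) # 1
#' od_from_intensity(0.5, 1, conventional = TRUE)
#' @export
od_from_intensity <- function(I, I0, conventional = FALSE) {
  if (!is.numeric(I) || !is.numeric(I0) || any(I <= 0) || any(I0 <= 0)) {
    abort("intensities must be positive")
  }
  od <- log10(I / I0)
  if (conventional) -od else od
}
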