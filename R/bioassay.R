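#' Fit the yield-bioassay standard curve
#'
#' Calibrates tester-strain final turbidity against known organosulfur
#' concentration (GSH equivalents). Replicate wells are averaged per
#' concentration, standards outside the designated linear range are
#' excluded from the fit, and the result is an OLS line mean OD =
#' slope * conc + intercept. The detection floor is the blank mean plus two
#' blank standard deviations; when no blank (zero-concentration) wells are
#' present the floor falls back to the mean OD of the lowest standard, with
#' a warning.
#'
#' @param standards A plate table with columns `conc_uM` and `od600`
#'   (optionally `compound`, `replicate`); rows with `NA` concentration are
#'   ignored.
#' @param linear_range Length-2 numeric, uM: standards inside this range
#'   enter the fit. Default 0-2 uM, the GSH yield-assay linear range.
#' @return A [fit_standard_curve()] object whose responses are mean ODs and
#'   whose `detection_floor` is on the OD scale.
#' @examples
#' plate <- gen_bioassay_plate(compounds = "GSH")
#' fit_yield_curve(plate)
#' @export
fit_yield_curve <- function(standards, linear_range = c(0, 2)) {
  check_columns(standards, c("conc_uM", "od600"), "plate table")
  standards <- dplyr::filter(standards, !is.na(.data$conc_uM))
  if (length(unique(standards$conc_uM)) < 2) {
    abort("yield calibration requires >= 2 standard concentrations")
  }
  blanks <- standards$od600[standards$conc_uM == 0]
  if (length(blanks)) {
    floor_od <- mean(blanks) +
      2 * (if (length(blanks) > 1) sd(blanks) else 0)
  } else {
    warn("no blank wells; detection floor set from the lowest standard")
    lowest <- min(standards$conc_uM)
    floor_od <- mean(standards$od600[standards$conc_uM == lowest])
  }
  means <- standards |>
    dplyr::filter(.data$conc_uM >= linear_range[1],
                  .data$conc_uM <= linear_range[2]) |>
    dplyr::group_by(.data$conc_uM) |>
    dplyr::summarise(response = mean(.data$od600), .groups = "drop")
  if (nrow(means) < 2) {
    abort("fewer than 2 standards inside the designated linear range")
  }
  fit_standard_curve(
    data.frame(conc = means$conc_uM, response = means$response),
    detection_floor = floor_od
  )
}

#' Infer GSH-equivalent concentration from final turbidity
#'
#' Inverts the yield-bioassay calibration. Readings below the detection
#' floor are flagged `below_detection`; estimates above the calibration
#' maximum are flagged `above_range`. The point estimate is always reported
#' alongside the flag.
#'
#' @param unknown_od Final OD of the unknown well(s); vectorized.
#' @param curve A curve from [fit_yield_curve()].
#' @return A tibble with columns `od600`, `estimate_uM`, `flag`.
#' @export
infer_gsh_equivalents <- function(unknown_od, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) abort("calibration slope is zero")
  est <- (unknown_od - curve$intercept) / curve$slope
  floor_od <- curve$detection_floor %||% -Inf
  flag <- dplyr::case_when(
    unknown_od < floor_od ~ "below_detection",
    est > curve$valid_range[2] ~ "above_range",
    TRUE ~ "ok"
  )
  tibble(od600 = unknown_od, estimate_uM = est, flag = flag)
}

#' Convert oxidized glutathione to GSH equivalents
#'
#' Reduction of one GS-SG (glutathione disulfide) molecule yields two GSH
#' molecules, so an equimolar GS-SG solution carries twice the
#' GSH-equivalent content.
#'
#' @param conc_gssg GS-SG concentration, uM; non-negative.
#' @return uM GSH equivalents (exactly 2 x `conc_gssg`).
#' @examples
#' gssg_to_equivalents(0.5) # 1.0
#' @export
gssg_to_equivalents <- function(conc_gssg) {
  if (any(conc_gssg < 0)) abort("concentration must be non-negative")
  2 * conc_gssg
}

#' Rate-based bioassay: concentration from tester-strain growth rate
#'
#' Converts a fluorescence growth series into a methionine-equivalent
#' concentration by (1) estimating the maximal growth rate with
#' [max_growth_rate()] and (2) inverting a concentration-to-rate standard
#' curve by monotone piecewise-linear interpolation (no parametric form is
#' assumed). Rates outside the calibrated span are clamped to the nearest
#' endpoint and flagged.
#'
#' @param series A fluorescence series (`time_h`, `norm_intensity`).
#' @param rate_curve A data frame with columns `conc_uM` and
#'   `max_growth_rate` (h^-1); replicates at a concentration are averaged,
#'   after which the curve must be non-decreasing in concentration.
#' @return A one-row tibble: `max_growth_rate`, `estimate_uM`, `flag`
#'   (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
rate_bioassay <- function(series, rate_curve) {
  check_columns(rate_curve, c("conc_uM", "max_growth_rate"), "rate curve")
  curve <- rate_curve |>
    dplyr::group_by(.data$conc_uM) |>
    dplyr::summarise(rate = mean(.data$max_growth_rate), .groups = "drop") |>
    dplyr::arrange(.data$conc_uM)
  if (nrow(curve) < 2) abort("rate curve needs >= 2 concentrations")
  if (any(diff(curve$rate) < 0)) {
    abort("rate curve is not monotone non-decreasing after averaging")
  }
  mu <- max_growth_rate(series)
  flag <- dplyr::case_when(
    mu < min(curve$rate) ~ "below_range",
    mu > max(curve$rate) ~ "above_range",
    TRUE ~ "ok"
  )
  est <- approx(curve$rate, curve$conc_uM, xout = mu, ties = min,
                rule = 2)$y
  tibble(max_growth_rate = mu, estimate_uM = est, flag = flag)
}
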