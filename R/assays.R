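# Linear-calibration utilities for the wet-chemistry assays: peroxide
# value (ferric thiocyanate, 507 nm), total phenolics (Folin-Ciocalteu,
# caffeic-acid equivalents, 750 nm), DPPH radical scavenging (trolox
# equivalents, 517 nm), plus spin-trap dilution and oil-yield arithmetic.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of response on concentration over a set of
#' standards.
#'
#' @param concentration standard concentrations (>= 3 distinct values).
#' @param response measured responses (e.g. absorbance), same length.
#' @param x_unit,y_unit unit tags carried for documentation.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `x_unit`, `y_unit`, `range` (of the standards).
#' @examples
#' linear_calibration(c(0.05, 0.1, 0.2, 0.4), c(0.11, 0.21, 0.40, 0.81))
#' @export
linear_calibration <- function(concentration, response,
                               x_unit = "mg/mL", y_unit = "absorbance") {
  if (length(concentration) != length(response))
    stop("concentration and response lengths differ")
  if (length(concentration) < 3L) stop("at least 3 standards are required")
  if (length(unique(concentration)) < 3L)
    stop("at least 3 distinct concentrations are required")
  fit <- stats::lm(response ~ concentration)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot == 0) {
    warning("responses are constant; R^2 undefined, reported as 0")
    0
  } else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, x_unit = x_unit, y_unit = y_unit,
         range = range(concentration)),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> y = %.4g x %+.4g  (R^2 = %.4f, x in %s [%g, %g])\n",
    x$slope, x$intercept, x$r_squared, x$x_unit, x$range[1], x$range[2]))
  invisible(x)
}

# invert a calibration: response -> concentration
.inverse_cal <- function(curve, response, what = "reading") {
  conc <- (response - curve$intercept) / curve$slope
  lo <- curve$range[1]; hi <- curve$range[2]
  if (any(conc < lo - 1e-12) || any(conc > hi + 1e-12))
    warning(what, " outside the calibration range [",
            lo, ", ", hi, "] ", curve$x_unit)
  conc
}

#' Peroxide value from a ferric-thiocyanate reading
#'
#' Peroxides oxidize Fe(II) to Fe(III) (2 Fe per peroxide; one electron
#' each, so 1 umol Fe(III) = 1 ueq peroxide oxygen); the Fe(III)
#' thiocyanate complex is read at 507 nm against a FeCl3 calibration
#' curve expressed in ug Fe(III).
#'
#' @param abs_sample,abs_blank absorbances of sample and reagent blank.
#' @param curve a [linear_calibration()] mapping ug Fe(III) to absorbance.
#' @param oil_mass oil mass in g, > 0.
#' @return Peroxide value in ueq O2 per g oil.
#' @export
peroxide_value <- function(abs_sample, abs_blank, curve, oil_mass) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(oil_mass) || oil_mass <= 0) stop("oil_mass must be > 0 (g)")
  net <- abs_sample - abs_blank
  if (net == 0) return(0)
  fe_ug <- .inverse_cal(curve, net, "net absorbance")
  ueq <- fe_ug / 55.845  # ug Fe -> umol Fe = ueq peroxide oxygen
  ueq / oil_mass
}

#' Total phenolic concentration from a Folin-Ciocalteu reading
#'
#' The diluted reaction mixture is read at 750 nm against a caffeic-acid
#' calibration (mg/mL).  Default dilution chain: a 0.2 mL aliquot of the
#' phenolic extract brought to a 10 mL final volume.
#'
#' @param abs absorbance of the final reaction mixture.
#' @param curve caffeic-acid [linear_calibration()] (mg/mL vs absorbance).
#' @param extract_volume volume of phenolic extract obtained from the
#'   oil, mL.
#' @param final_volume final reaction volume, mL (default 10).
#' @param aliquot_volume extract aliquot taken into the reaction, mL
#'   (default 0.2).
#' @param oil_mass oil mass extracted, g.
#' @return Total phenolics in mg caffeic acid per g oil.
#' @export
total_phenolics <- function(abs, curve, extract_volume,
                            final_volume = 10, aliquot_volume = 0.2,
                            oil_mass) {
  stopifnot(inherits(curve, "calibration_curve"))
  vols <- c(extract_volume, final_volume, aliquot_volume)
  if (any(!is.finite(vols)) || any(vols <= 0)) stop("volumes must be > 0 (mL)")
  if (!is.finite(oil_mass) || oil_mass <= 0) stop("oil_mass must be > 0 (g)")
  if (abs == curve$intercept) return(0)
  conc <- .inverse_cal(curve, abs, "absorbance")  # mg CA / mL in final mix
  conc * final_volume / aliquot_volume * extract_volume / oil_mass
}

#' DPPH radical scavenging activity in trolox equivalents
#'
#' The inhibition fraction `(abs_control - abs_sample) / abs_control` of
#' the DPPH absorbance at 517 nm is mapped through a trolox standard
#' curve (umol trolox vs inhibition fraction) and normalized by oil mass.
#' Samples absorbing more than the control are clipped to zero inhibition
#' with a warning.
#'
#' @param abs_control absorbance of the DPPH control, > 0.
#' @param abs_sample absorbance after reaction with the oil solution.
#' @param trolox_curve [linear_calibration()] of inhibition on umol
#'   trolox.
#' @param oil_mass oil mass in g.
#' @return RSA in umol trolox per g oil.
#' @export
rsa_dpph <- function(abs_control, abs_sample, trolox_curve, oil_mass) {
  stopifnot(inherits(trolox_curve, "calibration_curve"))
  if (!is.finite(abs_control) || abs_control <= 0)
    stop("abs_control must be > 0")
  if (!is.finite(oil_mass) || oil_mass <= 0) stop("oil_mass must be > 0 (g)")
  inhibition <- (abs_control - abs_sample) / abs_control
  if (inhibition < 0) {
    warning("sample absorbance exceeds control; inhibition clipped to 0")
    inhibition <- 0
  }
  if (inhibition == 0) return(0)
  umol <- .inverse_cal(trolox_curve, inhibition, "inhibition")
  umol / oil_mass
}

#' Final spin-trap concentration after solvent evaporation
#'
#' The PBN stock is dried under nitrogen before the oil is added, so the
#' solute is carried over but the stock volume is not: the final molarity
#' is `stock_volume * stock_conc / oil_volume` (reported in mM).
#'
#' @param stock_volume spin-trap stock volume in uL.
#' @param stock_conc stock concentration in mol/L.
#' @param oil_volume oil volume in uL.
#' @return Final concentration in mM.
#' @examples
#' pbn_final_concentration(5, 2.5, 100)  # 125 mM
#' @export
pbn_final_concentration <- function(stock_volume, stock_conc, oil_volume) {
  if (!is.finite(oil_volume) || oil_volume <= 0)
    stop("oil_volume must be > 0 (uL)")
  if (!is.finite(stock_conc) || stock_conc < 0 ||
      !is.finite(stock_volume) || stock_volume < 0)
    stop("stock volume and concentration must be >= 0")
  1000 * stock_volume * stock_conc / oil_volume
}

#' Gravimetric oil yield
#'
#' @param oil_mass extracted oil mass in g.
#' @param seed_mass seed mass in g; `oil_mass <= seed_mass`.
#' @return Yield as % w/w.
#' @examples
#' oil_yield(9.37, 100)  # 9.37
#' @export
oil_yield <- function(oil_mass, seed_mass) {
  if (!is.finite(seed_mass) || seed_mass <= 0) stop("seed_mass must be > 0")
  if (!is.finite(oil_mass) || oil_mass < 0) stop("oil_mass must be >= 0")
  if (oil_mass > seed_mass) stop("oil mass cannot exceed seed mass")
  100 * oil_mass / seed_mass
}
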