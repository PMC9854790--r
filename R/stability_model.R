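# Empirical oxidative-stability model:
#   AUC / 1e6 = c_PV * PV - |c_TPC| * TPC - |c_FFA| * FFA
# (no intercept; the TPC and FFA coefficients carry negative signs).
# PV feeds radical production, phenolic antioxidants suppress it, and
# free fatty acids are the most oxidation-prone substrate.

#' One oil record: composition, assays, and measured AUC
#'
#' Bundles the per-oil quantities the stability model uses.  Units are
#' fixed: PV in ueq O2/g oil, TPC in mg caffeic acid/g oil, RSA in
#' umol trolox/g oil, FFA and fatty acids in % of total fatty acids,
#' yield in % w/w, AUC in arbitrary units.
#'
#' @param method extraction method, one of `"ME"` (mechanical), `"HX"`
#'   (cold n-hexane), `"2-MeTHF"`, `"EtOAc"`.
#' @param PV peroxide value, >= 0.
#' @param TPC total phenolic concentration, >= 0.
#' @param FFA free fatty acids (%), >= 0.
#' @param AUC_measured measured area under the kinetic curve, or `NA`.
#' @param yield_pct oil yield (% w/w), optional.
#' @param RSA radical scavenging activity, optional.
#' @param fatty_acids named numeric with entries `C16:0`, `C18:0`,
#'   `C18:1`, `C18:2` in %, optional; must sum to <= 100.
#' @param sd named numeric of standard deviations for any of the above
#'   (names like `"PV"`, `"AUC"`), optional.
#' @return An object of class `oil_record`.
#' @export
oil_record <- function(method, PV, TPC, FFA, AUC_measured = NA_real_,
                       yield_pct = NA_real_, RSA = NA_real_,
                       fatty_acids = NULL, sd = NULL) {
  method <- match.arg(method, c("ME", "HX", "2-MeTHF", "EtOAc"))
  for (nm in c("PV", "TPC", "FFA")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0) stop(nm, " must be a non-negative number")
  }
  if (!is.na(AUC_measured) && AUC_measured < 0) stop("AUC must be >= 0")
  if (!is.null(fatty_acids)) {
    if (any(fatty_acids < 0)) stop("fatty-acid percentages must be >= 0")
    if (sum(fatty_acids) > 100) stop("fatty-acid percentages sum to > 100")
  }
  structure(list(method = method, PV = PV, TPC = TPC, FFA = FFA,
                 AUC_measured = AUC_measured, yield_pct = yield_pct,
                 RSA = RSA, fatty_acids = fatty_acids, sd = sd),
            class = "oil_record")
}

#' Coefficients of the no-intercept AUC model
#'
#' On the `AUC / 1e6` scale the published model is
#' `AUC/1e6 = 1.62 * PV - 12.78 * TPC - 2.44 * FFA`; the signs are part
#' of the coefficients.
#'
#' @param c_PV,c_TPC,c_FFA finite multipliers on the AUC/1e6 scale.
#' @return An object of class `stability_coefficients`.
#' @examples
#' published_coefficients()
#' @export
stability_coefficients <- function(c_PV, c_TPC, c_FFA) {
  v <- c(c_PV, c_TPC, c_FFA)
  if (any(!is.finite(v))) stop("coefficients must be finite")
  structure(list(c_PV = c_PV, c_TPC = c_TPC, c_FFA = c_FFA),
            class = "stability_coefficients")
}

#' @rdname stability_coefficients
#' @export
published_coefficients <- function() {
  stability_coefficients(c_PV = 1.62, c_TPC = -12.78, c_FFA = -2.44)
}

#' @export
print.stability_coefficients <- function(x, ...) {
  cat(sprintf("<stability_coefficients> AUC/1e6 = %.4g*PV %+.4g*TPC %+.4g*FFA\n",
              x$c_PV, x$c_TPC, x$c_FFA))
  invisible(x)
}

#' Predict AUC from PV, TPC and FFA
#'
#' @param record an [oil_record()] (PV, TPC, FFA must be present).
#' @param coef a [stability_coefficients()]; defaults to the published
#'   values.
#' @return Predicted AUC in arbitrary units (the model value times 1e6).
#' @examples
#' hx <- oil_record("HX", PV = 99.51, TPC = 0.33, FFA = 3.1)
#' predict_auc(hx)  # ~1.49e8
#' @export
predict_auc <- function(record, coef = published_coefficients()) {
  stopifnot(inherits(record, "oil_record"),
            inherits(coef, "stability_coefficients"))
  vals <- c(record$PV, record$TPC, record$FFA)
  if (any(is.na(vals))) stop("PV, TPC and FFA must all be present")
  1e6 * (coef$c_PV * record$PV + coef$c_TPC * record$TPC +
           coef$c_FFA * record$FFA)
}

#' Fit the no-intercept AUC model to measured records
#'
#' Ordinary least squares of `AUC/1e6` on `(PV, TPC, FFA)` without an
#' intercept.  With exactly three records this is an exact 3x3 linear
#' solve (the model is exactly identified).
#'
#' @param records list of [oil_record()]s with measured AUC, length >= 3.
#' @return A [stability_coefficients()].
#' @export
fit_coefficients <- function(records) {
  if (inherits(records, "oil_record")) records <- list(records)
  if (length(records) < 3L) stop("at least 3 records are required")
  ok <- vapply(records, inherits, logical(1), "oil_record")
  if (!all(ok)) stop("all elements must be oil_record objects")
  X <- t(vapply(records, function(r) c(r$PV, r$TPC, r$FFA), numeric(3)))
  y <- vapply(records, function(r) r$AUC_measured, numeric(1)) / 1e6
  if (any(is.na(y))) stop("every record needs a measured AUC")
  if (qr(X)$rank < 3L) stop("rank-deficient design: PV/TPC/FFA are collinear")
  beta <- qr.coef(qr(X), y)
  stability_coefficients(beta[1], beta[2], beta[3])
}

#' Residual diagnostics of the AUC model
#'
#' Compares predicted and measured AUC per record and flags records whose
#' absolute error exceeds 3 printed standard deviations of the measured
#' AUC — the published model holds for solvent-extracted oils but fails
#' for the mechanically pressed one.
#'
#' @param records list of [oil_record()]s with measured AUC.
#' @param coef a [stability_coefficients()].
#' @return A data frame with columns `method`, `predicted`, `measured`,
#'   `delta`, `sd`, `delta_over_sd`, `flagged`.
#' @export
model_residuals <- function(records, coef = published_coefficients()) {
  if (inherits(records, "oil_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    pred <- predict_auc(r, coef)
    meas <- r$AUC_measured
    s <- if (!is.null(r$sd) && "AUC" %in% names(r$sd)) r$sd[["AUC"]] else NA_real_
    d <- pred - meas
    data.frame(method = r$method, predicted = pred, measured = meas,
               delta = d, sd = s,
               delta_over_sd = abs(d) / s,
               flagged = is.finite(s) && abs(d) > 3 * s)
  })
  do.call(rbind, rows)
}

#' Saturated to polyunsaturated fatty-acid ratio
#'
#' `(C16:0 + C18:0) / C18:2` — palmitic plus stearic over linoleic, the
#' sole polyunsaturated fatty acid quantified in these oils.  For myrtle
#' seed oils the ratio is about 0.14 regardless of extraction method.
#'
#' @param record an [oil_record()] whose `fatty_acids` include `C16:0`,
#'   `C18:0` and `C18:2`.
#' @return Dimensionless ratio.
#' @export
sfa_pufa_ratio <- function(record) {
  stopifnot(inherits(record, "oil_record"))
  fa <- record$fatty_acids
  need <- c("C16:0", "C18:0", "C18:2")
  if (is.null(fa) || !all(need %in% names(fa)))
    stop("fatty_acids must include C16:0, C18:0 and C18:2")
  if (fa[["C18:2"]] <= 0) stop("PUFA (C18:2) is zero; ratio undefined")
  (fa[["C16:0"]] + fa[["C18:0"]]) / fa[["C18:2"]]
}
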