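# Quantification of first-derivative EPR spectra: baseline correction,
# double integration, and least-squares unmixing into component species.

#' Polynomial baseline correction using the spectrum wings
#'
#' Fits a polynomial of the given order to the outer 10% of points on each
#' side of the sweep (assumed signal-free) and subtracts it from the whole
#' trace.  The field axis is unchanged.
#'
#' @param spectrum an `epr_spectrum`.
#' @param order polynomial order, one of 0, 1, 2.
#' @return The corrected spectrum.
#' @export
baseline_correct <- function(spectrum, order = 1L) {
  .check_spectrum(spectrum)
  order <- as.integer(order)
  if (is.na(order) || !(order %in% 0:2))
    stop("baseline order must be 0, 1 or 2")
  n <- length(spectrum$field)
  k <- max(1L, floor(0.1 * n))
  wing <- c(seq_len(k), seq(n - k + 1L, n))
  # centered Vandermonde basis for numerical stability
  xc <- spectrum$field - mean(spectrum$field)
  basis <- outer(xc, 0:order, `^`)
  fit <- stats::lm.fit(basis[wing, , drop = FALSE], spectrum$intensity[wing])
  spectrum$intensity <- spectrum$intensity - drop(basis %*% fit$coefficients)
  spectrum
}

#' Double integral of a first-derivative EPR spectrum
#'
#' Integrates the derivative trace once (trapezoids) to recover the
#' absorption profile, then integrates the absorption to obtain the total
#' area, which is proportional to the radical-adduct concentration.
#' No wing extrapolation is performed.
#'
#' @param spectrum an `epr_spectrum` on a uniform field axis.
#' @return The double integral (arbitrary units).
#' @examples
#' sp <- simulate_spectrum(spin_system("a", 2.0057, 14.9, 2.48, weight = 2),
#'                         acquisition_settings(sweep_width = 120))
#' double_integrate(sp)  # ~2
#' @export
double_integrate <- function(spectrum) {
  .check_spectrum(spectrum)
  h <- mean(diff(spectrum$field))
  absorption <- .cumtrapz(spectrum$intensity, h)
  .trapz(absorption, h)
}

.cumtrapz <- function(y, h) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * h))
}
.trapz <- function(y, h) {
  n <- length(y)
  sum((y[-1] + y[-n]) / 2 * h)
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
# Small dense problems only (a handful of candidate species).
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Decompose a spectrum into non-negative fractions of candidate species
#'
#' Each candidate spin system is simulated at unit weight on the field
#' axis of the input spectrum (same microwave frequency, no noise), and
#' the observed intensity is decomposed by non-negative least squares.
#' Because the bases are unit-weight (unit double integral), the fitted
#' coefficients are double-integral contributions; they are normalized to
#' fractions summing to one.
#'
#' @param spectrum an `epr_spectrum`.
#' @param candidates a list of [spin_system()] candidates (their `weight`
#'   fields are ignored).
#' @return An object of class `decomposition_result`: list with `weights`
#'   (named non-negative fractions summing to 1), `coefficients` (raw
#'   double-integral contributions) and `residual_norm` (fraction of the
#'   total signal power left unexplained, in `[0, 1]`).
#' @examples
#' mix <- simulate_spectrum(pbn_adducts(), acquisition_settings())
#' decompose_spectrum(mix, pbn_adducts())$weights
#' @export
decompose_spectrum <- function(spectrum, candidates) {
  .check_spectrum(spectrum)
  if (inherits(candidates, "spin_system")) candidates <- list(candidates)
  if (!is.list(candidates) || length(candidates) == 0L)
    stop("candidate list must be non-empty")

  st <- spectrum$meta
  basis_settings <- acquisition_settings(
    microwave_frequency = st$microwave_frequency,
    center_field = st$center_field,
    sweep_width = st$sweep_width,
    n_points = st$n_points,
    noise_sd = 0
  )
  A <- vapply(candidates, function(sys) {
    sys$weight <- 1
    base <- suppressWarnings(simulate_spectrum(sys, basis_settings))
    if (max(abs(base$field - spectrum$field)) > 1e-6)
      base$intensity <- stats::approx(base$field, base$intensity,
                                      xout = spectrum$field, rule = 2)$y
    base$intensity
  }, numeric(length(spectrum$field)))

  # collinearity guard: name the offending pair
  if (ncol(A) > 1L) {
    cc <- stats::cor(A)
    diag(cc) <- 0
    if (any(abs(cc) > 1 - 1e-10)) {
      idx <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
      stop("collinear candidate basis: '",
           candidates[[idx[1]]]$label, "' vs '",
           candidates[[idx[2]]]$label, "'")
    }
  }
  if (qr(A)$rank < ncol(A)) stop("singular candidate basis")

  coefs <- .nnls(A, spectrum$intensity)
  names(coefs) <- vapply(candidates, `[[`, character(1), "label")
  total <- sum(coefs)
  if (total <= 0) stop("decomposition found no signal: all weights zero")
  resid <- spectrum$intensity - drop(A %*% coefs)
  structure(
    list(weights = coefs / total,
         coefficients = coefs,
         residual_norm = min(1, sum(resid^2) / sum(spectrum$intensity^2))),
    class = "decomposition_result"
  )
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("<decomposition_result>\n")
  for (nm in names(x$weights))
    cat(sprintf("  %-16s %6.2f %%\n", nm, 100 * x$weights[[nm]]))
  cat(sprintf("  residual_norm    %.3g\n", x$residual_norm))
  invisible(x)
}
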