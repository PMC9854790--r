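# Isotropic first-derivative EPR simulation of nitroxide spin adducts.
#
# A PBN (or MNP) spin adduct gives a nitrogen triplet (m_N = -1, 0, +1)
# split by a beta-hydrogen doublet (m_H = -1/2, +1/2): six lines of equal
# intrinsic intensity.  Line positions are first-order:
#   B = B0 + m_N * a_N + m_H * a_H
# and B0 follows from the electron Zeeman condition h*nu = g*muB*B0.

# CODATA 2018 constants
.PLANCK_H <- 6.62607015e-34   # J s
.BOHR_MUB <- 9.2740100783e-24 # J / T

#' Describe one nitroxide spin-adduct species
#'
#' A spin system holds the isotropic spin-Hamiltonian parameters of one
#' persistent nitroxide radical adduct: its g-factor, the nitrogen and
#' beta-hydrogen hyperfine coupling constants, a peak-to-peak derivative
#' linewidth, the lineshape model, and a relative weight (the fraction of
#' total double-integral intensity this species contributes in a mixture).
#'
#' @param label character tag for the species.
#' @param g dimensionless g-factor; must lie in (1.9, 2.1) for an organic
#'   radical.
#' @param a_N nitrogen hyperfine constant in gauss, > 0.
#' @param a_H beta-hydrogen hyperfine constant in gauss, >= 0 (0 collapses
#'   the doublet).
#' @param linewidth_pp peak-to-peak first-derivative linewidth in gauss.
#' @param lineshape one of `"lorentzian"`, `"gaussian"`, `"pseudo-voigt"`.
#' @param eta Lorentzian mixing fraction in `[0, 1]`, used only for
#'   `"pseudo-voigt"`.
#' @param weight non-negative relative double-integral fraction.
#'
#' @return An object of class `spin_system`.
#' @examples
#' spin_system("PBN-adduct-1", g = 2.00573, a_N = 14.90, a_H = 2.48)
#' @export
spin_system <- function(label, g, a_N, a_H,
                        linewidth_pp = 1.5,
                        lineshape = c("lorentzian", "gaussian", "pseudo-voigt"),
                        eta = 0.5,
                        weight = 1) {
  lineshape <- match.arg(lineshape)
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.finite(g) || g <= 1.9 || g >= 2.1)
    stop("g-factor must lie in (1.9, 2.1); got ", g)
  if (!is.finite(a_N) || a_N <= 0) stop("a_N must be > 0 (gauss)")
  if (!is.finite(a_H) || a_H < 0) stop("a_H must be >= 0 (gauss)")
  if (!is.finite(linewidth_pp) || linewidth_pp <= 0)
    stop("linewidth_pp must be > 0 (gauss)")
  if (!is.finite(weight) || weight < 0) stop("weight must be >= 0")
  if (lineshape == "pseudo-voigt" && (eta < 0 || eta > 1))
    stop("eta must lie in [0, 1]")
  structure(
    list(label = label, g = g, a_N = a_N, a_H = a_H,
         linewidth_pp = linewidth_pp, lineshape = lineshape,
         eta = eta, weight = weight),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf(
    "<spin_system> %s: g = %.5f, a_N = %.2f G, a_H = %.2f G, lw = %.2f G (%s), weight = %g\n",
    x$label, x$g, x$a_N, x$a_H, x$linewidth_pp, x$lineshape, x$weight))
  invisible(x)
}

#' The two persistent PBN adducts observed in heated myrtle seed oil
#'
#' Returns the pair of spin systems seen throughout the thermal treatment
#' of myrtle seed oil at 90 degC: the dominant adduct (65% of the radical
#' double-integral intensity; a_N 14.90 G, a_H 2.48 G, g 2.00573) and the
#' minor adduct (35%; a_N 14.70 G, a_H 2.88 G, g 2.00573).  Linewidths are
#' not reported for these species; the package default (1.5 G) is used.
#'
#' @param weights length-2 non-negative numeric, double-integral fractions
#'   of the two species (default `c(0.65, 0.35)`).
#' @param linewidth_pp peak-to-peak linewidth in gauss applied to both.
#' @return A list of two `spin_system` objects.
#' @examples
#' pbn_adducts()
#' @export
pbn_adducts <- function(weights = c(0.65, 0.35), linewidth_pp = 1.5) {
  stopifnot(length(weights) == 2L, all(weights >= 0))
  list(
    spin_system("PBN-adduct-1", g = 2.00573, a_N = 14.90, a_H = 2.48,
                linewidth_pp = linewidth_pp, weight = weights[1]),
    spin_system("PBN-adduct-2", g = 2.00573, a_N = 14.70, a_H = 2.88,
                linewidth_pp = linewidth_pp, weight = weights[2])
  )
}

#' Acquisition settings for a simulated EPR sweep
#'
#' @param microwave_frequency microwave frequency in GHz (X band ~ 9.4).
#' @param center_field center of the sweep in gauss; `NULL` places it at
#'   the resonance field of the first spin system.
#' @param sweep_width width of the sweep in gauss.
#' @param n_points number of field points (>= 2).
#' @param modulation_amplitude modulation amplitude in mT.  Carried as
#'   metadata only; modulation broadening is not modeled.
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   intensity units (0 = deterministic).
#' @param seed integer seed; required when `noise_sd > 0`.
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(microwave_frequency = 9.4,
                                 center_field = NULL,
                                 sweep_width = 100,
                                 n_points = 1024L,
                                 modulation_amplitude = 0.106,
                                 noise_sd = 0,
                                 seed = NULL) {
  if (!is.finite(microwave_frequency) || microwave_frequency <= 0)
    stop("microwave_frequency must be > 0 (GHz)")
  if (!is.finite(sweep_width) || sweep_width <= 0)
    stop("sweep_width must be > 0 (gauss)")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) stop("n_points must be >= 2")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd > 0 && is.null(seed))
    stop("an explicit integer seed is required when noise_sd > 0")
  structure(
    list(microwave_frequency = microwave_frequency,
         center_field = center_field, sweep_width = sweep_width,
         n_points = n_points, modulation_amplitude = modulation_amplitude,
         noise_sd = noise_sd, seed = seed, window_warning = FALSE),
    class = "acquisition_settings"
  )
}

#' Resonance field of a g-value at a given microwave frequency
#'
#' Computes the electron Zeeman resonance condition `B0 = h * nu / (g * muB)`
#' and returns the field in gauss (1 T = 1e4 G), using CODATA 2018 values
#' of the Planck constant and the Bohr magneton.
#'
#' @param g dimensionless g-factor, > 0.
#' @param frequency microwave frequency in GHz, > 0.
#' @return Resonance field in gauss.
#' @examples
#' resonance_center(2.00573, 9.4)
#' @export
resonance_center <- function(g, frequency) {
  if (!all(is.finite(g)) || any(g <= 0)) stop("g must be > 0")
  if (!all(is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be > 0 (GHz)")
  1e4 * .PLANCK_H * frequency * 1e9 / (g * .BOHR_MUB)
}

#' First-order hyperfine line positions of a nitroxide adduct
#'
#' The six allowed transitions of the nitrogen triplet x beta-hydrogen
#' doublet sit at `center + m_N * a_N + m_H * a_H` for
#' `m_N` in `{-1, 0, +1}` and `m_H` in `{-1/2, +1/2}`, all with equal
#' intrinsic amplitude (1:1:1 triplet times 1:1 doublet).
#'
#' @param system a [spin_system()].
#' @param center center field in gauss (usually the resonance field).
#' @return A data frame with columns `field` (gauss, sorted increasing)
#'   and `amplitude` (relative, each 1/6).
#' @examples
#' sys <- spin_system("a1", g = 2.00573, a_N = 14.90, a_H = 2.48)
#' line_positions(sys, resonance_center(sys$g, 9.4))
#' @export
line_positions <- function(system, center) {
  stopifnot(inherits(system, "spin_system"), is.finite(center))
  grid <- expand.grid(m_N = c(-1, 0, 1), m_H = c(-0.5, 0.5))
  field <- center + grid$m_N * system$a_N + grid$m_H * system$a_H
  out <- data.frame(field = field, amplitude = rep(1 / 6, 6L))
  out[order(out$field), , drop = FALSE]
}

# Unit-area absorption lineshapes and their first derivatives, expressed
# in terms of the peak-to-peak derivative linewidth dBpp:
#   Lorentzian: HWHM  Gamma = sqrt(3)/2 * dBpp
#   Gaussian:   sigma = dBpp / 2
.deriv_lorentzian <- function(x, dBpp) {
  gam <- sqrt(3) / 2 * dBpp
  -(2 / pi) * gam * x / (gam^2 + x^2)^2
}
.deriv_gaussian <- function(x, dBpp) {
  sig <- dBpp / 2
  -x / (sig^3 * sqrt(2 * pi)) * exp(-x^2 / (2 * sig^2))
}
.deriv_lineshape <- function(x, dBpp, lineshape, eta) {
  switch(lineshape,
    lorentzian = .deriv_lorentzian(x, dBpp),
    gaussian = .deriv_gaussian(x, dBpp),
    `pseudo-voigt` = eta * .deriv_lorentzian(x, dBpp) +
      (1 - eta) * .deriv_gaussian(x, dBpp),
    stop("unknown lineshape: ", lineshape)
  )
}

#' Simulate a first-derivative EPR spectrum of one or more spin systems
#'
#' Each species contributes six first-derivative lines of equal intrinsic
#' amplitude at its hyperfine positions; each species' total double
#' integral is proportional to its `weight` (a unit-weight species has
#' double integral 1 on a sufficiently wide window).  Additive Gaussian
#' noise of standard deviation `noise_sd` is drawn reproducibly from
#' `seed`.
#'
#' If the sweep window does not extend at least 10 linewidths past the
#' outermost line a warning is raised and `meta$window_warning` is set.
#'
#' @param systems a single [spin_system()] or a list of them.
#' @param settings an [acquisition_settings()].
#' @return An object of class `epr_spectrum`: list with `field` (gauss),
#'   `intensity` (arbitrary units, first-derivative convention) and
#'   `meta` (the settings, with `center_field` resolved).
#' @examples
#' sp <- simulate_spectrum(pbn_adducts(), acquisition_settings())
#' @export
simulate_spectrum <- function(systems, settings = acquisition_settings()) {
  if (inherits(systems, "spin_system")) systems <- list(systems)
  if (!is.list(systems) || length(systems) == 0L)
    stop("at least one spin system is required")
  ok <- vapply(systems, inherits, logical(1), what = "spin_system")
  if (!all(ok)) stop("all elements of 'systems' must be spin_system objects")
  stopifnot(inherits(settings, "acquisition_settings"))

  center <- settings$center_field
  if (is.null(center))
    center <- resonance_center(systems[[1]]$g, settings$microwave_frequency)
  settings$center_field <- center

  field <- seq(center - settings$sweep_width / 2,
               center + settings$sweep_width / 2,
               length.out = settings$n_points)

  intensity <- numeric(settings$n_points)
  all_pos <- numeric(0)
  max_lw <- 0
  for (sys in systems) {
    b0 <- resonance_center(sys$g, settings$microwave_frequency)
    lines <- line_positions(sys, b0)
    all_pos <- c(all_pos, lines$field)
    max_lw <- max(max_lw, sys$linewidth_pp)
    for (i in seq_len(nrow(lines))) {
      intensity <- intensity + sys$weight * lines$amplitude[i] *
        .deriv_lineshape(field - lines$field[i], sys$linewidth_pp,
                         sys$lineshape, sys$eta)
    }
  }

  if (min(all_pos) - 10 * max_lw < field[1] ||
      max(all_pos) + 10 * max_lw > field[length(field)]) {
    warning("sweep window does not cover all lines plus 10 linewidths; ",
            "double integrals will be truncated")
    settings$window_warning <- TRUE
  }

  spec <- structure(list(field = field, intensity = intensity,
                         meta = settings),
                    class = "epr_spectrum")
  if (settings$noise_sd > 0)
    spec <- add_noise(spec, settings$noise_sd, settings$seed)
  spec
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<epr_spectrum> %d points, %.1f-%.1f G, nu = %.3f GHz, max |I| = %.3g\n",
    length(x$field), min(x$field), max(x$field),
    x$meta$microwave_frequency, max(abs(x$intensity))))
  invisible(x)
}

#' Add reproducible Gaussian noise to a spectrum
#'
#' @param spectrum an `epr_spectrum`.
#' @param sd noise standard deviation in intensity units, >= 0.
#' @param seed integer seed; the same seed and inputs give bitwise
#'   identical output.  Global RNG state is left untouched.
#' @return The noisy spectrum (`sd = 0` returns the input unchanged).
#' @export
add_noise <- function(spectrum, sd, seed) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  if (!is.finite(sd) || sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(spectrum)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(spectrum$intensity), 0, sd))
  spectrum$intensity <- spectrum$intensity + noise
  spectrum
}

# validate the epr_spectrum container invariants; used by readers
.check_spectrum <- function(spec) {
  stopifnot(inherits(spec, "epr_spectrum"))
  if (length(spec$field) != length(spec$intensity))
    stop("field and intensity lengths differ")
  d <- diff(spec$field)
  if (any(d <= 0)) stop("field axis must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * mean(d))
    stop("field axis must be uniformly spaced")
  invisible(spec)
}
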