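# Spectrum simulation: resonance condition, hyperfine line positions,
# lineshape areas, superposition, and noise contract.

test_that("resonance_center matches the CODATA h*nu/(g*muB) oracle", {
  # frozen oracle values: 1e4 * 6.62607015e-34 * nu / (g * 9.2740100783e-24)
  expect_equal(resonance_center(2.0023193, 9.4), 3354.154, tolerance = 1e-6)
  expect_equal(resonance_center(2.00573, 9.4), 3348.450, tolerance = 1e-6)
  # linear in frequency
  expect_equal(resonance_center(2.00573, 18.8) / resonance_center(2.00573, 9.4),
               2, tolerance = 1e-12)
  expect_error(resonance_center(-2, 9.4), "g must be")
  expect_error(resonance_center(2, 0), "frequency")
})

test_that("line_positions give the 3x2 first-order pattern", {
  sys <- spin_system("a1", g = 2.00573, a_N = 14.90, a_H = 2.48)
  lp <- line_positions(sys, 3348.2)
  expect_equal(nrow(lp), 6L)
  expect_false(is.unsorted(lp$field, strictly = TRUE))
  # outermost span = 2 a_N + a_H
  expect_equal(max(lp$field) - min(lp$field), 2 * 14.90 + 2.48)
  # symmetric about the center, equal amplitudes
  expect_equal(mean(lp$field), 3348.2)
  expect_equal(lp$amplitude, rep(1 / 6, 6))
})

test_that("a_H = 0 collapses the doublet to 3 doubly degenerate fields", {
  sys <- spin_system("deg", g = 2.0057, a_N = 15, a_H = 0)
  lp <- line_positions(sys, 3000)
  expect_equal(length(unique(lp$field)), 3L)
  expect_equal(as.vector(table(lp$field)), rep(2L, 3L))
})

test_that("single-line derivative spectrum is antisymmetric about its center", {
  sys <- spin_system("one", g = 2.0057, a_N = 14.9, a_H = 0)
  # isolate the central line (m_N = 0) by symmetry of the full pattern:
  # simulate a single resonance by setting a_N tiny is not allowed, so
  # check antisymmetry of the whole pattern about the resonance center
  st <- acquisition_settings(sweep_width = 120, n_points = 1025)
  sp <- simulate_spectrum(sys, st)
  center <- resonance_center(sys$g, st$microwave_frequency)
  i0 <- which.min(abs(sp$field - center))
  k <- min(i0 - 1L, length(sp$field) - i0)
  left <- sp$intensity[i0 - seq_len(k)]
  right <- sp$intensity[i0 + seq_len(k)]
  expect_equal(left, -right, tolerance = 1e-9)
})

test_that("intensity is linear in the species weights", {
  st <- acquisition_settings(sweep_width = 120)
  base <- simulate_spectrum(pbn_adducts(), st)
  for (k in c(2, 5)) {
    scaled <- simulate_spectrum(pbn_adducts(weights = k * c(0.65, 0.35)), st)
    expect_equal(scaled$intensity, k * base$intensity, tolerance = 1e-12)
  }
})

test_that("a mixture spectrum is the sum of its single-species spectra", {
  st <- acquisition_settings(sweep_width = 120)
  systems <- pbn_adducts()
  mix <- simulate_spectrum(systems, st)
  # single-species sweeps must share the mixture's field axis
  st1 <- acquisition_settings(center_field = mix$meta$center_field,
                              sweep_width = 120)
  s1 <- simulate_spectrum(systems[[1]], st1)
  s2 <- simulate_spectrum(systems[[2]], st1)
  expect_equal(mix$intensity, s1$intensity + s2$intensity, tolerance = 1e-12)
})

test_that("line pattern is invariant under hyperfine sign conventions", {
  # flipping the signs of m_N and m_H relabels the same six transitions
  sys <- spin_system("s", g = 2.0057, a_N = 14.9, a_H = 2.48)
  lp <- line_positions(sys, 3348)
  flipped <- 3348 - (lp$field - 3348)
  expect_equal(sort(lp$field), sort(flipped))
})

test_that("unit-weight double integral: exact for Gaussian, truncated-area
           oracle for Lorentzian", {
  st <- acquisition_settings(sweep_width = 120)
  # Gaussian: ±10 linewidths is ±20 sigma, total area to machine precision
  gau <- simulate_spectrum(
    spin_system("g", 2.0057, 14.9, 2.48, lineshape = "gaussian"), st)
  expect_equal(double_integrate(gau), 1, tolerance = 1e-3)
  # Lorentzian tails hold ~5% of the area outside any realistic sweep;
  # oracle = analytic area of the truncated lineshape, averaged over the
  # six line positions
  lor <- simulate_spectrum(spin_system("l", 2.0057, 14.9, 2.48), st)
  gam <- sqrt(3) / 2 * 1.5
  b0 <- resonance_center(2.0057, 9.4)
  pos <- line_positions(spin_system("l", 2.0057, 14.9, 2.48), b0)$field
  lo <- b0 - 60; hi <- b0 + 60
  # the windowed double integral of the derivative equals the truncated
  # absorption area minus the (small) absorption at the window edge
  trunc_area <- mean((atan((hi - pos) / gam) - atan((lo - pos) / gam)) / pi)
  edge <- mean(gam / (gam^2 + (lo - pos)^2) / pi)
  expect_equal(double_integrate(lor), trunc_area - edge * (hi - lo),
               tolerance = 1e-3)
})

test_that("noise is reproducible, honest about its sd, and optional", {
  st <- acquisition_settings(sweep_width = 120)
  clean <- simulate_spectrum(pbn_adducts(), st)
  expect_identical(add_noise(clean, 0, 1), clean)
  n1 <- add_noise(clean, 1, 123)
  n2 <- add_noise(clean, 1, 123)
  expect_identical(n1$intensity, n2$intensity)
  expect_equal(sd(n1$intensity - clean$intensity), 1, tolerance = 0.1)
  expect_error(add_noise(clean, -1, 1), "sd")
})

test_that("narrow windows warn and flag; bad inputs error", {
  expect_warning(
    sp <- simulate_spectrum(pbn_adducts(),
                            acquisition_settings(sweep_width = 40)),
    "window")
  expect_true(sp$meta$window_warning)
  expect_error(simulate_spectrum(list(), acquisition_settings()), "at least one")
  expect_error(spin_system("bad", g = 2.5, a_N = 14, a_H = 2), "g-factor")
  expect_error(spin_system("bad", g = 2.0, a_N = -1, a_H = 2), "a_N")
  expect_error(acquisition_settings(noise_sd = 1), "seed")
})
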