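# Quantification: baseline correction, double integration, NNLS unmixing.

test_that("baseline correction removes polynomial offsets exactly", {
  # Gaussian lineshape so the wings are genuinely signal-free
  sp <- simulate_spectrum(
    spin_system("g", 2.0057, 14.9, 2.48, lineshape = "gaussian"),
    acquisition_settings(sweep_width = 120))
  plus_const <- sp; plus_const$intensity <- sp$intensity + 5
  expect_equal(baseline_correct(plus_const, 0)$intensity, sp$intensity,
               tolerance = 1e-6)
  ramp <- sp; ramp$intensity <- sp$intensity + 2 + 0.03 * (sp$field - 3300)
  expect_equal(baseline_correct(ramp, 1)$intensity, sp$intensity,
               tolerance = 1e-6)
  expect_error(baseline_correct(sp, 3), "order")
})

test_that("baseline correction is idempotent", {
  sp <- simulate_spectrum(pbn_adducts(), acquisition_settings(sweep_width = 120))
  sp$intensity <- sp$intensity + 1 + 0.01 * sp$field
  once <- baseline_correct(sp, 2)
  twice <- baseline_correct(once, 2)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-9)
})

test_that("double integral is zero for silence, linear and additive", {
  st <- acquisition_settings(sweep_width = 120)
  zero <- simulate_spectrum(pbn_adducts(weights = c(0, 0)), st)
  expect_equal(double_integrate(zero), 0)

  di <- vapply(c(1, 2, 5), function(w) {
    double_integrate(simulate_spectrum(
      spin_system("w", 2.0057, 14.9, 2.48, weight = w), st))
  }, numeric(1))
  expect_equal(di[2] / di[1], 2, tolerance = 1e-6)
  expect_equal(di[3] / di[1], 5, tolerance = 1e-6)

  systems <- pbn_adducts()
  st1 <- acquisition_settings(center_field = resonance_center(2.00573, 9.4),
                              sweep_width = 120)
  mix <- simulate_spectrum(systems, st1)
  parts <- sum(vapply(systems, function(s)
    double_integrate(simulate_spectrum(s, st1)), numeric(1)))
  expect_equal(double_integrate(mix), parts, tolerance = 1e-9)
})

test_that("double integral is linear in weight with R^2 ~ 1", {
  st <- acquisition_settings(sweep_width = 120)
  w <- c(0.5, 1, 2, 3, 5)
  di <- vapply(w, function(wi) double_integrate(simulate_spectrum(
    pbn_adducts(weights = wi * c(0.65, 0.35)), st)), numeric(1))
  fit <- lm(di ~ w)
  r2 <- 1 - sum(residuals(fit)^2) / sum((di - mean(di))^2)
  expect_gt(r2, 1 - 1e-9)
})

test_that("noiseless decomposition recovers generation weights exactly", {
  st <- acquisition_settings(sweep_width = 120)
  for (w1 in c(0.2, 0.5, 0.65, 0.9)) {
    mix <- simulate_spectrum(pbn_adducts(weights = c(w1, 1 - w1)), st)
    res <- decompose_spectrum(mix, pbn_adducts())
    expect_equal(unname(res$weights), c(w1, 1 - w1), tolerance = 1e-6)
    expect_equal(sum(res$weights), 1, tolerance = 1e-9)
  }
})

test_that("self-decomposition gives weight 1 and ~zero residual", {
  st <- acquisition_settings(sweep_width = 120)
  sys <- spin_system("solo", 2.00573, 14.90, 2.48, weight = 3)
  sp <- simulate_spectrum(sys, st)
  res <- decompose_spectrum(sp, list(sys))
  expect_equal(unname(res$weights), 1)
  expect_lt(res$residual_norm, 1e-9)
})

test_that("the 65:35 mixture is recovered under 1% noise", {
  st0 <- acquisition_settings(sweep_width = 120)
  clean <- simulate_spectrum(pbn_adducts(), st0)
  noisy <- add_noise(clean, 0.01 * max(abs(clean$intensity)), seed = 11)
  res <- decompose_spectrum(noisy, pbn_adducts())
  expect_equal(unname(res$weights[1]), 0.65, tolerance = 0.02 / 0.65)
  expect_lt(abs(res$weights[1] - 0.65), 0.02)
})

test_that("an absent transient species gets (near) zero weight", {
  st0 <- acquisition_settings(sweep_width = 120)
  clean <- simulate_spectrum(pbn_adducts(), st0)
  noisy <- add_noise(clean, 0.01 * max(abs(clean$intensity)), seed = 12)
  res <- decompose_spectrum(noisy, c(pbn_adducts(), list(mnp_adduct())))
  expect_lt(unname(res$weights[3]), 0.02)
})

test_that("residual_norm decreases as the true basis is completed", {
  st0 <- acquisition_settings(sweep_width = 120)
  mix <- simulate_spectrum(pbn_adducts(), st0)
  partial <- decompose_spectrum(mix, pbn_adducts()[1])
  full <- decompose_spectrum(mix, pbn_adducts())
  expect_lt(full$residual_norm, partial$residual_norm)
})

test_that("collinear candidates are reported by name", {
  st0 <- acquisition_settings(sweep_width = 120)
  mix <- simulate_spectrum(pbn_adducts(), st0)
  a <- spin_system("twin-A", 2.00573, 14.90, 2.48)
  b <- spin_system("twin-B", 2.00573, 14.90, 2.48)
  expect_error(decompose_spectrum(mix, list(a, b)), "twin-[AB].*twin-[AB]")
})
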