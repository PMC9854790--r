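---
title: "Methods: EPR spin-trapping oxidative stability of seed oils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EPR spin-trapping oxidative stability of seed oils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxistab)
```

## Scope and model

`oxistab` analyzes the thermal oxidative stability of bulk seed oils as
measured by PBN spin trapping. The chain is:

1. **Spectrum model** (`spin_sim`). An isotropic nitroxide adduct gives
   six first-order lines at `B0 + m_N a_N + m_H a_H`
   (`m_N ∈ {−1,0,1}`, `m_H ∈ {−½,½}`), all of equal intrinsic
   amplitude, with `B0 = hν/(gμ_B)` from CODATA 2018 constants. Each
   line is the first derivative of a unit-area lineshape; a species of
   weight *w* contributes total double integral *w*. Superposition is
   exact, so mixtures are sums of single-species spectra.
2. **Quantification** (`spin_quant`). Wing-based polynomial baseline
   correction; trapezoidal double integration (derivative → absorption →
   area), which is the concentration-proportional readout; and
   non-negative least-squares unmixing against unit-weight simulated
   bases, with the fitted coefficients read directly as double-integral
   fractions.
3. **Kinetics** (`kinetics`). Adduct intensity vs time is summarized by
   the 4-parameter Boltzmann sigmoid
   `I(t) = I1 + (I2−I1)/(1+exp((t0−t)/dt))` with induction period
   `IP = t0 − 2 dt` (intersection of the inflection tangent with the
   initial plateau), and by the trapezoidal AUC of the **raw** series —
   larger AUC, less stable oil.
4. **Stability model** (`stability_model`). The no-intercept empirical
   relation `AUC/10⁶ = c_PV·PV + c_TPC·TPC + c_FFA·FFA` with published
   coefficients (1.62, −12.78, −2.44). The signs encode the chemistry:
   peroxides feed radical production, phenolic antioxidants quench it,
   free fatty acids are the most oxidizable substrate. With three
   records the fit is an exact linear solve (the model is exactly
   identified), which is how the coefficients are audited.
5. **Assays** (`assays`) and **chemometrics** (`chemometrics`), below.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `linewidth_pp` | 1.5 | G | typical peak-to-peak width of solution nitroxide adducts; not reported for these species, so it is a package choice, applied to every species unless overridden |
| `lineshape` | lorentzian | — | solution-state nitroxides are near-Lorentzian; `gaussian` and `pseudo-voigt(η)` selectable |
| `sweep_width` | 100 | G | covers the ~32 G six-line span; 120 G is used throughout the tests to keep ≥10 linewidths of margin |
| `n_points` | 1024 | — | the instrument resolution of the emulated acquisition |
| `microwave_frequency` | 9.4 | GHz | X band |
| `modulation_amplitude` | 0.106 | mT | **metadata only** — modulation broadening is not modeled |
| Boltzmann `dt` bounds | [0.1, 500] | min | below the sampling step / far beyond the observation window |
| flag threshold | 3·SD | — | a record whose model error exceeds 3 printed SDs of its measured AUC is flagged; the source work states the failure qualitatively, the threshold is ours |
| Pareto block weight | 1 | — | assay columns are scaled like any feature; a scalar block weight is exposed but unweighted fusion is the default |

Field values are gauss internally; mT inputs are converted with ×10 at
the I/O boundary.

## Numerical choices

**Boltzmann fitting.** The two plateaus enter the model linearly, so
they are profiled out exactly (a 2-column least squares per candidate
`(t0, dt)`, with `I1` clipped at 0 and refit on the boundary) and only
`(t0, dt)` are optimized by bounded L-BFGS-B from a deterministic 5×2
start grid (five `t0` quantiles × two `dt` scales), lowest RSS winning.
A joint 4-parameter bounded Gauss–Newton fit was tried first and failed
with singular gradients on steep sigmoids (the two plateau columns of
the Jacobian sum to one); the profiled form converged in every cell of
the recovery grid. A series is declared non-sigmoidal
(`converged = FALSE`, never an error) when (a) no start converges, (b)
`dt` escapes to ≥95% of its upper bound — the curve is effectively
linear over the window, (c) the plateaus invert, or (d) the series has
an interior maximum with a final value below 75% of the smoothed
maximum — the rise-then-decay shape of mechanically pressed oil, for
which the monotone sigmoid has no meaningful induction period. AUC is
still computed for such series; fitting a double sigmoid is out of
scope.

**Lorentzian truncation.** A Lorentzian has heavy tails: ±10 linewidths
(±15 G at the default width) still excludes ≈5.5% of the area, so the
double integral of a unit-weight Lorentzian line on a realistic sweep is
*not* 1 to three decimals — no window a spectrometer would sweep makes
it so. The tests therefore check Gaussian lines against exact unit area
and Lorentzian lines against the closed-form truncated area (including
the small offset from anchoring the running integral at the window
edge). All quantitative comparisons in the pipeline are ratio-based, and
because decomposition bases are simulated on the same window as the
spectrum they unmix, truncation cancels from the recovered fractions.

**NNLS.** Weights are constrained non-negative (radical concentrations
cannot be negative) with a compact Lawson–Hanson active-set solver;
noiseless mixtures are recovered to optimizer tolerance, and a candidate
basis with a correlation above 1−1e−10 between columns is rejected with
the offending pair named. `residual_norm` is the residual power fraction
`‖r‖²/‖y‖²`.

**Double integration** uses trapezoids with no wing extrapolation, on a
uniformly spaced axis (enforced to 1e−9 relative).

**PCA** is a plain SVD of the scaled matrix; `r2x_k = d_k²/Σd²` on that
matrix (the R2X convention of chemometrics software); component signs
are fixed by making the largest-magnitude loading of each component
positive. The pipeline order raw → total-normalized → (fused) → Pareto →
PCA is enforced: stages called out of order raise, and PCA on an
unscaled matrix warns.

**Assays** are linear calibrations plus unit bookkeeping, each a forward
model with an exact inverse (property-tested round trips). The peroxide
assay converts µg Fe(III) to µeq O₂ via µmol Fe = µeq peroxide oxygen
(each Fe²⁺→Fe³⁺ transfers one electron; two Fe per peroxide is the
equivalence that makes the µmol↔µeq identification exact). The
total-phenolics dilution chain defaults to a 0.2 mL extract aliquot in a
10 mL final volume; all volumes are overridable, and our reading of the
partially implicit published chain is encoded in these defaults.

## The synthetic world

The generators state the measurement world once; their defaults are not
tuned to any test outcome.

- **EPR time series**: the two persistent PBN adducts at a 65:35
  double-integral ratio (a_N 14.90/2.48 G and 14.70/2.88 G, both
  g 2.00573), total weight following a Boltzmann sigmoid sampled every
  5 min over 0–200 min. Temperature presets are illustrative, chosen to
  reproduce the reported qualitative ordering (slower rise and longer
  induction at lower temperature): 80 °C → (t0 160, dt 25) with the
  plateau not reached in-window; 90 °C → (t0 100, dt 16), giving
  IP = 68 min; 100 °C → (t0 12, dt 4), i.e. no usable induction phase.
  They are not fits to the original curves, which were never released.
- **Feature tables**: log-normal base peak areas (meanlog 12, sdlog 1 —
  typical LC-MS dynamic range), 10% of features per extraction-method
  group shifted by a fold change drawn log-uniformly in [2, 5] (the
  range of solvent-dependent phenolic differences a Folin assay would
  corroborate), biological CV 0.3, technical CV 0.1. Both the 24-row
  (4×3×2) and 36-row (4×3×3) layouts of the ambiguous published design
  are available.
- **Reference records**: the printed per-oil means and SDs (yield, PV,
  AUC, fatty acids, FFA, TPC). RSA was published only as a figure; the
  fixture values are approximate bar readings flagged
  `rsa_synthetic = TRUE` and excluded from quantitative assertions.

What a green test does **not** establish: the generator draws i.i.d.
log-normal features with clean multiplicative group shifts — no
retention-time drift, censored/missing peaks, heteroscedastic detector
noise or correlated metabolite blocks — so the silhouette > 0.5
separation says the pipeline recovers structure the generator put in,
not that real extracts separate this cleanly. Likewise the published
78.49%/10.71% PCA variance split and the 4/68-min induction periods at
90/80 °C depend on raw instrument data that were never deposited; they
are covered only qualitatively (temperature monotonicity, recovery-grid
bias/RMSE bounds, loading-sign checks), never asserted numerically.

## Known limitations

- First-order hyperfine positions only; no second-order corrections,
  anisotropy/powder patterns, field-modulation or saturation effects.
- Modulation amplitude is carried as metadata; 0.106 mT ≈ 0.7× the
  default linewidth, so real spectra are slightly broader than simulated
  ones.
- Hyperfine constants are taken as known; only mixture weights are
  fitted, not a_N/a_H.
- The stability model is empirical and exactly identified from three
  oils: it interpolates their composition space and demonstrably fails
  outside it (the mechanically pressed oil), which the diagnostics
  surface rather than hide.
- Refitting the coefficients from the printed, rounded means reproduces
  c_PV to 0.002 but c_TPC/c_FFA only to ~6% — consistent with the
  original fit having used unrounded or replicate-level data.
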