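---
title: "Methods: resolving the HYX/EPH/THP ternary mixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resolving the HYX/EPH/THP ternary mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternspec)
```

## The problem

Hydroxyzine hydrochloride (HYX), ephedrine hydrochloride (EPH) and
theophylline (THP) are co-formulated for respiratory disorders. Their
UV absorption spectra in methanol overlap so strongly below 230 nm that no
single zero-order wavelength is selective for HYX or EPH; only THP has an
isolated band (λmax 271 nm). This package implements the two standard
chemometric answers — a univariate ratio-subtraction/derivative pipeline
and multivariate PLS-1/PCR calibration — and everything needed to validate
them.

All concentrations are in µg/mL, absorbances in AU, wavelengths in nm, and
the path length is fixed at 1 cm throughout.

## Method A: ratio-subtraction combined with third-derivative spectrophotometry

For a mixture obeying Beer–Lambert additivity,
$A(\lambda) = C_H s_H(\lambda) + C_E s_E(\lambda) + C_T s_T(\lambda)$,
division by the spectrum of a pure THP standard of concentration $d$ gives

$$ R(\lambda) = \frac{C_H s_H(\lambda)}{d\, s_T(\lambda)}
             + \frac{C_E s_E(\lambda)}{d\, s_T(\lambda)} + \frac{C_T}{d}. $$

The THP term is a wavelength-independent constant. In the *plateau region*
around 271 nm, where $s_H \approx s_E \approx 0$, the ratio spectrum equals
that constant, so averaging it there and subtracting removes THP entirely.
The subtracted spectrum is read at 234.2 nm (where $s_E \approx 0$) for
HYX, and after a third-derivative transform at 222 nm (the zero crossing of
the HYX ratio-derivative) for EPH.

Parameters that matter, with defaults:

* **Divisor concentration** `divisor_conc = 22` µg/mL of THP. Changing it
  rescales the HYX/EPH response slopes by $22/d$ but leaves inverted
  concentrations unchanged, which the test suite asserts; 22 µg/mL is the
  concentration at which the measurement wavelengths were characterised.
* **Derivative** `derivative_params(order = 3, delta_lambda = 4,
  scaling_factor = 100)`. The default scheme is an iterated central
  half-lag difference,
  $A(\lambda) \mapsto [A(\lambda + \Delta\lambda/2) -
  A(\lambda-\Delta\lambda/2)]/\Delta\lambda$, applied three times. The
  derivative algorithms of commercial spectrophotometer software are
  generally unpublished; this form was chosen because it is linear, exact
  through cubic polynomials, and convention-invariant in the sense that
  calibration and prediction share the same operator — so the estimator
  does not depend on the convention, only the intermediate amplitudes do.
  A Savitzky–Golay smoothing-derivative scheme is available for users who
  need to match a specific instrument. The scaling factor only makes
  amplitudes numerically convenient; it cancels in calibration inversion
  (asserted to 1e-9).
* **Plateau constant**: mean of the ratio spectrum over 271 ± 2 nm rather
  than the single 271 nm point. On noiseless spectra the two are identical
  (the ratio is constant there); under noise the window average is less
  variable. Subtracting the constant before the derivative is provably
  immaterial for EPH — derivatives annihilate constants — and the suite
  asserts this to 1e-10.
* **Division floor** `floor = 0.01` AU: ratio values where the divisor
  falls below the floor are masked rather than computed, because dividing
  by near-zero absorbances amplifies noise without bound. How instrument
  software handles this region is never specified; masking with a hard
  error on any attempt to *read* a masked wavelength is the conservative
  choice. The three measurement wavelengths must be unmasked or
  `quantify_ternary()` aborts.
* **λmax of THP** is taken as 271 nm everywhere (271 and 272 both appear
  in descriptions of this system; all quantitative statements use 271).
* Out-of-range inverted concentrations are returned with a warning — never
  clipped — so that diluting-and-reassaying decisions stay with the
  analyst.

## Method B: multivariate calibration

The training set is a 25-run, five-level, three-factor multilevel design
(HYX {2,4,6,8,10}, EPH {3,6,9,12,15}, THP {2,6,10,14,18} µg/mL). The
generator uses a cyclic construction: run 1 sits at the centre and each
factor's remaining 24 runs follow a fixed 24-term cycle of coded levels,
each factor offset by one position. This guarantees every level occurs
exactly five times per factor and keeps inter-factor correlations small
(|r| < 0.35 in coded units), which is what makes a 25-run design
informative for three analytes.

Spectra are restricted to the 210–230 nm window sampled every 0.2 nm
(101 variables, boundaries inclusive) — the region where all three
components carry signal; wavelengths above 230 nm would let the THP band
dominate the decomposition, and below 210 nm solvent cut-off noise
dominates real measurements.

Models are **mean-centred only** (no variance scaling) by default, since
centring is what demonstrably improves these models on absorbance data;
autoscaling is available behind the `scale` flag. PLS-1 is implemented by
NIPALS with per-component deflation and the regression vector assembled as
$b = W(P^TW)^{-1}q$; PCR takes principal components from the SVD of the
centred matrix and regresses the centred response on the first $k$
orthogonal scores. A fixed sign convention (largest-magnitude loading
element positive) makes loadings reproducible across platforms. Internal
consistency — score-path predictions equal regression-vector predictions —
is asserted to 1e-8.

Component count: leave-one-out cross-validation refits the model from
scratch on each fold (including re-centring, so no information leaks from
the held-out sample) and reports RMSECV for $k = 0 \ldots k_{max}$
(default `kmax = 10`; $k=0$ is the mean-only model, whose RMSECV equals
the leave-one-out standard deviation of the response — a useful closed-form
check). Three selection rules are provided: `fixed` (default 5 components,
the count at which both model families are typically run on this system),
`min`, and `one-se` for parsimony. On noiseless three-component data the
curve collapses below 1e-6 at $k = 3$, the generating rank.

## Validation statistics

`summary_stats()` uses the $n-1$ standard deviation — required to
reproduce standard validation-table arithmetic from printed recovery
columns. `two_sample_t()` is the two-sided pooled-variance form at
α = 0.05 (critical value 2.228 at df = 10), and the F ratio always places
the larger variance in the numerator (critical value 5.050 at df 5,5), the
convention used in method-comparison tables. Printed t/F statistics in
rounded literature tables are generally *not* recoverable from the rounded
means and SDs they accompany; the package therefore treats critical values
and RSD/variance arithmetic as reproducible, and recomputes statistics
from data. `standard_addition()` scores recovery of spiked amounts as
$100(\mathrm{found}_{spiked} - \mathrm{found}_{base})/\mathrm{added}$,
flagging (not dropping) negative recoveries; the differencing is what
cancels a constant excipient bias, which the suite demonstrates with a
simulated broad-band excipient background.

## The synthetic-data generator

True molar absorptivity curves for the three drugs are not tabulated
anywhere usable, and the methods' correctness depends only on the
*geometry* of the spectra, so `default_profiles()` targets the geometry
directly with sums of Gaussian bands:

* THP: bands at 271 nm (σ = 9, peak 0.0467 AU·mL·µg⁻¹·cm⁻¹, matching the
  order of magnitude of a realistic 271 nm response) and a broad 215 nm
  band so it absorbs across the multivariate window;
* HYX: main band at 234 nm (σ = 6) plus an overlap band near 222 nm whose
  centre is *tuned at build time* (by root finding on the actual grid and
  derivative operator) so the third derivative of the HYX/THP ratio
  spectrum crosses zero at exactly 222.0 nm; the tuned crossing is
  verified with `find_null_wavelength()` before the profiles are returned;
* EPH: bands at 213 and 218 nm, transparent (< 1e-6 AU per µg/mL) at both
  234.2 and 271 nm.

Noise is additive homoscedastic Gaussian with σ = 0.002 AU by default —
routine photometric repeatability for a double-beam instrument in the
0–1 AU range; a shot-noise-like heteroscedastic option and a smooth
excipient background band are available behind flags, both off by default.

What the generator does **not** emulate: wavelength-registration error,
baseline drift, stray light, slit-width (bandpass) convolution, band
asymmetry, and inter-day response drift. Passing tests on this generator
therefore demonstrate the correctness of the *algorithms* under the
stated spectral geometry and noise model, not the field performance of
any laboratory's instrument.

## Numerical choices and degenerate inputs

* Grids must be strictly increasing; a uniform step is required (to
  1e-9 nm) for derivatives. The default acquisition grid is 200–400 nm at
  0.2 nm — the sampling density needed by the multivariate window is
  adopted globally for consistency.
* Amplitude reads interpolate linearly between bracketing grid points, so
  234.2 nm works on any grid; on-grid reads return stored values exactly.
* `find_null_wavelength()` requires the analyte amplitude to be at least
  10% of its window maximum (configurable) and breaks ties toward the
  larger analyte amplitude.
* Degenerate fits fail loudly: constant concentrations or responses in
  `build_calibration()`, zero-variance response or `k` beyond the rank in
  the multivariate fitters, zero pooled variance in `two_sample_t()`. One
  deliberate exception: NIPALS stops early (with a warning) when the
  residual covariance vanishes, so cross-validation curves can extend past
  the rank of noiseless data.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script simulate at the study's own
scale: 25 training and 7 validation mixtures per replicate, 101
wavelengths in the multivariate window, 100 seeded replicates for the
univariate noise study, 50 for the multivariate one, and 2000 replicates
for the t-test size check. These sizes give Monte-Carlo standard errors
comfortably below the asserted bounds while keeping the whole suite fast.

## Known limitations

* The univariate EPH estimate inherits the noise amplification of a third
  derivative; its replicate RSD is several-fold that of HYX/THP at equal
  noise. This mirrors the method itself, not an implementation artifact.
* JCAMP-DX support is deliberately minimal: single-block
  `(X++(Y..Y))` AFFN data, no compression schemes, no multi-block files.
* The multivariate module fits one response at a time (PLS-1); PLS-2 and
  variable-selection schemes (iPLS, GA) are out of scope, as are
  calibration transfer and any instrument control.
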