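---
title: "Methods: receptor-noise-limited conspicuousness modeling in rnlvision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor-noise-limited conspicuousness modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnlvision)
```

## Scope and model

`rnlvision` estimates how conspicuous a colored surface is to a given animal
viewer against a given natural background, and which study factors explain
variation in that conspicuousness. The chain is: reflectance spectra →
quantum catches under a viewer-specific receptor set → receptor-noise-limited
(RNL) chromatic contrast ΔS and Weber-scaled achromatic contrast ΔL, both in
just-noticeable differences (JND) → distance-preserving perceptual-space
coordinates → AICc-based multi-model inference on linear mixed models of the
contrast tables.

## Spectral preprocessing

Raw spectrometer output is noisy at the range edges and below the dark
noise floor. The cleaning chain is fixed as **trim → clip → smooth →
interpolate → average**:

* trim to 300–700 nm (inclusive; spectra that do not cover the window are an
  error, not silently padded);
* negative reflectance values are measurement noise and are set to zero;
* LOESS smoothing with span 0.2 (degree-2 local polynomials, tricube
  weights, single pass — no robustness iterations; the span is the only
  free parameter and 0.2 is the conventional setting for 1-nm-resolution
  reflectance data);
* linear interpolation to the common 1-nm grid (401 points), needed before
  receptor integration;
* pointwise arithmetic averaging of replicates (4 dorsal readings per frog,
  6 readings per substrate object; substrate objects are further averaged to
  one mean spectrum per substrate class).

Whether smoothing precedes or follows clipping is not independently
determined; clip-then-smooth is the declared convention (smoothing a clipped
spectrum cannot re-introduce large negative excursions, and the result is
re-clipped at zero). Percent-scaled inputs (maximum > 2) are auto-detected
and divided by 100 with a warning.

## Visual systems

Receptor sensitivities are built from the Govardovskii-style vitamin-A1
template (alpha plus beta band), peak-normalized, with an optional logistic
long-pass oil-droplet filter `T(λ) = 1/(1 + exp(−s(λ − c)))`. The original
oil-droplet treatment (hard cutoff vs. graded transmission) is not
documented for these systems; the logistic slope `s` (default 0.04 nm⁻¹,
i.e. a ~50-nm transition band) exposes this choice — `s → ∞` recovers a hard
cutoff. Filtering is followed by re-peak-normalization, so it reshapes but
never rescales a receptor curve.

| system | λmax (nm) | oil cutoffs | η | chromatic ω (anchor) | luminance channel (ω) |
|---|---|---|---|---|---|
| bird | 370, 458, 547, 600 | — | 1, 1.9, 2.7, 2.7 | 0.1 (LWS) | single 563-nm double cone (0.05) |
| lizard | 370, 495, 550, 590 | 330, 371, 463, 507 | 1, 1, 1, 3 | 0.05 (LWS) | summed MWS+LWS catches (0.05) |
| crab | 430, 590 | — | 1, 2 | 0.12 (LWS) | summed SWS+LWS catches (0.12) |

Receptor noise follows the density rule `e_i = ω_ref √(η_ref/η_i)`, anchored
at the LWS receptor in all three systems (the receptor for which a Weber
fraction is actually quoted in the source physiology). "Summed response" for
the lizard luminance channel is implemented as summed quantum catches; the
alternative (summing sensitivity curves before integrating) differs only by
a fixed scale factor, which cancels in the ΔL log-ratio.

The bundled forest-shade illuminant is **synthetic**: a smooth green-peaked
curve with strong attenuation below 400 nm. It emulates the spectral shape
of forest-shade irradiance but is not a measurement; analyses of real field
data must load the measured illuminant (`read_spectra(..., role =
"irradiance")` overrides it bit-for-bit).

## Contrasts

ΔS is computed from raw catches via log ratios (`Δf_i = ln(Q_{i,a}/Q_{i,b})`)
through the general-n RNL quadratic form; relative catches are kept only for
color-space description, since the common normalization cancels in Δf
differences. No explicit photon-shot-noise term is included: noise is purely
Weber/density-anchored, matching the bright-light assumption. ΔL is the
absolute luminance log-ratio over the luminance Weber fraction.

The published workflow excluded "individuals deviating greatly from the
mean" by eye; that is not reproducible, so the package substitutes a
deterministic surrogate: within each locality × predator × substrate cell,
records more than k = 3 scaled median absolute deviations from the cell
median (in ΔS or ΔL) are *flagged*, never deleted; `k = Inf` disables the
rule. Cells with fewer than 4 records are not screened.

## Perceptual spaces

Coordinates are obtained by whitening, not multidimensional scaling: the RNL
quadratic form on log-catches is an exact Euclidean metric on the
(n−1)-dimensional quotient by the uniform (intensity) direction, so mapping
centered log catches through `Λ^{1/2} U'` (eigendecomposition of the metric)
reproduces every pairwise ΔS to machine precision, deterministically and in
the correct dimension. MDS would only approximate this. Rigid-motion freedom
is fixed by convention: axes ordered by decreasing eigenvalue, axis 1 signed
so the stimulus with the highest relative LWS catch is positive, remaining
axes signed by their dominant receptor loading. Published color-space plots
use a different (unspecified) internal rotation, so coordinates match them
only up to rigid motion — distances, which carry the science, are invariant.
The luminance coordinate is appended as a separate centered axis
(`ln Q_L / ω_L`), never mixed into the chromatic whitening. For the
dichromatic crab the chromatic space is the signed 1-D coordinate, oriented
long-wavelength-negative / short-wavelength-positive.

## Statistics

All 113 marginality-respecting models in the four predictors (species,
morph, substrate, predator; pairwise interactions) are fitted as Gaussian
random-intercept (per individual) mixed models by **maximum likelihood** —
REML likelihoods are not comparable across fixed-effect structures. `k`
counts fixed coefficients plus the two variance parameters. A retention cap
(default 100, the count the original workflow tabulated) keeps the best
models by AICc before weights are recomputed. The two published set rules
("weight > 0.01" and "top 95% of evidence weight") conflict; the 95%
cumulative rule is primary and the weight floor is available as an option.
Averaging is conditional (per-term weight renormalization, matching a
per-term "number of models" column); a zero-substitution mode is available.
Unconditional standard errors follow the Burnham–Anderson formula
`SE = Σ w̃_i √(se_i² + (β_i − β̄)²)`; a term is *important* at summed
importance ≥ 0.80 and *strong* when its 95% CI excludes zero. Importance is
reported over the 95% confidence set (computing it over the full candidate
set is a one-line change and gives near-identical values when the set is
concentrated). Reference levels are O. granulifera / green / bird / green
leaf, so coefficient signs read as in the conventional report layout.

## Synthetic data: what it does and does not establish

The generator emulates the study layout — 9 localities (4 O. granulifera, 5
O. pumilio; red and green morphs as in the field design), 8 males per
locality, 4 dorsal reads per frog, 3 substrate classes × 6 reads — with
parametric idealizations: red dorsa are a logistic long-pass edge at 590 nm,
green dorsa a Gaussian band at 550 nm; green leaf is a 555-nm Gaussian with
a small near-infrared rise, leaf litter a monotone brown ramp, trunk a low
flat gray-brown. Amplitudes (red plateau 0.50, green amplitude 0.35,
baseline 0.04) and noise scales (individual offset sd 0.015, per-read sd
0.008) were chosen once as field-plausible reflectance magnitudes such that
morphs separate in tetrachromat color space; they were not adjusted against
test outcomes. A separate generator draws contrast tables directly from the
random-intercept linear model for statistics-recovery testing.

What the generator does **not** emulate: locality-specific pattern elements
(dots, limb coloration), spatial/angular effects, locality-varying
illuminants, and — importantly — the empirical covariance structure of real
field spectra. A green test therefore establishes correctness of the
*machinery* (integration, RNL algebra, embedding, model averaging), not
replication of the field study's numbers.

One acceptance check is knowingly red in this synthetic world: real-data
analyses find birds perceiving the highest luminance contrasts, while the
synthetic defaults give mean ΔL of 12.0 (bird), 13.8 (lizard), 5.6 (crab)
at seed 1. With identical luminance Weber fractions (0.05) for bird and
lizard, the ordering is driven entirely by channel shape: the lizard's
summed MWS+LWS channel is long-pass filtered (oil droplets at 463/507 nm)
and concentrated where the idealized red-edge frogs differ most from the
dark substrates, while the broad 563-nm double cone integrates mid-wavelength
regions where synthetic frogs and backgrounds are more alike. Real dorsal
and substrate spectra evidently distribute their energy differently. The
check is left failing rather than re-tuning the generator post hoc.

## Numerical choices and edge cases

* Quantum-catch integration is a plain Riemann sum at Δλ = 1 nm on a shared
  grid; grid mismatch is an error, never silent resampling.
* All-zero stimuli produce zero raw catches and a degenerate flag; ΔS/ΔL on
  nonpositive catches raise errors naming the receptor.
* ΔS symmetry, scaling invariance, the triangle inequality, and agreement of
  the general-n formula with the dichromat/tetrachromat closed forms and a
  GLS (uniform-direction-projected) oracle are enforced by tests to 1e−9.
* LOESS output is validated against a direct tricube local-quadratic oracle
  at probe wavelengths (agreement to machine precision).
* The ML mixed-model log-likelihood is validated against a dense
  marginal-Gaussian log-density oracle.
* AICc requires n > k + 1 and errors otherwise; weights are invariant to
  adding constants to log-likelihoods (tested).

## Known limitations

* No ocular-media transmission or von Kries adaptation; relative-catch
  normalization is the only adaptation step, and it cancels in ΔS.
* Gaussian responses only; no random slopes; no p-values by design.
* Perceptual coordinates are unique only up to the declared orientation
  convention.
* The bundled illuminant is a stand-in; quantitative claims about real
  scenes require a measured irradiance spectrum.
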