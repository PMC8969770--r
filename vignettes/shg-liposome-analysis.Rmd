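---
title: "Methods: SHG adsorption and transport analysis at liposome surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SHG adsorption and transport analysis at liposome surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liposhg)
```

## The measurement and its model

Second harmonic generation (SHG) is dipole-forbidden in centrosymmetric
bulk media and allowed at interfaces, which makes it a surface-specific
probe of adsorption on colloidal particles. A cationic dye adsorbing to
the outer leaflet of a liposome bilayer produces a coherent
second-harmonic field; as molecules translocate to the inner leaflet they
adopt the opposite orientation and radiate with opposite phase. Because
the bilayer (≈5 nm) is far thinner than the SHG coherence length, the two
contributions subtract:

$$E_\mathrm{SHG} \propto (N_\mathrm{outer} - N_\mathrm{inner})\,E_\omega^2,
\qquad I_\mathrm{SHG} = E_\mathrm{SHG}^2 .$$

`coherent_field()` and `shg_intensity()` implement exactly this and
nothing more; all orientational and tensorial detail is folded into the
proportionality constant, which cancels in every quantity the package
reports.

Three fitted layers sit on top.

### Depletion-corrected Langmuir adsorption

Colloidal liposome suspensions present so much surface area that binding
measurably depletes the bulk dye. With $C$ the total added dye
concentration, $N$ the adsorbed concentration, $N_\max$ the adsorption
site concentration, and $W = 55.5\ \mathrm{M}$ the molar concentration of
water that renders the equilibrium constant $K$ dimensionless,

$$\frac{N}{N_\max - N} = \frac{K}{W}\,(C - N).$$

`langmuir_coverage()` solves the equivalent quadratic and always selects
the "−√" root

$$N = \tfrac12\Big[(C + N_\max + W/K) - \sqrt{(C + N_\max + W/K)^2 - 4\,C\,N_\max}\Big],$$

because the "+√" root exceeds $\min(C, N_\max)$ and is unphysical. The
observed time-zero intensity is modeled as

$$I(C) = A\,(N/N_\max)^2 + \alpha\,(C - N) + B,$$

a coherent term quadratic in surface coverage (required for the
$A/N_\max^2$ signal-per-coverage comparison between samples to make
sense), an incoherent hyper-Rayleigh scattering (HRS) term linear in the
*free* dye concentration $C - N$, and a constant dye-free baseline $B$.
Only $A$, $N_\max$, $K$ are free in the isotherm fit; $\alpha$ and $B$
are fixed from control series.

Two open modeling choices were closed as follows.

* **HRS inside the model, not subtracted from data.** Correcting the data
  requires knowing $C - N$, i.e. the fit result; putting the term in the
  model keeps the correction self-consistent. Subtractive workflows can
  be emulated with `hrs_mode = "total"` ($\alpha C$), provided for
  sensitivity checks.
* **Scalar spectral readout is a baseline-subtracted trapezoidal area
  over 400 ± 10 nm** (configurable), not the peak height. Area is robust
  to line-shape noise; since the intensity units are arbitrary counts,
  the choice rescales $A$ and $\alpha$ coherently and cancels in every
  derived ratio.

### Transport kinetics in the field domain

A first-order leaflet-exchange picture — total adsorbed population fixed
at its Langmuir value from $t = 0^+$, a fraction migrating inward with
rate $1/\tau$ — gives a population difference, hence an SHG *field*, that
is exactly single-exponential:

$$E(t) = A_0 + A_1 e^{-t/\tau}.$$

`fit_transport()` therefore fits in the field domain,
$E = \sqrt{\max(I - \mathrm{background}, 0)}$, and
`time_zero_intensity()` extrapolates $I(0) = (A_0 + A_1)^2 +
\mathrm{background}$. Extrapolation is used instead of the first sample
because adsorption completes faster than the experimental resolution.
The square-root transform also approximately variance-stabilizes
shot-noise-like intensity noise, which is why uniform weighting is the
default (`"poisson"` weighting, $1/E$, is available).

### Derived thermodynamics

$\Delta G = -RT\ln K$ with $R = 1.98720425\times10^{-3}$ kcal mol⁻¹ K⁻¹;
lipids per adsorption site $= [\mathrm{lipid}]/N_\max$; signal per
coverage $= A/N_\max^2$. The experiments this package targets do not
state a temperature; the default is $T = 293$ K ("ambient"),
configurable everywhere it enters. At 293 K the published-scale constants
$K = 5\times10^7$ and $9\times10^7$ map to $-10.32$ and $-10.66$
kcal/mol, inside the ±0.1 bands such tables print.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `W` (`shg_constants$water_uM`) | µM | 55.5×10⁶ | water reference making K dimensionless; single-unit (µM) convention avoids the mol/L-vs-µM mixing that silently wrecks this model |
| `T` | K | 293 | ambient; unstated in the source experiments |
| integration window | nm | 400 ± 10 | covers the ≈4.7 nm FWHM emission peak with margin; median-of-outside baseline estimator is robust to peak tails |
| K box constraint | — | $[10^3, 10^{12}]$ | seven decades of scale disparity with A and Nmax; fitted as $\log_{10} K$ |
| bootstrap replicates | — | 0 (off); ≥100 when on | residual resampling; percentile 68% intervals |

## What the generator emulates — and what it does not

`default_truth()` *is* the stated experimental world: pure 75 µM DOPC and
75 µM DOPC + 25 µM APAP samples with $(A, N_\max, K)$ = (174, 2.9 µM,
5×10⁷) and (241, 3.6 µM, 9×10⁷); a Gaussian emission peak at 400 nm with
4.7 nm FWHM; dye concentrations 0.5–8 µM. Values the source experiments
leave unstated were fixed once:

* **HRS slope α = 5 counts/µM** — reproduces the observed ≈3.5× ratio of
  liposome SHG to dye-alone HRS at 6 µM dye.
* **Baseline B = 2 counts** — "negligible before dye is added" relative
  to ≈100-count signals.
* **τ = 300 s**, with τ(APAP) = 1.5×τ(pure) for C ≥ 3 µM and equal below
  — published transport times for these samples live in an unreproduced
  supplement, so the profile encodes *only* the stated ordering, at a
  magnitude typical of dye flip-flop at fluid-phase bilayers. Users
  must not mistake these defaults for measured values.
* **Partition fraction f = 0.3** — real traces decay to a nonzero
  plateau, implying f < 0.5 (full cancellation); f is the fraction of
  adsorbed dye on the inner leaflet at equilibrium.
* **Noise: 5% multiplicative + 1 count additive Gaussian** — a pragmatic
  stand-in for CCD shot + read noise.

The generator deliberately omits photobleaching, liposome
polydispersity, aggregation, scattering-angle effects, and any
mechanistic effect of APAP on membrane elasticity. A green test
therefore establishes that the *estimators* recover a world obeying the
stated model at realistic noise — not that real instruments lack
systematic effects outside that model.

## Numerical choices

* **Cancellation-safe coverage root.** The "−√" root is evaluated as
  $2\,C\,N_\max / (b + \sqrt{b^2 - 4 C N_\max})$, $b = C + N_\max + W/K$,
  avoiding subtractive cancellation in the dilute regime; discriminants
  in $(-10^{-12} b^2, 0)$ from rounding are clamped to zero, anything
  more negative is an internal error. An independent plain-bisection
  oracle (`langmuir_coverage_oracle()`) brackets $[0, \min(C, N_\max)]$
  and agrees to $10^{-9} N_\max$ across the tested ranges.
* **Exponential fits: tolerance ladder + fallback.** `nls` is run with
  `scaleOffset = 1` (sound convergence on zero-residual problems) at
  tolerance $10^{-11}$ with a small iteration cap — this makes noiseless
  round trips exact to ≈10⁻⁸ — then at $10^{-8}$ and the default for
  noisy data; a ladder of τ starting values (interpolated $1/e$ crossing,
  span/10, span/3, span) precedes a Nelder–Mead fallback with one `nls`
  polish. A constant trace returns $A_1 = 0$ with an `unresolved` flag
  rather than an error; so does a fitted τ above 100× the trace span.
* **Sandwich covariance for τ.** Trace noise is closer to multiplicative
  than additive, so the classical homoscedastic `nls` covariance
  under-covers τ (empirically ≈0.80 at nominal 0.95). `fit_transport()`
  reports the heteroscedasticity-consistent sandwich covariance, which
  restores ≈0.93–0.95 empirical coverage; the suite asserts [0.90, 0.99].
* **Isotherm fit.** Weighted least squares (weights $1/\sigma_{I_0}^2$
  when propagated uncertainties exist, uniform otherwise) over
  $(A, N_\max, \log_{10} K)$ with the port algorithm and box constraints;
  initialization $A = \max(I_0) - B$, $N_\max = \max(C)/2$,
  $K = W/\max(C)$ (half-depletion heuristic); five seeded ±50% jittered
  restarts before declaring failure; $N_\max$ reaching its $10\max(C)$
  bound is flagged `saturation_unidentified` instead of silently
  reported. A linear-K parameterization is kept solely to verify that
  both reach the same optimum on clean data.
* **Background fixed point.** The incoherent background of a trace,
  $\alpha(C - N) + B$, is constant in time but depends on the isotherm
  fit. `run_pipeline()` iterates kinetics → isotherm → background update
  (first sweep uses $B$ alone) until the backgrounds change by less than
  $10^{-8}$ relative (≤15 sweeps). The iteration contracts because the
  background is a small fraction of the signal; at zero noise its fixed
  point is the generating truth, which is what makes the end-to-end
  $10^{-4}$ round-trip criterion attainable with field-domain fitting.
  This iteration is the package's own design; a single-pass pipeline
  with background $B$ leaves an $O(\alpha M / I)$ bias in every τ and
  $I(0)$.
* **Uncertainty method.** The source tables print ± values without a
  method. Both covariance-based standard errors (delta method for K and
  the derived quantities: $\sigma_{\Delta G} = RT\,\sigma_K/K$) and a
  seeded residual bootstrap (percentile 68%) are provided; reports quote
  the bootstrap when draws exist.
* **Ties and degenerate inputs.** Duplicate (sample, concentration)
  pairs aggregate by the mean with combined standard errors, with a
  message; isotherms need ≥4 distinct concentrations; calibration needs
  ≥3 distinct dye-only concentrations and ≥1 dye-free spectrum; negative
  mean dye-free intensity clamps B at 0 with a warning.

## Determinism

Every stochastic component (generator noise, restart jitter, bootstrap)
draws from an explicit seed and restores the caller's RNG state.
Identical config + seed produces byte-identical persisted reports
(timestamps are deliberately excluded from provenance) and byte-identical
datasets (numeric CSV fields are written with 17 significant digits).

## Known limitations

* Single-exponential phenomenology only; multi-exponential or stretched
  kinetics, and mechanistic flip-flop models, are out of scope.
* One adsorption site class (no Frumkin/anti-cooperative extensions); no
  joint fitting of α, B with the isotherm; no global two-sample fit.
* No ΔH/ΔS decomposition (temperature enters only through −RT ln K).
* Detector gain, cosmic-ray spikes and wavelength calibration are
  assumed handled upstream.
* Arbitrary intensity units: A and α are only meaningful jointly with
  the chosen spectral readout; cross-instrument comparison should use
  the dimensionless and ratio quantities (K, ΔG, lipid/site, A/Nmax²).
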