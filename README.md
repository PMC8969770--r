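# liposhg

Analysis of second harmonic generation (SHG) spectroscopy experiments that
probe molecular adsorption and translocation at colloidal liposome
surfaces. The package is written for membrane biophysicists who use
SHG-active probes (cationic triphenylmethane dyes such as malachite green
isothiocyanate, MGITC) to measure how a drug-like molecule binds to and
crosses a phospholipid bilayer — e.g. DOPC liposomes with or without an
additive such as acetaminophen (APAP) — and who need the full chain from
raw spectra and time traces to adsorption free energies and transport
times, with honest uncertainties.

## The model

SHG is coherent and interface-specific: dye adsorbed on the outer leaflet
radiates a second-harmonic field, dye that has translocated to the inner
leaflet radiates with opposite phase, so

    E_SHG ∝ (N_outer − N_inner) · E_ω²,   I_SHG = E_SHG².

Three pieces of physics are fitted:

1. **Depletion-corrected (modified) Langmuir isotherm.** With a large
   cumulative liposome surface area, binding depletes the bulk. The
   adsorbed concentration N at total dye concentration C solves

       N / (Nmax − N) = (K / W) (C − N),   W = 55.5 M (water reference),

   taken as the physical root of the quadratic
   N = ½[(C + Nmax + W/K) − √((C + Nmax + W/K)² − 4 C Nmax)].
   The observed time-zero intensity is
   I(C) = A·(N/Nmax)² + α·(C − N) + B, where A is the saturation SHG
   intensity, α the hyper-Rayleigh scattering (HRS) slope calibrated from
   dye-only controls, and B the dye-free liposome baseline. Only A, Nmax
   and K are fitted; α and B are fixed by calibration.

2. **Transport (flip-flop) kinetics.** In the field domain each trace
   follows E(t) = A0 + A1·exp(−t/τ); τ is the membrane transport time and
   (A0 + A1)² extrapolates the time-zero intensity used in the isotherm.

3. **Derived thermodynamics.** ΔG = −RT ln K (kcal/mol), lipids per
   adsorption site = [lipid]/Nmax, and signal per coverage = A/Nmax².

A seeded synthetic-experiment generator (two-leaflet population model,
Gaussian 400 nm emission peak, HRS calibration series, configurable noise)
makes the entire pipeline testable without instrument data.

## Worked example

```r
library(liposhg)

# thermodynamic identities from published-scale parameters
adsorption_free_energy(5e7, 293)$delta_g   # -10.32187  kcal/mol
lipids_per_site(75, 2.9)                   #  25.86207  lipids per site
signal_per_coverage(174, 2.9)              #  20.68966  counts uM^-2
langmuir_coverage(6, 2.9, 5e7)$N_adsorbed  #   2.239132 uM adsorbed of 6 uM added

# one full simulated experiment (5% multiplicative + 1 count additive noise)
report <- run_pipeline(shg_run_config("simulate", seed = 42))
print(report)
```

```
SHG pipeline report (simulate mode, seed 42): alpha = 4.834 counts/uM, B = 3.277 counts
Derived report ('dopc_apap', T = 293 K):
  deltaG          = -10.821 +/- 0.100 kcal/mol
  lipids/site     = 19.9 +/- 0.41
  A/Nmax^2        = 16.1 +/- 0.91 uM^-2
Derived report ('pure_dopc', T = 293 K):
  deltaG          = -10.556 +/- 0.088 kcal/mol
  lipids/site     = 23 +/- 0.77
  A/Nmax^2        = 14.7 +/- 1.1 uM^-2
```

A single noisy replicate scatters around the generating truth
(ΔG −10.32 / −10.66, lipid/site 25.9 / 20.8); medians over 20 replicates
recover K to within ±1×10⁷ and Nmax to within the published-style ±0.3–0.5
µM bands (see `tests/testthat/test-acceptance.R`). The sample comparison
flags the APAP-induced differences:

```r
compare_samples(report)
#   quantity          diff        sigma exceeds_1sigma
# 1        K -4.304685e+07 2.314713e+07           TRUE
# 2     Nmax -5.047471e-01 1.335209e-01           TRUE
# 3  delta_g  2.647727e-01 1.332091e-01           TRUE
```

(Differences are second sample minus first, here pure − APAP.)

## Command line

```sh
Rscript inst/cli/liposhg.R simulate --seed 1 --out dataset_dir
Rscript inst/cli/liposhg.R run --in dataset_dir --out results_dir --bootstrap 500
Rscript inst/cli/liposhg.R run --seed 1 --out results_dir   # simulate + analyze
```

`results_dir` receives `report.json`, `transport_table.csv`, and
`table1.csv` (sample, A, K, Nmax, lipid/site, ΔG, each with its
uncertainty).

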