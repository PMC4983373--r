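# fabsec

Quantification of free therapeutic antibody and ADA immune complexes by
size-exclusion chromatography (SEC) with a fluorescent Fab detection
reagent.

## The problem

Therapeutic antibodies dosed into animals or patients can elicit anti-drug
antibodies (ADA). Drug and ADA form circulating immune complexes whose
*size* is a suspected driver of acute post-dose reactions, so toxicology
studies need to track not just free drug but the size distribution and
clearance of complexes. One assay format does this in a single run: spike
serum with a fluorescently labelled *monovalent* Fab fragment that binds a
constant epitope of the drug (two epitopes per ~200 kDa drug molecule),
separate by SEC, and quantify the fluorescence peaks — free dye, free Fab,
drug–Fab, and progressively larger ADA complexes at shorter retention
times.

`fabsec` implements the computational content of that assay for
bioanalytical scientists: the binding model, the fits, the peak
quantification statistics, and the study-level analyses — plus seeded
synthetic-data generators so every stage is exercisable and testable
without instrument data.

## What is inside

* **Tight-binding equilibrium** (`solve_bound_complex`, `fraction_bound`,
  `signal_model`): the mass-action quadratic
  `[AB] = s − sqrt(s² − a·x)`, `s = (a + x + K_D)/2`, evaluated in a
  cancellation-free form, with explicit site-concentration doubling for
  the drug's two Fab epitopes and µg/mL ↔ nM ↔ serum unit conversions.
* **K_D fitting** (`fit_kd`): Levenberg–Marquardt fit of
  `Y = F + (F_max − F)·[AB]/a` to a titration, with depletion-aware
  initialisation and a weak-identifiability flag when the Fab
  concentration swamps the affinity.
* **SPR kinetics** (`simulate_sensorgram`, `global_fit_langmuir`,
  `expected_rmax`): exact closed-form 1:1 Langmuir sensorgrams, a global
  (shared-parameter) kinetic fit on log-scaled rates, and the
  mass-ratio stoichiometry arithmetic for expected saturation response.
* **Chromatogram quantification** (`render_chromatogram`,
  `integrate_window`, `snr`, `detect_lod`, `percent_complex`): Gaussian
  forward model over a species-calibrated retention table, trapezoidal
  window integration above a constant baseline, the percentage-area
  signal-to-noise statistic, limit-of-detection search, and the
  percent-complex statistic.
* **Pipelines** (`ada_series_analysis`, `pellet_mass_balance`,
  `timecourse_analysis`, `concordance_check`): ADA-titration complex
  profiling, supernatant/pellet densitometry mass balance with the 20/80
  volume-split correction, multi-dose timecourse quantification, and
  LBA/SEC concordance.
* **Generators** (`generator_config`, `gen_titration`, `gen_kd_points`,
  `gen_sensorgrams`, `gen_ada_series`, `gen_study`): seeded, bit-for-bit
  reproducible emulations of every input, each exposing its pre-noise
  truth for recovery testing.

## Worked example

```r
library(fabsec)
cfg <- generator_config(seed = 42)      # truths: K_D 22.5 nM, SPR K_D 18.2 nM

# SEC titration -> K_D
fit <- fit_kd(gen_kd_points(cfg), a_total = 585)
print(fit)
#> K_D fit (n = 22, a_total = 585 nM)
#>   K_D   = 24.01 nM (se 2.17)
#>   f_min = 0.1066 (se 0.244), f_max = 99.06 (se 0.318)
#>   RSS   = 11.69

# SPR sensorgrams -> global kinetic fit
print(global_fit_langmuir(gen_sensorgrams(cfg)))
#> global 1:1 Langmuir fit (n = 10812 points)
#>   kon  = 1e+05 /(M s) (se 135)
#>   koff = 0.00182 /s (se 1.89e-06)
#>   Rmax = 37 RU (se 0.0164)
#>   K_D  = 18.19 nM (se 0.0292)

# detection limit from the chromatogram titration
tit <- gen_titration(cfg)
cal <- default_calibration()
lod <- detect_lod(tit$samples, tit$blank, cal[cal$species == "DRUG_FAB", ])
assay_to_serum(molar_to_mass(as.numeric(lod), 200000), 5)
#> [1] 10        # 10 nM in assay = 10 ug/mL in 100% serum

# ADA titration: complex maximum, precipitation-driven decline, mass balance
ada <- gen_ada_series(cfg)
print(ada_series_analysis(ada$samples))
#> ADA titration complex profile
#>  ada_conc_nM percent_complex
#>            0      0.08649233
#>          750      0.79483632
#>         1500      0.81023771
#>         2000      0.80621868
#>         3500      0.78745217
#> max % complex at 1500 nM ADA; decline to highest ADA: 2.8%
round(pellet_mass_balance(ada$pellets[["ada_3500nM"]]), 3)
#>  huDVD    ADA Fab488
#>  0.397  0.240  0.187   # generator truth: 0.40 / 0.20 / 0.20
```

A single noisy titration fits K_D to ~2 nM of the 22.5 nM truth (the Fab
excess needed for sensitivity makes single-titration K_D intrinsically
imprecise — the fit flags this regime); the SPR route recovers 18.2 nM
tightly; the S/N = 1.5 search reproduces a 10 nM in-assay detection limit;
and the volume-split mass balance recovers the precipitated fractions from
noisy densitometry.

## Documentation

The methods vignette (`vignettes/fabsec-methods.Rmd`) describes the
models, their assumptions, every tunable default with its rationale, the
scenario rules encoded in the generators, and what passing tests do and do
not demonstrate about real data.
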