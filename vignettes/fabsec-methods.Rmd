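---
title: "Models and methods behind fabsec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fabsec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabsec)
```

## The assay in one paragraph

A therapeutic antibody (here a ~200 kDa dual-variable-domain IgG, "the
drug") administered to animals can raise anti-drug antibodies (ADA) that
form circulating immune complexes with it. Large complexes are the
suspected driver of acute post-dose reactions, so their size distribution
and clearance matter. The assay spikes serum with a fluorescently labelled
*monovalent* Fab fragment (~47 kDa) that binds a constant epitope on the
drug (two epitopes per drug molecule; a monovalent reagent cannot
cross-link and so cannot create artificial complexes), separates the sample
by size-exclusion chromatography (SEC), and reads laser-induced
fluorescence. Every peak in the fluorescence trace is either the free dye,
the free Fab, or a drug-containing species carrying Fab; larger species
elute earlier. `fabsec` implements everything downstream of the detector —
and, because no instrument data ship with the package, a set of seeded
generators that emulate each experiment.

## Tight-binding equilibrium and the K_D fit

With total Fab concentration $a$, total drug *site* concentration $x$ and
dissociation constant $K_D$, mass action gives the bound complex as the
physical root of a quadratic:

$$[AB] = s - \sqrt{s^2 - a x}, \qquad s = \tfrac{1}{2}(a + x + K_D).$$

`solve_bound_complex()` evaluates the algebraically identical form
$a x / (s + \sqrt{s^2 - a x})$. The textbook difference form subtracts two
nearly equal numbers when $K_D \ll a, x$ and loses most significant digits
exactly where this assay operates (tight binding, high reagent
concentrations); the product form does not. The package works in nM
throughout and converts at the boundaries (`mass_to_molar()`,
`assay_to_serum()`), because the assay's bookkeeping mixes µg/mL in serum,
µg/mL in the diluted assay, and nM.

The drug's two Fab epitopes are treated as independent and identical:
binding is modelled in *sites*, and callers double the drug concentration
explicitly with `effective_site_concentration()`. No cooperative model is
offered; nothing in the titration data could identify one.

`fit_kd()` fits $Y = F + (F_{max} - F)\,[AB]/a$ — the complex peak as a
share of total fluorescence — by Levenberg–Marquardt least squares
(unweighted by default; the data carry no replicate-based weights).
Two numerical choices matter:

* **Initialisation.** In the tight-binding regime the half-maximal signal
  sits near $x = a/2 + K_D$, not at $x = K_D$, so the starting value is the
  interpolated half-max concentration minus $a/2$ (floored at a twentieth
  of the half-max concentration). A naive half-max start is off by an
  order of magnitude here and can strand the optimiser.
* **Engine.** The raw `nls.lm` optimiser is used rather than an
  `nls`-style wrapper, because a nearly stoichiometric titration makes the
  Jacobian in $K_D$ almost singular and model construction would throw
  where we want a *flagged result*: when $a > 50\,K_D$ the result carries
  `weak_identifiability = TRUE`. This is a real failure mode — detection
  sensitivity forces the Fab concentration (585–678 nM) far above the
  low-nM affinity, which is why the fitted $K_D$ from a single titration
  scatters by ~20% even at 2% measurement noise, and why recovery is
  asserted on the *mean* over replicates.

## SPR: 1:1 Langmuir kinetics and stoichiometry

For the 1:1 interaction the sensorgram has an exact closed form
($R_{eq}(1 - e^{-(k_{on}C + k_{off})t})$ in association, exponential decay
in dissociation), so `simulate_sensorgram()` never integrates an ODE.
Mass-transport limitation, baseline drift and bulk refractive-index jumps
are deliberately out of scope; noise is additive Gaussian.
`global_fit_langmuir()` fits one shared $(k_{on}, k_{off}, R_{max})$ across
all concentrations, with the rate constants on a log10 scale — this
enforces positivity and fixes the conditioning problem of parameters eight
orders of magnitude apart. Starting values are data-driven ($k_{off}$ from
a log-linear regression on the top curve's dissociation tail, $R_{max}$
just above the largest plateau). An independent equilibrium-only route
(fitting plateau vs concentration to $R_{max}C/(C + K_D)$) is used in the
test suite as a cross-check on the kinetic fit, never as its replacement.

SPR response is proportional to bound mass, so stoichiometry is arithmetic:
`expected_rmax()` returns
$RU_{ligand} \times n_{sites} \times m_{analyte} / m_{ligand}$. For 78 RU
of captured drug and two Fab sites this predicts 36.8 → 37 RU, matching
the measured Fab saturation response and confirming the 1:2 model. (For a
nominal 80 RU the formula gives 37.7, not the 36 sometimes quoted from a
back-of-envelope rounding; the package follows the formula.)

## Chromatograms: rendering, integration, S/N, LOD

The forward model (`render_chromatogram()`) places one Gaussian per species
at the centre of its calibrated retention window, with area equal to the
species' *fluorescence weight*: concentration × number of Fab molecules
carried. Free dye and the unspecific serum peak weigh by concentration
alone. Defaults: peaks at 19.5 (free dye), 18 (free Fab), 15 min
(drug–Fab) anchored to observed elution times; the ADA-complex windows
(13–14, 12–13, 9.5–11.9 min) are figure-informed placeholders and
configurable, since their exact retention times are not printed anywhere. A
shared peak width of σ = 0.25 min would be consistent with the figures,
but σ = 0.20 min is used as the default so that every 1-minute window
captures ≥ 98.8% of its peak and window-to-window capture differences stay
well inside the 2% round-trip tolerance; the width is a parameter, not a
claim about the column.

Integration (`integrate_window()`) is trapezoidal above a constant
baseline estimated as the median of the first and last 5% of the trace (no
baseline-handling procedure is documented for the assay; a constant is the
least-assuming choice and is exact for the synthetic traces). Areas are
floored at zero with noisy data.

The detection statistic (`snr()`) is the *percentage* of trace area in the
complex window of a sample divided by the same percentage in a drug-free
control — a ratio of fractions, hence invariant to overall scaling of
either trace. `detect_lod()` returns the first concentration of an
ascending titration whose S/N reaches 1.5.

For the blank to have a nonzero window percentage at all, real serum must
contribute diffuse background fluorescence under the peaks. The generator
models this as a broad Gaussian (σ = 2.5 min, centred mid-elution) of
total area 220 AU·min at the standard 20% serum load. That area is an
explicit *calibration*, not a measurement: it is chosen once so that the
default titration design (678 nM Fab, twofold-ish drug ladder) crosses
S/N = 1.5 between 5 and 10 nM drug, i.e. the generator reproduces a 10 nM
in-assay detection limit (10 µg/mL in 100% serum after the 1:5 dilution
and the 200 kDa mass conversion). Baseline noise itself (default
0.05 AU) contributes almost nothing to integrated areas; the S/N ladder is
governed by the background, which is the realistic regime for a
fluorescence SEC assay.

## ADA titration, precipitation, and the mass balance

`gen_ada_series()` emulates the complex-formation titration (830 nM drug,
678 nM Fab, 0–3.5 µM ADA). The composition rule is *not* a measured
mechanism — the experiments resolve only the size classes — so it lives
entirely in the generator and the analysis stages stay scenario-agnostic.
With $r$ the ADA:drug molar ratio: complexed drug fraction
$1 - e^{-4r}$ (polyclonal ADA binds much tighter than the detection Fab);
of the complexed drug a share $1 - e^{-r/1.2}$ sits in the large
unresolved class, the rest split evenly between the 1:1 and 1:2 ADA:drug
classes; pellet fractions grow as $(r/r_{max})^{1.5}$, scaled to end at
40% of drug, 20% of ADA and 20% of Fab at 3.5 µM ADA. Note these endpoint
percentages *require* sub-stoichiometric Fab in the pellet (0.4 Fab per
precipitated drug against ~0.8 in solution): the generator books the
missing fluorescence against the large-complex window, consistent with
sterically hindered Fab binding in large complexes. A detection-efficiency
multiplier on the large-complex class is available for stronger hindrance
scenarios but defaults to 1. Under these defaults the percent-complex
statistic peaks at 1.5 µM ADA and declines at higher ADA — the
precipitation signature — though the default decline (~3%) is milder than
the worst case seen in vitro (up to ~50%).

The mass balance itself (`pellet_mass_balance()`) corrects for the volume
split of the fractionation: the pellet lane contains all precipitated
protein *plus* 20% of the soluble protein (it holds 20% of the reaction
volume), so soluble $= S/0.8$, precipitated $= P - 0.2 \cdot$ soluble, and
a soluble-only protein correctly maps to zero. The inversion is exact on
noiseless forward data for any split and any precipitated fraction;
densitometry noise can push estimates slightly outside $[0, 1]$, which is
clipped *and flagged*, never silent.

## Study timecourse

`gen_study()` encodes the qualitative clinical picture as generator truth:
after dose 1 only free drug circulates (maximal 15 min post-dose, monotone
decay to 168 h, Cmax 400 µg/mL serum — a typical value for a 20 mg/kg
dose); after doses 6 and 13, high ADA titres clear free drug quickly and
complexes appear transiently at 15 min and 4 h, dose 13 with a larger
large-complex share. Every sample carries a constant-area unspecific serum
peak (excluded from drug quantification), ligand-binding-assay values that
track free drug with 5% noise and are floored at the 0.136 µg/mL
quantitation limit (carried as a flag, never as zero), and western
intensities tracking total drug. `timecourse_analysis()` reports per-class
percent areas and per-dose peak times; `concordance_check()` verifies that
every sample measurable by LBA above the SEC bound (10 µg/mL serum) also
shows drug-linked SEC signal, judged against the predose trace of the same
dose.

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* the analyses assume:
exact equilibrium partitioning, Gaussian peaks in fixed windows, additive
baseline noise, a smooth serum background, multiplicative assay noise, and
internally consistent LBA/western/SEC truths. They do not emulate real
serum matrix effects, peak tailing or drift, overlapping-peak
deconvolution, Fab exchange kinetics, or physiological PK. Passing tests
therefore demonstrate that the estimators recover what the models define —
not that the models capture every property of real chromatograms.
Problem sizes used in the shipped checks (200 titration replicates, 100
sensorgram-series replicates, 1000-system equilibrium sweeps) were chosen
so the whole suite runs in seconds while leaving Monte-Carlo error far
below every tolerance asserted.

## Known limitations

* The interface consists of R functions plus the `scripts/acceptance.R`
  driver; no shell CLI is shipped.
* ADA-complex retention windows are placeholders until calibrated on a
  real column.
* The fitted $K_D$ from a single titration at assay-realistic Fab excess
  is weakly identified (flagged, and quantified in the replicate scatter).
* Only additive Gaussian noise models; no heteroscedastic detector model.
* The large-complex class is composition-agnostic beyond carrying two Fab
  per drug; the chromatography cannot resolve more.
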