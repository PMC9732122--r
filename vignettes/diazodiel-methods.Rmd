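---
title: "Methods: diel photophysiology, electron budgets and the CFM-CC model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel photophysiology, electron budgets and the CFM-CC model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazodiel)
```

`diazodiel` analyzes diel (12:12 light:dark) photobioreactor experiments
on unicellular nitrogen-fixing cyanobacteria and feeds the resulting
phase-integrated budgets into a minimal two-species competition model.
This vignette documents the models, the tunable constants, the numerical
choices, and what the synthetic-data generator does and does not
emulate.

## The measurement models

### Electron transport from FRRf yields

Fast repetition rate fluorometry delivers, per actinic irradiance step,
the dark-regulated minimum and maximum yields F0 and Fm and the
light steady-state and saturated yields F′ and Fm′. The absorption
method converts these to an absolute, chlorophyll-normalized electron
transport rate:

$$\mathrm{ETR} = \frac{F_m F_0}{F_m - F_0}\cdot
\frac{F_m' - F'}{F_m'}\cdot E \cdot \frac{K_A}{[\mathrm{Chl}\,a]}
\cdot \frac{1}{3600}$$

with E in µmol photons m⁻² s⁻¹, the instrument calibration factor
$K_A = 11800$ m⁻¹ and Chl *a* in mg m⁻³. Only yield ratios enter, so
yields are treated as dimensionless relative fluorescence and the
synthetic generator normalizes F0 to 1.

A unit audit note: the trailing factor is implemented as a division by
3600, exactly as the formula is conventionally printed, although
$E\cdot K_A/[\mathrm{Chl}]$ is a per-second quantity and a strict
seconds-to-hours conversion would multiply. Because the factor is a
global scale it does not affect any ratio, saturation parameter, or
budget *fraction* the package reports; `etr_context(invert_time_factor
= TRUE)` flips the convention for users who prefer the multiplicative
reading. The synthetic generator inverts whichever convention the
analysis uses, so round trips are exact either way.

### P–E response curves

Both the ETR and carbon stages fit the Eilers–Peeters rational model

$$P(E) = \frac{E}{aE^2 + bE + c},\qquad
P_{max} = \frac{1}{b+2\sqrt{ac}},\quad \alpha = \frac1c,\quad
E_{opt} = \sqrt{c/a},\quad E_K = P_{max}/\alpha$$

through one shared fitter (`fit_pe_curve()`), so identical inputs give
identical parameters regardless of the entry point. The model was chosen
because it yields both a saturation plateau and an optional
photoinhibition optimum from 11-step ladders; $a = 0$ (no
photoinhibition, $E_{opt}=\infty$) is admissible.

Numerical choices: Levenberg–Marquardt on $(a, b, c)$ with $a \ge 0$ and
$c > 0$ enforced; starting values take $\alpha_0$ from the slope of the
two lowest-irradiance responses, $P_{max,0}$ from the maximum response
and $E_{opt,0}$ from its irradiance; up to 500 iterations with function
and parameter tolerances of 1e-15 (the fit is cheap, so the optimizer is
simply run to numerical convergence). Degenerate designs — fewer than 4
distinct irradiances, all-zero responses — raise typed errors rather
than returning garbage. The fitter's stated domain requires
sub-saturating coverage: if the true $E_K$ lies below the lowest
non-zero ladder step, $\alpha$ is not identifiable from the design and
recovery is not guaranteed.

### Carbon uptake, O₂ exchange, N₂ fixation

¹⁴C incorporation uses standard single-endpoint tracer calculus:
blank-corrected fraction of added activity × DIC × isotope
discrimination, normalized to incubation time and Chl. Defaults (DIC
2050 µmol L⁻¹, discrimination 1.05, 0.5 h incubations, 1.11e6 dpm
added) are configurable because published protocols rarely print them;
negative net counts clamp to zero with a warning, keeping rates
physical.

Gross O₂ evolution is net evolution at saturating light plus the
respiration magnitude measured in the dark immediately afterwards.
Respiration is stored as a positive magnitude everywhere; signs appear
only in budget arithmetic.

Acetylene reduction converts the headspace ethylene change to moles via
the ideal gas law (R = 0.08206 L atm mol⁻¹ K⁻¹, vial temperature and
pressure configurable, 28 °C / 1 atm defaults) and divides by the 4:1
C₂H₄:N₂ molar ratio. Ethylene dissolved in the liquid phase is
neglected by default — exact for the synthetic data and a small bias
(order of the Bunsen coefficient times the phase ratio) for real
vials; `constants$vial$bunsen` enables the correction.

### Phase budgets

Diel rate series are integrated into 12-h day/night totals by composite
trapezoid, treating rates as piecewise linear between samples. Phase
edges (0, 12, 24 h) are filled by extending the nearest measured value,
never by extrapolating a trend; a sample lying exactly on a phase
boundary informs the edge of both adjacent phases (it is the rate at the
transition instant). This makes the integral additive under any split at
a sample and exact for piecewise-linear rates sampled through the
boundary. A `mean12` convention (phase mean × 12 h) is available by
flag because sparse historical datasets are sometimes summarized that
way; trapezoid is the default.

### Electron budgets

Nitrogenase demand multiplies the daily N₂ amount by 8 e⁻ per N₂ and is
expressed as a percentage of the light-phase ETR integral evaluated
along the culture's own growth light profile. The electron-per-carbon
efficiencies are $\Phi_{max} = \mathrm{ETR}_{max}/P_m^B$ (ratio of the
fitted maxima) and $\Phi_{lim} = \alpha^{ETR}/\alpha^C$. Because
$\mathrm{ETR}_{max}$ varies over the day, $\Phi_{max}$ is also carried
as the mean over per-timepoint ratios; the two conventions differ on
real data and the summary stores both.

## The synthetic generator

The generator emulates one diel photobioreactor run with fully known
truth; its defaults are the study conditions of the two presets.

* **Light**: half-sine over a 12 h photoperiod,
  $E(t) = E_{max}\sin(\pi t/12)$, zero in the dark; `E_max` 400
  (Crocosphaera-like) or 130 (Cyanothece-like) µmol photons m⁻² s⁻¹.
  Hours count from light onset: light phase [0, 12), dark [12, 24).
* **FRRf ladders** at 1, 3, 5, 7, 9, 11 h into the light: 11 steps from
  0 to ~1500 µmol photons m⁻² s⁻¹, yields obtained by exact inversion
  of the ETR formula (no non-photochemical quenching: Fm′ = Fm), with
  Fv/Fm of 0.45/0.50 — typical dark-acclimated values for these taxa.
* **Preset P–E curves** are calibrated once, before any test was
  written, so the analysis reproduces the measured physiology: carbon
  curves pinned at the measured $E_{K,C}$ (331/88) and hourly $P_m^B$
  (0.237/0.175 µmol C (µg Chl)⁻¹ h⁻¹) with $E_{opt}$ solved so the
  light-phase carbon integral equals the published 12-h totals
  (1.66/1.01); ETR curves pinned at the measured hourly maxima
  (1.260/2.290 µmol e⁻ (µg Chl)⁻¹ h⁻¹), $E_{opt}$ 1300/900, and
  $\alpha^{ETR}$ solved so the light-phase ETR integral equals the
  published 6.80/8.03. The initial slopes are otherwise unpublished; a
  consequence of this calibration is an emergent $\Phi_{lim}$ of ~4.0
  and ~5.0 for the two presets, inside or near the reported spread
  (3.7 ± 1.3 / 3.7 ± 0.9). Matching the integrated ETR — which anchors
  the nitrogen electron-fraction chain — was judged the more important
  constraint, and the choice was not revisited.
* **O₂ electrode series** every 2 h: a diel gross-capacity schedule
  whose sparse-sampling phase totals equal the published day/night
  budgets (2.04/1.14 and 3.09/2.22 µmol O₂ (µg Chl)⁻¹ 12 h⁻¹), with
  constant per-phase respiration magnitudes reproducing 0.51/1.19 and
  1.10/0.92. Shapes between samples (mid-light peak, the
  Crocosphaera-like nocturnal capacity loss during active fixation) are
  qualitative anchors, not published data.
* **N₂ fixation schedules**: hourly dark-phase rates whose
  sparse-sampling night totals are exactly 77.1 and 93.7 nmol N₂
  (µg Chl)⁻¹, with the published peaks (31.7 at 10 h into the dark;
  43.0 at 6 h) and onset timing (delayed ~4-6 h vs immediate; both
  ceasing ~2 h before dawn). Intermediate hourly values are drawn once
  to interpolate those anchors. Ethylene accumulates linearly in each
  vial at 4× the scheduled rate.
* **OD₇₃₅** as a carbon-pool proxy: a state variable integrates the
  true carbon P–E curve along the light schedule minus a consumption
  term that ramps linearly over the light phase (respiration scaling
  with the accumulated store — this is what lets the optical density
  peak *before* lights-off) and is constant in the dark. Three
  calibration knobs (peak hour, reference fold, end-of-night fold) pin
  the published diel folds: 2.3× at 9 h light / 1.4× at dawn, and
  1.6× at 9 h / peak near the transition / 1.1× at dawn.
* **Noise**: multiplicative Gaussian with a single CV on every
  instrument readout, truncated at zero, through per-instrument RNG
  streams derived from one master seed — so adding noise to one
  instrument never shifts another's draw, and one seed fixes the whole
  dataset bit-for-bit. The source experiments do not report instrument
  CVs; 0.05 is the shipped default (replicate scatter of the published
  rates is mostly 2-15 %), and noise-free runs (`noise_cv = 0`) are
  used wherever exact recovery is asserted.

What the generator does **not** emulate: PSII photophysics (no
σPSII, no connectivity, no non-photochemical quenching, no diel
variation of the photosynthetic parameters), cell division and
population structure, electrode drift, dissolved-ethylene partitioning,
or count statistics of the scintillation counter (noise is Gaussian,
not Poisson). Passing recovery tests therefore demonstrates the
*calculus* of the pipeline is right, not that it is robust to every
artifact of real instruments.

## The CFM-CC competition model

Each species is reduced to a maximum photosynthesis rate `pmax` and a
constant respiration rate `m` (both d⁻¹); growth over the nutrient
repletion factor $f_N \in [0,1]$ is

$$\mu_i = P_{Max,i}\, f_N - m_i .$$

Because the laws are linear, the niche structure is fully determined by
the crossover $f_N^* = (m_b - m_a)/(P_{Max,b} - P_{Max,a})$, reported
only when it falls inside [0, 1]; equal slopes are classified as
`absent` (parallel) or `identical`. The grid evaluation
(`run_competition()`) labels exact ties explicitly rather than breaking
them arbitrarily.

The absolute parameter values behind the published model figure are not
available, so the default parameterization maps each species' measured
day-phase gross O₂ evolution onto `pmax` and its total daily respiration
onto `m` through a single proportionality constant (1 d⁻¹ per µmol O₂
(µg Chl)⁻¹ 12 h⁻¹, configurable). The constant rescales both axes but
cannot change the winner map's structure; what the package asserts is
therefore the *ordering* (the coastal-type species wins at high $f_N$,
the oceanic-type at low $f_N$, with exactly one transition at
$f_N \approx 0.30$), not absolute growth rates.

## Problem sizes and reproducibility

The shipped analyses are deliberately desk-scale: 11-point ladders × 6
timepoints, 12 electrode samples, 18 vials, a 5-min OD grid and a
101-point competition grid run in a few seconds, and the full test suite
(including 1000-pair property sweeps) in well under a minute. Diel
integrals use a 0.05 h trapezoid step (halving the step changes smooth
integrals by <1e-4 relative; steps above 0.25 h are flagged by the
config validator). All randomness flows from one integer seed recorded,
together with a hash of the scientific configuration, in the run log;
identical config and seed give byte-identical output files.

## Known limitations

* The published per-12-h ETRmax summary row follows a convention (its
  value matches neither 12× the hourly maximum nor the diel integral)
  that could not be reconstructed; the summary therefore carries both
  computable conventions and asserts neither.
* $\Phi_{max}$ computed from the fitted maxima (ratio of means) differs
  from per-timepoint averaging (mean of ratios) whenever ETRmax varies
  over the day; both are reported, and on the Cyanothece-like preset
  the ratio-of-means value (13.09) sits below the published
  per-timepoint mean (13.6 ± 3.1).
* Headspace-only ARA accounting slightly underestimates ethylene
  production when the dissolved phase is significant.
* The CFM-CC mapping from O₂ budgets to carbon-unit growth parameters
  assumes a fixed photosynthetic/respiratory quotient across species.
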