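# diazodiel

Diel photophysiology and electron budgets of unicellular marine
diazotrophs.

Unicellular nitrogen-fixing cyanobacteria such as *Crocosphaera watsonii*
(open-ocean, oligotrophic) and *Cyanothece* sp. (coastal, nutrient-rich)
separate oxygenic photosynthesis from oxygen-sensitive N₂ fixation in
time: carbon is fixed and stored by day, and nitrogenase runs at night on
the respired store. Quantifying that daily ledger requires stitching
together several instruments — fast repetition rate fluorometry (FRRf),
¹⁴C uptake incubations, Clark-electrode O₂ exchange, acetylene-reduction
assays and photobioreactor OD₇₃₅ logs — each with its own calculus.
`diazodiel` implements that full chain as a tested, config-driven R
pipeline, for experimentalists analyzing 12:12 L:D photobioreactor runs
and for modellers who need the resulting phase-integrated budgets.

## What it computes

**Absolute Chl-normalized electron transport** from FRRf yields
(absorption method):

    ETR = (Fm·F0)/(Fm−F0) · (Fm′−F′)/Fm′ · E · KA/[Chl a] · 1/3600

**P–E curves** (shared by the ETR and ¹⁴C stages) with the
Eilers–Peeters rational model

    P(E) = E / (aE² + bE + c),
    Pmax = 1/(b+2√(ac)),  α = 1/c,  Eopt = √(c/a),  Ek = Pmax/α

fitted by Levenberg–Marquardt least squares.

**Carbon uptake** from scintillation counts (blank-corrected fraction of
added activity × DIC × isotope discrimination, per hour and µg Chl),
**gross O₂ evolution** (net light rate + dark respiration magnitude),
**N₂ fixation** from headspace ethylene via the ideal-gas law and the
theoretical 4:1 C₂H₄:N₂ ratio, and 12-h **phase budgets** by trapezoidal
integration of the diel series.

**Electron budgets**: nitrogenase demand (8 e⁻ per N₂) as a share of
daytime electron transport, and the electron-per-carbon efficiencies
Φ_max = ETRmax/P_mᴮ and Φ_lim = α^ETR/α^C.

**CFM-CC competition model**: each species is reduced to a linear growth
law μᵢ = PMaxᵢ·f_N − mᵢ over the nutrient repletion factor f_N ∈ [0, 1];
the package computes the analytic niche crossover and the winner map of
the two-species competition.

A seeded **synthetic-data generator** emulates the photobioreactor
experiment (half-sine 12:12 light, diel OD₇₃₅ rise and fall, FRRf
ladders, nocturnal fixation windows, configurable multiplicative noise)
with fully known ground truth, so the entire pipeline is testable by
parameter recovery.

## Worked example

```r
library(diazodiel)
cfg <- default_config(seed = 1, noise_cv = 0)   # noise-free study conditions
report <- run_pipeline(cfg)
print(report$physiology$crocosphaera)
```

```
crocosphaera physiology (Chl-normalized, per 12-h phase):
  Ek_C 331; ETRmax 1.26 h-1; PmB 0.237 h-1
  ETR integral 6.8; C integral 1.66 (light phase)
  O2 evolution day/night 2.04/1.14; respiration 0.51/1.19
  N2 fixation day/night 0/0.0771 umol; e- demand 0.6168 (9.07% of daytime ETR)
  Phi_max 5.316 (mean-of-ratios 5.316); Phi_lim 3.997 e- C-1; day respiration 25% of gross O2
```

Reading: carbon uptake saturates at Ek_C = 331 µmol quanta m⁻² s⁻¹; over
the light phase the cells transport 6.8 µmol e⁻ (µg Chl)⁻¹ and fix
1.66 µmol C; nightly N₂ fixation (77.1 nmol) costs 0.62 µmol e⁻, about
9 % of the daytime electron flux; a quarter of gross daytime O₂
production is respired in place.

```r
print(report$crossover)
#> $status
#> [1] "crossover"
#> $fN
#> [1] 0.3047619
```

With growth laws proportional to the measured budgets, the
*Crocosphaera*-like species wins below f_N ≈ 0.30 (oligotrophic end) and
the *Cyanothece*-like species above it — the measured difference in
carbon consumption alone separates the niches.

Outputs on disk (`summary_table1.csv`, `comparison.json`,
`competition.csv`, `crossover.json`, per-species `pe_fit.csv`,
`phase_budgets.csv`, `n2fix_rates.csv`, provenance log) land in
`cfg$output_dir`; identical config + seed reproduces them byte-for-byte.

There is also a thin CLI:

```sh
Rscript inst/cli/diazodiel.R all --config inst/extdata/config.yaml --seed 1 --out results/
```

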