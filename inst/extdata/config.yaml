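# Default diazodiel run configuration.
# mode: synthetic (generate seeded datasets) or csv (analyze existing
# per-species directories under input_dir).
mode: synthetic
seed: 1
noise_cv: 0.05

constants:
  KA: 11800              # FRRf calibration factor, m^-1
  invert_time_factor: false
  dt: 0.05               # diel integration step, h (<= 0.25)
  ara_ratio: 4           # mol C2H4 per mol N2
  electrons_per_n2: 8
  budget_method: trapezoid
  c14:
    t_inc: 0.5           # h
    dic: 2050            # umol C L^-1
    discrimination: 1.05
  vial:
    headspace_ml: 10
    sample_ml: 5
    dt_h: 1
    temperature: 28      # deg C
    pressure: 1          # atm
    bunsen: 0            # dissolved-ethylene correction, off by default

species:
  crocosphaera:
    preset: crocosphaera
    E_max: 400           # umol photons m^-2 s^-1
    chl: 150             # mg m^-3
  cyanothece:
    preset: cyanothece
    E_max: 130
    chl: 150

cfm:
  k_scale: 1             # d^-1 per umol O2 (ug Chl)^-1 12 h^-1
  n_grid: 101
  # species: {crocosphaera: {pmax: 2.04, m: 1.70}, ...} to override
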