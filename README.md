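# musmb

Simulation and on-line mass-spectrometric monitoring of micro
simulated-moving-bed (µSMB) desalting.

## The problem

Native ESI mass spectrometry is one of the most informative readouts for
biopharmaceutical process monitoring, but most biological buffers kill it:
Tris at even 0.01 mM measurably suppresses protein signals, and at 1 mM
less than 40% of a heme protein is still detected. Conventional LC
desalting is batch-wise and therefore never truly on-line. A micro
simulated-moving-bed size-exclusion process solves this: four small
desalting columns, switched countercurrently to the flow, continuously
exchange the buffer of a protein feed, and the protein-rich raffinate
stream (fixed at 30 µL/min) is infused straight into the ESI source.

`musmb` implements the full computational chain of such a system for
process designers and PAT (process analytical technology) developers:

* **Transport correlations** — Chung–Wen axial dispersion,
  Wilson–Geankoplis film transfer, Polson diffusivity
  (D_m = 2.74·10⁻⁹ · M_w^(−1/3) m²/s), particle Reynolds number.
* **Column model** — the lumped rate model with pores for pure size
  exclusion: bulk convection–dispersion coupled to a film-limited,
  well-mixed pore phase with capacity ε_p·K_d per species
  (K_d = 1 fully permeating, 0 fully excluded); finite-volume
  discretization, Danckwerts boundaries, stiff method-of-lines
  integration via `deSolve`. Tracer-pulse analysis recovers
  ε_int, ε_total, ε_p from first moments.
* **SMB process** — triangle-theory operating points on the flow-rate
  ratios m_j = (Q_j·t_s − V·ε_int)/(V(1−ε_int)); four-zone open-loop
  simulation with port switching, node balances, cyclic-steady-state
  (CSS) detection, desalting level 1 − c̄_raff/c_feed and protein
  recovery.
* **MS detector model and processing** — synthetic native ESI-TOF
  spectra (charge envelopes 7+–9+ of holo-/apo-myoglobin, sodium-adduct
  ladders, heme at m/z 616.18/633.16, the saturating Tris ion at
  m/z 593.23, log-logistic buffer suppression, Poisson counting noise),
  plus the standard processing chain: extracted-ion chromatograms
  (±0.02 m/z), baseline trace (m/z 400–500), zero-charge protein
  reconstruction (input 1700–2600 m/z, output 5–20 kDa at 0.5 Da),
  peak-group integrals and the per-switch apo-protein percentage.
* **Synthetic experiments** — complete seeded in-silico runs
  (conductivity sensors with the reference calibrations, continuous MS
  acquisition across feed exchanges, ground-truth tables) written as
  CSV/mzML bundles with a JSON manifest, and an analyzer that recomputes
  the metrics from the files alone.

## Worked example

Simulate the reference desalting run (100 mM Tris + 0.2 g/L myoglobin
feed) at the experimentally optimized operating point:

```r
library(musmb)

cfg <- smb_preset("reference")
report_operating_parameters(cfg)
#>   diluent_flow: 122
#>   extract_flow: 44
#>   feed_flow: 15
#>   raffinate_flow: 30
#>   waste_flow: 63
#>   switching_time: 120

res <- simulate_smb(cfg, column_params(),
                    default_species(tris_mM = 100, mb_gL = 0.2),
                    n_cycles = 6)
m <- process_metrics(res)
#> CSS reached at cycle 5
#> mean raffinate Tris at CSS: 0.051 mM
#> desalting level: 99.95%
#> protein recovery in raffinate: 96.8%
```

The six operating parameters are the flow preset; the last four lines are
computed: the raffinate profile repeats to within 1% (relative L2) from
cycle 5 on, the CSS-mean raffinate Tris of 0.051 mM corresponds to a
99.95% desalting level with these idealized columns (a real, less
efficient column train reaches ~98%), and 96.8% of the fed protein leaves
through the raffinate, i.e. into the mass spectrometer.

A complete synthetic µSMB-MS experiment, including detectors:

```r
plan <- preset_plan("constant_tris")   # 10 mM Tris, 0.2 g/L Mb, 6 cycles
bundle <- generate_run(plan, scan_interval = 1)
write_run_bundle(bundle, "run2_bundle")
cmd_analyze("run2_bundle")
```

A thin command-line front end covering `design`, `simulate`, `generate`
and `analyze` ships as `inst/cli/musmb.R`.

## Vignette

`vignettes/musmb-methods.Rmd` documents the models, their assumptions,
the numerical choices, the synthetic-data generator's fidelity and its
known limitations.
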