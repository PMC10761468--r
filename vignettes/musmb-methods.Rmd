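---
title: "Models and methods behind musmb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind musmb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`musmb` simulates a micro simulated-moving-bed (µSMB) size-exclusion
desalting process hyphenated to a native ESI-TOF mass spectrometer, and
implements the complete analysis chain an operator of such a system would
run: operating-point design, process simulation, cyclic-steady-state (CSS)
detection, desalting metrics, synthetic detector traces, and MS
post-processing down to the apo-protein percentage. The model system is
myoglobin (Mb, a heme protein whose intact "holo" form is distinguishable
from its dissociated "apo" form) being transferred continuously out of a
Tris buffer — a buffer that is notoriously incompatible with electrospray
ionization — into a volatile ammonium acetate buffer.

All data the package consumes can be generated in-silico by its own
synthetic-data module; external chromatogram/spectrum tables (CSV, mzML)
are accepted through the same readers.

# Column model

## Lumped rate model with pores

A single desalting column is modelled with the lumped rate model with
pores (LRMP). Per species $i$, with interstitial concentration $c$ and
pore-phase concentration $c_p$:

$$\frac{\partial c}{\partial t} =
  -u_\mathrm{int}\frac{\partial c}{\partial z}
  + D_\mathrm{ax}\frac{\partial^2 c}{\partial z^2}
  - \frac{1-\varepsilon_\mathrm{int}}{\varepsilon_\mathrm{int}}
    \frac{3}{r_p} k_\mathrm{film}\,(c - c_p),$$
$$\varepsilon_p K_{d,i}\frac{\partial c_p}{\partial t} =
  \frac{3}{r_p} k_\mathrm{film}\,(c - c_p).$$

There is no adsorption term: the separation is pure size exclusion, and
the entire size-exclusion effect is carried by the pore-access
(distribution) coefficient $K_d \in [0,1]$ — 1 for a fully permeating
solute (Tris, acetone), 0 for a fully excluded macromolecule (Mb, blue
dextran). A fully excluded species has no pore exchange at all. The LRMP
was chosen over the general rate model because, for this separation, film
transfer and intraparticle diffusion cannot be distinguished from
single-column pulse data; a single lumped film coefficient is the most
complex transport description the data can support.

Transport parameters come from standard literature correlations evaluated
in SI units at a single conversion boundary (`R/params.R`): axial
dispersion from the Chung–Wen correlation, the film coefficient from
Wilson–Geankoplis, molecular diffusivity from the Polson molar-mass
correlation $D_m = 2.74\times10^{-9}\,M_w^{-1/3}$, and the particle
Reynolds number with the interstitial velocity
$u_\mathrm{int} = Q/(A\,\varepsilon_\mathrm{int})$ (the standard
interstitial convention). At zero velocity the dispersion correlation
returns exactly 0 so that momentarily stopped zones remain representable.

## Numerics

The spatial discretization is finite-volume with first-order upwind
convection and central dispersion; the inlet boundary is the Danckwerts
flux condition (pure advective influx $u\,c_\mathrm{in}$ into the first
cell), the outlet is zero-gradient. This conserves mass exactly at the
scheme level; pulse tests close the balance to a few times $10^{-5}$
relative. The method-of-lines system is linear with constant
coefficients, so the stiff integrator (`deSolve::ode`, lsoda) is run with
the exact Jacobian at tolerances rtol $10^{-8}$/atol $10^{-10}$. The
default grid of 60 cells changes the outlet first moment by less than
0.2% on refinement to 120 cells; first moments agree with the analytic
LRMP value $V[\varepsilon_\mathrm{int} +
(1-\varepsilon_\mathrm{int})\varepsilon_p K_d]/Q$ to well under 1%.
Solver output is floored at zero for reporting only, never inside the
integrator.

Tracer analysis follows the classic two-tracer scheme: blue dextran
(excluded) probes the interstitial porosity, acetone (permeating) the
total porosity, and
$\varepsilon_p = (\varepsilon_\mathrm{tot}-\varepsilon_\mathrm{int})/(1-\varepsilon_\mathrm{int})$.
The first-moment estimator exposes the injection-width correction
(subtract half the plug width) as an option, since whether measured
moments were so corrected is ambiguous in practice; the package's own
round-trip tests use the correction and recover random porosity pairs
within 2%.

# SMB process

## Topology and port switching

The process is a four-zone open-loop SMB with one column per zone: fresh
diluent enters zone 1, the extract (Tris-rich) is drawn after zone 1, the
feed is mixed in before zone 3, the raffinate (protein-rich) is drawn
after zone 3, and the zone 4 outlet goes to waste. The fourth zone is not
needed thermodynamically in an open loop, but it decouples the zone 3
flow from the raffinate flow, which lets the raffinate — the stream
infused into the MS — be fixed (30 µL/min here). Because the raffinate
outlet cannot be pressure-controlled when it feeds the ESI source, its
flow follows the overall liquid balance: diluent + feed − extract −
waste. Port switching is implemented as a rotation of the column-to-zone
assignment with each column moving one zone upstream per switch —
equivalent to switching the columns against the direction of the mobile
phase. Column states persist across switches, so the start-up transient
and CSS emerge rather than being imposed.

Within one switching interval the four columns are solved sequentially
(the coupling is strictly downstream), each receiving the upstream
outlet, interpolated on the sampling grid, as its inlet; the feed node
mixes $c_\mathrm{in} = (Q_2 c_{Z2,\mathrm{out}} + Q_F c_F)/Q_3$. A
single-switch simulation is therefore *identical* to manually chaining
single-column solves — this is asserted bitwise in the tests.

## Operating-point design

For linear SEC the triangle-theory constraints act on the flow-rate
ratios $m_j = (Q_j t_s - V\varepsilon_\mathrm{int}) /
(V(1-\varepsilon_\mathrm{int}))$ against the pore-phase capacities
$H_i = \varepsilon_p K_{d,i}$. `triangle_design()` places $m_1$ above
$H_\mathrm{strong}$ and $m_4$ below $H_\mathrm{weak}$ with a relative
safety margin, and $m_2, m_3$ symmetrically inside
$(H_\mathrm{weak}, H_\mathrm{strong})$ shrunk by the same margin, which
maximizes the feed flow under that margin. When a fixed raffinate flow is
requested, zone 4 is set to the largest flow that still retains the weak
species and $Q_3 = Q_4 + Q_R$; the symmetric $m_3$ is used when smaller.
This is a deliberate simplification: the experimentally used operating
point came from a stochastic optimizer that we do not reproduce, so the
experimentally optimized stream flows (diluent 122, extract 44, feed 15, raffinate 30,
waste 63 µL/min, 120 s switching) are shipped verbatim as
`smb_preset("reference")` and all worked examples use them directly.

## CSS and metrics

CSS is declared at the smallest cycle whose raffinate profile differs
from the previous cycle's by less than $10^{-2}$ in relative L2 norm — a
deliberately strict criterion chosen to be robust against the detector
noise the synthetic-data module injects. From a cold start the reference
system needs 5 cycles by this criterion, slightly more than the 2–3
cycles a visual "recurring pattern" judgement would give. The desalting
level is $1 - \bar c_\mathrm{raff}/c_\mathrm{feed}$ with the mean taken
over CSS cycles only, making it independent of process time; protein
recovery is the analogous raffinate/feed mass-flow ratio.

Optional per-column porosity perturbations (±1%, seeded) reproduce the
experimentally observed pattern that peak heights differ between columns
but recur every fourth switch.

# MS detector model and processing

## Spectrum synthesis

Spectra live on a uniform m/z grid (default 0.01 spacing over the
acquisition range 400–2600, so the ±0.02 extraction window holds five
samples). Proteins appear as Gaussian peaks (σ = 0.05 m/z; isotope fine
structure is deliberately omitted) at
$(M + n_\mathrm{Na}\cdot 21.98249 + z\cdot 1.00728)/z$ for their charge
states and a geometrically decaying sodium-adduct ladder — each adduct
replaces a proton, so the neutral-mass spacing is ~22 Da (the
"approximately 23 Da" read off measured reconstructions is observational
rounding). The default envelope puts holoMb (17566.0 Da) at charges 7–9
and apoMb (16950.5 Da) at 8–9, the five-peak pattern of the native
spectrum; which of the six mass/charge combinations is invisible is a
configuration choice.

Amplitudes are calibrated on the reconstruction: the amplitude share of
peak $(z, n_\mathrm{Na})$ is $w_z w_n/(z\sigma\sqrt{2\pi})$, so a
species' reconstruction peak-group integral equals `response_factor` ×
concentration exactly in the continuum limit (each m/z Gaussian maps to a
mass-domain Gaussian of width $z\sigma$). The holo response is anchored
at 46.4 kcps for 0.01 g/L at zero buffer; the 0.5 Da reconstruction grid
undersamples the ~0.4 Da mass-domain peaks, which biases the discrete
integral by ~3% — visible in the acceptance output and accepted as a
discretization property rather than calibrated away. The heme group is a
fixed-peak species (m/z 616.18, oxidized form 633.16 at 1:4) with a
response factor set above apo's equimolar response, reflecting the higher
ion yield of the small molecule; free heme is generated equimolar to apo.

The Tris buffer ion at m/z 593.23 follows limited growth
$A_\mathrm{max}(1-e^{-c/c_\mathrm{sat}})$ with $c_\mathrm{sat}$ = 0.5 mM,
reaching ~23 kcps in the ±0.02 window at saturation; the same saturation
drives a broadband background (per-point Poisson floor 2 cps rising by 18
cps at saturation, placing the 100 mM-feed baseline at ~10× the
buffer-free baseline). Counting noise is Poisson on every grid point,
seeded. Flow-stop artifacts (baseline drops during feed exchanges) are
not injected by default.

## Suppression model

Ionization suppression by Tris is log-logistic in concentration,
$f(c) = 1/(1+(c/c_{50})^h)$, fitted through two anchors — 88% detected at
0.01 mM and 35% at 1 mM, consistent with the qualitative bounds "below
90%" and "below 40%" — giving $c_{50} = 0.335$ mM, $h = 0.567$. $f(0)=1$
by construction and $f$ is monotone; the small non-monotone enhancement
some systems show at trace buffer levels is representable through extra
anchor points but disabled by default. Suppression multiplies all
protein and heme responses; the buffer ion itself is not suppressed.
Because Mb elutes countercyclically to the Tris breakthrough within each
switch, the time-resolved detected holo fraction in a µSMB run exceeds
$f(\bar c)$ at the mean raffinate concentration — the mechanism by which
the hyphenation recovers most of the signal even at 10–100 mM feed Tris.

## Post-processing

The processing chain mirrors standard vendor tooling: extracted-ion
chromatograms sum a ±0.02 m/z window per scan; the baseline chromatogram
is the 400–500 m/z window; the zero-charge reconstruction maps the
1700–2600 m/z range onto a 5–20 kDa mass grid at 0.5 Da by summing
interpolated intensities at $(M + z\cdot1.00728)/z$ over all charges
landing in the input range; peak-group integrals (trapezoidal, default
±100 Da) capture the adduct satellites; and the apo percentage
$A_\mathrm{apo}/(A_\mathrm{apo}+A_\mathrm{holo})$ is computed per
switching interval aligned to the switch boundaries. Windows shorter than
one switching interval sample different phases of the countercyclical
concentration waves and are demonstrably noisier; the tests assert this.

# Synthetic experiments

`generate_run()` chains SMB sections (feed schedule, states carried over,
detector clock continuous across feed exchanges), then renders detectors:
calibrated conductivity sensors (slopes 15.359/15.382 mM/(mS/cm),
intercepts 0.3656/0.2993 mM for extract/raffinate) with Gaussian noise
(σ = 0.01 mS/cm — the real sensor noise is unreported, so this is an
exposed guess) floored at zero, and the streaming MS detector (per-scan
XICs and per-switch mean-spectrum reconstructions, O(one spectrum)
memory). Preset plans encode the two reference hyphenated experiments: a stepwise
Tris staircase 0/1/5/10/50/100 mM (11 cycles, then 3 each) and a constant
10 mM run over six cycles. All randomness flows from one run-level seed
with fixed per-detector substreams; identical seeds give bit-identical
bundles.

## What the generator does and does not emulate

It emulates: tracer pulses with detector noise, conductivity traces with
the reference sensor calibrations, start-up and CSS dynamics, inter-column
heterogeneity (every-fourth-peak pattern), charge envelopes with sodium
adducts, concentration-dependent suppression, baseline saturation at
high buffer levels, and the countercyclical Tris/Mb elution. It does not
emulate pump/pressure dynamics, switching-time flow spikes, valve
leakage, memory effects at the ESI interface, or isotope structure —
so passing tests validate the computational chain on idealized columns,
not the hardware. Two consequences are worth knowing. First, with the
idealized default transport parameters (the experimentally fitted values
live in supplementary material that is not reproduced here) the
reference operating point desalts to ~99.9%, better than the ~98%
a real lower-efficiency column train achieves; the desalting *analysis*
is validated against the generator's own ground truth, not against that
measured value. Second, the resulting raffinate Tris level sits below the
raffinate sensor's calibration intercept (0.2993 mM), so the synthetic
raffinate sensor reads mostly its floor; sensor-derived desalting is
still within one percentage point of truth at 100 mM feed, and the
extract sensor (≈34 mM) round-trips cleanly.

# Problem sizes and numerical defaults

Defaults used by the examples, tests and the acceptance script, chosen as
a deliberate accuracy/effort compromise: 60 axial cells per column,
1 s outlet sampling, 6-cycle stand-alone runs and 4-cycle hyphenated runs,
MS scans at 1–2 s intervals on the 0.01 m/z grid (the instrument's 0.25 s
accumulation is the generator default and scales linearly). CSS tolerance
$10^{-2}$ relative L2; solver rtol $10^{-8}$; porosity round-trip
tolerance 2%; mass-balance defect bound 1%.

# Known limitations

* $K_d$ values are binary by default (0 or 1); partially permeating
  species are supported but the shipped system does not use them.
* The film-transfer correlation is used as-is rather than fitted, so
  front sharpness — and with it the absolute desalting level — is
  optimistic relative to a real packed bed.
* The suppression law is a two-parameter interpolation of measured
  anchors, not a mechanistic ESI model; extrapolation far above 100 mM is
  not meaningful.
* The reconstruction is a plain zero-charge transform; it is exact for
  the synthetic Gaussian envelopes but is not a maximum-entropy style
  deconvolution and will ring on overlapping envelopes.
* mzML export writes profile spectra through `mzR`; vendor-specific
  metadata is not modelled.
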