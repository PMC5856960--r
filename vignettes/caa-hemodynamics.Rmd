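---
title: "Reduced-order hemodynamics of coronary artery aneurysms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order hemodynamics of coronary artery aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caahemo)
```

## Why this package exists

Kawasaki disease can leave children with coronary artery aneurysms (CAAs).
The standing clinical rule initiates anticoagulation when the maximum
aneurysm diameter reaches 8 mm (or Z-score > 10), yet two aneurysms with the
same maximum diameter can expose their walls to very different shear
environments depending on their *length*: a long fusiform dilation holds a
large, slowly turning-over blood volume at low wall shear stress (WSS), a
known precursor of thrombosis, while a short one does not. `caahemo`
implements a desk-scale model chain that makes this argument quantitative:

1. **geometry** — virtually morph a fusiform aneurysm of prescribed maximum
   diameter `D_max` and length `L` onto a vessel centerline;
2. **circulation** — a closed-loop lumped-parameter network (LPN) of the left
   heart, systemic load and a coronary outlet bed, tuned to clinical targets,
   produces a periodic coronary flow waveform;
3. **hemodynamics** — a quasi-steady Poiseuille closure converts the flow and
   the lumen radius profile into distributed WSS and the standard
   thrombosis-risk surrogates: TAWSS, low-WSS area fractions
   (`Area_WSS4`, `Area_WSS1`), OSI, and a residence-time surrogate;
4. **pipeline** — a virtual cohort of four aneurysms (8/20, 8/40, 7/40,
   7/80 mm `D_max`/length) plus an unmorphed control, all driven by one tuned
   flow so that every hemodynamic difference is induced by geometry alone.

The model is deliberately reduced-order. It replaces a 3D finite-element
Navier–Stokes solution with a one-dimensional closure, so individual WSS
*magnitudes* are approximate; the quantities the package stands behind are
*orderings* across geometries sharing a flow (the aspect-ratio trend),
area fractions, and the tuned circulation's physiology.

## Aneurysm morphing

A centerline is an ordered polyline of 3D points (cm); cumulative Euclidean
segment lengths give the arclength parameter $s$. A morph specification
carries `D_max` (mm), length `L` (mm), the proximal neck position (cm) and
the healthy baseline diameter `D_0` (mm); the dimensionless **aspect ratio**
is `L / D_max`. Geometry is held internally in CGS units; specifications use
clinical mm and are converted on ingest.

The radius profile interpolates
$(s_0, r_0) \to (s_0 + L/2, D_{max}/2) \to (s_0 + L, r_0)$ with zero slope at
all three control points, using the clamped cubic Hermite step
$h(u) = 3u^2 - 2u^3$ on each shoulder. Because $h$ is monotone and bounded,
the profile can neither overshoot $D_{max}/2$ nor undershoot $r_0$, and it is
continuously differentiable everywhere including the necks.

**Shoulder length is set by a bounded taper angle, not by the aneurysm
length.** Each neck taper spans
$\ell = \min(L/2,\; \Delta r / \tan\theta)$ with $\Delta r = (D_{max}-D_0)/2$
and a default taper half-angle $\theta = 20^\circ$; between the shoulders the
profile holds the full caliber $D_{max}/2$. This was a genuinely open design
point, and the choice is load-bearing. If instead the whole profile is
stretched affinely with $L$, the distribution of radii over normalized
arclength is *identical* for every length, and any area-averaged function of
$r(s)$ — including Poiseuille TAWSS — becomes length-invariant at fixed
`D_max`, erasing the central aspect-ratio trend. Morphologically, fusiform
aneurysms dilate over a limited taper at each neck and extend their *body*;
the bounded-angle shoulder encodes exactly that, and the trend (longer
aneurysm → proportionally more full-caliber, low-shear body → lower mean
TAWSS, higher low-WSS area) then emerges from the closure rather than being
imposed. The morph is single-lobe and axisymmetric; real CAAs with multiple
lobes and asymmetry are outside this generator's vocabulary.

Surface areas and lumen volumes are surfaces/solids of revolution,
$\int 2\pi r \sqrt{1 + r'^2}\, ds$ and $\int \pi r^2\, ds$, integrated by
composite Simpson quadrature with 800 intervals by default (configurable).
The profile is $C^1$ with curvature jumps at the control points, so Simpson's
nominal order degrades locally; at 800 intervals halving the step changes
results by far less than 0.01%, which the test suite asserts.

## The closed-loop circulation

The LPN is the minimal closed loop that produces realistic aortic pressure
and left-coronary flow waveforms — six states:

* **Left ventricle** (volume $V$): time-varying elastance
  $P_{lv} = E(t)\,(V - V_0)$ with
  $E(t) = E_{min} + (E_{max}-E_{min})\,a(t)$ and a single smooth raised-cosine
  activation $a(t) = \tfrac12(1 - \cos 2\pi t/T_s)$ over the systolic
  interval $T_s = 0.3\sqrt{T}$ (seconds; $T$ = cycle length). The square-root
  scaling mimics the physiologic shortening of systole at faster rates.
* **Valves**: ideal diodes smoothed by a logistic opening over 0.1 mmHg with
  small forward resistances, keeping the right-hand side smooth for the
  integrator.
* **Systemic load**: proximal resistance $R_p$ in series with the aortic
  valve, arterial compliance $C_{sys}$ at the aortic node, distal resistance
  $R_d$ to the venous capacitor.
* **Coronary branch**: $R_a$ – $C_a$ – $R_{a,micro}$ – $C_{im}$ – $R_v$. The
  intramyocardial compliance $C_{im}$ is referenced to the tissue pressure
  $P_{im}(t) = \gamma P_{lv}(t)$ (default $\gamma = 0.5$), so ventricular
  contraction squeezes the distal bed and throttles systolic perfusion —
  the mechanism that makes left coronary flow diastolic-dominant. Setting
  $\gamma = 0$ removes the coupling and demonstrably lowers the diastolic
  share.
* **Venous return**: a large venous capacitance through a return resistance
  into a constant-elastance atrium (modeled as the capacitor
  $C_{la} = 1/E_{la}$).

Summing the stored volumes shows the loop conserves total blood volume
exactly at the continuous level; at periodic steady state the tests require
the cycle-net ventricular volume change to stay below 0.5% of stroke volume
and every capacitor node to return to its starting pressure.

Integration uses adaptive `lsoda` (relative tolerance 1e-6, absolute 1e-8)
cycle by cycle, with output on a 500-steps-per-cycle grid (the output grid
does not constrain the internal adaptive step). **Periodic steady state** is
declared when the maximum relative cycle-to-cycle change of aortic pressure
falls below a tolerance; the default reporting tolerance is 1%, while tuning
and quantitative measurements use 2e-4, which empirically places the final
cycle within ~0.02% of the exact limit cycle.

### Parameter scaling and tuning

Starting parameters come from zero-order circuit relations normalized to the
patient: total systemic resistance from $(\mathrm{MAP} - P_{ven})/CO$ with
$\mathrm{MAP} = P_{dia} + PP/3$, arterial compliance from $SV/PP$, coronary
chain resistance from current division at the requested coronary flow
fraction (split 0.32/0.52/0.16 across $R_a$/$R_{a,micro}$/$R_v$, the standard
proportions for left-coronary outlet beds), elastance from systolic pressure
over stroke volume, and volumes/compliances scaled by stroke volume.

Tuning is a deterministic damped fixed-point iteration, not a generic
optimizer: each pass simulates to periodic steady state and rescales
$\{R_d, R_p\}$ by the implied MAP/CO ratio, $C_{sys}$ by the pulse-pressure
ratio, $E_{max}$ by the stroke-volume ratio, and the coronary chain by the
flow-fraction ratio, each with damping exponent 0.7. Because matching the
formula-MAP and pulse pressure is algebraically equivalent to matching
systolic and diastolic pressure, the loop drives all four targets jointly.
The loop aims at a 20% safety margin inside the user-facing 5% tolerance so
that a re-simulation from any initial state still verifies within 5%; an
initial parameter set that already matches within 5% is a fixed point and is
returned unchanged. Exhausting the 40-iteration budget raises an error
carrying the final residuals.

## Shear metrics

With flow taken uniform along the modeled segment (rigid wall,
incompressible, no side branches), the quasi-steady Poiseuille closure gives
$$\tau(s,t) = \frac{4 \mu\, Q(t)}{\pi\, r(s)^3},$$
signed with the instantaneous flow direction, with $\mu = 0.04$ poise and
$\rho = 1.06$ g/cc as fluid constants (mL/s and cm³/s coincide, so no unit
conversion enters). No Womersley correction is applied by default; at
coronary Womersley numbers the amplitude correction would rescale pulsatile
components without affecting the orderings the package reports.

* **TAWSS**$(s) = \frac1T \int_0^T |\tau|\,dt$ (trapezoid on the waveform
  grid); the per-case value is the *surface-area-weighted* mean over the
  aneurysm span, since the quantity of interest is exposure of the wall.
* **Area fractions**: percentage of span surface area with TAWSS strictly
  below 4 (resp. 1) dyn/cm²; ties at the threshold count as not-exposed.
  Areas use the same surface-of-revolution weights as the mean, so nesting
  `Area_WSS1 ≤ Area_WSS4` holds structurally; sub-ulp summation overshoot is
  clamped at 100.
* **OSI**$(s) = \tfrac12\left(1 - |\int \tau\,dt| / \int |\tau|\,dt\right)$,
  defined 0 where the shear vanishes identically, clamped to $[0, 0.5]$.
* **Residence time**: aneurysm lumen volume over cycle-mean flow — a
  volume-turnover surrogate for Lagrangian particle residence time, labeled
  as such; it requires a positive cycle-mean flow.

The metric grid uses 401 axial samples across the span. The aneurysm region
for all denominators is the morphed span $[s_0, s_0 + L]$ — the only
unambiguous delimitation for a virtual morph.

## Synthetic data: what it does and does not emulate

No patient images or accessions back this package; the synthetic module
replaces them.

* `table1_cohort()` returns the four morph specifications and the unmorphed
  control. The shared baseline diameter defaults to **3.5 mm** (typical adult
  LAD caliber; the healthy caliber of the source anatomy is not published)
  and the proximal neck sits 1 cm from the inlet with at least 1 cm of
  straight run-out beyond the longest morph.
* `default_clinical_targets()` fixes the cohort's shared physiology: heart
  rate 80 beats/min, 110/70 mmHg, stroke volume 60 mL, BSA 1.5 m², coronary
  branch fraction 0.04 — a school-age/adolescent profile typical of the
  population carrying giant CAAs. These are the held-constant study
  conditions, chosen once.
* `generate_patient(seed)` draws plausible targets (uniform HR 60–100,
  systolic 90–130, diastolic 50–85 with systolic > diastolic enforced, SV
  scaled to BSA, coronary fraction 0.03–0.05) and a gently curved centerline,
  deterministically per seed and without touching the caller's RNG state.
* `fixture_flow_waveform()` provides constant, sinusoid and
  biphasic-coronary shapes so shear metrics are testable without the LPN.

Because the closure depends on the radius profile against *arclength* only,
centerline curvature does not influence the metrics; curvature-induced
secondary flows, lobed/asymmetric lumens, stenoses and branch take-offs are
genuinely 3D features that passing tests here say nothing about.

## Numerical choices, in one place

| Quantity | Default | Rationale |
|---|---|---|
| Axial metric samples | 401 over the span | resolves the shoulder profile; halving changes fractions < 0.5 pp |
| Quadrature | Simpson, 800 intervals | < 0.01% change on step halving |
| ODE tolerances | rtol 1e-6, atol 1e-8 | waveform features ≫ tolerance |
| Output grid | 500 steps/cycle | trapezoid integrals < 0.2% error |
| Valve smoothing | 0.1 mmHg logistic | non-stiff switching, < 1e-3 leak |
| Steady-state tol | 0.01 report / 2e-4 measure | limit-cycle gap ~0.02% at 2e-4 |
| Tuning | damping 0.7, margin 0.8 × tol, budget 40 | deterministic, transfer-safe |
| Taper half-angle | 20° | fusiform neck morphology; trend mechanism |

Degenerate inputs are contracts, not surprises: a morph with
`d_max = baseline` is a uniform tube; zero-length intervals integrate to 0;
inverted intervals, spans beyond the centerline, non-positive thresholds,
zero total flux (diastolic fraction) and non-positive mean flow (residence
time) raise typed errors.

## Worked cohort run

```{r cohort, eval = FALSE}
rep <- caa_table1(seed = 1)
rep$report
rep$trend
```

The report carries one row per case (control last) with the documented
column order `case_id, d_max_mm, length_mm, aspect_ratio, tawss, area_wss4,
area_wss1, osi_max, residence_time_s`; the trend table gives the Spearman
rank correlation between aspect ratio and mean TAWSS within each fixed-
`D_max` group and a strict-ordering flag. Runs are deterministic: the same
configuration and seed reproduce reports byte for byte.

## Known limitations

* WSS magnitudes inherit all Poiseuille assumptions; only orderings,
  fractions and bounded indices are acceptance-grade outputs.
* The coronary flow waveform never reverses in this topology, so OSI is 0
  for LPN-driven runs; OSI becomes informative only under prescribed
  oscillatory fixtures.
* One coronary branch; no autoregulation, exercise states, right heart or
  pulmonary circulation fidelity.
* The residence-time surrogate is a bulk turnover time, blind to intra-
  aneurysmal recirculation structure.
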