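---
title: "Methods: clearance-coupled nasal drug absorption in mucoclear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clearance-coupled nasal drug absorption in mucoclear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucoclear)
```

## The problem and the modelling idea

A metered nasal spray deposits drug-laden carrier droplets on the
mucus-coated nasal wall. Two clocks then race each other. The *diffusion
clock*: the dissolved drug solute must cross the mucin gel layer (about
10 µm thick) before the epithelium can take it up, and the crossing time
grows steeply with the solute's macromolecular radius because the mucin
fibre network obstructs large molecules. The *clearance clock*: the mucus
blanket is continuously propelled towards the nasopharynx at a few mm/min,
so a carrier only spends a limited time over any given region — and
whatever solute is still in the gel when the carrier reaches the
nasopharynx outlet is swallowed.

`mucoclear` couples these clocks on a deliberately reduced, fully
synthetic stage: a parametric unwrapped 2-D wall domain, a mass-balanced
reduced mucus flow, a generative deposition model and the analytical 1-D
diffusion–absorption solution. Everything a full CFD pipeline would
provide (patient geometry, airflow, impaction physics) is replaced by
calibrated surrogates, so every downstream number is reproducible on a
laptop and every mechanism is testable in isolation.

## Surface domain

The wall is a structured grid in an unwrapped plane: `x` runs anterior to
posterior, `y` across the unwrapped circumference. The two chambers are
independent strips (sealed along the shared mid-line) that merge into a
single nasopharynx strip ending at the outlet edge. Band layout per
chamber: an anterior vestibule band, a septum band along the mid-line, an
olfactory band along the outer edge ("ceiling") in the posterior half, and
main-passage cells elsewhere, with a small ostium patch marking where the
maxillary sinus drains into the main passage. The sinus interior is not
meshed — nothing deposits there and mucus only flows out of it — but its
configured area participates in the regional bookkeeping.

Because only areas (not shapes) of the regions are known, per-cell areas
are scaled per region so that the cell sums reproduce the configured
regional areas exactly; the plane is parametric, not isometric, exactly as
a real unwrapped surface is not. The default regional areas total
225.05 cm². Grid coordinates, however, control distances and therefore
transit times: the default plane is 85 mm long (13 mm vestibule band,
13 mm nasopharynx strip, 56 mm chamber width at 2 mm resolution). The
length is a free modelling parameter — only regional areas are prescribed —
and 85 mm was fixed once so that clearance times land in the physiological
tens-of-minutes range (see *Calibration*, below).

A dimensionless *metric width factor* multiplies face conductances in the
flow solve; it is 1 in the chambers and decays linearly to 0.4 across the
nasopharynx strip, emulating the rapidly shrinking circumference that
accelerates mucus towards the outlet.

## Mucus flow

At mucus speeds of mm/min the Reynolds number is of order 1e-4; inertia is
irrelevant and the thin-film flow driven by distributed sources is
curl-free to an excellent approximation. The module therefore solves a
metric-weighted potential problem with a 5-point finite-volume stencil:
`div(w grad phi) = -w s`, `phi = 0` on the outlet faces, zero normal flux
everywhere else, and `v = -grad phi`. The per-cell source density `s`
carries the mucus production: weight proportional to cell area on the
mucus-producing mucosa (main passage, septum, olfactory), plus a
concentrated share on the ostium patches standing in for the sinuses. The
literature gives no numeric value for the production rate, only its
calibration rule, so the source magnitude is a single scale factor fixed
by requiring an area-weighted mean speed of 6 mm/min over the main cavity
wall (vestibules and sinuses excluded). Without the swirl perturbation the
problem is linear and calibration is one rescale; with it, a bracketed
root search (tolerance 0.1%) is used. The discrete source/outlet flux
balance of the solved field is at solver precision (~1e-13 relative).

**Swirl perturbation.** A potential field cannot recirculate, but the real
flow does: mucus produced behind the vestibule boundary stirs the
vestibule's posterior margin, which is how vestibule-deposited drug
eventually escapes into the absorbing regions. The module superposes a
divergence-free stream-function eddy pair (one compact counter-rotating
eddy per chamber, radius 4 mm, peak speed 8 mm/min, centred on the
vestibule/main-passage boundary in the main-passage band). Constructing
the eddy velocities from corner stream-function differences keeps the
perturbation discretely divergence-free, so the mass balance is untouched.
The eddy's near tail reaches a few mm into the posterior vestibule:
deposits inside that reach are stirred across the boundary within minutes,
deposits beyond it essentially never leave — which is the behaviour the
absorption trade-off needs (below).

## Spray population and drag kinetics

Droplet mass follows the Rosin–Rammler law, retained mass fraction
`exp(-(d/78)^2.7)` truncated to 1–150 µm, discretised into 150 equal-width
bins with 200 streams per bin in the reference configuration; number
weights are mass over the per-droplet mass `rho pi d^3/6`, which puts the
number mode in the smallest bins while the mass mode sits near 70 µm. Each
stream carries `mass_fraction/streams` of a unit total spray mass; all
outputs are percentages (or use the dosage formula), so the normalisation
is immaterial.

Droplet flight in a carrier air flow follows the standard
discrete-phase-model equation `du/dt = f_D + f_G` with
`f_D = (18 mu / (rho_p d_p^2)) (C_D Re_p/24) (u_air - u)` and the
Morsi–Alexander piecewise drag coefficient (the empirical constants are
tabulated in the code; band-edge discontinuities are below 2.5%). Two
choices deserve a note:

* **Reynolds density.** Some formulations write the particle density
  into the particle Reynolds number; the standard DPM formulation uses the carrier
  gas density, and only the latter is consistent with Stokes-regime
  relaxation times of the form `tau_p = rho_p d_p^2/(18 mu)`. The default
  is gas density; `particle_reynolds(..., density = "particle")` restores
  the particle-density form for comparison.
* **Integrator.** A fixed-step classical RK4 with automatic
  relaxation-time-based substepping (`dt_sub <= tau_p/20`) replaces an
  adaptive embedded scheme. The fixed-step form makes the order of
  convergence directly observable (halving `dt` divides the
  closed-form-relaxation error by ≥ 16 in the tests) and trajectory
  accuracy, not scheme order, is what matters: the velocity relaxation in
  a uniform stream matches `u_air (1 - e^{-t/tau_p})` to better than 0.1%
  at `t = 3 tau_p`.

Full in-airway trajectories to deposition are *not* simulated — they would
require the airflow CFD that is outside this package's scope. The kinetics
operators exist so that the transport law itself is verifiable in
prescribed analytic flows.

## Synthetic deposition

Deposition is generative, not mechanistic. Each droplet stream draws a
position from a mixture of 2-D Gaussian hot-spots selected by its size
class (large > 60 µm, medium 20–60 µm, small < 20 µm), truncated to the
regions of the hot-spot's macro-bucket (vestibule; main cavity = main
passage + septum + olfactory; nasopharynx). The default anchors encode the
qualitative impaction pattern of a right-nostril spray: large droplets in
a band across the posterior vestibule, anterior septum and middle
turbinate tip; ~20 µm droplets in the anterior main passage; ~30 µm
droplets near the ostium; only fine droplets in the nasopharynx tail.
Bucket probabilities per size class are rescaled once at build time
(iterative proportional fitting over the population's class mass
fractions) so the expected regional mass split equals the configured
79.8 / 19.0 / 1.2% over vestibule / main cavity / nasopharynx. Every
stream deposits (100% deposition efficiency).

What the generator does *not* emulate: insertion-angle or flow-rate
sensitivity, inter-patient geometric variation, droplet evaporation or
bounce, and any causal link between nozzle parameters and the pattern.
Passing tests therefore demonstrate the correctness and calibration of the
clearance–absorption machinery on a representative pattern — not a
validated deposition prediction for any real administration.

## Clearance

Deposited carriers are passive surface tracers (at 6 mm/min, inertia and
resuspension are irrelevant). Positions advance by midpoint RK2 with
bilinear interpolation of the cell-centred velocities; steps longer than
one cell at the peak speed are automatically sub-divided (with a warning).
Region transitions are detected by cell lookup each step and the crossing
time is linearly interpolated from the crossed grid line, with half-open
intervals (the crossing instant belongs to the downstream region), so each
particle's `(region, t_in, t_out)` record tiles its history exactly. A
particle is removed when it crosses the posterior outlet edge; otherwise
its last interval closes at the horizon and it is flagged in-transit.

Two horizons are used: 30 min for trajectory/snapshot runs, and a 4 h cap
for absorption accounting (long enough that every carrier that will ever
clear has cleared; vestibule deposits outside the eddy's reach never do).

## Diffusion and absorption

The gel layer is 1-D: reflective at the air-facing top (`x = 0`),
absorbing at the bottom (`x = h_g`), the dose initially at the top. The
normalised concentration and the absorbed fraction are classical
separation-of-variables series; `absorption_fraction()` truncates the
alternating series by its remainder bound (tolerance 1e-12, term cap
10,000 with an error if the bound is unmet), returns exactly 0 at `t = 0`,
and clamps to [0, 1]. The profile's term cap uses a geometric tail bound.
The series is cross-checked in the test suite against an independent
explicit finite-difference solution (cell-centred, ghost-cell boundaries,
`lambda = 0.4`) to 1e-4, and `∫ c dx = 1 - A(t)` to 1e-6 by quadrature.

Diffusivities: Stokes–Einstein in water, reduced by the
Obstruction-Scaling factor `exp(-(pi/4)((r_s+r_f)/(r_g+r_f))^2)` with
mucin fibre radius 3.5 nm and mesh spacing 50 nm. The package defaults to body-temperature water constants
(T = 310.15 K, µ0 = 6.913e-4 Pa·s), which place the absorption of a 90 nm
solute at 97.9% by 500 s — within a percentage point of the 97% reference
timing this model family is benchmarked against — and both are
configuration values.

Bookkeeping per carrier: a single absorption clock runs from deposition
(diffusion does not pause while the carrier moves). Each passage interval
credits `alpha m [A(t_out) - A(t_in)]` to its region if the region
absorbs; increments accrued on the vestibule are *discarded* (lost), not
deferred — the only reading under which the fast-diffusion total equals
the non-vestibule deposited mass fraction, which it does in the default
scenario to well within 2 points. On clearance the remainder
`alpha m [1 - A(t_clear)]` is booked cleared-unabsorbed; at the horizon,
as in-mucus residual. The four buckets sum to `alpha m` identically
(enforced at 1e-10 relative). The dosage operator converts final absorbed
fractions to an absolute mass, `(4/3) pi c Σ A_i r_i^3`.

## Calibration of the default scenario — and what it produces

The free parameters (domain length, eddy geometry/amplitude, hot-spot
anchors, ostium source share 0.3) were fixed once against the qualitative
behaviour reported by full-geometry CFD clearance studies and then
frozen:

* clearance ordering and scales: nasopharynx deposits clear in well under
  a minute, septum in ~11 min, main passage in ~13 min (its anterior group
  detours towards the vestibule first), and the vestibule slowest by far,
  with a substantial never-cleared fraction;
* the deposition split and hot-spot pattern described above;
* the absorption-vs-radius trade-off: with the frozen defaults the total
  absorption curve is flat near 20% for small radii (the non-vestibule
  deposited mass), rises once vestibule escapees start outliving their
  vestibule residence, peaks *inside* the studied 1–110 nm range (22.8% at
  105 nm under the default seed), and falls again as clearance outruns
  diffusion for every carrier. The vestibule-origin contribution rises
  steeply beyond ~80 nm while the main-passage-origin contribution falls —
  the same mechanism balance reported by full-geometry CFD clearance
  studies, whose quantitative curves (e.g. a 23.9% peak at 95 nm) depend
  on patient geometry and solver fields and are not desk-reproducible.

The timing balance matters and is worth stating plainly: the interior
maximum exists because vestibule escape (minutes, for the sub-population
within the eddy's reach) is *faster* than bulk clearance (tens of
minutes), while most vestibule mass never escapes at all. Configurations
in which escape is slower than clearance but eventually complete push the
maximum beyond 110 nm.

## Problem sizes and numerical settings

Routine runs and the test suite release 40 streams per bin (6,000
streams); the reference configuration of 200 per bin (30,000 streams) is
the `spray_config()` default. At 6,000 streams the regional mass split
resolves to ~0.5 percentage points, well below every tolerance asserted.
Advection uses `dt = 3 s` over a 4 h horizon at 2 mm resolution; the
linear solve is a direct sparse factorisation (residual guard 1e-8);
series tolerance 1e-12; calibration tolerance 0.1%.

## Known limitations

* The reduced flow cannot reproduce geometry-specific recirculation;
  the eddy pair is a calibrated surrogate, and regional clearance *times*
  should be read as order-of-magnitude, not patient predictions.
* Deposition is a statistical emulation; nozzle-parameter studies are out
  of scope.
* The gel model ignores wall-normal convection, dissolution kinetics and
  periciliary transport (instantaneous uptake at the gel bottom), and
  treats the solute mass fraction alpha as constant.
* Plasma pharmacokinetics are not modelled; outputs stop at epithelial
  uptake.
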