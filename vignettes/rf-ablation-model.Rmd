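---
title: "Modelling bipolar RF renal-artery ablation with rfablate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bipolar RF renal-artery ablation with rfablate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rfablate)
```

## The physical problem

Renal denervation ablates the sympathetic nerves that run within a few
millimetres of the renal artery wall.  A bipolar radiofrequency catheter
drives a 500 kHz sinusoid between two small metal tube electrodes pressed
against the inner wall; conduction currents deposit Joule heat in the wall
and the surrounding connective tissue, and tissue that stays at or above
60 °C long enough is irreversibly damaged.  `rfablate` simulates this
process end to end for two scenarios:

* **artery** — two coaxial tube electrodes (0.61 mm OD, 3 mm long, 1.5 mm
  apart) inside a 4.1 mm lumen with a 0.5 mm wall, connective tissue
  around it, and blood flowing through the lumen;
* **phantom** — the same electrode pair resting on a slab of
  tissue-mimicking thermochromic gel on a bench, the configuration used to
  validate such models photographically.

## Model and numerical scheme

**Quasi-static electric solve.**  At 500 kHz in tissue, displacement
currents and dielectric loss are negligible, so each coupling step solves
the conduction problem `div(sigma grad V) = 0` on a uniform cell-centred
voxel grid with harmonic-mean face conductances.  The solve is performed
once per coupling step at the RMS differential voltage
(`v_rms = v_pp / (2*sqrt(2))`, 21.21 V for a 60 Vp-p drive), so the source
term `q = sigma |E_rms|^2` equals the cycle-averaged resistive dissipation
`(1/2) Re(J* . E)` and the reported power is exactly `V_RMS * I`.  The
electrode metal (10^9 S/m, nine orders above tissue) is treated as an
equipotential Dirichlet region — the positive terminal at `+v_rms/2`, the
negative at `-v_rms/2` — which avoids the conditioning blow-up of carrying
the contrast in the matrix.  In the artery scenario the outer boundary is
grounded (0 V); because the bipolar pair is a dipole whose far field decays
like `1/r^2`, the choice of grounded versus insulated far boundary changes
the terminal current by well under 1% at the default 14 mm transverse
half-extent (a boundary-doubling check is part of the test suite's
refinement evidence).  The bench phantom has no return path, so its
boundary is insulated.  The linear system is solved by Jacobi-preconditioned
conjugate gradients (relative tolerance 1e-8, deterministic, warm-started
from the previous potential during coupling).

**Electrode windows and the embedded-boundary contact.**  Each electrode is
insulation-coated except for an exposed window (2.5 mm axial × 1 mm
circumferential arc; the printed "1 mm × 2.5 mm" is realised this way
because the axial dimension cannot exceed the 3 mm electrode).  The tube
touches the wall (or the gel surface) *tangentially*, so the constriction
resistance at the contact is controlled by sub-voxel geometry.  A naive
staircase voxelisation makes the computed terminal current non-monotone in
the grid spacing; `rfablate` therefore uses a first-order embedded-boundary
treatment: every grid face between an electrode cell and a conducting cell
whose midpoint falls inside a window carries conductance
`sigma_tissue * h^2 / d`, where `d` is the distance from the tissue cell
centre to the analytic tube surface, clamped to `[h/4, h]`.  Faces outside
the windows carry no current (the coating); heat still conducts through
them.  With this treatment the terminal current at the reference 0.25 mm
spacing sits within a few percent of the 0.5, 0.4, 0.3 and 0.15 mm values
(residual staircase scatter of order 10% remains at isolated spacings,
against the 2-to-3-fold swings of the naive voxelisation).

**Materials.**  The property table (shipped as
`inst/extdata/materials_500khz.tsv`, user-overridable) stores the 500 kHz
constants for blood, artery wall, connective tissue, the Pebax-class
insulation and PtIr electrodes.  Tissue conductivity follows the linear law
`sigma(T) = sigma0 * (1 + k1 * dT)` with `k1 = 2.05 %/°C` for artery wall,
connective tissue and the gel, and `dT = clamp(T, 30, 80) − 37 °C`: the
law was measured between 30 and 80 °C, so it is clamped (not extrapolated)
outside that range, which also prevents runaway conductivity above 80 °C.
The reference temperature is taken as body temperature (37 °C), matching
the thermal boundary and initial conditions.  Relative permittivity is
stored but unused by the solver (resistive loss only).  The gel mimics
connective tissue electrically; thermally it uses water-like constants
(density 1030 kg/m³, heat capacity 4186 J/(kg °C), conductivity
0.6 W/(m °C)) appropriate for a high-water-content polyacrylamide gel.

**Bioheat transient.**  The Pennes equation
`rho Cp dT/dt = div(k grad T) + q + rho_b Cp_b omega_b (T_b − T)` is
advanced by an explicit finite-volume step with harmonic-mean face
conductivities; cells whose local diffusion number exceeds the explicit
limit *because of their material* (the metal shell, thermal diffusivity
~30× tissue) are advanced point-implicitly, which is unconditionally
bounded and keeps the global step at the tissue limit.  The default step is
half the tissue stability bound.  The metabolic source is zero and the
default perfusion rate is zero — no value is tabulated for periarterial
connective tissue — but the Pennes sink is implemented and exposed
(`perfusion_params`) so its effect can be quantified.  Boundaries are held
at the initial temperature (37 °C in the artery, bench temperature 22 °C
for the phantom); the gel-air surface is adiabatic.

**Lumen blood.**  Three treatments are provided because the flow handling
of such studies is rarely fully specified: `static` (conduction only),
`clamped` (blood held at 37 °C — the infinite-convection limit) and
`advective` (the default for the headline scenario): implicit first-order
upwind plug flow at 0.7 m/s along the artery axis, inflow at 37 °C on the
upstream face, zero-gradient outflow, flowing from the negative toward the
positive electrode.  The implicit sweep is unconditionally stable, so the
60 s run does not need the ~0.4 ms CFL step that explicit advection at
0.7 m/s on a 0.25 mm grid would require; the price is strong numerical
diffusion *within the lumen*, acceptable because the physically relevant
quantities — bulk blood temperature and the downstream wall plume — are
dominated by the near-wall energy balance, not by the lumen profile.

**Electro-thermal coupling.**  Tissue conductivity rises ~2%/°C, so the
potential must be re-solved as the field heats.  A full re-solve (with the
previous potential as the CG starting point) is triggered when any voxel
has drifted more than 1 °C since the last solve or after 1 s of simulated
time, whichever comes first, with a floor of 0.25 s between drift-triggered
solves: the first seconds of the transient otherwise trigger a re-solve on
every thermal step for no measurable change in the outcome (halving both
cadence parameters changes the final peak temperature by well under 1%,
which is part of the test suite).

**Damage model.**  A tissue voxel is ablated when its *cumulative* time at
or above the damage temperature (60 °C) reaches the damage time (1 s), or
immediately if it ever reaches the necrosis temperature (100 °C); the
enthalpy change is zero, so no latent-heat term enters the bioheat solve.
Cumulative rather than contiguous dwell matches threshold-transformation
damage models; for monotone heating the two coincide.  The instant-kill
role of the necrosis temperature is a documented switch
(`necrosis_instant_kill`), since threshold models vary on this point.  The
ablation zone of a bipolar pair consists of up to two elongated lobes, one
per electrode; `zone_extents` reports the bounding box of the union of the
two largest face-connected components (ties broken by smallest voxel
index), so the long box dimension runs along the electrode pair, and the
zone volume counts every ablated voxel.

## Scenario geometry choices

The computational domain is a uniform voxel grid with the artery axis along
x and cell centres at `(i − (n+1)/2) h` (exactly mirror-symmetric in
floating point, which the symmetry tests exploit).  The unbounded surround
is truncated at the grid extents (12 mm axial, 14 mm transverse by
default) with grounded, body-temperature Dirichlet conditions; the
`padding_radius` field of `artery_geometry` documents the intended
truncation and is validated, while the realised padding is set by the
configured grid extents.  Both electrode windows face the same wall
(configurable), the window pressed flush against it; the electrode interior
is insulator (the carrier tube), and a metal shell thinner than a voxel is
voxelised as a one-voxel ring around the true mid-surface so coarse grids
keep a connected, correctly placed shell (the shell *volume* test runs at
0.05 mm where the 0.1 mm wall is resolved).  In the phantom scenario the
pair rests on the gel surface with the windows facing down; there is no
blood and no artery wall, and the saline film that a bench experiment
spreads around the electrodes is *not* modelled — see Limitations.

## Phantom imaging

`render_synthetic_tcp` emulates a top-view photograph of an ablated
thermochromic gel at a configurable pixel scale (86 px/mm by default):
pink background, magenta-family ablated region, seeded Gaussian channel
noise.  `hsb_threshold` reproduces hue/saturation/brightness thresholding
on the 0-255 scale (hue ≤ 217, saturation ≥ 121, brightness ≥ 68 by
default, all six band edges configurable, "no dark background" making the
brightness bound a minimum), and `measure_ablated_region` converts the
passing-pixel count and the largest component's bounding box to mm² and
mm.  The synthetic colours were chosen once so the default thresholds
separate the classes with ≥ 14 hue-byte margin, far above the default
noise (sd 4); a round-trip test (render → threshold → measure) recovers
known areas within 5% across seeds.  What these tests show is that the
*quantification chain* is correct; they say nothing about camera,
illumination or the gradual colour transition of real gel, which are out
of scope.

## Reproducing the headline numbers, and what to expect

`scripts/acceptance.R` re-runs the two reference scenarios (0.25 mm
voxels; the artery run takes a few minutes on one CPU) and writes the
ablation-box dimensions, lumen and plume temperatures, and the phantom
power comparison as JSON.  Two caveats, established quantitatively while
building the package and worth stating plainly:

* **Terminal current.**  With the printed electrode geometry and material
  constants, the computed bipolar resistance at 37 °C is ~600 Ω (the
  solver reproduces slab and concentric-cylinder closed forms to < 1%, and
  independent spreading-resistance estimates for ~2.5 mm² contacts in
  0.3-0.75 S/m media give the same order).  Published figures of
  ~110-120 mA at 21.2 V RMS imply ~190 Ω, which no variant we tested —
  fully bare electrodes, grounded or insulated far boundary, all tissue at
  the 80 °C conductivity clamp — comes close to.  The package reports what
  its inputs imply; the power-level discrepancy propagates to any quantity
  that depends on the absolute heating rate.
* **Resolution.**  Reference runs use 0.25 mm voxels, chosen with a
  refinement study (terminal current within 8% across a 0.5-to-0.25 mm
  halving; temperature convergence tested by step- and cadence-halving) to
  keep the full 60 s coupled run at desk scale on one CPU.

## Limitations

* Rigid, straight artery; no wall contact mechanics, no catheter basket.
* Plug-flow advection with strong numerical diffusion inside the lumen; no
  Navier-Stokes hemodynamics or pulsatility.
* Temperature-threshold damage only — no Arrhenius kinetics; no
  vaporisation or charring (runs abort above 150 °C as outside validity).
* The phantom scenario omits the saline film around the electrodes and
  uses the connective-tissue conductivity for the gel as printed; both
  choices lower the simulated bench current relative to reported bench
  measurements.
* Material properties are single-frequency (500 kHz) constants.

## A minimal session

```{r example}
library(rfablate)

cfg <- read_scenario_config(bundled_config("artery_coarse"))
res <- run_scenario(cfg)
print(res$report)          # ablation box, volume, peak power
head(res$log)              # per-solve current / power / peak temperature

r <- res$result
lumen_bulk_temperature(r)  # bulk blood temperature, C
downstream_wall_peak(r)    # warmed wall plume downstream, C

# phantom round trip: simulate, photograph, quantify
php <- run_scenario(read_scenario_config(bundled_config("phantom_coarse")))
top <- mask_top_view(php$result$report$mask)
img <- render_synthetic_tcp(top, spacing_mm = 0.4, scale = 86,
                            noise_sd = 4, seed = 1)
measure_ablated_region(hsb_threshold(img), img$scale)
```
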