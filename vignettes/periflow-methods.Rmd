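---
title: "Modelling blood and fibrinogen recruitment around textured implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blood and fibrinogen recruitment around textured implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a screw-shaped implant is placed in bone, the narrow gap between the
implant surface and the bone wall fills with blood within seconds. How much
blood — and how much of the proteins dissolved in it, such as fibrinogen —
reaches the immediate implant interface, and how fast that fluid keeps
moving there, shapes the earliest stages of osseointegration: slow,
concentrated flow near the surface lets proteins and cells settle and
adhere. `periflow` implements a desk-scale computational model of this
filling transient for three implant surface topographies:

* **amorphous** — a smooth surface with no texture;
* **nano** — trabeculae-like nodular protrusions (300 nm high, 300 nm wide);
* **hybrid** — cactus-like meso-scale spikes (40 um high, 50 um wide)
  carved by crisscrossing grooves, overlaid with the same nano nodules.

The quantities of interest are zone-resolved: an **interface zone** (fluid
within 100 um of the implant surface), a **thread zone** (the bays of the
screw threads), and the remaining **outer** fluid. For each zone the model
reports the liquid (plasma) fraction over time, the infiltrated fibrinogen
quantity, and the liquid-weighted mean velocity decomposed into a vertical
(upbound, toward the outlet) and a horizontal (inbound, toward the implant)
component.

## Geometry

The domain is a 2D planar cross-section through the implant axis — the
published visualizations of this class of model are cross-sectional, and a
2D half-domain (symmetry axis through the implant centre) keeps the model
runnable on a laptop. The implant profile is a core rectangle with
triangular thread ridges (default: 3 threads, depth 0.35 mm, pitch 1.2 mm —
typical commercial dental implant proportions; the thread form is
configurable). The crest-to-bone gap is 0.3 mm. Blood enters at the implant
apex and through a segment of the bone side-wall, and exits upward through
the top outlet. The geometry is rasterized onto a uniform structured grid;
`assign_zones()` labels every fluid cell with exactly one zone, and the
thread envelope is anchored at the first ridge tip so each thread
contributes exactly one disjoint pocket.

Surface roughness is characterized by the standard areal parameters:
`Sa` (mean absolute deviation from the mean plane), `Sz` (largest peak
height plus largest pit depth), and `Sdr` (the extra surface area
contributed by the texture, from triangulated facets). `Sdr` is reported
both as a dimensionless fraction and as a percentage, since usage in the
field mixes the two conventions.

## Flow and transport model

Filling is simulated as transient incompressible two-phase flow: blood
plasma (liquid) displacing the initial void (gas), captured with a
volume-of-fluid (VOF) liquid fraction on a staggered MAC grid. One time
step performs

1. conservative VOF advection of the liquid fraction with a compressive
   interface-sharpening flux, bounded by a Zalesak-type FCT limiter;
2. fibrinogen transport: the species load `c * alpha` rides the same
   (limited) face fluxes with upwind concentration, plus explicit
   diffusion `div(D alpha grad c)` — the protein is confined to its
   liquid carrier by construction;
3. a variable-density, variable-viscosity momentum update with
   continuum-surface-force (CSF) surface tension, wall contact angles,
   and the texture drag/imbibition layer described below;
4. a pressure projection to a discretely divergence-free velocity field,
   solved by conjugate gradients preconditioned with a geometric multigrid
   V-cycle (red-black Gauss-Seidel smoothing, coefficient-averaged coarse
   operators on the masked grid hierarchy).

The time step is the minimum of the advective CFL bound, the capillary
bound `sqrt(rho_mean h^3 / (2 pi sigma))`, and the explicit viscous and
diffusive limits.

### Wetting and the unresolved texture scales

The nano nodules (300 nm) can never be meshed at domain scale, and the
meso spikes (50 um) are below the default grid spacing as well. Unresolved
scales act through three sub-grid models:

* **Effective wetting (Wenzel).** The equilibrium contact angle on a rough
  surface satisfies `cos(theta_eff) = r cos(theta_base)` with the
  roughness area ratio `r = prod(1 + Sdr_scale)` over the unresolved
  scales (Wenzel ratios of superposed textures multiply). With the default
  intrinsic angle of 70 degrees this gives roughly 47 degrees for the nano
  surface and complete wetting for the hybrid surface.
* **Darcy drag layer.** Folded meso spikes form a porous layer one spike
  height (40 um) thick along the implant surface, with Kozeny-Carman
  permeability at grain size = spike width and porosity 0.5. The layer
  exerts an implicitly integrated Darcy sink on the momentum equation —
  this is what slows and retains near-surface flow on the hybrid surface.
* **Imbibition.** The same layer wicks liquid in: inside layer cells the
  resolved interface curvature is replaced by the sub-grid pore curvature
  `-2 cos(theta_eff) / r_pore` with `r_pore = spike_width / 4`, so the CSF
  term becomes a capillary suction that draws the liquid front into the
  texture. Without this term a drag layer alone would slow the filling of
  the very zone the texture is supposed to recruit into.

The contact angle at resolved walls is imposed by re-orienting the
interface normal in wall-adjacent interface cells
(`n = cos(theta) n_wall + sin(theta) t`), which makes menisci climb or
depress walls correctly; the capillary-channel benchmark checks the
resulting meniscus suction against `2 sigma cos(theta) / W` in a slot.

### Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| liquid density / viscosity | 1025 / 1.4e-3 | kg/m3, Pa s | blood plasma |
| gas density / viscosity | 1.2 / 1.8e-5 | kg/m3, Pa s | air |
| surface tension | 0.058 | N/m | plasma-air |
| intrinsic contact angle | 70 | degrees | moderately wetting implant ceramic |
| fibrinogen diffusivity | 2e-11 | m2/s | literature scale for a 340 kDa protein |
| implant length x diameter | 11 x 4 | mm | standard dental implant |
| implant-bone gap | 0.3 | mm | modelled gap |
| interface thickness | 100 | um | one third of the gap; >= 3 cells at default grids |
| spike height / width | 40 / 50 | um | meso texture |
| nodule height / width | 300 / 300 | nm | nano texture |
| end time | 3 | s | fill transient studied |

All are configurable through `run_config()` / YAML.

## The scaled comparison experiment

The three-topography comparison runs on a scaled implant domain
(`mini_implant`): a 3.6 mm x 2.4 mm implant with the same three threads
(pitch 0.9 mm, depth 0.35 mm), the same 0.3 mm gap, interface band and
texture parameters, on a 30 um grid — about 3800 fluid cells, which keeps
a full 3 s transient to a few minutes on one CPU. Three further choices
define this experiment:

* **Scaled capillarity.** The filling regime is capillary-dominated: what
  matters is that capillary pressure greatly exceeds viscous and dynamic
  pressures, and how wetting differs between topographies — not the
  absolute surface tension. The experiment therefore runs at
  `sigma = 3 mN/m` (capillary pressure is then still two orders of
  magnitude above the viscous pressure drop) with the gas viscosity
  reduced in step, which relaxes the capillary time-step bound by a factor
  of about four. Contact angles, the Wenzel contrast and the drag layer
  are unaffected by this scaling. The closed-form benchmarks keep the
  physical surface tension.
* **Inlet speed.** The inlet magnitude is not a printed quantity; it is
  calibrated once against the qualitative fill sequence — thread bays
  still void at 1 s, substantially (but not completely) filled by 3 s, so
  that topography differences are still visible at the end of the
  transient. The scaled domain uses 0.35 mm/s at both inlets: thread bays are still void at 1 s and roughly three-quarters filled at 3 s, so the cross-topography differences the model is built to compare are still visible at the end of the transient.
* **Projection tolerance.** The scaled experiment uses a relative
  projection tolerance of 1e-5 (the package default is 1e-8); the
  resulting per-step divergence defect contributes far less than the 1%
  mass-balance budget, and the solver records the worst relative residual
  so the tests can assert it.

## Validation benchmarks

Every stage is testable without external data via `make_case()`:

* `poiseuille` — body-force-driven channel flow against the parabolic
  profile (L2 error about 0.1% at 32 cells, second-order convergence);
* `static_droplet` — 2D Young-Laplace pressure jump (`sigma / R`);
* `gaussian_diffusion` — the radial second moment of a diffusing release
  grows at exactly `4 D t` for the 5-point discretization;
* `capillary_channel` — slot meniscus suction `2 sigma cos(theta) / W`;
* `mini_implant` — the scaled filling run, with the global liquid
  mass-balance defect as its error metric.

What these benchmarks (and the passing test suite) show is that the
discrete operators are consistent and conservative and that wetting,
capillarity and transport behave quantitatively on problems with known
answers. What they cannot show is fidelity to real peri-implant
haemodynamics: the model is 2D, Newtonian, isothermal, ignores coagulation
and adsorption, represents both texture scales through sub-grid closures,
and its inlet conditions are idealized. Cross-topography comparisons
should therefore be read as directional (orderings and fold changes), not
as absolute predictions.

## Numerical choices and degenerate inputs

* VOF bounds are enforced by the FCT limiter; residual round-off is
  clamped to [0, 1] and the clamped volume is accumulated in the run
  diagnostics (it stays at round-off level).
* Species concentration obeys a discrete maximum principle up to the same
  clamping; clamp totals are likewise recorded.
* Cells whose zone holds no liquid report `NA` (undefined) mean vectors
  rather than zero.
* Zone means are liquid-weighted by default (`weighted = FALSE` gives
  unweighted means); reported `speed` is the magnitude of the mean vector,
  with the mean of per-cell speeds kept as a secondary column.
* The pressure system fixes its level through the outlet Dirichlet
  condition; geometries must expose at least one outlet face.
* A geometry error is raised for threads that do not fit the shank,
  serrated boundaries that self-intersect, grids that resolve the gap
  with fewer than 8 cells, and interface bands at least as wide as the
  gap.
* Determinism: runs are bit-identical for identical configurations; the
  only random element in the package is the optional seeded nano-nodule
  amplitude jitter (off by default).

## Known limitations

* The helical 3D thread is reduced to ring-like ridges in the cut plane;
  azimuthal transport is absent.
* The compressive VOF scheme keeps interfaces 2-3 cells wide; films
  thinner than the grid cannot be represented outside the sub-grid layer
  model.
* Spurious capillary currents of the CSF formulation are mitigated by
  normal smoothing but not eliminated; speed metrics use the magnitude of
  the zone-mean vector partly because spurious components largely cancel
  in the mean.
* The qualitative Table-style labels use fixed fold-ratio thresholds
  (1.5 and 1.15) that are package conventions, configurable in
  `compare_topographies()`.
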