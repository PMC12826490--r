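---
title: "Modeling EGFR signaling on the growing egg chamber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling EGFR signaling on the growing egg chamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`grksim` simulates the secretion, transport and receptor-mediated readout of
the Gurken (GRK) ligand in the perivitelline space of the *Drosophila* egg
chamber between stages S7 and S10A (model time 3–19.5 h), together with EGFR
trafficking, dpERK production and the Sprouty/Kekkon-1 negative feedback in
the follicle-cell layer. This vignette is the package's account of the model:
its assumptions, the parameters and why their defaults are what they are, the
numerical scheme, and what the package can and cannot tell you.

## The physical picture and its assumptions

The perivitelline space (PVS) is the thin fluid gap between the oocyte and
the follicle cells. Its thickness (H = 0.5 µm) is negligible against the
chamber dimensions (tens to hundreds of µm), so ligand transport is modeled
as diffusion on a curved two-dimensional surface: a prolate spheroid with
semi-axes `L_AP(t)` (half the egg-chamber length, along z) and `L_DV(t)`
(half its width, along x and y). The six measured stages pin the axes at
t = 3, 7.5, 10.5, 13.5, 16.5 and 19.5 h; between stages every dimension is
interpolated piecewise-linearly (the minimal assumption for six time points).

Three kinematic fields ride on this geometry:

* **Growth.** A point keeps its angular coordinates `(eta, theta)` while the
  semi-axes change (the coordinate-preserving growth map). The corresponding
  velocity `v = (b'/b x, b'/b y, a'/a z)` is the simplest map consistent with
  outward, surface-normal-dominated growth; the material growth field of the
  real epithelium is not known at this resolution.
* **Nucleus / source movement.** The oocyte nucleus sits at the posterior
  pole (`eta = 0`) until late S8 (10.5 h), travels along the dorsal meridian
  (`theta = 0`) and anchors at the dorsal-anterior boundary of the oocyte by
  early S9 (13.5 h), afterwards tracking that boundary as the oocyte grows.
  The anchoring time follows the mechanistic-perturbation convention that
  freezing the nucleus at 10.5 h leaves it posterior: the nucleus must
  therefore still be at the pole at 10.5 h, and anchored one stage later. The
  exact path between these times is not published; we use a linear ramp of
  the polar angle.
* **Follicle-cell shift.** The columnar follicle-cell domain is the posterior
  cap of axial extent `L_FC(t)`. Its anterior edge, expressed as a polar
  angle, detaches from the anterior pole at 10.5 h and sweeps posterior. The
  shift velocity `w` is meridional (toward the posterior), zero at the
  posterior pole, linear in meridian arc-length up to the edge and constant
  beyond it, scaled so the edge tracks `L_FC(t)` exactly. This pole-fixed
  linear profile is the minimal smooth kinematics consistent with the
  measured domain extents. Because the edge angle behaves like a square root
  right after detachment, its rate is evaluated with a backward-looking
  difference; a centered one would smear the detachment backward in time.

All follicle-cell species are restricted to the columnar-cell cap (the
stretched cells over the nurse cells are treated as receptor-free): receptor
production is masked to the cap and concentrations outside it are zeroed each
step. When the shift is disabled (`fc_shift = FALSE`) the cells keep covering
the whole chamber, so the mask is the full surface. The ligand lives on the
whole surface in both cases.

## Reaction network

Seven species per surface point: ligand `L`, free receptor `R`, surface
complex `C`, internalized complex `Ci`, signal `S` (dpERK), and the
inhibitors `STY` and `KEK1`. Binding (`k_on/H`), unbinding (`k_off`),
internalization (`k_ec`), recycling (`alpha_rec k_rec`) and degradation
(`alpha_deg k_deg`) of internalized complexes, ligand-independent receptor
turnover (`k_er`, production `Q_r`), signal production from internalized
complexes (`k_s`) and decay (`k_d`). KEK1 inhibits receptor engagement and
STY inhibits downstream signal production:

`k_on_eff = k_on / (1 + gamma_KEK1 KEK1 / K)`,
`k_s_eff  = k_s  / (1 + gamma_STY  STY  / K')`.

The receptor equation treats binding as a receptor *loss* term, which is the
mass-consistent reading of the network (a receptor engaged by ligand is no
longer free); `receptor_binding_sign = +1` reproduces the literal
opposite-sign variant for comparison. Argos is not expressed in this stage
window and is not modeled.

## Parameters

Defaults ship in `inst/extdata/kinetic_params.yaml`; every value is
config-overridable. Point values inside published ranges:

* `D = 360 µm²/hr`. The literature range spans four orders of magnitude
  (36–360,000). The default must satisfy the explicit-Euler diffusion
  stability bound at the package's mesh resolutions: the number of diffusion
  sub-steps per run grows linearly with `D`, and values near the top of the
  range would need ~10⁷ sub-steps for one run at `n = 32` — far beyond the
  intended problem sizes. 360 µm²/hr gives a diffusion length of ~77 µm over
  the simulated window, enough to spread ligand over the signaling domain
  while keeping full runs at minutes on one core. See *Limitations* for what
  this regime choice implies.
* `k_on = 6e22 mol⁻¹ µm³ hr⁻¹` (range bottom). The binding rate sets the
  stiffest local reaction rate (`k_on R0 / H ≈ 80 hr⁻¹` at the default);
  larger values shrink the reaction-accuracy time step proportionally without
  changing the saturated-uptake behavior that actually governs the pattern.
* `k_er = 0.6 hr⁻¹`, forced by consistency of the resting receptor density:
  `Q_r / k_er = 6.67e-22 ≈ R0`.
* `alpha_rec = 0.7`, `alpha_deg = 0.3` (sum 1; the validator warns when the
  configured fractions do not balance).
* Inhibitor kinetics `k_STY = k_KEK1 = 1 hr⁻¹`, `k_dSTY = k_dKEK1 = 2.3 hr⁻¹`
  (matching the network's other degradation rates; the inhibitor equations'
  rate constants are not published).
* Feedback normalizations `K`, `K'`. These unpublished constants set the
  inhibitor concentration at which feedback becomes order-one. We use
  `K = (k_prod/k_deg) * S_ref` with `S_ref` the *self-consistent* signal
  scale under feedback: the receptor pipeline saturates internalized
  complexes at `Ci_cap = Q_r / (alpha_deg k_deg)`, the feedback-free signal
  would be `(k_s/k_d) Ci_cap`, and the calibrated STY strength suppresses it
  by `1 + gamma_STY_ref` (with `gamma_STY_ref = 5e4`, the calibrated value).
  Anchoring `K` to the realized signal scale makes `gamma_STY = 500x10²` and
  `gamma_KEK1 = 10x10²` act as order-one dimensionless sensitivities. The
  naive alternative (`S_ref` from `Ci ~ R0` without feedback) puts realized
  inhibitor levels five orders of magnitude below `K`: the feedback never
  engages, receptors saturate everywhere ligand reaches, and the signal field
  is spatially flat — a qualitatively wrong regime.
* Source shape ratios (dorsal length, posterior width, anterior width of the
  T-shaped secretion footprint, each relative to the oocyte's corresponding
  extent) default to 0.5 at every stage. These are placeholders for
  unpublished stage-resolved measurements and should be overridden for
  production use (`source_ratios_csv` in the config). The width ratios are
  interpreted as fractions of the transverse arc (`|theta| <= ratio * pi/2`);
  the meridional thickness of the T's transverse bar is not published and
  defaults to 10% of the oocyte's curved length (`bar_thickness`).
* Secretion scaling: total flux `Q(t) = V0 * A_oocyte(t)`, distributed
  uniformly (top-hat) over the support — so `V0` is the per-area flux when
  the support covers the oocyte, matching its published units, and total
  secretion is proportional to the oocyte surface. Before the first measured
  oocyte stage the oocyte cap is back-extrapolated linearly and floored at
  5 µm of axial extent.

## Mesh and discrete operators

Prolate spheroidal coordinates are degenerate at the poles, so the surface is
meshed with cubed-spheroid coordinates: regular grids on the faces of the
inscribed cube (half-side `L_AP/sqrt(3)`), projected radially onto the sphere
of radius `L_AP`, then onto the spheroid orthogonally to the z-axis. The
problem is mirror-symmetric in the dorsal-ventral (xz) plane, so only the
half `y >= 0` is represented: 8 logically square `n x n` zones (two pole
half-faces, six quarter side faces), *cell-centered* so no cell sits on a
zone edge — `8 n²` cells, each exactly on the spheroid.

Cross-zone coupling uses two precomputed structures, both built on the
reference sphere and therefore reused unchanged as the spheroid grows:

* ghost cells, one ring per zone, whose positions extend the zone's own chart
  smoothly across the edge and whose values are interpolated from the
  neighbouring chart by 4x4 Lagrange stencils (fourth-order; clamped one-sided
  at cube corners, mirrored through y = 0 at the symmetry plane, where the
  reflection also supplies the Neumann closure);
* face pairings: the cube-edge partitions of adjacent zones coincide exactly,
  so every interface face is shared one-to-one and is given a single flux
  value (the average of the two one-sided diffusive estimates, or the upwind
  flux using the paired interior cells). Symmetry-plane faces carry no flux.

Both operators are flux-form finite volume with the analytic metric of the
composed projection map (first fundamental form assembled from precomputed
chart combinations, so a growth update costs a handful of vectorized
operations). Consequences verified by the test suite: constants map to zero;
mass is conserved to rounding under diffusion, transport and growth;
spherical-harmonic eigenvalues converge at second order; a harmonic decays at
the analytic heat rate within 2% at `n = 32`. The maximum-norm error is
first-order in the eight cube-corner cells (the usual cubed-sphere corner
behavior); eigenvalues and integral norms converge at order ~2.

The flux loops run in compiled code (`src/kernels.cpp`); everything else is
vectorized R.

## Time integration

Operator splitting with forward Euler, four sub-steps per macro step:

1. **Diffusion** of the ligand only, sub-cycled: the sub-step obeys
   `dt <= safety * 1.15 / (D * lambda)` where `lambda` is the Gershgorin
   row-sum scale of the discrete operator (its spectral radius is ≤ ~1.7x
   that scale on these meshes), additionally capped by the classical
   `0.9 h_min² / (4D)` bound.
2. **Growth**: fields are carried to the new spheroid index-wise and
   multiplied by the area-element ratio (old/new). This is the discrete
   conservative realization of the growth transport term under the
   coordinate-preserving map — mass is conserved exactly. Geometry updates
   are quantized (relative axis change of 5e-4, with an exact sync at every
   snapshot time) so metric terms are not rebuilt every step.
3. **Follicle-cell shift** of all species except the ligand, by conservative
   upwind transport of the analytic `w` evaluated at face midpoints. Upwind
   was chosen for positivity and robustness; its numerical diffusion
   (~`|w| h / 2`, a few µm²/hr) is small against `D`. Applications are
   batched over a few macro steps under a CFL bound of 0.3.
4. **Reactions and source**: forward Euler on the local network plus the
   secretion flux added to the ligand.

The macro step adapts to the currently realized rates: the binding rate is
evaluated with the KEK1-suppressed effective `k_on` pointwise, and
`dt = 0.35 / lambda_max` (stability needs only `dt < 2 / lambda_max`). Any
negative concentrations produced by the explicit update are floored at zero
and counted (`clip_count` in the diagnostics); clipped amounts are a
negligible fraction of the species masses at the default resolutions.

Internally the solver works with concentrations in units of `R0` (state
variables of order one) while keeping micrometers and hours;
`nondimensionalize()` / `redimensionalize()` expose the full exact rescaling
(concentration, length and time scales) with a round-trip guarantee, and the
stability bound is invariant under it. Snapshots are reported in mol/µm².

Degenerate inputs are handled explicitly: an empty source support on a coarse
mesh deposits the flux into the cell nearest the nucleus; a nucleus at the
pole degenerates the T to a polar cap; zero-rate parameter sets fall back to
a receptor-scale feedback normalization; `grk_multiplier = 0` switches the
source off entirely.

## Quantification

* AP profiles: 100 points evenly spaced in arc-length along the dorsal
  midline, from the anterior edge of the columnar cells to the posterior
  pole (the full chamber while the cells are cuboidal).
* DV profiles: 50 points along the transverse ring just posterior of the
  nucleus (5% of the oocyte arc behind it), restricted to the central 30% of
  the ring circumference — the outer portions of experimental DV profiles are
  dominated by edge autofluorescence and are not modeled.
* Elongation: arc-length of the full dorsal meridian circle (dorsal and
  ventral sides) where normalized dpERK exceeds a threshold, with linear
  interpolation at the crossings; 0.6 is the conventional threshold. The
  normalization reference is explicit: the run's own maximum for wild type,
  the wild-type maximum at the same stage for perturbations. (The 50%-of-max
  and 0.6 conventions coincide only approximately; both are exposed, the
  presets use 0.6.)
* Model–data error: L1 relative error, `∫|sim − ref| / ∫ref` by trapezoid
  sums on the simulated profile's fractional positions.
* `normalize_to_reference()` scales all simulated profiles by the single
  factor that matches the wild-type AP stage-10A curve to the reference at
  20% of its length.

`calibrate_gammas()` reruns the model over a grid of inhibitor strengths and
three ligand dosages (0.5x, 1x, 2x) and minimizes the summed L1 error;
`depletion_scan()` does the same over sty/EGFR depletion fractions
(25/50/75%). Both accept external reference curves or synthetic ones.

## The synthetic reference generator

`synth_reference_curves()` stands in for experimental immunostaining
intensity profiles: it runs the model at a chosen ground truth, extracts the
AP/DV profiles and adds seeded Gaussian noise proportional to each curve's
maximum. It emulates the *layout* and sampling of averaged intensity data and
curve-level measurement noise. It does not emulate systematic features of
real immunostainings — border-cell signal at the dorsal anterior, edge
autofluorescence, fixation losses of unbound ligand, batch variation between
dissections, or model misspecification. Recovery of self-generated truth
(exact at zero noise; the exact grid point in ≥ 90% of replicates at 5%
noise) therefore demonstrates that the calibration machinery is correct and
reasonably noise-robust, not that the model is identifiable from real data.

## Problem sizes

The package defaults to `n = 32` cells per zone edge (8192 cells) for
headline runs, with `n = 16` for calibration sweeps and grid studies and a
refinement check at `n = 48` available through `cubed_spheroid()`. A full
wild-type run at `n = 32` takes on the order of two minutes on one core;
`n = 16` about 25 seconds. These sizes keep the full acceptance workflow —
three mechanistic runs plus a calibration/depletion recovery study — at
around a quarter of an hour.

## Known limitations

* **Kinetic regime.** With the runtime-constrained default `D = 360 µm²/hr`,
  ligand does not equilibrate across the chamber within a stage: the local
  dpERK level tracks the local (per-area) secretion flux, which is roughly
  stage-constant, rather than the total secretion. Published behavior in
  which the overall *level* of signal responds to total secretion — notably
  the growth-stop experiment, where a frozen small oocyte secretes much less
  in total and dpERK drops with a much shorter extent — belongs to the
  well-mixed regime, `D` near the top of the literature range, whose explicit
  stability bound is out of reach at these resolutions (~10⁷ sub-steps per
  run). With the package defaults the growth-stop run reproduces the reduced
  maximum but not the strong reduction in absolute elongation, and the
  wild-type elongation at stage 10A comes out shorter than the published
  value. Users with patience (or a coarse mesh) can rerun with a larger `D`
  in the configuration; nothing else changes.
* First-order splitting and upwind transport: sub-step ordering error is
  O(dt), and the shift transport smears sharp fronts by design.
* The mirror symmetry restriction (half surface) is exact for this model —
  source, kinematics and initial data are all symmetric in the dorsal-ventral
  plane — but rules out simulating asymmetric perturbations without meshing
  the full surface.
* Hard masking of follicle-cell species at the columnar-cap boundary deletes
  the (small) amounts transported past the edge rather than tracking
  stretched-cell biology; border cells are not modeled at all.
* The source footprint ratios are placeholders (see *Parameters*), so
  absolute spatial extents at default settings are indicative, not
  calibrated.
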