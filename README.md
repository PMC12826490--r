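# grksim

Dynamic simulation of EGFR signaling on the growing *Drosophila* egg chamber.

During mid-oogenesis (stages S7–S10A, about 3–19.5 h in the model's clock) the
TGF-α-like ligand Gurken (GRK) is secreted from the oocyte around its nucleus
into the perivitelline space — the thin (H = 0.5 µm) gap between the oocyte and
the overlying follicle cells (FCs) — where it diffuses, binds EGFR on the FCs
and triggers the dpERK signal that patterns the eggshell. Three morphological
movements happen at the same time: the egg chamber grows about four-fold along
the anterior–posterior (AP) axis and three-fold dorso-ventrally (DV); the
oocyte nucleus (and with it the secretion source) migrates from the posterior
pole to the dorsal anterior; and the FCs compact toward the posterior as they
become columnar. `grksim` implements a transport–reaction–diffusion model of
this system for people who want to ask how each of those mechanistic changes
shapes the signal — including perturbations (stopping growth, stopping the
nucleus, removing the FC shift) that are lethal or infeasible in the fly.

## The model

The perivitelline space is a prolate spheroid with time-varying semi-axes
`L_AP(t)`, `L_DV(t)` taken from a measured six-stage dimension table. On this
growing surface the ligand `L` and the follicle-cell species — free receptor
`R`, surface complex `C`, internalized complex `Ci`, signal `S` (dpERK) and
the feedback inhibitors `STY` (Sprouty) and `KEK1` (Kekkon-1) — obey

```
∂L/∂t  + ∇·(vL)           = D Δ_t L + V(t,x) − (1/H) k̄_on R L + k_off C
∂C/∂t  + ∇·(vC) + ∇·(wC)  =  (1/H) k̄_on R L − k_off C − k_ec C + α_rec k_rec Ci
∂Ci/∂t + ∇·(vCi)+ ∇·(wCi) =  k_ec C − α_deg k_deg Ci − α_rec k_rec Ci
∂R/∂t  + ∇·(vR) + ∇·(wR)  = −(1/H) k̄_on R L + k_off C − k_er R + Q_r
∂S/∂t  + ∇·(vS) + ∇·(wS)  =  k̄_s Ci − k_d S
∂STY/∂t  + transport      =  k_STY  S − k_dSTY  STY
∂KEK1/∂t + transport      =  k_KEK1 S − k_dKEK1 KEK1
```

with the negative feedback

```
k̄_on = k_on / (1 + γ_KEK1 KEK1 / K),    k̄_s = k_s / (1 + γ_STY STY / K′).
```

Here `Δ_t` is the Laplace–Beltrami operator of the surface at time `t`
(time-varying because the surface grows), `v` is the growth velocity field,
`w` the tangential posterior FC-shift field, and `V(t,x)` the moving T-shaped
secretion flux whose total is proportional to the oocyte surface area.
Numerically, the surface is discretized by a cell-centered cubed-spheroid
mesh (eight logically square zones, no pole degeneracy) and integrated by
operator splitting with forward Euler: ligand diffusion (sub-cycled under the
explicit stability bound), growth transport with exact area-Jacobian
dilution, upwind FC-shift transport, then reactions plus source. Diffusion
and transport are conservative to rounding by construction (single-valued
interface fluxes between mesh zones).

## Worked example

```r
library(grksim)

tl <- chamber_timeline()
dims_at(tl, c(3, 10.5, 19.5))
#> # A tibble: 3 × 8
#>   time_hr   L_E   L_O  L_FC   W_E   W_O  L_AP  L_DV
#>     <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     3      71    NA    71    45    NA  35.5  22.5
#> 2    10.5   132    31   132    74    58  66    37
#> 3    19.5   307   149   149   129   129 154.   64.5

meridian_circumference(dims_at(tl, 19.5))
#> [1] 713.7151    # µm around the full AP meridian at stage 10A

sim <- simulate_chamber(simulation_config(n = 16))   # ~25 s
glance(sim)
#> # A tibble: 1 × 7
#>   t_end max_dpERK ligand_mass signal_mass elongation_um n_steps clip_count
#>   <dbl>     <dbl>       <dbl>       <dbl>         <dbl>   <int>      <dbl>
#> 1  19.5  3.57e-27    4.23e-16    1.23e-22          223.   12197       8154

extract_ap_profile(sim, 19.5) |> head(3)
#> # A tibble: 3 × 7
#>   axis  stage time_hr position_um position_frac   eta    value
#>   <chr> <chr>   <dbl>       <dbl>         <dbl> <dbl>    <dbl>
#> 1 AP    S10A     19.5        0           0       1.54 2.62e-27
#> 2 AP    S10A     19.5        1.76        0.0101  1.53 2.73e-27
#> 3 AP    S10A     19.5        3.51        0.0202  1.52 2.83e-27
```

`max_dpERK` (mol/µm²) is the peak signal over the surface at stage 10A; it
sits on the dorsal midline just posterior of the nucleus. `elongation_um` is
the field's standard spatial-extent metric: the arc-length of the dorsal meridian
where normalized dpERK exceeds 0.6. `ligand_mass` is the total unbound GRK on
the surface (mol·µm⁻²·µm², i.e. moles up to the surface-density convention).
Profiles and simulation fields are tibbles throughout, so they pipe straight
into dplyr/ggplot2; `autoplot(sim)`, `autoplot(extract_ap_profile(sim, 19.5))`
and `tidy(sim)` give quick views.

Perturbation presets mirror the published mechanistic experiments:

```r
wt  <- run_preset("wt",           config = simulation_config(n = 16))
gs  <- run_preset("growth-stop",  config = simulation_config(n = 16), wt = wt)
gs$metrics    # max dpERK per stage, elongation in µm and % of wild type
```

Calibration of the inhibitor strengths and RNAi-style depletion scans work
against reference intensity curves — either external CSVs (columns `axis`,
`time_hr`, `position_frac`, `value`, optional `dosage`) or synthetic ones from
`synth_reference_curves()`:

```r
cfg <- simulation_config(n = 16)
ref <- synth_reference_curves(cfg, dosages = c(0.5, 1, 2), times = 19.5)
calibrate_gammas(c(2.5e4, 5e4), c(1e3, 4e3), ref, cfg,
                 dosages = c(0.5, 1, 2), times = 19.5)
#> <gamma_calibration> best: gamma_STY = 50000 , gamma_KEK1 = 1000
```

## Package layout

- `chamber_timeline()`, `dims_at()`, `nucleus_position()`, `growth_velocity()`,
  `fc_shift_velocity()`, `meridian_circumference()` — measured geometry and
  its kinematics.
- `cubed_spheroid()`, `remesh_to()`, `surface_area()`, `mesh_nodes()` — the
  multi-zone surface mesh.
- `laplace_beltrami()`, `surface_divergence_transport()`,
  `integrate_surface()` — conservative discrete operators.
- `kinetic_params()`, `effective_rates()`, `reaction_rhs()`,
  `depletion_variant()` — the local kinetics.
- `source_spec()`, `source_flux()`, `dosage_variant()` — the moving secretion
  source.
- `simulation_config()`, `simulate_chamber()`, `step_chamber()`,
  `initial_state()`, `nondimensionalize()` — the integrator.
- `extract_ap_profile()`, `extract_dv_profile()`, `elongation()`,
  `max_signal()`, `l1_relative_error()`, `normalize_to_reference()`,
  `calibrate_gammas()`, `depletion_scan()`, `synth_reference_curves()` —
  quantification and calibration.
- `load_config()`, `run_preset()`, `run_manifest()` — configuration files,
  presets, provenance; `inst/scripts/run_preset.R` is a shell wrapper.

See the methods vignette (`vignettes/egg-chamber-signaling.Rmd`) for the
modeling assumptions, parameter choices and known limitations.
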