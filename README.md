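# ctffr

Desk-scale functional assessment of coronary stenosis from CT: segmentation,
surface reconstruction, and a reduced-order fractional flow reserve (FFR)
model, with a cohort-statistics layer for SYNTAX-score risk stratification.

## The problem

Coronary CT angiography shows *how narrow* a stenosis is, but not *how much
it matters* to the myocardium downstream. The functional question is settled
by fractional flow reserve,

```
FFR = Ps / Pr
```

the ratio of mean distal coronary pressure `Ps` to mean aortic pressure `Pr`
at maximal hyperemia: FFR ≤ 0.80 conventionally marks a lesion as
hemodynamically significant. Measuring FFR invasively requires a pressure
wire; computing it from CT requires a chain of image-analysis and flow-model
steps. `ctffr` implements that chain end to end at desk scale, on synthetic
CT phantoms with known ground truth, so every stage can be validated against
closed forms:

1. **Phantom generation** — seeded synthetic contrast-enhanced CT volumes of
   a stenosed vessel (bright lumen, soft-tissue background, Gaussian noise),
   plus synthetic patient cohorts with controlled correlation and event-rate
   structure.
2. **Segmentation** — two-class clustering-threshold segmentation: scan a
   test threshold `t`, split voxels into foreground/background with class
   means `a1`, `a2` and counts `M1`, `M2`, and minimise the within-class
   scatter `G(t) = Σ_fg (p − a1)² + Σ_bg (p − a2)²` (the Otsu / two-means
   criterion). An interactive live-wire (minimum-cost-path) boundary
   extractor is included for slice-wise editing.
3. **Reconstruction** — watertight triangle surface of the binary mask by
   marching-cubes isosurface extraction over a tetrahedral cell
   decomposition, with topology validation (Euler characteristic, edge
   manifoldness), Laplacian smoothing, and STL/PLY export.
4. **Hemodynamics** — steady axisymmetric reduction of the incompressible
   Navier–Stokes equations (`∇·v = 0`, `ρ dv/dt = −∇P + μ∇²v`) over the
   lumen radius profile `r(s)`: segmentwise Poiseuille drop
   `Δp = 8μLQ/(πR⁴)` plus a Young–Tsai expansion loss across the throat;
   pressure–pressure conditions are inverted by bisection; FFR follows from
   the station pressures or from averaged pressure waveforms.
5. **Cohort statistics** — SYNTAX grouping (low 0–22, medium 23–32,
   high ≥ 33), the strict vessel inclusion filter (diameter > 1.5 mm,
   stenosis > 50 %), Pearson correlation with Fisher-z intervals, one-way
   ANOVA, chi-square tests, diagnostic accuracy/sensitivity/specificity at
   the FFR ≤ 0.80 cutoff, and ROC/AUC.

Everything tabular goes in and out as tibbles; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` figures.

## Worked example

```r
library(ctffr)

geom <- vessel_geometry(L = 30, R0 = 2, d = 0.5)   # 50% diameter stenosis
geom
#> <vessel_geometry> L = 30 mm, R0 = 2 mm, d = 0.5 (throat r = 1 mm at s0 = 15 mm, w = 3 mm)

vol <- rasterize_ct(geom, spacing = 0.4, lumen = 400, background = 50,
                    noise_sd = 20, seed = 1)
vol
#> <ct_volume> 21 x 21 x 76 voxels, spacing (0.4, 0.4, 0.4) mm, range [-36.0556, 473.016]

thr <- optimal_threshold(vol)
thr
#> <threshold_result> t* = 127 (G = 1.35273e+07); foreground M1 = 4388 (mean 400),
#>                    background M2 = 29128 (mean 50.1)

mask <- largest_component(apply_threshold(vol, thr$t_star))
mask_jaccard(mask, lumen_truth_mask(geom, spacing = 0.4))
#> [1] 1

prof <- extract_lumen_profile(mask)
sol  <- solve_steady_flow(prof, fluid_model(),
                          flow_bc(inlet_pressure = 100, inlet_flow = 3))
compute_ffr(sol$pressure_mmhg[nrow(sol)], 100)
#> <ffr_result> FFR = 0.964 (Ps = 96.4, Pr = 100)
```

The threshold lands in the empty intensity gap between tissue (mean 50) and
contrast-filled lumen (mean 400), the recovered mask matches the ground-truth
lumen voxel for voxel (Jaccard 1), and the 50 % lesion costs ~3.6 mmHg at a
hyperemic 3 mL/s — a clearly non-ischemic FFR of 0.96 for this short,
large-calibre segment. Severity sweeps show the expected steepening collapse:

```r
ffr_vs_severity(c(0, 0.3, 0.5, 0.7))
#> # A tibble: 4 × 6
#>       d q_ml_s pr_mmhg ps_mmhg dp_mmhg   ffr
#> 1   0        3     100    99.5   0.501 0.995
#> 2   0.3      3     100    98.8   1.18  0.988
#> 3   0.5      3     100    95.3   4.68  0.953
#> 4   0.7      3     100    58.4  41.6   0.584
```

The one-call pipeline (`run_pipeline(default_pipeline_config())`) chains
phantom → segment → reconstruct → profile → solve, writing every intermediate
artifact (MetaImage volume and mask, STL/PLY mesh, profile CSV, FFR JSON) and
a manifest with per-artifact MD5 sums. A thin command-line front-end with the
same stages lives at `inst/cli/ctffr`. Cohort analyses:

```r
coh <- simulate_cohort(n = 90, seed = 7)
pearson_r(coh$syntax_score, coh$total_cholesterol)
group_event_rates(coh)$rates
```

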