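---
title: "Methods: from synthetic coronary CT to fractional flow reserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from synthetic coronary CT to fractional flow reserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctffr)
```

`ctffr` chains five stages — phantom generation, clustering-threshold
segmentation, isosurface reconstruction, a reduced-order flow solve, and
cohort statistics — into a validated desk-scale pipeline for CT-derived
fractional flow reserve (FFR). This vignette is the package's account of the
models behind each stage: the assumptions they make, the parameters that
matter, the numerical choices taken where the design was genuinely open, and
what the synthetic experiments do and do not demonstrate about real data.

## 1. The phantom generator

### Geometry

A vessel is a straight tube of length $L$ and baseline radius $R_0$ with one
focal stenosis. The radius profile along arclength $s$ is

$$ r(s) = R_0\,\bigl(1 - d\,g(s)\bigr), \qquad
   g(s) = \exp\!\left(-\frac{(s-s_0)^2}{2w^2}\right), $$

so $d \in [0,1)$ is the fractional *diameter* reduction at the throat — the
"percent diameter stenosis" of angiography divided by 100 — and $w$ (mm) is
the Gaussian width of the lesion. A Gaussian bump was chosen because it is
smooth, two-parameter, and standard for idealised stenoses; it guarantees
$r(s) > 0$ everywhere and $r \to R_0$ away from the lesion. Defaults
($R_0 = 2$ mm, i.e. a 4 mm proximal-calibre lumen; $L = 30{-}40$ mm;
$w = 3{-}4$ mm) describe a clinically relevant epicardial segment: vessels
below 1.5 mm diameter are conventionally excluded from scoring, and a 4 mm
lumen keeps the full severity sweep $d \in \{0, 0.3, 0.5, 0.7\}$ inside the
physical FFR range at hyperemic flow.

### Rasterisation

`rasterize_ct()` sweeps the tube along the z axis of a voxel grid sized to
enclose it (voxel centers at `origin + (index − 1) · spacing`). Each voxel is
classified by its center — inside voxels get the lumen intensity (default
400, a contrast-enhanced HU-like value), outside voxels the background
(default 50, soft tissue) — and seeded Gaussian noise is added. Hard
center-classification is the default (`supersample = 1`) so that the
noise-free volume is an *exact indicator* of the lumen: the same in/out rule
defines the ground-truth mask, which makes segmentation-recovery experiments
exact rather than approximate. Setting `supersample = k` instead estimates
fractional occupancy from $k^3$ sub-voxel points, emulating partial-volume
blur; the occupancy mass then approximates the analytic cylinder volume
$\pi R_0^2 L$ while the center-count converges to $\pi R_0^2 (L + h)$ at
spacing $h$ (the grid carries one voxel-center plane at each end face).
Voxel-center disk counts fluctuate with the lattice (the Gauss circle
phenomenon), so convergence with spacing is verified over a coarse-to-fine
pair (0.8 mm to 0.4 mm) where the error contraction is clean.

All randomness flows through one seeded stream that is isolated from the
session RNG: the same `seed` gives a bit-identical volume, and generating a
phantom never perturbs user-level random state.

### The synthetic cohort

`simulate_cohort()` emulates the statistical structure of a post-PCI
observational cohort: $n = 90$ patients by default; a non-negative integer
SYNTAX score; four lipid measures correlated with the score; binary
risk-factor covariates; and a MACCE flag with group-dependent probability.
The dependence structure is a single-factor Gaussian copula: a latent
standard normal $z_0$ drives each lipid latent as
$z_j = r_j z_0 + \sqrt{1-r_j^2}\,\varepsilon_j$, which makes any vector of
targets $|r_j| < 1$ feasible by construction (a user-supplied full latent
correlation matrix is Cholesky-checked instead). Marginals are monotone
transforms of the latents: the score is a rounded gamma (shape 7, scale
27/7 — mean 27, SD ≈ 10, right-skewed, spanning 0–50 so all three SYNTAX
groups are populated), total cholesterol and LDL-C are normal, triglyceride
and ApoB/ApoA1 are log-normal (positive, mildly skewed). Default correlation
targets (0.234, 0.237, 0.285, 0.298) and covariate prevalences are the
observed values in the kind of cohort the generator stands in for; default
group MACCE probabilities are (0.1, 0.1, 0.4), encoding a high-score excess
risk with no low/medium contrast.

Two consequences of the monotone marginals matter for validation. First,
rounding and non-linear transforms attenuate the observable Pearson
correlation slightly below the latent target (at a target of 0.3 the
realised population value is ≈ 0.29). A confidence-interval coverage test
must therefore target the generator's *actual* population correlation —
estimated once from a large draw ($n = 2 \times 10^5$) — not the latent
parameter; against that target, Fisher-z intervals at $n = 90$ achieve
nominal-level coverage (checked over 200 seeded replicates). Second, the
generator reproduces correlation and incidence structure only; it does not
model measurement error, missingness, censoring, or confounding, so passing
tests certify the statistics layer's arithmetic, not clinical effect
estimates.

## 2. Clustering-threshold segmentation

Contrast-filled lumen is bright, so a test threshold $t$ partitions voxels
into foreground $B_1 = \{p \ge t\}$ and background $B_2 = \{p < t\}$ with
means $\bar a_1, \bar a_2$ and counts $M_1, M_2$. The objective is the total
within-class scatter

$$ G(t) = \sum_{p \in B_1} (p - \bar a_1)^2 + \sum_{p \in B_2} (p - \bar a_2)^2, $$

the two-class k-means / Otsu criterion; `optimal_threshold()` scans a
discrete grid of $t$ and returns the exact argmin. Open choices fixed here:

- **Foreground rule** is $\ge t$ (not $> t$): the lumen is the bright class
  under contrast enhancement.
- **Scan granularity** defaults to every integer intensity in the volume's
  range — CT intensities are calibrated integers, so an integer grid scans
  "all $t$" at the data's native resolution. The scan is computed from
  prefix sums over the sorted intensities ($O(n\log n + T)$), which is
  algebraically identical to the per-threshold two-pass computation.
- **Ties** in $G$ break toward the smallest $t$, making the result
  deterministic; on a two-valued volume every threshold strictly between the
  modes attains $G = 0$ and the smallest scanned one is returned.
- **Empty classes** contribute zero scatter, so degenerate thresholds at the
  range ends are well-defined rather than errors; the result carries an
  `empty_class` flag.

`largest_component()` removes noise specks before reconstruction using
iterative minimum-label propagation under 6/18/26-connectivity. Labels are
seeded with linear voxel indices, so each component's label is its minimum
linear index and size ties resolve deterministically to the
lowest-linear-index component.

The live-wire operation is exposed programmatically (no GUI loop): the
minimum-cumulative-cost 8-connected path under a local cost
$l(q) = w_g(1 - |\nabla I|_q / \max|\nabla I|) + w_z(1 - z(q))$, with
$z(q)$ the Laplacian zero-crossing indicator and diagonal steps scaled by
$\sqrt 2$. The weights $w_g = 0.8$, $w_z = 0.2$ are the classic live-wire
literature values; nothing in the clustering-threshold construction
constrains them, so the two operations are implemented independently.
Optimality is relative to that declared cost and is verified against an
independent shortest-path implementation.

## 3. Isosurface reconstruction

`marching_cubes()` extracts the triangle surface of a level set. Rather than
the classic 15-case cube table — whose ambiguous face configurations need an
extra decision rule to avoid holes — each grid cell is split into six
tetrahedra by the translation-invariant Kuhn decomposition along the cell's
main diagonal. Neighbouring cells then share identical face diagonals, and a
tetrahedron's linear interpolant has no ambiguous sign patterns, so the
extracted surface is **watertight by construction** wherever the level set
stays interior to the volume; the small tetrahedral case table is derived by
enumeration in code at call time. Within each tetrahedron, vertices are
placed by linear interpolation along cut edges; vertices are welded per
global grid edge (computed once, so coordinates are bitwise identical across
incident triangles); triangles are oriented outward using the generating
tetrahedron's inside/outside centroids. The cost of the tetrahedral split is
a finer triangulation than cube-based tables produce — more triangles per
unit area, with a mild direction-dependent bias — which the validation
quantifies: on a 10 mm sphere sampled at 1 mm, surface area and enclosed
volume land well inside 2 % of $4\pi r^2$ and $\tfrac43 \pi r^3$, with both
errors shrinking when the spacing halves.

Binary masks are surfaced as 0/1 fields at isolevel 0.5 ("inside" is
strictly above the isolevel, so 0/1 data never sits on the surface);
optional box pre-smoothing of the field (`pre_smooth`) tames the voxel
staircase before surfacing, and is off by default to keep binary semantics.
A vessel whose ends touch the volume boundary yields an open tube:
`mesh_report()` distinguishes watertight meshes from
watertight-up-to-boundary-rings by counting edges incident to exactly one
triangle, and reports $\chi = V - E + F$, total area, and signed enclosed
volume. `smooth_mesh()` is uniform Laplacian smoothing — it preserves the
vertex count and connectivity (hence topology) and mildly shrinks closed
surfaces, the standard trade-off accepted for taming stair-step artifacts.

`extract_lumen_profile()` bridges reconstruction to the flow model: for a
vessel aligned with a grid axis (the v1 restriction), the equivalent radius
at each station is $r(s) = \sqrt{A(s)/\pi}$, with $A(s)$ either the
foreground pixel count times pixel area (mask route) or the signed polygon
area of the mesh's plane section (mesh route, assembled from oriented
triangle crossings). The two estimators agree to discretisation tolerance
and differ in failure modes, which is why both exist.

## 4. The reduced-order flow model

The paper-scale question — what pressure does a stenosis cost at hyperemia —
is answered with a steady, axisymmetric, rigid-wall reduction of the
incompressible continuity and momentum equations. At the steady hyperemic
operating point the acceleration term of the momentum balance vanishes;
pulsatility enters only through waveform averaging (`mean_pressure()`,
trapezoidal). The solver guarantees:

- **Mass conservation exactly**: one flow rate $Q$, $v(s) = Q/A(s)$.
- **Distributed viscous loss**: trapezoid integration of the Poiseuille
  gradient $8\mu Q / (\pi r(s)^4)$ along the profile. In the uniform-tube
  limit this reproduces $\Delta p = 8\mu L Q/(\pi R^4)$ to rounding error,
  which is the oracle any correct 3-D solver must also satisfy.
- **Stenosis expansion loss**: the Young–Tsai empirical model. As a
  standalone operation, `stenosis_loss()` returns
  $K_v \mu Q/(A_0 D_0) + K_t \frac{\rho}{2A_0^2}(A_0/A_s - 1)^2 Q^2$ with
  $K_v = 32\,(0.83 L_a + 1.64 D_s)/D_0 \cdot (A_0/A_s)^2$ and $K_t = 1.52$
  (classic empirical values); $A_0, D_0$ are taken at the profile inlet,
  $L_a$ is the full width at half the radius deficit, and the loss is zero
  for uniform profiles. Inside `solve_steady_flow()` only the turbulent
  $K_t$ term is added across the throat, because the constriction's viscous
  excess is already carried by the integrated Poiseuille term — adding the
  $K_v$ term there would double-count it.
- **Monotone inversion**: with pressure conditions at both ends,
  $Q \mapsto \Delta p(Q)$ is strictly increasing, so $Q$ is recovered by
  bisection (200 iterations, relative tolerance $10^{-12}$), bracketed above
  by the zero-loss Poiseuille bound
  $Q_{\max} = \Delta p\, \pi r_{\max}^4 / (8\mu L)$, which guarantees the
  root is enclosed.

Boundary conditions mirror clinical practice: an aortic pressure with an
outlet pressure or distal resistance, or — the hyperemic operating point —
a prescribed hyperemic flow anchored by the aortic pressure. Maximal
hyperemia defaults to three times a 1 mL/s resting flow; a reduced distal
resistance model is exposed as the alternative. Fluid defaults are standard
blood values, $\rho = 1060$ kg/m³, $\mu = 0.0035$ Pa·s; geometry enters in
mm and pressures in mmHg, converted internally to SI. The measurement
stations for $P_s$ and $P_r$ default to the modelled segment's outlet and
inlet and are exposed as the station table, since no convention fixes them
more precisely. `compute_ffr()` flags FFR > 1 as non-physical rather than
erroring: waveform averaging of measured traces can legitimately produce it
by noise.

What the reduction omits — and therefore what the validation does not claim:
3-D secondary flow, vessel-wall elasticity and fluid–structure interaction,
blood gravity, non-Newtonian rheology, and multi-outlet coronary trees.
Uniform-tube fidelity, monotonicity in $(Q, \mu, d)$, and FFR physics
(identity at zero loss, decrease with severity, range $(0, 1]$) are the
properties a correct 3-D solver must share, and they are what the tests pin.

## 5. Cohort statistics

The analysis layer mirrors a standard three-group clinical table. SYNTAX
grouping partitions the non-negative integers as low $[0,22]$, medium
$[23,32]$, high $\ge 33$ — the only reading that partitions the score line
given the medium band — with fractional scores rounded half-up first, since
the scoring system is integer-valued. The vessel inclusion filter is
strict on both criteria (diameter > 1.5 mm *and* stenosis > 50 %).
Correlation, ANOVA and chi-square go through the standard R implementations
(`cor.test`, `oneway.test(var.equal = TRUE)`, `chisq.test(correct = FALSE)`),
wrapped to tidy one-row tibbles with the package's validation (zero-variance
and zero-margin inputs are rejected with specific errors; the small-expected-
count asymptotic caveat of the chi-square is documented rather than warned on
every call). The test suite re-derives each from textbook formulas as an
independent oracle. ROC/AUC is implemented directly — every unique score as
a threshold, trapezoidal integration — because the ROC point table is an
output format; its AUC equals the Mann–Whitney concordance probability
exactly, which the tests check by exhaustive pair counting and against an
established ROC package. Pairwise group contrasts are reported unadjusted by
default (matching common clinical reporting practice for three groups), with
a Bonferroni option. Time-to-event modelling is out of scope: follow-up is
summarised as crude incidence.

The diagnostic layer dichotomises FFR at 0.80, the universal clinical
cutoff, with the usual confusion-table identities.

## 6. Pipeline reproducibility

`run_pipeline()` validates the whole configuration before any stage runs,
then executes phantom → segment → reconstruct → profile → solve (and
optionally cohort) with **file-mediated stages**: every stage reads its
inputs from the written artifacts of the previous one. This is what makes
stagewise execution equal single-shot execution bit for bit — there is no
in-memory shortcut to diverge from. Volumes and masks travel as MetaImage
(`MET_DOUBLE` / `MET_UCHAR`, lossless), so the round trip is exact; the
manifest records the seed, the full configuration, its MD5, and per-artifact
MD5 sums, making bit-reproducibility checkable from the manifest alone.

## 7. Problem sizes and tolerances used in validation

The suite runs phantoms at 0.4–0.5 mm spacing (volumes around
$21 \times 21 \times 76$ voxels), threshold-oracle checks on 100 random
volumes up to $16^3$, sphere reconstruction at 1 mm and 0.5 mm, solver grids
of 24 $(\mu, L, R, Q)$ combinations, 200-replicate coverage runs at
$n = 90$, and a 3000-patient event-rate contrast — sizes chosen so each
property is tested at a scale where its failure would be unambiguous while
the whole suite stays fast. Key tolerances: solver vs Poiseuille $10^{-3}$
relative (observed at rounding-error level), mass conservation $10^{-10}$
relative, sphere metrics 2 %, segmentation Jaccard 0.9 at contrast-to-noise
10, CI coverage ≥ 90 % at nominal 95 %.

## Known limitations

Single straight vessel with one stenosis (no bifurcations or tortuosity); no
CT physics (beam hardening, motion, gating artifacts) in the phantom; no
registration step (single-volume pipeline); axis-aligned profile extraction;
rigid-wall steady hemodynamics as above; no DICOM series reader (MetaImage
and NIfTI are the supported volume formats); cohort tables are structural
stand-ins, not clinical estimates.
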