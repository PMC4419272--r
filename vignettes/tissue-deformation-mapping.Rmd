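---
title: "Mapping tissue deformation from sparse landmarks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tissue deformation from sparse landmarks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphomapr)
```

`morphomapr` turns sparse paired landmarks from a growing 2D organ into
smooth deformation maps and tissue-level growth and anisotropy fields, and
replays those fields through a geometric simulator. This vignette is the
package's account of its science: the models, their assumptions, every
tunable parameter that matters, and what the validation on synthetic data
does and does not show about real data.

## Coordinates and tensors

All positions are micrometres in the frontal (AP–PD) plane: +x is
proximal→distal (`pd`), +y anterior→posterior (`ap`), right-handed. The
deformation over one stage interval is the map **x** = φ(**X**). Its
gradient **F** (2×2, dimensionless) decomposes as **F** = **RU**; tissue
growth rate is det **F**, deformation anisotropy is λ₁/λ₂ of **U** with the
λ₁ eigenvector as axis. All tensors, and in particular anisotropy axes, are
expressed in the *reference* (before-deformation) frame — the axis of
maximal stretch of the material element, comparable across stages. Drawing
axes in the deformed frame (rotate by **R**) is the alternative convention;
we fix the reference frame because pooled per-stage comparisons are made on
reference-lattice cells.

Numerical choices:

- `polar_decompose()` uses the exact 2×2 closed form
  `R = [[a+d, b−c], [c−b, a+d]]/r`, `r = √((a+d)² + (b−c)²)`, defined
  whenever det F > 0. It is exact to rounding and keeps the SVD construction
  (`R = WVᵀ`, `U = VΣVᵀ`) available as a genuinely independent oracle in the
  test suite.
- Anisotropy is an axis, not a vector. The reported direction is the
  representative with non-negative `pd` component (non-negative `ap` on
  exact ties). For λ₁ = λ₂ (within 1e−12 relative) the axis is undefined:
  the magnitude is returned as exactly 1 with a flagged `NA` direction
  rather than an arbitrary eigenvector.
- Tensors with condition number above 1e12 raise a degeneracy error.

## The map estimator

A regular square lattice (default `spacing = 200` µm, inside the 150–250 µm
range that resolves organ-scale growth patterns without chasing marker
noise; `margin_cells = 1` padding) envelops all before-positions. The model
is linear-Gaussian:

- observation: each after-position is the bilinear interpolation of the four
  deformed node positions of its cell, plus isotropic Gaussian noise of
  variance σ² (µm²) — the only assumption about the data beyond smoothness;
- prior: the node displacement field `d` has Gaussian penalty `α‖L d‖²`,
  with `L` the stacked second-difference operator along both grid axes plus
  √2-weighted mixed differences per cell (a thin-plate-type discrete
  penalty). Its null space is exactly the affine fields, so uniform growth,
  stretch and shear are unpenalised — a uniform expansion should not be
  shrunk toward the identity. Without the mixed term, bilinear shear wiggles
  would be invisible to the prior and contaminate the derived det F field.

The posterior mean solves `(WᵀW + λ LᵀL) d = Wᵀ(x − W·ref)` per coordinate
with λ = ασ². It is computed as augmented least squares on
`[W; √λ L]` via QR, which is backward-stable across the entire λ range (the
normal equations lose the affine component for λ ≳ 1e9). When the QR detects
rank deficiency (degenerate landmark configurations), a tiny ridge
(√1e−8-scaled rows) on nodes without data support restores solvability; in
regular use no ridge is applied, which is what makes noiseless affine data
reproduce `A·X + b` at every node to better than 1e−6 µm for any α.

**Hyperparameters.** With `alpha = NULL`, λ is selected by empirical Bayes:
the type-II (marginal) log-likelihood, with the penalty null space treated
as diffuse and σ² profiled in closed form
(σ̂² = Σ(RSS + λ dᵀKd)/(2(n − p₀)), both coordinates pooled, p₀ = 3), is
maximised over a 25-point log-spaced grid spanning eight decades of the
smoothness weight around an affine-prefit noise scale. The fitted `alpha`
is reported as λ/σ̂². Fixed `alpha`/`sigma2` can be supplied instead — e.g.
cross-validated values — and a short fixed-point iteration profiles σ² when
only `alpha` is given.

**Pooling and registration.** All embryos of an interval are pooled into one
fit. Embryos are first mapped into a common frame by rigid Procrustes
(rotation + translation, Kabsch; *no scaling* — inter-embryo size
differences are biology, not nuisance) on outline vertex correspondences,
either to the consensus outline (generalized Procrustes, two passes) or to a
supplied reference/atlas outline. Exact duplicate `X` positions are treated
as measurement replicates and averaged with a warning.

## Cross-validation

`cross_validate()` defaults to leave-one-embryo-out, matching the pooled
design: the natural exchangeable unit is the embryo, and per-marker holdout
would leak the held-out embryo's frame and noise structure into training.
Seeded k-fold over markers is available for single-embryo data. Held-out
points outside a training lattice are skipped and counted; folds with fewer
than 6 training pairs are skipped with a warning. Errors are reported as
means (medians alongside) of |Δpd|, |Δap| and the Euclidean distance, pooled
over all held-out predictions and per fold. Hyperparameters are re-selected
per fold.

## Derived fields

`compute_field()` evaluates **F** once per lattice cell, at the cell centre,
from the bilinear shape-function gradient of the cell's four nodes —
bilinear gradients are discontinuous across edges, so per-cell centre
evaluation is the honest resolution of the estimate. Cells whose centre
falls inside the convex hull of the landmark before-positions are flagged
`supported`; statistics use supported cells only (no imputation). Cells with
det F ≤ 0 are flagged, not fatal, and the map records whether it is
fold-free.

D-V growth at **X** is `h(φ(X))/H(X)` with bilinear interpolation of the
gridded thickness fields; queries outside either support are masked `NA` and
excluded from volumetric growth, which is the exact per-cell product of area
and D-V growth. Bead-region statistics (`region_change()`) average
treated-minus-control differences over lattice *cells* whose centres lie
within the disc (default radius 200 µm) — averaging a dense resampling of
the same piecewise-constant field would only re-weight boundary cells.
`affine_anisotropy()` fits the least-squares affine map to ≥ 3 non-collinear
markers (the translation absorbs common drift, so only relative positions
matter) and reports the anisotropy of its linear part — the estimator for
few-crystal DiI experiments.

## Cell-cycle estimation

Dual-label pulse-chase counts (first label IddU, second BrdU, Δt hours
apart) are converted under steady-state asynchronous cycling with uniform
age structure: the flux out of S phase is constant, so
`T_s = Δt · n_s/n_leaving` and `T_c = T_s · n_total/n_s` (the S-phase
fraction equals the duration fraction). This is the standard
leaving-fraction estimator; no growth-fraction correction is applied — if a
quiescent subpopulation exists, `T_c` is overestimated proportionally.
Counts classified so that `n_s + n_leaving > n_total` warn rather than
error, keeping algebraic boundary cases computable. Percentile bootstrap
CIs (`cell_cycle_boot()`, multinomial resampling of classified cells,
seeded) quantify count noise. Regional proliferation-rate ratios are inverse
`T_c` ratios.

## The vertex-model simulator

The tissue is a fixed-topology polygonal mesh — mesenchymal packing, no T1
neighbour rearrangements, consistent with the observed invariance of
neighbour relationships among markers. The energy contains *only geometric
constraints*, no line tensions or elastic moduli:

E = Σ_c [ K_A (A_c/A_c* − 1)² + K_S ‖S_c/tr S_c − T_c/tr T_c‖²_F ]

with `S_c` the cell's area-normalised second-moment (gyration) tensor about
its centroid and `T_c` its target. Growth and anisotropy are prescribed, not
emergent: each step multiplies the target area by the local growth factor g
and transforms the target shape by `B = R(θ) diag(√(ga), √(g/a)) R(θ)ᵀ`, so
target anisotropy compounds multiplicatively across steps (the alternative —
resetting rather than compounding — cannot accumulate a 24 h elongation from
small per-step biases, contradicting the observed persistent alignment).

Defaults `K_A = K_S = 1` weight a relative area error against a normalised
shape mismatch, both dimensionless and O(1). The descent is overdamped
backtracking gradient descent with analytic gradients (verified against
finite differences); "`step = 0.05`" is interpreted as the fraction of
√(mean target area) moved by the steepest vertex per iteration, since the
raw energy gradient has units 1/µm. Each step's descent is initialised by a
uniform scaling about the tissue centroid by √(mean prescribed growth),
which makes uniform isotropic growth an exact fixed point (area multiplies
by g and the outline stays self-similar to well under 2 % per step — one of
the simulator's validation anchors). Polygon flips trigger step halving;
persistent flips abort. `max_iter = 500` descent iterations per growth step
suffice for the ~100–400-cell tissues used here.

`init_tissue()` tiles the outline with regular hexagons (a centroidal
Voronoi tessellation) clipped to the outline by Sutherland–Hodgman, merging
shared vertices at 1e−6 µm resolution; targets are initialised to the
as-built geometry so the initial state has zero energy. Scenario fields are
sampled *once* at initial cell centroids (material/Lagrangian assignment)
and compounded as the steps-th root per step; centroids outside a
`deformation_field`'s support take the nearest valid cell's value. The
virtual mutants: `vMT_I` keeps the growth pattern and flattens anisotropy to
1; `vMT_II` keeps the anisotropy pattern and replaces growth by its
initial-area-weighted spatial mean, which conserves total prescribed growth
exactly — that is why WT and vMT_II final areas agree within the descent
tolerance.

## The synthetic study

The generator emulates the dye-injection design with known ground truth. The
default conditions are fixed once: a paddle-shaped domain of 2000 × 1000 µm
(capsule polygon, a stage-22-like bud), 8 embryos × 30 markers per interval
(within the 20–50 markers injected per embryo), marker noise σ = 20 µm
(below the ~40–50 µm prediction-error scale of real data), base area growth
1.4 per 12 h (an organ that roughly doubles in a day), growth contrast 2
across the domain, PD-aligned anisotropy 1.3, and per-embryo rigid frame
jitter of 25 µm translation / 2° rotation sd — small mounting variability
that outline Procrustes removes. Seed 7.

Ground-truth maps are separable monotone C¹ maps whose diagonal gradient
realises the growth mode via cosine-tapered plateaus (C¹ smoothness matches
the estimation prior; the antiderivatives are closed-form, so φ, F, det F
and the anisotropy field are all analytic, and the inverse is obtained by
per-axis root finding). The three modes place the growth bump distally,
posteriorly, or proximally. Thickness pairs are built so that the implied
D-V growth field equals a known closed-form ratio field; when a target
correlation with det F is requested, the independent component is
residualised against det F over interior calibration points, making the
calibration-point correlation exactly the target. The camera-frame
demonstration returns `v(x) = k (x − x_anchor)` for uniform exponential
growth — different profiles in different frames, identical velocity gradient
k everywhere, which is why velocity fields alone cannot characterise tissue
deformation.

What passing recovery tests show — and what they do not: under the default
conditions the pipeline recovers det F within 10 % at ≥ 90 % of
data-supported cells and holds leave-one-embryo-out error below 2σ. Real
dye-marking data differ in ways the generator does not emulate: projection
error from the 3D→2D flattening onto the frontal plane, depth-dependent
deformation, stage-assignment error between embryos, non-Gaussian marker
localisation error, and spatially correlated biological variability between
embryos. Recovery on synthetic data is therefore a necessary check of the
estimator, not a guarantee about any particular experiment.

## Problem sizes and run times

The shipped tests run the full synthetic study at its native size
(240 landmark pairs, ~100-node lattices, 8-fold embryo cross-validation) and
the simulator on coarse 60–130-cell tissues over 2–10 growth steps; the
whole suite completes in about a minute on one core. Larger tissues and
finer lattices scale as the dense QR of the augmented system and the
per-step descent, both comfortably interactive at several times these sizes.

## Known limitations

- 2D only: no 3D tensors, no strain-rate/velocity-gradient estimation from
  tracking data, no multi-interval trajectory integration.
- The estimator assumes a single smoothness scale; strongly localised
  deformation (e.g. a point source) will be over-smoothed at the
  empirical-Bayes optimum, which balances fit over the whole organ.
- The simulator is geometric by construction: it demonstrates which
  *prescribed* deformation characteristics suffice to reproduce shapes, and
  deliberately says nothing about forces, stresses or material properties.
- The cell-cycle estimator assumes steady-state asynchronous cycling with
  growth fraction 1 over the labelling interval.
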