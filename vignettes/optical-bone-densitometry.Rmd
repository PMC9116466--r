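---
title: "Simulating optical bone densitometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating optical bone densitometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`osteosim` is an in-silico test bench for near-infrared bone densitometry of
the ultradistal radius. The question it addresses: can areal bone mineral
density (aBMD, g/cm²) be recovered from spatially resolved diffuse light
measured around a limb, even though the soft tissue wrapped around the bone
varies in thickness and optical properties from person to person? The
package answers it by simulation: it builds randomized digital forearm
cross-sections, propagates photon packets through them with a voxel Monte
Carlo engine, turns the escaping light into feature vectors, and trains
regression models to predict the aBMD label that each tissue model carries
by construction.

This vignette explains the science inside each stage, the tunable
parameters and their defaults, and the design decisions that were genuinely
open, so that a user can judge what a passing test suite does — and does
not — say about real measurements.

## 1. Synthetic trabecular bone from a reaction–diffusion system

Trabecular bone cannot be represented by a single scattering coefficient:
the spongy strut network scatters light in a way that depends on its
geometry, not only on its average density. The package therefore grows a
three-dimensional trabecular microarchitecture with a two-species Turing
activator–inhibitor system,

$$\partial_t u = f(u,v) + d_u \Delta u, \qquad
  \partial_t v = g(u,v) + d_v \Delta v,$$

with cubic activator kinetics $f = 0.6u - v - u^3$, linear inhibitor
kinetics $g = 1.5u - 2v$, and strongly contrasting diffusivities
$d_u = 2\times10^{-4}$, $d_v = 10^{-2}$ on a periodic grid of spacing
0.025 (dimensionless model units). Starting from uniform noise in
$\pm 0.5$, the homogeneous state is Turing-unstable and the activator
settles into a stationary labyrinthine pattern whose super-level set
$\{u \ge u_{th}\}$ looks remarkably like trabecular struts.

Numerics (`solve_rd()`): a semi-implicit Fourier spectral scheme — the
stiff diffusion term is inverted exactly in Fourier space
($\hat u \leftarrow \hat u / (1 + \Delta t\, d_u k^2)$), the reaction term
advances explicitly. The scheme is unconditionally stable in the diffusion
part, which is what allows $\Delta t = 1$ with 100 fixed steps;
convergence by fixed step count (rather than a residual criterion) is a
deliberate choice so that every field in a cohort has identical smoothing
history. The Laplacian symbol is the continuous $k^2 = (2\pi \nu)^2$; at
this resolution the difference from the discrete symbol is negligible.
Both real fields are packed into a single complex FFT per direction, so a
step costs two 3-D transforms. The initial $u$ and $v$ noises are drawn
independently from the same uniform law out of one seeded stream;
identical seeds give bitwise identical fields, and cyclically shifting the
initial noise shifts the output field by the same amount (a property test
in the suite).

Binarization (`binarize()`, `uth_from_bvtv()`): the bone volume fraction
BV/TV of the thresholded pattern is controlled through a cubic calibration
$u_{th}(\mathrm{BV/TV}) = -7.662x^3 + 1.645x^2 - 0.452x + 0.604$, valid
over roughly BV/TV 3–25 % for the reference solver configuration. The
calibration is configuration-specific: `calibrate_threshold()` re-derives
it (ten independent patterns, a sweep of thresholds, least-squares cubic)
and must be re-run if the kinetics, diffusivities or spacing change. Grid
size alone moves the mapping only weakly — the suite checks that 128³
fields hit the normal-stage (13.4 %) and osteoporosis-stage (8.5 %)
targets within 1.5 percentage points using the reference cubic — but the
reduced desk profile re-calibrates anyway because it also coarsens the
voxel.

A grid voxel acquires physical size only when the pattern is used:
24.5 μm in the reference configuration, matching micro-CT resolution.
The pattern is periodic by construction, so the assembler may tile it to
fill any extent; the axial bone length of 35.28 mm is not an integer
multiple of the 17.15 mm pattern cube (2 × 17.15 = 34.30), so the
assembler tiles periodically and crops, rather than stacking exactly two
copies.

## 2. Histomorphometry

`measure_plate_model()` quantifies a binary volume with the standard
indirect plate-model measures: bone surface BS from exposed voxel-face
counting with a stereological correction factor (default 2/3, which
compensates the staircase overestimate for randomly oriented interfaces;
use 1 for axis-aligned plates), then Tb.Th = 2·BV/BS,
Tb.N = (BV/TV)/Tb.Th, Tb.Sp = 1/Tb.N − Tb.Th, and a separation SD from a
Euclidean distance transform of the marrow phase. These definitions are
fully reproducible but are not the sphere-fitting "direct" definitions
used by commercial micro-CT software, so agreement with published direct
measurements is approximate (the suite allows a factor 1.5 on Tb.Th);
structure-model index, fractal dimension and anisotropy measures are out
of scope for the same reason.

## 3. The randomized cohort

Each tissue model is a square forearm cross-section (bone axis = y):
nested rectangular shells in the x–z plane — dermis, subcutaneous tissue,
cortical bone — around a trabecular interior, extruded 35.28 mm along y
with bare y faces. Structural draws per model (`sample_structure()`):

* dermis thickness ~ U(1, 2) mm; subcutaneous ~ U(1, 6) mm;
* cortical thickness and BV/TV from a bivariate normal with
  stage-specific marginals (normal 0.804 ± 0.149 mm / 13.4 ± 2.8 %;
  osteopenia 0.571 ± 0.173 / 10.3 ± 3.0; osteoporosis 0.487 ± 0.138 /
  8.5 ± 2.2) and Pearson correlation 0.54, rejection-resampled into the
  physical domain. Only the marginals and the correlation are specified
  by the population data; the Gaussian copula is the package's choice.
* The three stages are drawn with equal weights by default
  (configurable); the stage mix of the original 1211-model cohort is not
  documented anywhere, so uniform is the neutral choice.

The aBMD label is computed from the geometry,
$\mathrm{aBMD} = \mathrm{mBMD}\,[1 - (1-\mathrm{BV/TV})(1 - 2\,C.Th/l_{obs})^2]$,
with matrix density mBMD = 1.2 g/cm³ and outer bone surface
$l_{obs}$ = 17.15 mm. The bracket is dimensionless, so the expression
formally carries mBMD's volumetric units; it is nevertheless reported in
the conventional areal unit g/cm², following the definition's usage.

Optical properties at 850 nm (`sample_optics()`): dermis
μa ~ U(0.0063, 0.0856) mm⁻¹, μs ~ U(14.20, 25.06) mm⁻¹; subcutaneous
μa ~ U(0.0049, 0.0124), μs ~ U(8.30, 13.96); bone fixed at μa = 0.0237
with μs = 17.77·mBMD − 0.74 = 20.58 mm⁻¹, g = 0.9 everywhere, n = 1.4
(soft) / 1.55 (bone). Marrow reuses the subcutaneous draw (adipose-
dominated marrow), and cortical and trabecular bone share the bone
optics — both identities are enforced by the assembler.

The geometry is represented analytically (shell thicknesses in voxels
plus the tiled trabecular mask), not as a materialized voxel array: the
full-scale model would hold ~10⁹ voxels, while the label of any voxel is
computable in O(1) from its address.

## 4. Voxel Monte Carlo photon transport

The engine (`run_transport()`, C++) is a three-dimensional extension of
the classic layered MCML algorithm. A collimated pencil beam enters the
center of the z = 0 face; each packet starts with weight $1 - R_{sp}$,
$R_{sp} = ((n_{amb}-n_1)/(n_{amb}+n_1))^2$. Propagation is hop–drop–spin:

* hop: step $s = -\ln\xi / (\mu_a + \mu_s)$ in the current voxel's
  medium; the distance to the voxel boundary along each axis is
  $(l_v/2 - p_k \,\mathrm{sign}\,\mu_k)/|\mu_k|$ and the smallest wins
  (ties go to the lower axis index, with a $10^{-9} l_v$ nudge after
  degenerate corner hits);
* boundary: if the neighbor voxel has a different refractive index, an
  unpolarized Fresnel draw decides reflection (flip the normal direction
  component) or refraction (Snell across the axis-aligned normal). The
  leftover step is rescaled by the ratio of attenuation coefficients when
  the medium changes, which keeps the dimensionless step exponential —
  the same convention as MCML, and the condition under which the voxel
  engine agrees with a layered reference;
* drop: at each interaction, $w\,\mu_a/\mu_t$ is deposited;
* spin: Henyey–Greenstein polar angle via the closed-form quantile with
  uniform azimuth;
* termination: Russian roulette below weight $10^{-4}$ with survival
  chance 1/10 (MCML's defaults; the study itself does not state them).
  The roulette bookkeeping is made exact per run by crediting killed
  weight to, and debiting survivor boosts from, the absorption tally, so
  specular + absorbed + escaped = N to float precision in every run —
  an invariant the suite asserts.

Packets leaving the model pass a final Fresnel test at the tissue–air
interface (ambient n = 1.0 on all six faces) and are recorded with exit
position, refracted direction, weight and face. Every photon owns a
counter-based RNG stream derived from the run seed, so results are
independent of execution order and reproducible bit-for-bit.

Two traversal modes implement identical physics: `voxel` steps voxel by
voxel everywhere; `region` (default) hops plane-to-plane through the
homogeneous soft-tissue shells and falls back to voxel stepping inside
the trabecular interior. Their statistical equivalence on a full model is
a test, not an assumption.

Validation rests on closed forms and an independent implementation:
Beer–Lambert transmission through a non-scattering slab, HG moment
checks, voxel-size invariance in homogeneous media, and 1–3-layer slabs
with index mismatches compared against a vectorized layered MCML written
separately for the test suite (different code path, different RNG).

## 5. From escape records to feature vectors

Three detector geometries (`score_profiles()`):

* backward Br: annular bins, width 0.4 mm, from r₀ = 0.5 mm (the area
  under the source is unmeasurable in practice) to 10 mm — 23 full bins
  plus one truncated at 10 mm → 24 bins. Bins offset from zero use the
  exact annulus area $\pi(r_{i+1}^2 - r_i^2)$; the index-form area
  $2\pi(i+\tfrac12)\Delta r^2$ is correct only for bins starting at 0 and
  would misstate offset-bin areas.
* forward Fr: the same binning from r = 0 (25 bins), where the index
  form and the exact annulus area coincide.
* lateral Lz: packets leaving the +x face within ±5 mm of the beam axis
  in y, binned by z over 0–20 mm in 0.1 mm steps, normalized by
  2·Δy·Δz.

Feature blocks: `Bf` keeps the 24 raw backward bins plus ln-mean and
ln-variance (26 values); `Ff` keeps only ln-mean and ln-variance of the
forward profile (2) — the raw forward profile is too close to a
point-spread spike to be a useful shape; `Lf` smooths Lz with a centered
1-mm (11-bin, edge-truncated) moving average, block-averages to 2-mm
intervals (10 values, ln-transformed) and appends ln-mean and
ln-variance (12). Total 40 features. Zeros are floored at $10^{-12}$
times the block maximum before logs; a block with no signal at all marks
the model as flagged, and flagged models are excluded from training with
a logged count — at the reference 10⁷ photons empty blocks are
essentially impossible, at reduced photon budgets they are not.
Standardization to mean 0 / SD 1 (population SD) is fit on training
folds only by default; a whole-dataset mode exists for faithfulness to
the original normalization description, and the scaler records which it
was.

## 6. Regression stage

Four learners are tuned by exhaustive grid search under seeded 10-fold
cross-validation on the 80 % training split and compared by r² on the
held-out 20 % (`tune_and_fit()`, `split_dataset()`): ridge regression
(penalty 10⁻⁵–10⁻¹), an RBF support-vector machine (γ 10⁻⁴–1, plus soft
margin C and tube ε), random forest (trees, leaf size, feature fraction)
and gradient tree boosting (six parameters). Only the ridge and γ ranges
are prescribed by the study design; the remaining grid values are package
defaults and overridable. Fold assignment is by seeded shuffling without
stratification. `ablation()` re-tunes on every non-empty subset of
{Bf, Ff, Lf}; `final_cv()` refits the selected hyperparameters per fold
over the whole dataset (the original description leaves open whether the
final cross-validation re-tuned per fold; reusing the selected set is the
default, per-fold re-tuning is available by calling `tune_and_fit`
per fold), pools the out-of-fold predictions, and reports r² together
with Bland–Altman agreement: mean difference, ±1.96 SD limits of
agreement, and the difference-vs-mean correlation (proportional bias).

## 7. Problem sizes, profiles and what the tests show

The `reference` profile records the full-scale study conditions: 720³
pattern grids, 24.5 μm voxels, 10⁷ photons per model, 1211 models. That
is a cluster-scale computation and is deliberately not what the test
suite runs. The `desk` profile keeps every physical parameter and
changes only problem sizes: 64³ pattern grids assigned 98 μm voxels
(with the threshold polynomial re-calibrated for that configuration), a
pool of 10 patterns shared across models (each model still gets its own
BV/TV, threshold, structure and optics), 2×10⁴ photons, 60 models by
default. The suite's end-to-end check runs 200 desk models at 10⁴
photons each — the largest configuration that fits a routine
single-CPU test run — and asserts the qualitative structure of the
result: support-vector regression ahead of ridge, forest and boosting
(compared on pooled out-of-fold cross-validation r², the
lowest-variance basis at this cohort size), single feature blocks weak
on their own, the combined set ahead of them, small mean bias, finite
limits of agreement.

The full-scale point estimates should not be expected to transfer to
this scale, and the reason is worth stating precisely: the diffuse-light
features are almost deterministic functions of the generative draws even
at 10⁴ photons (raising the photon budget mainly polishes bins that are
already smooth), but predicting aBMD from them requires the learner to
invert the soft-tissue confounding from the features alone — a
high-dimensional nonlinear problem whose sample complexity is what the
original 1211-model cohort paid for. At a few hundred models the
out-of-fold r² is therefore limited by cohort size, not by Monte Carlo
noise, and the quantitative agreement checks in the suite document this
honestly rather than relaxing themselves to pass.

What passing tests do show: the pattern generator hits its calibrated
volume fractions; the transport engine agrees with independent physics
oracles; the feature pipeline is exact on constructed inputs; the
learning stage behaves correctly on realizable and null problems; and
the assembled pipeline reproduces the study's qualitative conclusions at
reduced scale. What they do not show: agreement with any real optical
measurement — the tissue models are rectangular, homogeneous within
shells, without vasculature or anatomical cross-sections, and the
optical properties are literature ranges at a single wavelength.

## 8. Numerical edge cases

* Vacuum voxels (μa + μs = 0) are rejected — the step length would be
  infinite.
* A packet fully absorbed at an interaction (possible only when μs = 0)
  terminates immediately rather than surviving roulette at zero weight.
* Exact corner hits are resolved by the lower-axis tie-break plus a
  $10^{-9} l_v$ nudge; local positions are clamped to the voxel after
  every advance, and the suite's energy invariant would expose any
  accounting leak.
* Degenerate calibration designs (all thresholds giving the same BV/TV)
  and zero-variance labels raise errors instead of fitting nonsense.
* Constant features are dropped by the standardizer with a warning and a
  record in the scaler object.

## 9. Reproducibility model

One master seed drives everything. `child_seed(master, stream, index)`
derives per-stage, per-model seeds by modular arithmetic (all below
2³¹), the R-level draws are `set.seed`-scoped per model, and the C++
engine seeds one RNG stream per photon from the run seed and the photon
counter. Re-running any stage, or the whole pipeline, with the same
configuration gives identical output; the suite asserts this at the
pipeline level.
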