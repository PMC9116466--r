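# osteosim

Simulation test bench for **optical bone densitometry**: can areal bone
mineral density (aBMD, g/cm²) of the ultradistal radius be predicted from
spatially resolved diffuse near-infrared light, robustly against
person-to-person variation in the soft tissue around the bone?

The package answers the question in silico, end to end:

1. **Trabecular bone generator** — a Turing activator–inhibitor
   reaction–diffusion system
   (∂u/∂t = 0.6u − v − u³ + dᵤΔu, ∂v/∂t = 1.5u − 2v + dᵥΔv;
   dᵤ = 2·10⁻⁴, dᵥ = 10⁻²) solved with a semi-implicit Fourier spectral
   scheme on a periodic grid produces labyrinthine activator patterns;
   thresholding at the calibrated cubic
   u_th = −7.662x³ + 1.645x² − 0.452x + 0.604 (x = BV/TV) yields binary
   trabecular volumes with a prescribed bone volume fraction.
2. **Randomized cohort** — layered square forearm cross-sections
   (dermis | subcutaneous | cortical | trabecular/marrow) with uniform
   soft-tissue thickness and optics draws, stage-specific correlated
   (C.Th, BV/TV) draws (r = 0.54), and the geometric label
   aBMD = mBMD·[1 − (1 − BV/TV)(1 − 2·C.Th/l_obs)²].
3. **Voxel Monte Carlo engine** (C++) — MCML-style hop–drop–spin photon
   packet transport on the voxel grid: exponential steps, Fresnel
   reflection/refraction at refractive-index mismatches,
   Henyey–Greenstein scattering (g = 0.9), Russian roulette, exact
   per-run energy accounting, per-photon counter-based RNG streams.
4. **Diffuse-light features** — backward and forward radial profiles
   (Δr = 0.4 mm to 10 mm; backward starts at r₀ = 0.5 mm) and a lateral
   axial profile (Δz = 0.1 mm to 20 mm, ±5 mm effective width), reduced
   to the 40-element feature vector [Bf | Ff | Lf] with log-moment
   summaries and mean-0/SD-1 standardization.
5. **Regression** — ridge, RBF support-vector, random-forest and
   gradient-boosted models tuned by grid search under seeded 10-fold
   cross-validation, a feature-block ablation, and a final
   cross-validation with Bland–Altman agreement statistics.

## Worked example

One tissue model from draw to diffuse-light features (desk-scale sizes:
128³ pattern, 98 μm voxels, 2·10⁴ photons — seconds to a few minutes on
a laptop):

```r
library(osteosim)
set.seed(7)
p  <- sample_structure("osteopenia")   # thicknesses, C.Th, BV/TV
op <- sample_optics()                  # per-tissue mu_a, mu_s, g, n
compute_abmd(p)
#> [1] 0.1724133

u   <- solve_rd(rd_params(shape = c(128, 128, 128), seed = 1))
vol <- binarize(u, uth_from_bvtv(p$bvtv), voxel_size = 0.098)
vol
#> Trabecular volume 128x128x128 voxels, voxel 0.098 mm, BV/TV = 0.071

model <- assemble(p, op, vol)
model
#> Tissue model (radius): 275x360x275 voxels at 0.098 mm (26.9 x 35.3 x 26.9 mm)
#>   aBMD label 0.1724 g/cm^2

run <- run_transport(model, sim_config(n_photons = 2e4, seed = 11))
run
#> Monte Carlo run: N = 20000, specular 555.6, absorbed 7629, escaped 1.182e+04
#> z_min z_max x_max x_min y_min y_max
#> 17016   312   839   834   512   470

fv <- build_features(score_profiles(run), profile_spec())
round(fv[c("Bf_00", "Bf_lnm", "Ff_lnm", "Lf_lnm")], 4)
#>   Bf_00  Bf_lnm  Ff_lnm  Lf_lnm
#>  0.0636 -5.1927 -13.5255 -11.3274
```

Reading: this osteopenic model (BV/TV 6.6 %, cortical shell 0.36 mm,
aBMD label 0.172 g/cm²) reflects 85 % of the launched packet weight back
through the entry face, transmits a small forward fraction and leaks
measurable light laterally; the feature vector condenses those three
distributions into the 40 numbers the regressors consume. The full
cohort-scale study is one call, `run_pipeline(pipeline_config("desk"))`,
whose summary carries per-algorithm r², the feature-block ablation and
Bland–Altman agreement statistics.

The histomorphometry of a generated pattern at the reference 24.5 μm
voxel, thresholded at the normal-stage target:

```r
vol <- binarize(u, uth_from_bvtv(0.134))
measure_bvtv(vol)
#> [1] 0.1340432
measure_plate_model(vol)
#> BV/TV 13.4%  BS/BV 49.96 mm^-1  Tb.Th 40 um  Tb.N 3.35 mm^-1  Tb.Sp 259 um (SD 55)
```

(Plate-model definitions; direct sphere-fitting measures used by
commercial micro-CT software run systematically larger — see the
methods vignette.)

A thin command-line front end for shell use lives at
`inst/cli/osteosim.R` (`rd-generate`, `rd-calibrate`, `morphometry`,
`cohort`, `all`).

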