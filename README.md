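# dbtgan

Desk-scale R toolkit for **digital breast tomosynthesis (DBT)
pre-reconstruction processing**: it simulates limited-angle DBT acquisitions
on synthetic breast phantoms, translates low-dose ("object") projections
into the reference-dose domain with an unpaired cycle-consistent GAN whose
generator is an attention-gated, squeeze-and-excitation residual U-Net
(**rSEAG**), reconstructs slices by shift-and-add filtered backprojection
with the Ramachandran–Lakshminarayanan ramp kernel, and quantifies image
quality on the in-focus plane with three no-reference instruments: a
PIQE-style block-distortion score, GLCM texture features (homogeneity,
contrast), and a Gumbel extreme-value statistic of streak artifacts.

It is aimed at medical-imaging researchers who want to study the *machinery*
of GAN-based projection-domain denoising — losses, attention mechanisms,
reconstruction adjointness, artifact statistics — reproducibly on a laptop,
without clinical data.

## The method in brief

**Acquisition.** 15 projections over a 15° arc (configurable). The forward
model is a shear line-sum: a plane at height $z$ projects with lateral
parallax $s(\theta, z) = (z - z_c)\tan\theta / p$ pixels, so shift-and-add
backprojection is the *exact adjoint* of projection. Poisson noise enters
through Beer–Lambert photon statistics, and each projection carries detector
dose indices $\mathrm{EI}$ and $\mathrm{DI} = 10\log_{10}(\mathrm{EI}/\mathrm{EI}_t)$;
low-dose sets have negative DI.

**Translation.** Two generator/discriminator pairs are trained on unpaired
128×128 patch pools with the LSGAN adversarial loss, L1 cycle-consistency
loss and an SSIM fidelity loss ($1 - \mathrm{SSIM}$), optimised by Adam
(lr $10^{-4}$, $\beta_1 = 0.5$, $\beta_2 = 0.999$, minibatch 16). The rSEAG
generator augments a residual U-Net with a squeeze-and-excitation block on
the bridge and an additive attention gate on each skip:
$f = \mathrm{ReLU}(W_y y + W_\omega \omega)$,
$\beta = \sigma(\psi f) \in (0,1)$, skip replaced by $y \odot \beta$.
The optimal epoch is the minimum of a held-out validation-MSE curve. The
whole network stack (forward and backward passes) is implemented in the
package with C++ convolution kernels and is finite-difference-verified.

**Evaluation.** PIQE classifies 16×16 MSCN blocks as undistorted / artifact
/ noise and scores $100\,\Sigma D_k/(N+1)$ (lower = better); GLCM homogeneity
$\sum T(i,j)/(1+|i-j|)$ and contrast $\sum (i-j)^2 T(i,j)$ over a 256-level,
8-neighbourhood co-occurrence matrix; the Gumbel statistic fits sorted
per-profile maximal adjacent variations against the reduced variate
$-\ln(-\ln Q)$ with plotting positions $Q = (\partial - 0.5)/l$, reporting
location, scale, Pearson linearity and the mean maximum ± standard error.

## Worked example

Simulate one dense phantom at two dose levels, reconstruct, and compare the
in-focus planes:

```r
library(dbtgan)

geom <- acquisition_geometry(n_projections = 5L, detector_shape = c(64L, 128L),
                             pixel_pitch = 0.5)
phantom <- make_phantom(c(64L, 128L, 8L), "dense", n_masses = 1L, n_mcs = 2L,
                        seed = 1L, voxel_size = 2)
low  <- simulate_acquisition(phantom, geom, dose_level = 400,  seed = 1L)
high <- simulate_acquisition(phantom, geom, dose_level = 8000, seed = 2L)
low
#> Projection set: 5 projections of 64 x 128 (object domain), mean EI 222.6, mean DI -6.53
high
#> Projection set: 5 projections of 64 x 128 (reference domain), mean EI 4452.3, mean DI +6.49

vol_low  <- backproject(low,  plane_heights = seq(1, 15, by = 2))
vol_high <- backproject(high, plane_heights = seq(1, 15, by = 2))
cfg <- pipeline_config(list(output_dir = tempfile(),
                            metrics = list(gumbel_origin = c(18L, 60L))))
rep <- run_evaluate(cfg, list(
  low_dose  = in_focus_plane(vol_low, 8),
  high_dose = in_focus_plane(vol_high, 8)))
rep[, c("label", "piqe", "homogeneity", "contrast", "gumbel_mean_max")]
#>       label piqe homogeneity contrast gumbel_mean_max
#> 1  low_dose   97       0.192    165.0          0.0635
#> 2 high_dose    0       0.344     79.9          0.0389
```

The 20× dose reduction shows up in every instrument: the PIQE score jumps
(nearly all blocks noise-distorted), GLCM homogeneity drops and contrast
rises (more pixel-to-pixel variation), and the Gumbel mean maximal adjacent
variation — the streak/ripple magnitude — grows by ~60 %. Training the
translator on patch pools is one call
(`train_cyclegan(ref_patches, obj_patches, ...)`); full projections are then
processed with `translate_projection_set()` and reconstructed the same way.

## Scope

The phantom is structural (geometry, dose, artifacts), not anatomical;
reader studies, clinical diagnostic claims, cone-beam geometry, scatter and
detector-physics modelling are out of scope. See the methods vignette
(`vignettes/dbtgan-methods.Rmd`) for the full model description, parameter
defaults and limitations.
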