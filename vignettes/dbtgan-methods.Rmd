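---
title: "Methods: cycleGAN pre-reconstruction processing and quality evaluation for digital breast tomosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cycleGAN pre-reconstruction processing and quality evaluation for digital breast tomosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbtgan)
```

## Overview

Digital breast tomosynthesis (DBT) acquires a small number of low-dose
projections over a narrow arc (here 15 projections over 15 degrees) and
reconstructs quasi-3D slices by filtered backprojection (FBP). Because every
projection is taken at a fraction of a mammographic dose, the projections are
noisy, and the limited arc produces streak ("ripple") artifacts along the
X-ray sweep direction. `dbtgan` implements a *pre-reconstruction* denoising
strategy: an unpaired image-to-image translation network (a cycle-consistent
GAN) maps low-dose "object" projections into the distribution of
reference-dose projections *before* FBP, and a three-instrument evaluation
stack (PIQE block distortion, GLCM texture, Gumbel extreme-value statistics)
quantifies what the processing did to the reconstructed in-focus plane.

Clinical projections are not distributable, so the package also contains a
synthetic phantom and acquisition simulator that reproduces the *structure*
of such a study — two dose domains distinguished by detector dose indices,
breasts with and without masses, dense and non-dense — at desk scale. All
experiments in the package's tests run end-to-end on this simulator.

## The acquisition model

### Geometry and forward projection

The simulator uses a shear (shifted line-sum) forward model: for a tube angle
$\theta$ and a phantom plane at height $z$ above the detector, the plane's
content appears on the detector displaced along the sweep axis by

$$ s(\theta, z) = \frac{(z - z_c)\tan\theta}{p}, $$

in pixels, where $z_c$ is the rotation-centre height and $p$ the pixel pitch.
A projection is the sum of all planes shifted by their own parallax, weighted
by the slab thickness. For the $\pm 7.5^\circ$ arc of DBT this small-angle
approximation is standard, and it has a decisive structural advantage: the
sub-pixel shift operator (linear interpolation, zero fill) has an exact
transpose — the shift by $-s$ — so the shift-and-add backprojector is the
exact adjoint of the projector. The test suite verifies
$\langle A x, y\rangle = \langle x, A^{\mathsf T} y\rangle$ to $10^{-6}$
relative (in practice it holds to machine precision); the package's
`backproject()` output is the adjoint divided by
`n_projections * voxel_size`, i.e. a per-angle average, so that
backprojecting all-ones projections returns ones. Cone-beam geometry,
scatter, detector blur and compression-paddle effects are deliberately out of
scope.

### Phantom

`make_phantom()` builds a half-ellipsoidal compressed breast against the
chest-wall edge of the detector: an adipose background, fibroglandular
ellipsoidal inclusions grown until a target volume fraction is reached (40 %
for `"dense"`, 12 % for `"non_dense"` — values chosen once as representative
of heterogeneously dense vs scattered-density breasts), optional
soft-contrast mass lesions (attenuation 0.085/mm vs 0.080/mm for
fibroglandular tissue and 0.046/mm for adipose, roughly the 20 keV
ordering), and single-voxel microcalcifications at 0.6/mm. Masses are placed
with enforced pairwise separation so that the number of connected mass
components equals the number requested — a property the tests verify with an
independent BFS component-labelling oracle. The phantom is *structural*, not
anatomically textured: it supports geometry, dose and artifact experiments,
not observer studies.

### Dose, noise and exposure indices

`simulate_acquisition()` converts each noiseless line-integral projection
$L$ to expected photon counts $N_0 e^{-L}$ (Beer–Lambert with `dose_level`
$= N_0$ photons per pixel), draws Poisson counts, and log-converts back to a
line-integral image. Each projection is stamped with an exposure index

$$ \mathrm{EI} = c \cdot \overline{\text{counts}}_{\text{breast}},\qquad
   \mathrm{DI} = 10 \log_{10}(\mathrm{EI}/\mathrm{EI}_t), $$

following the standard exposure-index convention, with the breast region
taken as pixels whose attenuation signal exceeds 1 % of the image maximum.
Low-dose acquisitions therefore get negative deviation indices, and a
projection set is labelled `"object"` when its mean EI falls below the
configured split (default $\mathrm{DI} < -5$). The absolute dose levels
(defaults 8000 vs 800 photons/pixel, a 10:1 ratio) are free parameters of the
simulator; only the two-domain structure and the DI sign convention are
meaningful. Tests confirm that a 10:1 dose ratio produces a 10:1 EI ratio
within Poisson error and that count variance matches the Poisson mean within
5 % pooled over $10^4$ pixels.

## Preprocessing

`normalize_image()` standardises an image with its *population* standard
deviation and then maps it affinely onto a fixed range:

$$ I_{\text{temp}} = \frac{I - \bar I}{\sigma}, \qquad
   I_{\text{norm}} = 1 + \frac{I_{\text{temp}} - \min I_{\text{temp}}}
                              {\max I_{\text{temp}} - \min I_{\text{temp}}}. $$

The second stage as written lands exactly on $[1, 2]$; a `"zero_one"` mode
drops the unit offset and lands on $[0, 1]$. Both are available because the
two conventions differ only by that offset; the pipeline trains on the
$[0, 1]$ form (whose SSIM dynamic range is 1). Constant images are rejected
as degenerate.

`extract_patches()` draws a fixed number of fully-interior 128×128 windows
per projection with uniform-random origins from R's Mersenne-Twister stream
(documented so that origins are reproducible across platforms for a fixed
seed) and mirrors each patch horizontally with probability 0.5 — the
probability is a free choice where only "randomly selected and flipped" is
specified. Origins are sampled without any breast-mask exclusion. At study
scale the bookkeeping is: 45 cases × 15 projections = 675 projections per
dose domain, × 128 patches = 86,400 patch samples per domain, / 16 per
minibatch = 5,400 iterations per epoch; `dataset_bookkeeping()` computes
these from any configuration.

## Networks

### Generators

Three interchangeable generators share one I/O contract (one-channel image
in, same-size one-channel image out, linear final activation):

* **U-Net** — plain double-convolution encoder/decoder blocks;
* **ResUNet** — the same topology with residual blocks
  (conv–IN–ReLU–conv–IN plus a projected identity, ReLU on the sum);
* **rSEAG** — ResUNet plus a squeeze-and-excitation (SE) block after the
  bridge residual block and an additive attention gate (AG) on every skip
  connection.

The published architecture tables for the clinical networks are not
reproduced here; the package fixes its own defaults — depth 4, base 64
channels doubling per level, instance normalisation, strided-convolution
downsampling, nearest-neighbour-upsample + convolution decoding — all
configurable through `generator_spec()`, so deeper or wider variants drop
in. Tests run depth-2, 4–8-channel instances of the same graphs.

The **attention gate** computes, for skip features $y$ and a gating signal
$\omega$ (the decoder-side feature entering that skip's concatenation),

$$ f = \mathrm{ReLU}(W_y y + W_\omega \omega), \qquad
   \beta = \sigma(\psi f), $$

with $1{\times}1$ linear maps $W_y, W_\omega, \psi$, the gating signal
resampled to the skip grid by bilinear (trilinear across channels)
interpolation, and the skip rescaled pixelwise by $\beta \in (0,1)$ before
concatenation with the decoder feature. Concatenation (rather than
summation) follows standard attention-U-Net practice. The inter-channel
width defaults to half the skip channels. Because $\beta$ is a sigmoid
output it is strictly inside $(0,1)$, giving the strict attenuation bound
$|y \beta| \le |y|$ that the tests assert; with all-zero maps
$\beta \equiv \sigma(0) = 1/2$ exactly.

The **SE block** is the standard channel attention: global average pool,
bottleneck MLP (reduction ratio 16 by default, the original SE default) with
ReLU, sigmoid channel weights in $(0,1)$, channelwise rescale. It sits only
on the bridge.

The **discriminator** is a PatchGAN: stacked 4×4 convolutions (two stride-2
stages by default, then two stride-1 stages) with instance normalisation and
leaky ReLU, ending in a one-channel *spatial map* of realness scores — never
a scalar.

### Implementation note

No deep-learning framework is used: all layers (convolution, instance norm,
ReLU/leaky-ReLU/sigmoid, nearest upsampling, bilinear resize, SE, AG) carry
hand-written forward and reverse-mode backward passes, with the convolution
kernels in C++. Every backward pass is validated against central finite
differences in the test suite, for individual layers and through the full
rSEAG graph, and the SSIM loss gradient is derived in closed form and
checked the same way. Forward passes are deterministic given weights (there
is no dropout), and weight initialisation is He-normal from a seeded stream,
so networks are bit-reproducible per seed.

## Training

`train_cyclegan()` trains two generator/discriminator pairs on unpaired
pools (object→reference generator $G$, reference→object generator $F$) with

* **adversarial loss** — least-squares GAN form,
  $\mathbb{E}(D(\cdot) - t)^2$ with target 1 for real and 0 for fake (the
  cycleGAN default where only "adversarial loss" is named);
* **cycle-consistency loss** — L1 between a batch and its
  round-trip translation;
* **fidelity loss** — $1 - \mathrm{SSIM}$ (7×7 Gaussian window, standard
  constants $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$) between each translated
  patch and its *input*, encouraging structure preservation under unpaired
  translation.

Loss weights are unstated in the method being reproduced; the package
defaults to $\lambda_{\text{adv}} = 1$, $\lambda_{\text{cyc}} = 10$
(cycleGAN convention) and $\lambda_{\text{fid}} = 5$ (a mid-weight fidelity
term), all configurable. The optimiser is Adam with learning rate $10^{-4}$,
first/second moment decays 0.5 / 0.999, minibatch 16, no learning-rate
schedule (none is specified), and a 50-image history buffer for
discriminator updates (the classic cycleGAN stabilisation, configurable
off).

A held-out fraction (default 10 %) of the object pool never enters training;
after every epoch the validation MSE between those patches and their
translations $G(x)$ is recorded, and `select_optimal_epoch()` returns the
earliest minimum of that curve. Whether the original method computed its
per-epoch MSE at patch or projection level, and against which target, is
ambiguous; patch-level MSE against the input is the default here and
full-projection evaluation is available through `translate_projection_set()`
plus `mse()`.

Full-image inference tiles a projection into overlapping 128×128 patches and
blends the translated tiles with a 2-D raised-cosine window
(`translate_image()`); on constant input the blend is exact for any stride,
and an identity network round-trips the image bit-for-bit — both are tested.

### Problem sizes

The study-scale run (86,400 patches × 300 epochs) is a GPU-cluster workload
and is not reproduced. The package's training tests use the graphs at
reduced width: 200 patches of 32×32, depth-2 generators with 8 base
channels, 3 epochs, minibatch 16 — sizes chosen so the full suite exercises
every code path of the real architecture, and at which the two qualitative
training properties (total generator loss decreasing from epoch 1 to 3, and
identical-domain training moving $G$ towards the identity map) hold under
the pinned seeds. These are smoke-level checks of optimisation machinery,
not claims about denoising performance.

## Reconstruction

`ramlak_filter()` applies the ideal ramp $|f|$ (the
Ramachandran–Lakshminarayanan kernel) line-by-line along the sweep axis in
the frequency domain — the standard 1-D filtering for linear-motion
tomosynthesis. Lines are padded to at least twice their length by *edge
replication* before the FFT: this avoids circular wraparound while keeping
the filter linear, and it makes a constant line filter to exactly zero
(pure zero-padding would inject spurious edges at the line ends). No
apodisation is applied by default (the bare kernel is the reference); a
Hann window is available behind a flag. The discrete impulse response
reproduces the analytic kernel samples ($1/4$ at the centre, $-1/\pi^2$ at
odd offsets, $\approx 0$ at even offsets) and the implementation is checked
line-by-line against an explicit DFT-matrix oracle.

`backproject()` reconstructs planes at arbitrary heights (default spacing
1 mm — a free parameter, as no plane spacing is specified for the original
study) by shifting each (optionally filtered) projection by minus its
parallax and averaging. `in_focus_plane()` returns the slice nearest a
target height, resolving exact ties to the lower plane. For a point
phantom, the in-focus plane localises the point and its sweep-axis FWHM is
strictly smaller than on planes two or more spacings away.

## Quality evaluation

### PIQE-style block distortion

`piqe()` follows the canonical perception-based no-reference recipe: MSCN
coefficients $(I - \mu_{7\times7})/(\sigma_{7\times7} + 1)$ (Gaussian
window, edge-replicated borders), 16×16 block tiling, a spatial-activity
threshold of 0.1 on block MSCN variance, and classification of active
blocks as *distorted with artifact* (some length-6 segment along a block
edge is near-uniform — the blockiness signature) or *distorted with noise*
(block variance above 0.5). Because the stabilising constant 1 assumes an
8-bit scale, the image is min-max rescaled to 0–255 first. The score is
$100 \sum_k D_k / (N_{\text{dist}} + 1)$ with unit distortion per distorted
block, bounded in $[0, 100)$, lower is better. All thresholds are
arguments. Parity with any vendor implementation is *not* claimed: the
published algorithm summary leaves internals open, and this implementation
is the package's own, validated by its stated properties (bounded score,
strictly higher under added noise, noise blocks dominating on i.i.d. noise
input). On synthetic FBP reconstructions the absolute score is high — the
ramp filter's texture activates most blocks — so only comparisons between
processings of the same scene are meaningful, which is exactly how the
score is used.

### GLCM texture

`glcm()` quantises the image to 256 grey levels by linear min–max binning
(the float images here have no native integer scale), accumulates
co-occurrences over all 8 neighbour offsets, symmetrises and normalises to
sum 1. Homogeneity is $\sum T(i,j)/(1 + |i-j|)$ — the printed form of the
denominator omits the absolute value, but a signed difference would break
the matrix's symmetry and the stated "closeness to the diagonal" meaning,
so the standard $|i-j|$ is used. Contrast is $\sum (i-j)^2\, T(i,j)$. A
constant image gives homogeneity 1 and contrast 0; increasing i.i.d. noise
monotonically decreases homogeneity and increases contrast (tested over
three noise levels).

### Gumbel streak-artifact statistic

A rectangular window is placed on the in-focus plane near the breast
periphery, oriented so its profiles run along the sweep direction, "nearly
perpendicular" to the streaks. Each of the $l$ parallel single-pixel
profiles contributes its maximal adjacent pixel-value difference; the $l$
maxima are sorted and plotted against the symmetry-rank plotting positions
$Q_\partial = (\partial - 0.5)/l$ on the reduced variate
$u = -\ln(-\ln Q)$. A least-squares line $x = \mu + b u$ gives the Gumbel
location and scale; the Pearson correlation of the sorted maxima with $u$
measures linearity (Gumbel-ness), and the mean maximal variation ± standard
error ($s/\sqrt{l}$) is the headline artifact magnitude. The stated window
arithmetic (30 × 24 pixels yet 29 profiles of sampling size 29) is
internally inconsistent; this package takes profile length 30 along the
sweep and a configurable profile count defaulting to 29 so that $l = 29$,
with `extract_profiles()` exposing the raw 30 × 24 convention and
`gumbel_streak_statistic()` the $l = 29$ default. $l$ is always taken from
the actual profile count. Monte-Carlo tests confirm the fit recovers the
location of a true Gumbel sample within 10 % (mean over 500 replicates of
$l = 29$) with mean $r > 0.9$, and a paired low-dose vs high-dose
reconstruction experiment reproduces the intended ordering: more dose,
smaller maxima.

## Numerical choices and degenerate inputs

* Instance normalisation uses $\varepsilon = 10^{-5}$; a constant channel
  normalises to its bias.
* Sub-pixel shifts and bilinear resampling use linear interpolation with
  zero fill / edge clamping; their adjoints are implemented as exact
  transposes.
* `in_focus_plane()` ties resolve to the lower plane;
  `select_optimal_epoch()` ties resolve to the earliest epoch.
* Constant images are rejected by `normalize_image()` (zero variance), by
  `pearson_r()` (undefined correlation), and by `compute_dose_indices()`
  when no pixel clears the breast-region threshold.
* Photon counts of zero are clamped to 0.5 before the log conversion.
* The SSIM dynamic range defaults to the joint range of its inputs and is
  fixed to 1 inside training (patches live in $[0,1]$).

## What the synthetic experiments do and do not show

The simulator reproduces limited-angle geometry, Poisson dose dependence,
the two-domain EI/DI structure and FBP streaking, so tests of the
*machinery* — adjointness, filter response, metric behaviour, training
dynamics — transfer to real data. It does not reproduce anatomical texture,
scatter, detector physics or clinical artifact morphology, so no test here
certifies denoising quality on clinical projections, and the package makes
no diagnostic claims. Reproducing the clinical PIQE/GLCM/Gumbel values of
any particular study would require that study's patient images.

## Worked desk-scale example

```{r example, eval = FALSE}
cfg <- pipeline_config(list(
  output_dir = tempfile("dbtgan"),
  geometry = list(detector_shape = c(64L, 128L), pixel_pitch = 0.5,
                  n_projections = 5L),
  phantom = list(shape = c(64L, 128L, 8L), voxel_size = 2),
  dataset = list(n_train_cases = 2L, n_test_cases = 1L),
  metrics = list(gumbel_origin = c(18L, 60L))))

manifest <- run_simulate(cfg)                        # TIFF + JSON per domain
ps <- read_projection_set(manifest$path[manifest$domain == "object"][1])
vol <- run_reconstruct(cfg, ps)                      # Ram-Lak FBP
run_evaluate(cfg, list(no_processing = in_focus_plane(vol, 8)))
```
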