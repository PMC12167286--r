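---
title: "Semantic hyperspectral image synthesis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic hyperspectral image synthesis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intraoperative hyperspectral imaging (HSI) records a full reflectance
spectrum — here on the order of 100 bands between 500 and 1000 nm — at every
pixel of a surgical scene. Annotated surgical HSI datasets are scarce and
cannot be pooled with data from other optical modalities, because the
spectral dimension differs. What *is* transferable across modalities is
geometry: a semantic segmentation mask drawn on an RGB frame describes the
same organ layout an HSI camera would see. `hsisynth` implements a
mask-conditioned latent diffusion model (LDM) that converts such masks into
realistic labeled hyperspectral cubes, so that geometric annotations from
any modality can augment an HSI training set ("generative augmentation").

The package contains the full workflow — autoencoder, diffusion model,
guided sampler, mask augmentation, validation metrics and the downstream
three-arm experiment — plus a phantom generator that emulates the
statistical structure of surgical HSI data, so everything is exercisable
end-to-end without access to proprietary intraoperative recordings.

## Model overview

### Autoencoder

A KL-regularized variational autoencoder compresses cubes both spatially
(factor $f$) and spectrally ($C$ bands to $c_\mathrm{lat}$ channels). The
loss is a pixelwise reconstruction term plus a small KL penalty:

$$\mathcal{L}_{AE} = \frac{1}{n}\sum |x - \hat x| \;+\;
  \lambda_{KL} \cdot \tfrac{1}{2}\,\overline{(\mu^2 + \sigma^2 - 1 - \log\sigma^2)}$$

There is deliberately **no perceptual loss** (perceptual networks are not
defined for 25–100-band reflectance stacks) and **no adversarial loss**;
reconstruction quality alone drives training. The defaults are
$\lambda_{KL} = 10^{-6}$ (weak regularization measurably improves
reconstructions), L1 reconstruction, and a log-variance head clamped to
$[-30, 20]$ for numerical safety (the bounds are part of the contract and
are probed by tests).

The encoder is a *single strided convolution* (kernel $f$, stride $f$) onto
$2 c_\mathrm{lat}$ feature maps (posterior mean and log-variance); the
decoder is the mirrored transposed convolution. This is the smallest
architecture satisfying the "strided-convolution encoder, mirror decoder"
contract, and it is close to optimal on data whose pixel spectra lie near a
low-rank manifold spanned by a handful of class reference spectra — the
phantom data here, where a rank-$c_\mathrm{lat}$ linear map can already
approach the noise floor. On real tissue data a deeper nonlinear encoder
would be warranted; the training loop, loss and contracts would not change.

Training starts from a spectral initialization: the encoder/decoder pair is
set to the principal subspace of the training patches (deterministic
eigendecomposition) and Adam then refines it under the L1 + KL objective.
Beyond reliably reaching the reconstruction optimum, this matters
downstream: it hands the diffusion model a decorrelated, well-conditioned
latent basis, which proved decisive for the stability of strongly guided
sampling (below).

After AE training the global standard deviation of sampled training latents
is computed and its reciprocal stored as `scale_factor`; the diffusion
model operates on latents multiplied by this constant. Variance-preserving
diffusion assumes roughly unit-scale inputs, and an explicit recorded
constant keeps the convention auditable.

### Diffusion model

A standard variance-preserving diffusion process with $T$ steps and a
linear $\beta$ schedule ($10^{-4}$ to $2\times10^{-2}$; $T = 1000$ by
default, $T = 200$ in the desk-scale recipes) runs in the latent space:

$$z_t = \sqrt{\bar\alpha_t}\, z_0 + \sqrt{1 - \bar\alpha_t}\,\varepsilon,
  \qquad \bar\alpha_t = \prod_{s\le t}(1-\beta_s).$$

A small U-Net predicts the noise $\varepsilon$ from the channel
concatenation of $z_t$ and a **condition tensor**, with a sinusoidal
timestep embedding injected as per-channel biases. The condition tensor is
produced exactly once per image: the one-hot mask stack is rescaled to the
(padded) latent resolution with nearest-neighbor interpolation — labels
must never be interpolated — and passed through a single learned $1\times1$
convolution to `c_cond` channels. Latents whose spatial dims are not
multiples of $2^d$ (for $d$ U-Net downsamplings) are zero-padded
bottom/right and cropped after sampling; the pad/crop pair is an exact
identity.

Training minimizes the mean squared error between drawn and predicted
noise at uniformly sampled timesteps. With probability `p_drop` (default
0.1) a sample's condition tensor is replaced by the **null condition** — an
all-zeros tensor, not a learned embedding; the simplest contract consistent
with concatenation conditioning — so the same network also learns the
unconditional score needed for classifier-free guidance (CfG). The
learning rate decays geometrically to $0.1\times$ its initial value over
the run; the final (fully decayed) weights are used for sampling. The
depth of this decay matters far more than raw step count for guided-sample
quality (see the guidance note below). A weight EMA was evaluated during
development and discarded: with the decayed schedule it lags the converged
weights and measurably worsened guided samples on phantom data.

### Sampling

Deterministic DDIM (at $\eta = 0$) over a uniformly spaced sub-sequence of
timesteps including $T$ (default 100 steps; 50 in the desk recipes). Each
step makes two denoiser calls — conditioned and null-conditioned — and
combines them as

$$\hat\varepsilon = \varepsilon_u + \lambda_{CFG}\,(\varepsilon_c - \varepsilon_u)$$

with guidance scale $\lambda_{CFG} = 2$ by default ($\lambda = 1$
short-circuits to the conditional call alone, bit-exactly). The final
latent is divided by `scale_factor`, decoded, cropped and clipped at zero
to form a valid reflectance cube.

A practical note recorded from development: guidance with $\lambda > 1$
amplifies the *disagreement* between conditional and unconditional
predictions. Early in training the unconditional branch (which sees only
`p_drop` of the batches) lags behind, the disagreement stays large even at
low noise, and guided samples overshoot the class manifold — class-specific
absorption dips come out exaggerated. The effect disappears as both
branches converge; the deep learning-rate decay is what gets them there
reliably, and it improves guided samples far more than the (already flat)
loss curve suggests. Unguided samples do not show the effect, which makes
it easy to misattribute to the sampler rather than to training.

## The phantom generator

The phantom module emulates the statistical structure the method assumes,
not tissue optics:

* **Spectra.** Each class has a smooth reference spectrum: a linear
  baseline minus 1–3 Gaussian absorption dips at class-specific centers,
  clipped at a small positive floor. Classes are redrawn until all pairwise
  l1-normalized distances exceed 0.05, so classes remain spectrally
  decodable. Class 0 is the background cloth; the last class is an occluder
  material used only by occlusion variants.
* **Geometry.** Organs are random smooth blobs — ellipses with a low-order
  Fourier perturbation of the boundary radius — composited over background.
* **Hierarchy.** Each subject carries one log-normal multiplicative gain
  (σ = 0.15) shared by all of its images. This is the simplest mechanism
  that produces within-subject correlation, which is what the hierarchical
  (subject-first) aggregation and the subject-level bootstrap exist to
  respect.
* **Noise and illumination.** Per-voxel multiplicative noise
  (σ_m = 0.05), additive noise (σ_a = 0.01), and a linear illumination
  gradient of ±10% with random direction; values clipped at zero.
* **OoD variants.** `occlusion` overlays a multi-lobed ("hand") or
  elongated rectangular ("instrument") region of the occluder class;
  `isolation` keeps a single organ blob and fills the rest with background;
  `blur` convolves the cube with a Gaussian kernel (σ = 1.5 px).

No quantitative noise or illumination statistics of real intraoperative
data are published for the emulated device, so these parameters are
realistic-looking conventions, chosen once, not estimates. Consequently,
passing tests demonstrate that the *method* behaves as specified under a
controlled data-generating process — spectral recovery, guidance behavior,
augmentation benefit — and not that it would attain any particular accuracy
on real surgical recordings. Features of real data the phantom does not
emulate include specular highlights, spatial texture within organs,
camera-specific banding, and inter-organ spectral correlation.

## Metrics and statistics

* **Spectral agreement** (generated vs real): per image, the median
  l1-normalized pixel spectrum of a class; per subject, the mean over its
  images; across subjects, mean (and std). The report is the l1 distance
  between the two aggregated spectra. Normalization removes gain and
  illumination scale, so the comparison is about spectral *shape*.
* **DSC** and **NSD** per class, with NSD boundaries defined by
  8-connectivity, image-border region pixels counting as boundary, and
  exact Euclidean pixel distances; the tolerance τ defaults to 2 px at
  phantom scale. Both metrics are verified against exhaustive brute-force
  oracles. Records where a class is absent from prediction *and* ground
  truth are undefined and excluded — zero-filling would bias per-class
  means.
* **Hierarchical aggregation**: mean within subject, then mean across
  subjects, so subjects with many images do not dominate.
* **Bootstrap CIs on model differences**: subjects (not images) are
  resampled with replacement, jointly for both models; the percentile
  interval of the per-replicate difference of hierarchical aggregates is
  reported per class and pooled. Percentile rather than BCa because it is
  the simplest auditable choice; coverage is verified by simulation
  (nominal 95% within Monte-Carlo error at 20 subjects).
* **RGB previews** integrate reflectance over fixed windows (R 620–650,
  G 540–570, B 500–520 nm), jointly max-normalized, gamma 1/2.2. The
  sensor range starts at 500 nm, so there is no colorimetric blue; previews
  are for qualitative inspection only and are documented as
  non-colorimetric.

## Downstream experiment

Three segmentation models are trained with one shared seed list: *Baseline*
(real scenes only), *Synthetic* (as many synthetic scenes as Baseline has
real ones), and *Enhanced* (real plus all synthetic). Conditioning masks
pass through `reassign_ood_labels()` first: labels absent from the known
legend become background, mirroring how cross-modality masks with foreign
classes are handled. The package's toy segmenter is a small U-Net with two
downsamplings over all spectral bands; training excludes fill-label pixels
from the loss. Results are reported as hierarchically aggregated per-class
DSC/NSD per arm and test set, bootstrap CIs for Enhanced−Baseline and
Synthetic−Baseline, and the relative boost
$(\mathrm{Enhanced}-\mathrm{Baseline})/\mathrm{Baseline}$.

In the packaged experiment recipe the Baseline set is deliberately small
(4 subjects × 3 images): generative augmentation targets exactly the
data-starved regime, and a saturated baseline would leave no measurable
headroom at phantom scale.

## Problem sizes and numerical choices

The reference recipes used in the tests and the acceptance script are desk
scale by design: 32×32 scenes with 25 bands, 3 organ classes, 200 images
(20 subjects × 10); AE with $f = 2$, $c_\mathrm{lat} = 4$, 60 epochs;
diffusion with $T = 200$, a 16/32-channel U-Net, batch 8, 8000 steps with
the learning rate decayed to $0.1\times$; 50-step DDIM sampling at
$\lambda_{CFG} = 2$. These sizes were chosen so
the full pipeline trains on a single CPU core in minutes while leaving the
contracts identical to full camera scale (480×640×100, $f = 4$,
$c_\mathrm{lat} = 8$, $T = 1000$, 100 DDIM steps), which the shape tests
exercise directly.

Other fixed numerical conventions: pixel coordinates are 0-based,
row-major, origin top-left; ENVI I/O is BSQ float32 with nm wavelength
units (one canonical dialect, no silent unit drift); augmentation void
pixels are fill-labeled in the mask (always `max legend id + 1`) and black
in the cube; label dropout removes whole class regions rather than pixels,
keeping dropped masks plausible scene annotations; argmax ties in one-hot
decoding break toward the lower label id.

## Known limitations

* The hand-rolled neural-network core (im2col convolutions with manual
  backprop) is exact — gradients are finite-difference-verified — but not
  fast; training at full intraoperative-camera scale is out of scope.
* The linear autoencoder is matched to low-rank phantom spectra; real
  tissue requires a nonlinear encoder.
* Guidance scales well above 1 remain sensitive to unconditional-branch
  convergence (see above); the packaged recipes are sized to be past the
  unstable regime, but substantially shortened training will first degrade
  the guided (not the unguided) samples.
* The phantom's occluder and cloth spectra are synthetic conventions; OoD
  results quantify geometric transfer under the stated generator, nothing
  more.
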