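---
title: "Compensating visibility artefacts in linear-array photoacoustic imaging"
author: "pavision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compensating visibility artefacts in linear-array photoacoustic imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pavision)
```

## The visibility problem

Photoacoustic (PA) imaging with a conventional linear ultrasound array
suffers from two coupled artefacts. The *limited view*: a linear array only
collects wavefronts arriving within a narrow angular cone, so structures
elongated along the probe axis — whose coherent wavefronts propagate
sideways — are essentially invisible. The *limited bandwidth*: the
transducer is resonant and removes the low-frequency content of the PA
signal, so extended absorbers keep only their boundaries (their interiors
"hollow out"). Together these make the conventional delay-and-sum (DAS)
image of a vascular network show little more than its near-horizontal
segments and edges.

`pavision` implements a complete in-silico study of this problem and of a
learning-based correction:

1. a seeded generator of branching-vessel absorption maps,
2. a linear forward model producing element x time RF data,
3. DAS beamformers for the modulated (mBF) and demodulated (dmBF) images,
4. an L2-regularized FISTA inversion of the forward operator (baseline),
5. a modified U-Net trained to map mBF images to artefact-free images,
6. Monte-Carlo-dropout uncertainty maps and their calibration against the
   true error,
7. NCC / sSSIM evaluation and a transfer-learning study.

## Forward model

Every nonzero pixel of the absorption map acts as an acoustic point source.
Element $e$ at distance $r$ receives the system impulse response delayed by
$r/c$, scaled by the source amplitude, a 2D geometric decay $1/\sqrt{r}$,
and a soft $\cos\theta$ element directivity. The full RF set is the
superposition over pixels; this linearity is exact by construction and is
asserted to machine precision in the tests. The propagation matrix $A$ has
one column per grid pixel, equal to that pixel's vectorized RF response, so
$A\,\mathrm{vec}(X)$ reproduces the simulation exactly.

**Impulse response.** The true measured response of the physical probe is
not available, so the package synthesizes a Gabor pulse (Gaussian-envelope
sinusoid) at the 15.6 MHz centre frequency with a 60% fractional bandwidth
at -6 dB. The pulse is forced to exact zero mean — the missing DC is the
mechanism of the limited-bandwidth artefact — and normalized to unit peak.
The pulse is centred on the arrival time, so envelope peaks land exactly at
$t = r/c$; as a consequence "causality" in the tests means silence before
$r_{\min}/c$ minus the pulse half-duration.

**Sampling the continuum.** The discrete pixel sources only behave like a
continuous absorber if their spacing stays below half the acoustic
wavelength (about 48 µm at 15.6 MHz in water). Coarser rasters radiate
through grating lobes, which *artificially weakens* the limited-view
artefact: a vertical vessel sampled at 80 µm scatters toward the probe even
though the continuous vessel would not. Phantoms are therefore rasterized
at 40 µm for the acoustics, while the reconstruction and the network
operate on a coarser 80 µm grid (the ground-truth patch is mean-pooled by
the integer pitch ratio).

**Geometry.** The probe models a 128-element, 0.1 mm pitch high-frequency
linear array at the top of a water bath; the imaged field sits at a
10-20 mm standoff, as it does when a sample tank is coupled to the probe
through a membrane. The standoff matters: the angular half-aperture seen
from 15 mm depth is about 23 degrees, which is what makes vessels inclined
beyond roughly 30-45 degrees disappear. The same cross phantom that loses
over 95% of its vertical-bar energy under the linear array is recovered
with ratio about 1 under an omnidirectional ring aperture
(`visibilityDemo()`), tying the artefact to the acquisition geometry rather
than to the implementation.

**Noise.** Additive white Gaussian noise is calibrated so that the peak RF
amplitude of a horizontal reference bar at mid-depth divided by the noise
standard deviation equals the target amplitude SNR (default 60). Horizontal
structures are the natural reference because they are the fully visible
ones; the structures of interest produce far weaker signals than this
nominal figure suggests.

## Phantom generator

No generative model of the physical samples exists, so the package draws
recursive random binary trees of quadratic Bezier segments: trunks enter
from the field edges, segments either continue with small angular jitter or
bifurcate at 30 degrees (plus jitter), widths taper by level, and the
raster is anti-aliased. Defaults were chosen once for realism against the
imaged object class: vein widths span 0.12-0.48 mm (one to five acoustic
wavelengths, so that thick-vessel hollowing occurs), foreground coverage
lands in the 4-20% range, and orientations cover the circle. One primary
trunk per phantom is constrained to start within 10 degrees of vertical so
that every phantom genuinely exercises the limited-view mechanism; this is
asserted through a structure-tensor orientation histogram.

What the generator does *not* emulate: 3D structure projected to 2D (the
physical ground truth integrates absorption over the sample thickness),
fluence inhomogeneity, acoustic attenuation, and the irregular appendages
that manual sample preparation leaves behind. Passing tests therefore show
that the pipeline removes the *geometry-induced* artefacts under a correct
forward model; they do not certify performance on experimental data.

## Reconstruction

*mBF* is plain DAS on the real-valued RF signals (linear interpolation in
time, no apodization, no f-number, out-of-window delays contribute zero);
it is oscillatory because it is modulated by the impulse response. *dmBF*
is the modulus of DAS applied to the analytic (Hilbert-transformed)
signals — the conventional display image. The network consumes the mBF
image: its phase carries information that the envelope discards.

The FISTA baseline minimizes
$\tfrac12\lVert Y - AX\rVert_2^2 + \tfrac{\alpha}{2}\lVert X\rVert^2$
with step $1/L$ ($L$ from 50 power iterations), stopping at relative change
$10^{-6}$ or the iteration cap. Because the penalty is smooth this is
exactly accelerated gradient descent, and the minimizer has the ridge
closed form $(A^\top A + \alpha I)^{-1} A^\top Y$, which serves as the test
oracle. The regularization weight has no canonical value; `selectAlpha()` mirrors
the usual heuristic tuning by maximizing sSSIM against a held-out ground
truth. Deconvolution grids are kept at 64 x 64 so that $A$ (sparse, about
5M nonzeros) stays materializable.

## Network and training

The architecture is a standard U-Net encoder-decoder with skip
concatenations, with three modifications: batch normalization and
dropout in every scale block (conv3x3-BN-ReLU twice, then dropout), a
single-filter 1x1 output layer, and *no* final activation (the output is a
real-valued image, not a segmentation). The full-scale preset (4 levels,
base 64 filters) carries about 3.1e7 trainable parameters; the tests pin
this count as an architecture checksum. Desk-scale presets (base 16 at 64 px; depth 3 base
8 at 32 px) keep the same block structure.

Training uses the mean squared error and Adam at learning rate 5e-4 with
batches of 8 and $\beta_1 = 0.8$ (configurable; reference descriptions of
this training recipe give only an ambiguous "momentum" figure, and 0.8 is
the reading adopted here). Early stopping watches
the validation loss with patience 6-8 epochs and restores the
best-validation weights. Every mBF input is normalized by its maximum
absolute value before entering the network; targets are max-normalized at
dataset construction. All randomness (initialization, shuffling, dropout
masks) derives from explicit seeds, and training is bit-reproducible on a
fixed BLAS.

The engine itself (im2col convolutions on BLAS sgemm, batch-norm, inverted
dropout, 2x2 max pooling, stride-2 transposed convolutions, Adam) is
implemented in single-precision C++ inside the package and validated
against finite-difference gradients; note that under batch normalization a
convolution bias has exactly zero gradient (it is absorbed by the centring),
which the implementation exploits.

## Uncertainty

`mcDropoutPredict()` performs n = 20 stochastic forward passes with the
dropout layers active at the training rate (50%) and batch normalization in
inference mode, returning pixel-wise mean and standard deviation; mask
streams are seeded per pass. `noiseVariabilityMap()` instead keeps the
network deterministic and propagates repeated noisy acquisitions of one
object. The package quantifies the co-location of uncertainty and error —
usually assessed only visually — by (i) the Spearman rank
correlation between the std map and the absolute-error map over foreground
pixels, and (ii) the ratio of mean std inside the top |error| decile to the
bottom decile; the acceptance run requires this decile ratio to exceed 2.
The foreground mask (union of truth and prediction supports, dilated 2 px)
keeps background clutter from dominating the rank statistics.

## Metrics

*NCC* is the Pearson-normalized cross-correlation maximized over integer
displacements within ±3 px; the window absorbs sub-pixel registration
residue, and setting it to 0 recovers the zero-lag Pearson correlation.
The literature reference defines a correlation *map*; reducing it to one
number is a convention, flagged as such. *sSSIM* first fits the affine
intensity map $a\,\mathrm{pred} + b$ minimizing the squared error to the
truth, then computes mean SSIM (Gaussian 11 x 11 window, sigma 1.5,
standard stability constants, dynamic range from the truth). Several
scaled-SSIM variants circulate without a reproducible definition; this
least-squares scaled-and-shifted reading is the package's
operationalization.
`registerSimilarity()` recovers rotation/translation/scale by coarse grid
search with FFT translation estimation plus Nelder-Mead refinement, and is
validated by known-transform recovery to 0.5 px / 0.5 degree / 1% scale.

## Desk-scale studies and their sizes

The benchmark run trains the reduced U-Net (base 16, 64 x 64) on 300
training / 30 validation pairs for up to 25 epochs with early stopping and
evaluates 15 held-out pairs — the full-scale protocol uses 500/93/15 pairs
and the 3.1e7-parameter network, so the desk-scale absolute scores are
slightly conservative. The transfer-learning study uses the micro preset
(depth 3, base 8, 32 x 32): a domain shift is created by perturbing the
impulse response (+10% bandwidth, +5% centre frequency), adding SNR-60
noise, and synthesizing at 1480 m/s while beamforming assumes 1500 m/s.
The micro preset trains at learning rate 2e-3 (the 5e-4 default suits the
full-scale network; the micro network needs the larger step to converge
within the desk-scale epoch budget).
The "experimental" pool holds 255 pairs; training-set sizes
{10, 25, 50, 100, 200} are swept with 2 repeats per size (5 repeats at size
50 for the paired arm comparison), each repeat drawing a fresh random
subset with disjoint train/validation parts, all scored on one fixed
15-pair test set. The full-scale protocol sweeps 10-550 pairs with 30 repeats and pretrains
on 1400 simulated pairs; the desk default pretrains on 300.

## Numerical choices and degenerate inputs

Delay sampling uses linear interpolation; out-of-window delays contribute
zero rather than clamping (clamping paints edge streaks). Empty objects
simulate to zeros (or pure noise); zero RF beamforms to zero images.
Constant images make NCC and sSSIM undefined and raise errors rather than
returning NaN; constant uncertainty maps are reported as undefined with a
note. Division-free normalizations guard all max-normalizations of all-zero
images. FISTA's objective trace is monitored non-increasing up to the
method's known ripples.

## Known limitations

The forward model is 2D, homogeneous, and attenuation-free; directivity is
a smooth cosine rather than a measured element pattern; the ground truth is
exact (unlike a photographic projection of a 3D object), which is the main
reason purely simulated studies score higher than studies against physical
ground truths. The dmBF-vs-mBF input comparison and the transfer-learning direction
are verified at micro scale, where effect sizes are smaller than at full
scale. Serialization uses native R formats rather than HDF5 because no R
HDF5 binding is part of the package's dependency footprint.
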