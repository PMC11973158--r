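---
title: "Methods: complex-valued unrolled reconstruction for accelerated MR thermometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex-valued unrolled reconstruction for accelerated MR thermometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Proton-resonance-frequency (PRF) shift thermometry monitors tissue
temperature during hyperthermia by converting gradient-echo phase changes
into temperature changes. It needs *both* magnitude and phase images, at a
temporal resolution that fully sampled Cartesian acquisitions cannot
provide. Undersampling k-space accelerates the acquisition but violates the
Nyquist criterion, producing aliasing in the zero-filled reconstruction and
corrupting the phase on which thermometry depends.

`fourierpd` implements a complex-valued reconstruction chain for this
setting: retrospective variable-density Cartesian undersampling, unrolled
primal-dual networks built from complex convolutions, a k-space
data-consistency step, PRF temperature mapping and the evaluation metrics,
plus a synthetic heating-phantom generator so the whole chain is exercisable
without clinical data.

## Conventions

All 2D arrays are `(row, col) = (phase-encode, readout)`. The Fourier pair
`fft2c`/`ifft2c` is centred (DC at the 0-based index `rows %/% 2`) and
orthonormal, so Parseval holds exactly, the adjoint of the forward transform
is the inverse transform (which the hand-written backpropagation relies on),
and data-consistency identities can be asserted to `1e-10` rather than up to
a scale factor.

## Sampling masks

Two variable-density Cartesian patterns are provided.

* **1D Varden**: complete readout lines are sampled along the phase-encode
  direction; a block of 8 contiguous central lines is always acquired, and
  the remaining budget of `round(fraction * rows)` lines is drawn without
  replacement with probability proportional to a 1D normal density centred
  on DC. The density's scale is not dictated by the sampling scheme itself;
  we fix `sd = rows/6` so that roughly the central third of k-space
  dominates, a typical variable-density profile.
* **2D Varden**: a fully sampled central *disc* covering 2.5% of k-space
  (the `round(centre_fraction * N)` points nearest DC, ties broken by
  index), with the rest of the `round(fraction * N)` budget drawn without
  replacement from a 2D normal density (`sd = extent/6` per axis). The
  dense-centre shape is a free choice; a disc is isotropic in k-space and
  has no preferred axis.

Point budgets are exact (rounding half away from zero), asserted for every
generated mask. Weighted sampling without replacement uses the
exponential-race construction, which is distributionally identical to
sequential renormalised draws but `O(n log n)`. The theoretical acceleration
factor is defined as `1/fraction` (4 at 25%, 10 at 10%), independent of
grid-size rounding. One fixed mask is used per experiment; callers who want
per-slice mask redraws can simply generate masks with different seeds.

## Complex-valued network primitives

A complex convolution is four real convolutions,

    C_r = w_r * x_r - w_i * x_i
    C_i = w_i * x_r + w_r * x_i

implemented as an im2col patch matrix times a kernel matrix so the
arithmetic runs through BLAS; an equivalent stacked-real-matrix evaluation
path is kept for cross-checking. The training loss is the complex L1 loss,
the mean over all voxels of `|Re(err)| + |Im(err)|`. The per-sample mean is
folded into one mean over all voxels of all samples, which keeps the loss
scale independent of image resolution.

Choices the architecture family leaves open, fixed here once:

* **Activation**: split rectifier (CReLU) applied independently to real and
  imaginary parts — the standard choice in the complex-valued
  reconstruction lineage this package follows. Exposed as
  `complex_activation()`.
* **Initialisation**: independent real/imaginary Gaussian with per-component
  variance `1/(fan_in + fan_out)`, i.e. the Glorot scale halved per
  component so the complex magnitude matches the real-valued rule.
* **Bias**: complex (two real parameters per channel), on by default.

## The unrolled networks

Both models unroll `n_iterations` steps of a primal-dual scheme with
learned proximal operators. Each iteration concatenates the dual memory
(k-space, `n_dual` channels) with the FFT of the current primal estimate
(channel 2, following the learned primal-dual convention) and the measured
undersampled k-space, applies a complex fully-convolutional block, and adds
the result residually to the dual memory; then concatenates the primal
memory (image space, `n_primal` channels) with the inverse FFT of the first
dual channel and applies the primal block (fully convolutional in
Fourier-PDNet, a complex UNet in Fourier-PDUNet), again residually. The
primal memory is initialised with the zero-filled reconstruction replicated
across channels, the dual memory with zeros, and the output is the first
primal channel.

Returning the first primal channel (rather than appending a learned output
head) makes the network *exactly* the identity map onto the zero-filled
reconstruction when all weights are zero — a property the tests assert
bit-for-bit, and a useful guarantee: an untrained or deliberately zeroed
model composed with data consistency degrades gracefully to the
conventional baseline.

Architecture defaults (10 iterations, 5 primal / 5 dual channels, 32
filters, 3 conv layers per block, 3x3 kernels, UNet depth 3) follow the
primal-dual lineage; they are not claimed to be the exact values used in
any published experiment, and every one is overridable. The desk-scale
profile (`desk_model_config()`: 3 iterations, 8 filters, UNet depth 2) is
what the package's own CPU experiments and tests use.

The UNet primal block uses 2x2 average pooling and nearest-neighbour
upsampling: both are linear, so their adjoints (used in backpropagation)
are exact and cheap, and average pooling is well defined for complex
feature maps without ordering the complex numbers. Spatial sizes must be
divisible by `2^depth`; this is checked up front.

### Hand-written gradients

No automatic differentiation is available to this implementation, so the
backward pass is written by hand. The loss is real; for every complex
tensor the gradient is carried as the packing `dL/dRe + 1i * dL/dIm`.
Complex-linear operations then back-propagate through their conjugate
transpose (`Y = XW` gives `gX = gY W^H`, `gW = X^H gY`), the unitary FFT
through its inverse, and the split rectifier through its component masks.
Correctness is guarded by finite-difference gradient checks over random
parameter entries of both full architectures (tolerance `1e-4` on central
differences). One numerical caveat the tests respect: with zero-initialised
biases some pre-activations sit *exactly* on the rectifier kink and
finite differences straddle it, so gradient-check models use randomised
biases; the analytic gradients themselves use the standard one-sided
subgradient at 0.

## Training and inference

Training minimises the complex L1 loss between the *backbone* output and
the fully sampled target — data consistency is applied only at inference,
where `reconstruct()` replaces predicted k-space with the measured samples
at acquired locations (`k_out = mask * measured + (1 - mask) * fft(pred)`)
and inverse-transforms. The full-scale recipe is retained as
`train_config()`: 100 epochs, batch size 1, Adam (`lr = 1e-4` divided by 10
after every 50 epochs, `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-9`). Adam
treats each complex parameter as two real parameters (per-component second
moments), which is the standard way complex networks are optimised.

Each sample is normalised by the maximum magnitude of its zero-filled
reconstruction before entering the network and un-normalised afterwards.
Unrolled networks are scale-sensitive, the acquisitions this emulates have
arbitrary intensity scaling, and this particular scale is available at
inference time (it needs only the measured data). With a validation set,
the parameters with the best validation loss are kept.

### Desk-scale profile

The package's own experiments (acceptance tests, worked examples) run on
one CPU at deliberately small problem sizes, chosen as the desk-scale
study conditions:

* 64 x 64 phantoms; training set of 16 noiseless static phantoms (distinct
  seeds); one fixed 1D Varden 25% mask. The backbone is trained as a pure
  dealiasing operator against clean references; `make_training_set()` can
  also emit heated, noisy series frames (its general-purpose default,
  emulating thermometry acquisitions), which the unit tests exercise.
* Fourier-PDNet with 3 iterations and 8 filters;
* `desk_train_config()`: Adam at `lr = 1e-3`, 60 epochs over the 16
  samples = 960 optimiser steps, learning rate decayed by 10 after epoch
  50 (a short fine-tuning tail);
* evaluation on a held-out noiseless heated series (5 time points, Gaussian
  hotspot with `sigma = 6` px, 5 degC peak linear ramp) never seen in
  training, reconstructed with `reconstruct_series()` (one normalisation
  scale per series).

These sizes trade accuracy for runtime; the desk-scale claim being tested
is *ordering*, not absolute quality: the trained reconstruction should beat
the zero-filled baseline in magnitude SSIM and in the temperature-error
statistic. One caveat is intrinsic to these conditions and worth stating
precisely. The phantoms' background phase is a smooth low-order
polynomial, and the hotspot's spatial spectrum lies almost entirely within
the eight always-sampled centre lines. The zero-filled *phase difference*
between two frames acquired with the same mask then enjoys near-perfect
coherent artifact cancellation inside the hotspot ROI — zero-filling is
close to optimal there, even though its magnitude images are heavily
aliased. A learned nonlinear reconstruction responds slightly differently
to the reference and heated frames, and that frame inconsistency is of the
same order as the zero-filled ROI residual at this training scale: inside
the ROI the two methods sit at rough parity, and which one wins varies
with the random instantiation (phantom and mask seeds). The full-volume
temperature-error ordering (improvements of one to two orders of
magnitude) and the magnitude-SSIM ordering are the desk-scale claims that
hold robustly across seeds; the ROI ordering is asserted only at the fixed
study instantiation and should not be over-read. On clinical data the
situation differs — anatomical phase structure is damaged by undersampling
inside the tumour too, and acquisitions are noisy — so full-scale
ROI-restricted improvements are not contradicted by this desk-scale
behaviour.

## The phantom generator

The generator emulates single-channel complex gradient-echo acquisitions:

* **Magnitude**: a background ellipse plus `n_ellipses` random ellipses
  with random intensities, clamped to `[0, 1]` — piecewise-smooth like
  anatomy, in the spirit of the Shepp-Logan phantom.
* **Phase**: a random polynomial field of order 2 (default), scaled to lie
  within `(-pi, pi]`, emulating smooth coil/susceptibility background
  phase so phase reconstruction is non-trivial.
* **Heating**: a Gaussian hotspot whose peak ramps linearly over the time
  series (2–17 time points); frame t multiplies the reference by
  `exp(1i * gamma * alpha * B0 * TE * dT(v, t))`, the exact inverse of the
  PRF relation the thermometry module applies. Phases are *not*
  pre-unwrapped: large rises wrap, and handling that is the thermometry
  module's job.
* **Noise**: i.i.d. circular complex Gaussian in image space (equivalent
  to k-space Gaussian noise under the orthonormal FFT), parameterised as a
  fraction of peak magnitude.

What the phantoms do **not** emulate: B0 drift, motion, multi-coil
sensitivity profiles, tissue-dependent PRF coefficients, realistic sarcoma
anatomy, or scanner-specific intensity scaling. Passing the desk-scale
tests therefore demonstrates that the chain is implemented correctly and
that the qualitative reconstruction-beats-zero-filling ordering holds on
clean synthetic data — not that clinical accuracy is reproduced.

## Thermometry

The phase difference between reference and heated frames is computed on the
complex product, `atan2(Im(conj(ref) * heated), Re(conj(ref) * heated))`,
not by subtracting wrapped phase images: the product form only wraps when
the *true* difference leaves `(-pi, pi]`. A printed arctangent of a ratio
loses the quadrant; the four-quadrant form is what the complex construction
encodes. Voxels with zero magnitude in both images get 0 and a `FALSE`
entry in the `valid` attribute rather than NaN.

Temperature conversion divides by `gamma * alpha*1e-6 * B0 * TE` (rad/degC).
Defaults: proton `gamma = 2*pi*42.577e6` rad s^-1 T^-1, PRF coefficient
`alpha = -0.01` ppm/degC (the standard water value), `B0 = 1.5` T,
`TE = 19.1` ms — the longer of the two echo times of the acquisitions this
emulates; the generator and thermometry both parameterise TE rather than
fixing it, since either echo could feed thermometry in practice. The
reference frame is time point 1 of each series.

The temperature-error statistic is implemented exactly as its printed form,
`E_T = 100/(V*tau) * sum (dT_x - dT_y)^2` — a scaled mean of squared
differences, restricted to an ROI when one is supplied. Because reported
temperature accuracies in this field are often plain degC differences, a
clearly named RMS companion `temperature_rmse()` (degC) is also exposed;
neither is asserted to be what any particular published table used. The
hotspot ROI on synthetic data is the half-maximum disc of the injected
Gaussian (`scenario_roi()`).

## Metrics

* **SSIM**: local mode averages the statistic over all complete 7x7 uniform
  windows with unbiased covariance estimates, matching the common reference
  implementation to machine precision (cross-checked against an independent
  implementation in the tests); a global mode evaluates the literal
  whole-image formula, `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`.
* **NRMSE**: RMSE divided by the RMS of the reference (first argument);
  scale-invariant, not symmetric, and an explicit error on an identically
  zero reference.
* **UIQI**: computed globally from the printed moment formulas. The
  idiosyncratic `1/(M+N-1)` second-moment normaliser is reproduced in
  `"paper"` mode and the conventional `1/(MN-1)` in `"standard"` mode; the
  normaliser cancels algebraically in the three-factor product, so Q itself
  is identical in both modes (the tests assert this). Degenerate limits:
  two equal zero means give luminance similarity 1; exactly one constant
  image gives correlation 0; two constant images are an error.
* **Channels**: magnitudes are min-max scaled by the reference's range
  (same affine map applied to both images, L = 1); phases are mapped to
  `[0, 2*pi)` with `L = 2*pi`. These ranges are a package convention,
  documented rather than inherited.

## Numerical and degenerate-input policy

* Exact checks (mask budgets, data-consistency restoration, zero-weight
  identity) are asserted to `1e-10` or bit-for-bit; derivative checks to
  `1e-4`; oracle comparisons to `1e-6`–`1e-10` depending on conditioning.
* Ties in the 2D dense-centre selection are broken by linear index;
  mask generation is a pure function of its arguments (an internal
  seed-scoped RNG leaves the caller's RNG state untouched).
* Zero-magnitude voxels: flagged invalid in thermometry; excluded by
  construction nowhere else.
* A non-finite training loss aborts with the epoch/sample diagnostics
  rather than continuing silently.

## I/O and formats

Complex images travel as NIfTI magnitude/phase pairs with phase in float
radians (the native dialect); DICOM-style scaled-integer phase is converted
by an explicit declared-range linear map onto `[-pi, pi]` — dialects are
declared, never guessed, because vendor conventions differ. Masks are PNG +
JSON sidecar; heating series are per-timepoint NIfTI pairs + a JSON sidecar
with constants and scenario; measured k-space is a NIfTI real/imag pair +
sidecar (no single-channel raw standard exists for this). Every CLI
subcommand writes a manifest (arguments, seed, package version) so each
artifact is reproducible from its metadata.

## Known limitations

* Single-channel (coil-combined) data only; no parallel imaging, no
  radial/spiral trajectories, no partial Fourier.
* No B0-drift correction and no temperature-to-noise-ratio statistic.
* CPU-only training: the full-scale recipe is retained as configuration,
  but the package's own experiments run the desk-scale profile.
* The complex UNet uses average pooling / nearest upsampling rather than
  learned resampling; max-pooling has no canonical complex ordering.
* Phase-image quality metrics treat the wrapped phase map as an ordinary
  image on `[0, 2*pi)`; near-boundary phases can penalise metrics even for
  visually close images. This mirrors common practice and is documented
  rather than "fixed".
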