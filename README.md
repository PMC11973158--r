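# fourierpd

Complex-valued unrolled primal-dual reconstruction for accelerated
PRF-shift MR thermometry, in R.

## The problem

MR-guided hyperthermia heats tumour tissue to 39–44 °C and monitors the
temperature non-invasively with proton-resonance-frequency (PRF) shift
thermometry: the water proton frequency — and hence the gradient-echo
phase — depends linearly on temperature,

    ΔT = Δφ / (γ · α · B0 · TE),

with γ the gyromagnetic ratio, α ≈ −0.01 ppm/°C the PRF coefficient, B0
the field strength and TE the echo time. Thermometry therefore needs
*complex* (magnitude + phase) images, acquired fast. Undersampling k-space
accelerates the acquisition by a factor 1/f (f the sampled fraction) but
aliasses the zero-filled reconstruction and corrupts the phase.

`fourierpd` reconstructs undersampled single-channel Cartesian
acquisitions with unrolled primal-dual networks built from complex-valued
convolutions (`C_r = w_r⋆x_r − w_i⋆x_i`, `C_i = w_i⋆x_r + w_r⋆x_i`):
**Fourier-PDNet** (fully convolutional primal block) and
**Fourier-PDUNet** (complex UNet primal block). The networks alternate
between k-space (dual) and image-space (primal) residual blocks across
unrolled iterations; at inference a data-consistency step overwrites
predicted k-space with the measured samples, so the output agrees with the
acquisition exactly. Training minimises a complex L1 loss with Adam. The
package also provides variable-density Cartesian mask generation (1D/2D),
centred orthonormal FFTs, a synthetic heating-phantom generator, PRF
temperature mapping with a wrap-robust complex phase difference, the
temperature-error statistic `E_T`, and SSIM/NRMSE/UIQI image-quality
metrics — the full simulate → undersample → train → reconstruct →
thermometry → evaluate chain, on CPU, with hand-written gradients (no
autodiff dependency).

## Worked example

```r
library(fourierpd)

## a 64x64 complex gradient-echo phantom with a 5 degC Gaussian hotspot
constants <- thermo_constants()            # gamma, alpha=-0.01 ppm/degC, 1.5 T, TE=19.1 ms
phantom <- make_complex_phantom(phantom_config(grid_size = 64, seed = 1000))
scenario <- heating_scenario(hotspot_center = c(32, 36), hotspot_sigma = 6,
                             n_timepoints = 5, peak_delta_T = 5)
series <- simulate_heating_series(phantom, scenario, constants)

## 1D variable-density mask sampling 25% of k-space (acceleration 4)
mask <- make_varden1d_mask(64, fraction = 0.25, seed = 11)
theoretical_acceleration(mask)
#> [1] 4

## train a desk-scale Fourier-PDNet (3 iterations, 8 filters, 960 Adam steps)
dataset <- make_training_set(16, mask, grid_size = 64, noise_sd = 0,
                             seed = 101, heating = FALSE)
model <- init_recon_model(desk_model_config("fourier_pdnet"), seed = 1)
fit <- train_recon(model, dataset, desk_train_config(epochs = 60, seed = 1))

## reconstruct the held-out heated series and compare to zero-filling
mks <- lapply(series$frames, function(f) undersample(fft2c(f), mask))
rec <- reconstruct_series(fit$model, mks, mask)
zf  <- lapply(mks, zero_filled)
mean(sapply(1:5, function(t) eval_metric_pair(series$frames[[t]], rec[[t]])$ssim[1]))
#> [1] 0.6686    # magnitude SSIM, reconstruction
mean(sapply(1:5, function(t) eval_metric_pair(series$frames[[t]], zf[[t]])$ssim[1]))
#> [1] 0.6147    # magnitude SSIM, zero-filled

## temperature maps and the temperature-error statistic
tm_truth <- temperature_series(series$frames, constants)
temperature_error(tm_truth, temperature_series(zf, constants))    # E_T, zero-filled
#> [1] 3997.4
temperature_error(tm_truth, temperature_series(rec, constants))   # E_T, reconstruction
#> [1] 56.3
```

The SSIM numbers say the trained network recovers magnitude structure the
zero-filled baseline loses to aliasing; the `E_T` numbers (a scaled mean of
squared voxel-and-time temperature differences against the fully sampled
truth) show the reconstruction's temperature maps are far closer to the
truth over the full volume — here by almost two orders of magnitude.
`temperature_rmse()` reports the same comparison as a plain RMS difference
in °C. Numbers above were produced by this code with these seeds on the
desk profile (training takes ~10 minutes on one CPU).

## Command line

A thin CLI over the same functions lives at `inst/cli/fourierpd`:

```sh
fourierpd simulate --grid 64 --timepoints 5 --peak-dt 5 --seed 42 --out series/
fourierpd mask --kind varden1d --shape 64 --fraction 0.25 --seed 1 --out mask
fourierpd undersample --series series/ --mask mask --out us/meas
fourierpd train --mask mask --grid 64 --n-train 16 --epochs 60 --seed 1 --out ckpt/model
fourierpd reconstruct --ckpt ckpt/model --kspace us/meas --out rec/recon
fourierpd thermometry --series series/ --out thermo/t
fourierpd evaluate --truth series/ --pred rec/recon --out metrics.csv
```

Every subcommand writes a JSON manifest (arguments, seeds, version) next to
its outputs.

## Scope

Single-channel (coil-combined) Cartesian data only; no parallel imaging,
radial/spiral trajectories, B0-drift correction, or baseline ResNet
comparisons. See `vignettes/methods.Rmd` for the model, the design
decisions and their rationale, and known limitations.
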