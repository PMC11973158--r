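## Training (complex L1 loss, Adam with stepped learning-rate decay) and the
## inference-time k-space data-consistency step.

#' K-space data consistency
#'
#' Replaces the predicted k-space with the actually measured samples at every
#' acquired location: `k_out = mask * measured_k + (1 - mask) * fft2c(pred)`,
#' returned as `ifft2c(k_out)`. The network only fills the frequencies that
#' were never acquired, so the output agrees with the acquisition exactly (to
#' floating-point round-off) and the operation is idempotent.
#'
#' @param predicted complex image predicted by the network backbone.
#' @param measured_k zero-filled measured k-space (exact zeros off-mask).
#' @param mask the `sampling_mask` (or binary matrix).
#' @return Complex image after data consistency.
#' @export
data_consistency <- function(predicted, measured_k, mask) {
  g <- mask_grid(mask)
  predicted <- as_cplx_matrix(predicted)
  measured_k <- as_cplx_matrix(measured_k)
  stopifnot_same_shape(predicted, g, "prediction and mask")
  stopifnot_same_shape(measured_k, g, "measured k-space and mask")
  k_pred <- fft2c(predicted)
  ifft2c(g * measured_k + (1 - g) * k_pred)
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: 100 epochs, batch size 1, Adam
#' with initial learning rate 1e-4 decayed by a factor of 10 after every 50
#' epochs, beta1 = 0.9, beta2 = 0.999, eps = 1e-9. [desk_train_config()]
#' gives the CPU-scale profile used by the package's own experiments.
#'
#' @param epochs number of passes over the dataset.
#' @param batch_size samples per optimiser step (1, as in the full recipe;
#'   kept explicit for the record).
#' @param lr initial learning rate.
#' @param lr_decay_factor divide the learning rate by this factor...
#' @param lr_decay_every ...after every this many epochs.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param seed RNG seed controlling sample order (and any noise draws).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 1L, lr = 1e-4,
                         lr_decay_factor = 10, lr_decay_every = 50L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-9, seed = 1L) {
  if (any(c(epochs, batch_size, lr, lr_decay_factor, lr_decay_every,
            beta1, beta2, eps) <= 0)) {
    stop("all training hyperparameters must be positive")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  defaults <- list(epochs = 40L, lr = 1e-3, lr_decay_every = 20L, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

#' Learning rate at a given epoch
#'
#' Stepped schedule: `lr / lr_decay_factor^floor((epoch - 1) / lr_decay_every)`.
#' Under the full-scale recipe the rate is 1e-4 for epochs 1-50, 1e-5 for
#' 51-100, 1e-6 from epoch 101.
#'
#' @param config a [train_config()].
#' @param epoch epoch number (1-based).
#' @return The learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr / config$lr_decay_factor^floor((epoch - 1) / config$lr_decay_every)
}

#' Measured training sample
#'
#' Retrospectively undersamples a fully sampled complex image: the target is
#' the image itself, the measurement its masked k-space.
#'
#' @param target fully sampled complex image (ground truth).
#' @param mask a `sampling_mask`.
#' @return List with `measured_k` (zero-filled k-space), `mask`, `target`.
#' @export
measured_sample <- function(target, mask) {
  target <- as_cplx_matrix(target)
  measured_k <- undersample(fft2c(target), mask)
  structure(list(measured_k = measured_k, mask = mask, target = target),
            class = "measured_sample")
}

#' Build a phantom training set
#'
#' Generates phantoms (consecutive seeds starting at `seed`) and pairs each
#' frame with its retrospectively undersampled k-space under one fixed mask,
#' matching the retrospective-undersampling design. With `heating = TRUE`
#' (the default) each phantom contributes two frames of a simulated heating
#' series -- the unheated reference and a heated frame with a randomised
#' hotspot -- emulating the thermometry acquisitions the method is meant
#' for; with `heating = FALSE`, `n` static phantoms are used instead.
#'
#' @param n total number of samples (with heating, `n/2` phantoms times two
#'   frames; `n` must then be even).
#' @param mask the fixed `sampling_mask` shared by all samples.
#' @param grid_size phantom side length.
#' @param noise_sd phantom noise level (fraction of peak magnitude).
#' @param seed first phantom seed (also drives the hotspot randomisation).
#' @param heating include PRF-heated frames (see above).
#' @param constants [thermo_constants()] used for the heated frames.
#' @return List of [measured_sample()]s.
#' @export
make_training_set <- function(n, mask, grid_size = 64L, noise_sd = 0.01,
                              seed = 100L, heating = TRUE,
                              constants = thermo_constants()) {
  if (!heating) {
    return(lapply(seq_len(n), function(i) {
      ph <- make_complex_phantom(phantom_config(grid_size = grid_size,
                                                noise_sd = noise_sd,
                                                seed = seed + i - 1L))
      measured_sample(ph, mask)
    }))
  }
  if (n %% 2 != 0) stop("with heating, n must be even (two frames per phantom)")
  samples <- vector("list", n)
  for (i in seq_len(n / 2)) {
    # noiseless phantom; per-frame independent noise is added after heating,
    # as in an acquired time series
    ph <- make_complex_phantom(phantom_config(grid_size = grid_size,
                                              noise_sd = 0,
                                              seed = seed + i - 1L))
    frames <- with_seed(seed + 1000L + i, {
      scen <- heating_scenario(
        hotspot_center = round(stats::runif(2, 0.3, 0.7) * grid_size),
        hotspot_sigma = stats::runif(1, grid_size / 12, grid_size / 7),
        n_timepoints = 2,
        delta_T_peak_per_tp = c(0, stats::runif(1, 2, 8)))
      series <- simulate_heating_series(ph, scen, constants)
      s <- noise_sd * max(Mod(unclass(ph)))
      lapply(series$frames, function(f) {
        if (s > 0) add_complex_noise(f, s) else unclass(f)
      })
    })
    samples[[2 * i - 1]] <- measured_sample(frames[[1]], mask)
    samples[[2 * i]] <- measured_sample(frames[[2]], mask)
  }
  samples
}

## --- Adam on complex parameter trees -------------------------------------
## First moments live on the complex numbers; second moments are kept per
## real component (packed as a complex array: Re = v_r, Im = v_i), so the
## update is exactly real-valued Adam applied to the 2N real parameters.

adam_init <- function(params) {
  list(m = tree_map_leaves(params, function(x) x * 0),
       v = tree_map_leaves(params, function(x) x * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, b1, b2, eps) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m2 <- b1 * m + (1 - b1) * g
    vr <- b2 * Re(v) + (1 - b2) * Re(g)^2
    vi <- b2 * Im(v) + (1 - b2) * Im(g)^2
    mhat <- m2 / (1 - b1^t)
    vrh <- vr / (1 - b2^t); vih <- vi / (1 - b2^t)
    pr <- Re(p) - lr * Re(mhat) / (sqrt(vrh) + eps)
    pi <- Im(p) - lr * Im(mhat) / (sqrt(vih) + eps)
    pnew <- complex(real = pr, imaginary = pi)
    vnew <- complex(real = vr, imaginary = vi)
    dim(pnew) <- dim(p); dim(vnew) <- dim(v)
    list(p = pnew, m = m2, v = vnew)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

## per-sample max-magnitude normalisation scale, computed from the
## zero-filled reconstruction (available at inference time)
sample_scale <- function(measured_k) {
  s <- max(Mod(ifft2c(measured_k)))
  if (s == 0) 1 else s
}

#' Train an unrolled reconstruction model
#'
#' Optimises the complex L1 loss between the network backbone output and the
#' fully sampled target (no data consistency during training; the full
#' framework is used only at inference). Each sample is scaled by the max
#' magnitude of its zero-filled reconstruction before entering the network
#' (unrolled networks are scale-sensitive; the scale is known at inference
#' time too). Adam with the stepped learning-rate schedule of the config;
#' batch size 1. With a validation set, the parameters with the best
#' validation loss are returned; otherwise the final parameters.
#'
#' @param model a `recon_model` from [init_recon_model()].
#' @param dataset non-empty list of [measured_sample()]s.
#' @param config a [train_config()].
#' @param val_dataset optional validation list of [measured_sample()]s.
#' @param verbose print per-epoch losses.
#' @return List: `model` (trained), `loss_history` (per-epoch mean training
#'   loss), `val_history` (or `NULL`), `lr_history`.
#' @export
train_recon <- function(model, dataset, config = train_config(),
                        val_dataset = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("dataset must be non-empty")
  params <- model$iterations
  state <- adam_init(params)
  loss_hist <- numeric(config$epochs)
  val_hist <- if (!is.null(val_dataset)) numeric(config$epochs) else NULL
  lr_hist <- numeric(config$epochs)
  best_val <- Inf
  best_params <- params
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch)
      lr_hist[epoch] <- lr
      ord <- sample.int(length(dataset))
      losses <- numeric(length(ord))
      for (i in seq_along(ord)) {
        s <- dataset[[ord[i]]]
        sc <- sample_scale(s$measured_k)
        model$iterations <- params
        fw <- forward_recon(model, s$measured_k / sc, s$mask, training = TRUE)
        target <- s$target / sc
        loss <- complex_l1_loss(fw$out, target)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d, sample %d (lr=%g)",
                       epoch, ord[i], lr))
        }
        losses[i] <- loss
        gout <- complex_l1_grad(fw$out, target)
        grads <- backward_recon(model, fw$caches, gout)
        au <- adam_update(params, grads, state, lr,
                          config$beta1, config$beta2, config$eps)
        params <- au$params
        state <- au$state
      }
      loss_hist[epoch] <- mean(losses)
      if (!is.null(val_dataset)) {
        model$iterations <- params
        vl <- vapply(val_dataset, function(s) {
          sc <- sample_scale(s$measured_k)
          out <- forward_recon(model, s$measured_k / sc, s$mask)
          complex_l1_loss(out, s$target / sc)
        }, 0)
        val_hist[epoch] <- mean(vl)
        if (val_hist[epoch] < best_val) {
          best_val <- val_hist[epoch]
          best_params <- params
        }
      }
      if (verbose) {
        cat(sprintf("epoch %3d  lr %.2g  train %.5f%s\n", epoch, lr,
                    loss_hist[epoch],
                    if (!is.null(val_hist)) sprintf("  val %.5f", val_hist[epoch]) else ""))
      }
    }
  })
  model$iterations <- if (!is.null(val_dataset)) best_params else params
  list(model = model, loss_history = loss_hist, val_history = val_hist,
       lr_history = lr_hist)
}

#' Reconstruct a complex image from measured k-space
#'
#' The full inference framework: network backbone forward pass on the
#' (normalised) zero-filled measurement, followed by the k-space
#' data-consistency step. Acquired k-space locations of the output match the
#' measured data exactly.
#'
#' @param model a trained `recon_model`.
#' @param measured_k zero-filled measured k-space.
#' @param mask the acquisition `sampling_mask`.
#' @return A [complex_image()].
#' @export
reconstruct <- function(model, measured_k, mask) {
  measured_k <- as_cplx_matrix(measured_k)
  sc <- sample_scale(measured_k)
  out <- forward_recon(model, measured_k / sc, mask) * sc
  complex_image(data_consistency(out, measured_k, mask))
}

#' Reconstruct a dynamic series with a common normalisation scale
#'
#' Thermometry works on phase differences between frames of one
#' acquisition, so the whole series is reconstructed with a single
#' normalisation scale taken from the reference frame's zero-filled
#' reconstruction (rather than one scale per frame). This keeps the network
#' input of every frame on the same footing and avoids injecting
#' frame-to-frame scale differences into the phase maps.
#'
#' @param model a trained `recon_model`.
#' @param measured_list list of zero-filled measured k-space matrices (time
#'   points; the first is the reference).
#' @param mask the acquisition `sampling_mask`.
#' @return List of [complex_image()] reconstructions.
#' @export
reconstruct_series <- function(model, measured_list, mask) {
  if (length(measured_list) == 0) stop("empty series")
  sc <- sample_scale(as_cplx_matrix(measured_list[[1]]))
  lapply(measured_list, function(mk) {
    mk <- as_cplx_matrix(mk)
    out <- forward_recon(model, mk / sc, mask) * sc
    complex_image(data_consistency(out, mk, mask))
  })
}

#' Zero-filled reconstruction
#'
#' The conventional baseline: inverse FFT of the zero-filled measured
#' k-space.
#'
#' @param measured_k zero-filled measured k-space.
#' @return A [complex_image()].
#' @export
zero_filled <- function(measured_k) {
  complex_image(ifft2c(measured_k))
}
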