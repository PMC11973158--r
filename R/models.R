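## Unrolled primal-dual reconstruction networks.
##
## Both variants alternate, for n_iterations unrolled steps, between a dual
## block operating in k-space (input: dual memory, the FFT of the current
## primal estimate, and the measured undersampled k-space; residual update of
## the dual memory) and a primal block operating in image space (input:
## primal memory and the inverse FFT of the first dual channel; residual
## update of the primal memory). The primal block is a complex
## fully-convolutional block (Fourier-PDNet) or a complex UNet
## (Fourier-PDUNet); the dual block is always fully convolutional. The
## reconstruction is the first primal channel. Every block has its own
## weights (unrolled, not weight-tied).

#' Reconstruction model configuration
#'
#' @param variant `"fourier_pdnet"` (fully convolutional primal block) or
#'   `"fourier_pdunet"` (complex UNet primal block).
#' @param n_iterations number of unrolled primal/dual iterations.
#' @param n_primal,n_dual primal (image-space) and dual (k-space) memory
#'   channel counts.
#' @param n_filters convolution filters per hidden layer.
#' @param unet_depth pooling levels of the UNet primal block
#'   (`fourier_pdunet` only).
#' @param kernel_size convolution kernel side length.
#' @param n_conv_layers layers per fully-convolutional block.
#' @return A `recon_model_config` list.
#' @export
recon_model_config <- function(variant = c("fourier_pdnet", "fourier_pdunet"),
                               n_iterations = 10L, n_primal = 5L, n_dual = 5L,
                               n_filters = 32L, unet_depth = 3L,
                               kernel_size = 3L, n_conv_layers = 3L) {
  variant <- match.arg(variant)
  vals <- c(n_iterations, n_primal, n_dual, n_filters, kernel_size, n_conv_layers)
  if (any(vals < 1)) stop("all architecture sizes must be positive integers")
  if (variant == "fourier_pdunet" && unet_depth < 1) {
    stop("unet_depth must be >= 1 for fourier_pdunet")
  }
  structure(list(variant = variant, n_iterations = as.integer(n_iterations),
                 n_primal = as.integer(n_primal), n_dual = as.integer(n_dual),
                 n_filters = as.integer(n_filters),
                 unet_depth = as.integer(unet_depth),
                 kernel_size = as.integer(kernel_size),
                 n_conv_layers = as.integer(n_conv_layers)),
            class = "recon_model_config")
}

#' Desk-scale model configuration
#'
#' Shrunken architecture (3 iterations, 8 filters, UNet depth 2) for
#' CPU-scale experiments and tests.
#'
#' @inheritParams recon_model_config
#' @return A `recon_model_config`.
#' @export
desk_model_config <- function(variant = "fourier_pdnet") {
  recon_model_config(variant = variant, n_iterations = 3L, n_primal = 5L,
                     n_dual = 5L, n_filters = 8L, unet_depth = 2L)
}

new_layer <- function(kh, kw, cin, cout) {
  list(w = init_complex_kernel(kh, kw, cin, cout),
       b = complex(cout, real = 0, imaginary = 0))
}

## fully-convolutional complex block: cin -> f -> ... -> cout, split ReLU
## after every layer except (optionally) the last
conv_block_params <- function(cin, cout, f, n_layers, k) {
  chans <- if (n_layers == 1) c(cin, cout) else c(cin, rep(f, n_layers - 1), cout)
  lapply(seq_len(n_layers), function(j) new_layer(k, k, chans[j], chans[j + 1]))
}

unet_block_params <- function(cin, cout, k) {
  list(new_layer(k, k, cin, cout), new_layer(k, k, cout, cout))
}

unet_params <- function(cin, cout, f, depth, k) {
  enc <- vector("list", depth)
  ch <- cin
  for (l in seq_len(depth)) {
    fl <- f * 2^(l - 1)
    enc[[l]] <- unet_block_params(ch, fl, k)
    ch <- fl
  }
  bott <- unet_block_params(ch, f * 2^depth, k)
  dec <- vector("list", depth)
  up_ch <- f * 2^depth
  for (l in rev(seq_len(depth))) {
    fl <- f * 2^(l - 1)
    dec[[l]] <- unet_block_params(fl + up_ch, fl, k)
    up_ch <- fl
  }
  final <- new_layer(1L, 1L, f, cout)
  list(enc = enc, bottleneck = bott, dec = dec, final = final)
}

#' Initialise an unrolled reconstruction model
#'
#' @param config a [recon_model_config()].
#' @param seed RNG seed for the Glorot-style complex weight initialisation.
#' @return A `recon_model`: list with `config` and per-iteration `dual` /
#'   `primal` block parameters.
#' @export
init_recon_model <- function(config, seed = 1L) {
  if (!inherits(config, "recon_model_config")) stop("config must be a recon_model_config")
  k <- config$kernel_size
  with_seed(seed, {
    its <- lapply(seq_len(config$n_iterations), function(i) {
      dual <- conv_block_params(config$n_dual + 2L, config$n_dual,
                                config$n_filters, config$n_conv_layers, k)
      primal <- if (config$variant == "fourier_pdnet") {
        conv_block_params(config$n_primal + 1L, config$n_primal,
                          config$n_filters, config$n_conv_layers, k)
      } else {
        unet_params(config$n_primal + 1L, config$n_primal,
                    config$n_filters, config$unet_depth, k)
      }
      list(dual = dual, primal = primal)
    })
    structure(list(config = config, iterations = its), class = "recon_model")
  })
}

#' Set all model weights and biases to zero
#'
#' With zero weights every residual block update vanishes, so the network is
#' exactly the identity on its initialisation: the forward pass returns the
#' zero-filled reconstruction.
#'
#' @param model a `recon_model`.
#' @return The model with all parameters zeroed.
#' @export
zero_weights <- function(model) {
  model$iterations <- tree_map_leaves(model$iterations, function(x) x * 0)
  model
}

#' Number of real-valued learnable parameters
#'
#' Each complex weight counts as two real parameters.
#'
#' @param model a `recon_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  total <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else total <<- total + 2 * length(x)
    invisible(NULL)
  }
  walk(model$iterations)
  total
}

## apply f to every parameter leaf (complex arrays / bias vectors)
tree_map_leaves <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map_leaves, f = f) else f(x)
}

## --- block forward/backward ----------------------------------------------

block_fwd <- function(layers, x, act) {
  n <- length(layers)
  caches <- vector("list", n)
  h <- x
  for (j in seq_len(n)) {
    cf <- conv_fwd(h, layers[[j]]$w, layers[[j]]$b)
    caches[[j]] <- list(conv = cf$cache, pre = cf$out)
    h <- if (act[j]) complex_activation(cf$out) else cf$out
  }
  list(out = h, cache = list(layers = caches, act = act))
}

block_bwd <- function(layers, cache, gout) {
  g <- gout
  n <- length(layers)
  grads <- vector("list", n)
  for (j in rev(seq_len(n))) {
    if (cache$act[j]) g <- crelu_bwd(cache$layers[[j]]$pre, g)
    cb <- conv_bwd(cache$layers[[j]]$conv, layers[[j]]$w, g)
    grads[[j]] <- list(w = cb$gw, b = cb$gb)
    g <- cb$gx
  }
  list(gx = g, grads = grads)
}

fc_act <- function(n) c(rep(TRUE, n - 1), FALSE)

## --- UNet primal block ----------------------------------------------------

avgpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  o <- seq(1, H, 2); e <- seq(2, H, 2)
  oc <- seq(1, W, 2); ec <- seq(2, W, 2)
  (x[o, oc, , drop = FALSE] + x[e, oc, , drop = FALSE] +
     x[o, ec, , drop = FALSE] + x[e, ec, , drop = FALSE]) / 4
}

avgpool2_bwd <- function(g, H, W) {
  gi <- g / 4
  gi[rep(seq_len(H / 2), each = 2), rep(seq_len(W / 2), each = 2), , drop = FALSE]
}

upsample2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(g) {
  H <- dim(g)[1]; W <- dim(g)[2]
  o <- seq(1, H, 2); e <- seq(2, H, 2)
  oc <- seq(1, W, 2); ec <- seq(2, W, 2)
  g[o, oc, , drop = FALSE] + g[e, oc, , drop = FALSE] +
    g[o, ec, , drop = FALSE] + g[e, ec, , drop = FALSE]
}

concat3 <- function(...) {
  parts <- list(...)
  H <- dim(parts[[1]])[1]; W <- dim(parts[[1]])[2]
  parts <- lapply(parts, function(p) if (is.matrix(p)) array(p, c(H, W, 1L)) else p)
  array(unlist(parts, use.names = FALSE),
        c(H, W, sum(vapply(parts, function(p) dim(p)[3], 0))))
}

unet_fwd <- function(params, x) {
  depth <- length(params$enc)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H %% 2^depth != 0 || W %% 2^depth != 0) {
    stop(sprintf("UNet primal block needs spatial sizes divisible by %d", 2^depth))
  }
  skips <- vector("list", depth)
  enc_c <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    bf <- block_fwd(params$enc[[l]], h, act = c(TRUE, TRUE))
    skips[[l]] <- bf$out
    enc_c[[l]] <- bf$cache
    h <- avgpool2(bf$out)
  }
  bb <- block_fwd(params$bottleneck, h, act = c(TRUE, TRUE))
  h <- bb$out
  dec_c <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    h <- concat3(skips[[l]], upsample2(h))
    bf <- block_fwd(params$dec[[l]], h, act = c(TRUE, TRUE))
    dec_c[[l]] <- bf$cache
    h <- bf$out
  }
  ff <- conv_fwd(h, params$final$w, params$final$b)
  list(out = ff$out,
       cache = list(enc = enc_c, bott = bb$cache, dec = dec_c,
                    final = ff$cache, skip_dims = lapply(skips, dim)))
}

unet_bwd <- function(params, cache, gout) {
  depth <- length(params$enc)
  fb <- conv_bwd(cache$final, params$final$w, gout)
  grads <- list(enc = vector("list", depth), bottleneck = NULL,
                dec = vector("list", depth),
                final = list(w = fb$gw, b = fb$gb))
  g <- fb$gx
  gskips <- vector("list", depth)
  for (l in seq_len(depth)) {          # decoder, from finest back down
    bb <- block_bwd(params$dec[[l]], cache$dec[[l]], g)
    grads$dec[[l]] <- bb$grads
    sd3 <- cache$skip_dims[[l]][3]
    gskips[[l]] <- bb$gx[, , seq_len(sd3), drop = FALSE]
    g <- upsample2_bwd(bb$gx[, , -seq_len(sd3), drop = FALSE])
  }
  bb <- block_bwd(params$bottleneck, cache$bott, g)
  grads$bottleneck <- bb$grads
  g <- bb$gx
  for (l in rev(seq_len(depth))) {     # encoder, from coarsest up
    sd <- cache$skip_dims[[l]]
    gs <- avgpool2_bwd(g, sd[1], sd[2]) + gskips[[l]]
    bb <- block_bwd(params$enc[[l]], cache$enc[[l]], gs)
    grads$enc[[l]] <- bb$grads
    g <- bb$gx
  }
  list(gx = g, grads = grads)
}

## --- unrolled forward/backward -------------------------------------------

#' Unrolled network forward pass
#'
#' Initialises the primal memory with the zero-filled inverse FFT of the
#' measured k-space replicated across channels and the dual memory with
#' zeros, then runs `n_iterations` of dual block followed by primal block.
#' Returns the first primal channel (the network "backbone" output -- no
#' data consistency; see [reconstruct()] for inference with the full
#' framework).
#'
#' @param model a `recon_model` from [init_recon_model()].
#' @param measured zero-filled measured k-space (complex matrix, exact zeros
#'   at unsampled locations).
#' @param mask the `sampling_mask` (or binary matrix) used for acquisition.
#' @param training if `TRUE`, also return the caches needed by the backward
#'   pass.
#' @return A complex matrix (reconstructed complex image); with
#'   `training = TRUE`, a list `(out, caches)`.
#' @export
forward_recon <- function(model, measured, mask, training = FALSE) {
  cfg <- model$config
  g <- mask_grid(mask)
  measured <- as_cplx_matrix(measured)
  stopifnot_same_shape(measured, g, "measured k-space and mask")
  if (any(measured[g == 0] != 0)) {
    stop("measured k-space must be exactly zero at unsampled locations")
  }
  H <- nrow(measured); W <- ncol(measured)
  np <- cfg$n_primal; nd <- cfg$n_dual
  p_sel <- min(2L, np)
  zf <- ifft2c(measured)
  primal <- array(zf, c(H, W, np))
  dual <- array(0i, c(H, W, nd))
  caches <- if (training) vector("list", cfg$n_iterations) else NULL
  for (it in seq_len(cfg$n_iterations)) {
    fp <- fft2c(primal[, , p_sel])
    dual_in <- concat3(dual, fp, measured)
    db <- block_fwd(model$iterations[[it]]$dual, dual_in,
                    act = fc_act(length(model$iterations[[it]]$dual)))
    dual <- dual + db$out
    bd <- ifft2c(dual[, , 1])
    primal_in <- concat3(primal, bd)
    pb <- if (cfg$variant == "fourier_pdnet") {
      block_fwd(model$iterations[[it]]$primal, primal_in,
                act = fc_act(length(model$iterations[[it]]$primal)))
    } else {
      unet_fwd(model$iterations[[it]]$primal, primal_in)
    }
    primal <- primal + pb$out
    if (training) caches[[it]] <- list(dual = db$cache, primal = pb$cache)
  }
  out <- primal[, , 1]
  if (training) list(out = out, caches = caches) else out
}

## gradient of a real loss w.r.t. all model parameters, given the gradient
## packing of the loss w.r.t. the output image
backward_recon <- function(model, caches, gout) {
  cfg <- model$config
  H <- nrow(gout); W <- ncol(gout)
  np <- cfg$n_primal; nd <- cfg$n_dual
  p_sel <- min(2L, np)
  gprimal <- array(0i, c(H, W, np))
  gprimal[, , 1] <- gout
  gdual <- array(0i, c(H, W, nd))
  grads <- vector("list", cfg$n_iterations)
  for (it in rev(seq_len(cfg$n_iterations))) {
    pb <- if (cfg$variant == "fourier_pdnet") {
      block_bwd(model$iterations[[it]]$primal, caches[[it]]$primal, gprimal)
    } else {
      unet_bwd(model$iterations[[it]]$primal, caches[[it]]$primal, gprimal)
    }
    gprimal <- gprimal + pb$gx[, , seq_len(np), drop = FALSE]
    gbd <- pb$gx[, , np + 1]
    gdual[, , 1] <- gdual[, , 1] + fft2c(gbd)
    db <- block_bwd(model$iterations[[it]]$dual, caches[[it]]$dual, gdual)
    gdual <- gdual + db$gx[, , seq_len(nd), drop = FALSE]
    gfp <- db$gx[, , nd + 1]
    gprimal[, , p_sel] <- gprimal[, , p_sel] + ifft2c(gfp)
    grads[[it]] <- list(dual = db$grads,
                        primal = if (cfg$variant == "fourier_pdnet") pb$grads else pb$grads)
  }
  grads
}
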