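test_that("zero-weight networks are the identity on the zero-filled init", {
  set.seed(1)
  mask <- make_varden1d_mask(16, 0.5, centre_lines = 4, seed = 2)
  x <- rand_cplx(16)
  mk <- undersample(fft2c(x), mask)
  zf <- ifft2c(mk)
  for (variant in c("fourier_pdnet", "fourier_pdunet")) {
    cfg <- recon_model_config(variant, n_iterations = 2, n_primal = 3,
                              n_dual = 3, n_filters = 4, unet_depth = 1)
    m0 <- zero_weights(init_recon_model(cfg, seed = 1))
    expect_identical(forward_recon(m0, mk, mask), zf)
  }
})

test_that("forward pass is deterministic, finite and shape-preserving", {
  set.seed(2)
  mask <- make_varden1d_mask(64, 0.25, seed = 3)
  ph <- make_complex_phantom(phantom_config(grid_size = 64, seed = 4))
  mk <- undersample(fft2c(ph), mask)
  for (variant in c("fourier_pdnet", "fourier_pdunet")) {
    cfg <- recon_model_config(variant, n_iterations = 2, n_primal = 3,
                              n_dual = 3, n_filters = 4, unet_depth = 2)
    model <- init_recon_model(cfg, seed = 5)
    out1 <- forward_recon(model, mk, mask)
    out2 <- forward_recon(model, mk, mask)
    expect_identical(out1, out2)
    expect_identical(dim(out1), c(64L, 64L))
    expect_true(all(is.finite(Re(out1))) && all(is.finite(Im(out1))))
  }
})

test_that("the forward input contract rejects energy off the mask", {
  mask <- make_varden1d_mask(16, 0.5, centre_lines = 4, seed = 2)
  cfg <- recon_model_config(n_iterations = 1, n_primal = 2, n_dual = 2,
                            n_filters = 2)
  model <- init_recon_model(cfg, seed = 1)
  bad <- matrix(1 + 0i, 16, 16)   # nonzero everywhere, incl. off-mask
  expect_error(forward_recon(model, bad, mask), "unsampled")
})

test_that("parameter counts are a deterministic function of the configuration", {
  # independent arithmetic for the desk PDNet:
  # dual block  (7 -> 8 -> 8 -> 5, 3x3): (9*7*8+8) + (9*8*8+8) + (9*8*5+5)
  # primal block(6 -> 8 -> 8 -> 5, 3x3): (9*6*8+8) + (9*8*8+8) + (9*8*5+5)
  dual <- (9 * 7 * 8 + 8) + (9 * 8 * 8 + 8) + (9 * 8 * 5 + 5)
  primal <- (9 * 6 * 8 + 8) + (9 * 8 * 8 + 8) + (9 * 8 * 5 + 5)
  expected <- 2 * 3 * (dual + primal)    # 2 reals/complex, 3 iterations
  model <- init_recon_model(desk_model_config("fourier_pdnet"), seed = 1)
  expect_identical(count_params(model), expected)
  expect_identical(count_params(init_recon_model(desk_model_config("fourier_pdnet"),
                                                 seed = 99)),
                   expected)
})

test_that("swapping the variant changes only the primal block parameters", {
  count_tree <- function(x) {
    if (is.list(x)) sum(vapply(x, count_tree, 0)) else 2 * length(x)
  }
  pdnet <- init_recon_model(desk_model_config("fourier_pdnet"), seed = 1)
  pdunet <- init_recon_model(desk_model_config("fourier_pdunet"), seed = 1)
  for (it in seq_along(pdnet$iterations)) {
    expect_identical(count_tree(pdnet$iterations[[it]]$dual),
                     count_tree(pdunet$iterations[[it]]$dual))
  }
  expect_false(count_params(pdnet) == count_params(pdunet))
})

test_that("UNet primal block honours the spatial-size contract", {
  mask <- make_varden1d_mask(64, 0.25, seed = 3)
  ph <- make_complex_phantom(phantom_config(grid_size = 64, seed = 4))
  mk <- undersample(fft2c(ph), mask)
  cfg <- recon_model_config("fourier_pdunet", n_iterations = 1, n_primal = 2,
                            n_dual = 2, n_filters = 4, unet_depth = 2)
  model <- init_recon_model(cfg, seed = 6)
  expect_identical(dim(forward_recon(model, mk, mask)), c(64L, 64L))
  # sizes not divisible by 2^depth are rejected up front
  mask18 <- make_varden1d_mask(18, 0.5, centre_lines = 2, seed = 1)
  mk18 <- undersample(fft2c(rand_cplx(18)), mask18)
  expect_error(forward_recon(model, mk18, mask18), "divisible")
})

test_that("unrolled model gradients match finite differences and reach every parameter", {
  set.seed(20)
  n <- 8
  msk <- make_varden1d_mask(n, 0.5, centre_lines = 2, seed = 1)
  tgt <- rand_cplx(n)
  mk <- undersample(fft2c(tgt), msk)
  sqloss <- function(out) sum(Re(out - tgt)^2 + Im(out - tgt)^2) / length(tgt)
  for (variant in c("fourier_pdnet", "fourier_pdunet")) {
    model <- gradcheck_model(variant, seed = 2)
    fw <- forward_recon(model, mk, msk, training = TRUE)
    gout <- array(2 * (fw$out - tgt) / length(tgt), dim(tgt))
    gout <- array(complex(real = Re(gout), imaginary = Im(gout)), dim(tgt))
    grads <- fourierpd:::backward_recon(model, fw$caches, gout)
    fp <- flatten_params(model$iterations)
    fg <- flatten_params(grads)
    # every parameter leaf receives a nonzero gradient (no dead parameters)
    expect_true(all(vapply(fg$flat, function(g) any(Mod(g) > 0), TRUE)))
    eps <- 1e-6
    for (trial in 1:8) {
      li <- sample(length(fp$flat), 1)
      el <- sample(length(fp$flat[[li]]), 1)
      ana <- get_leaf(grads, fg$paths[[li]])[el]
      for (comp in c(1, 1i)) {
        vp <- fp$flat[[li]]; vp[el] <- vp[el] + eps * comp
        vm <- fp$flat[[li]]; vm[el] <- vm[el] - eps * comp
        mp <- model; mp$iterations <- set_leaf(mp$iterations, fp$paths[[li]], vp)
        mm <- model; mm$iterations <- set_leaf(mm$iterations, fp$paths[[li]], vm)
        num <- (sqloss(forward_recon(mp, mk, msk)) -
                  sqloss(forward_recon(mm, mk, msk))) / (2 * eps)
        a <- if (comp == 1) Re(ana) else Im(ana)
        expect_equal(num, a, tolerance = 1e-4)
      }
    }
  }
})
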