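# Shared fixtures and independent oracles.

rand_cplx <- function(n, m = n) {
  matrix(complex(real = stats::rnorm(n * m), imaginary = stats::rnorm(n * m)), n, m)
}

# Direct complex multiply-accumulate convolution (cross-correlation with
# zero padding), written as literal loops so it is independent of the
# im2col/BLAS path it checks.
oracle_complex_conv <- function(x, w, bias = NULL) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  d <- dim(w); kh <- d[1]; kw <- d[2]; cin <- d[3]; cout <- d[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  pad <- floor(kh / 2)
  xp <- array(0i, c(H + 2 * pad, W + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  out <- array(0i, c(H, W, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- 0i
      for (ci in seq_len(cin)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
        acc <- acc + xp[i + ki - 1, j + kj - 1, ci] * w[ki, kj, ci, co]
      }
      out[i, j, co] <- acc + if (is.null(bias)) 0i else bias[co]
    }
  }
  out
}

# Literal evaluation of the three UIQI moment/component formulas.
oracle_uiqi <- function(x, y) {
  M <- nrow(x); N <- ncol(x)
  f <- 1 / (M + N - 1)
  mx <- sum(x) / (M * N); my <- sum(y) / (M * N)
  sxy <- f * sum((x - mx) * (y - my))
  sx2 <- f * sum((x - mx)^2); sy2 <- f * sum((y - my)^2)
  (sxy / sqrt(sx2 * sy2)) * (2 * mx * my / (mx^2 + my^2)) *
    (2 * sqrt(sx2) * sqrt(sy2) / (sx2 + sy2))
}

default_constants <- function() thermo_constants()

tiny_heated_pair <- function(grid = 32, delta_T_peak = 3, seed = 7,
                             constants = default_constants()) {
  ph <- make_complex_phantom(phantom_config(grid_size = grid, seed = seed))
  scen <- heating_scenario(hotspot_center = c(grid / 2, grid / 2 + 2),
                           hotspot_sigma = grid / 8, n_timepoints = 2,
                           delta_T_peak_per_tp = c(0, delta_T_peak))
  list(series = simulate_heating_series(ph, scen, constants),
       scenario = scen, phantom = ph)
}

# Random small model with nonzero random biases, so no pre-activation sits
# exactly on the split-rectifier kink (finite differences would cross it).
gradcheck_model <- function(variant, seed = 2) {
  cfg <- recon_model_config(variant, n_iterations = 2, n_primal = 2, n_dual = 2,
                            n_filters = 3, unet_depth = 1, n_conv_layers = 2)
  model <- init_recon_model(cfg, seed = seed)
  model$iterations <- fourierpd:::tree_map_leaves(model$iterations, function(p) {
    p + complex(real = stats::rnorm(length(p), sd = 0.05),
                imaginary = stats::rnorm(length(p), sd = 0.05))
  })
  model
}

withr_tempdir <- function() {
  d <- tempfile("fourierpd-test-")
  dir.create(d, recursive = TRUE)
  d
}

flatten_params <- function(tree) {
  flat <- list(); paths <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (i in seq_along(x)) walk(x[[i]], c(path, i))
    } else {
      flat[[length(flat) + 1]] <<- x
      paths[[length(paths) + 1]] <<- path
    }
  }
  walk(tree, integer(0))
  list(flat = flat, paths = paths)
}

set_leaf <- function(tree, path, val) {
  if (length(path) == 0) return(val)
  tree[[path[1]]] <- set_leaf(tree[[path[1]]], path[-1], val)
  tree
}

get_leaf <- function(tree, path) {
  if (length(path) == 0) return(tree)
  get_leaf(tree[[path[1]]], path[-1])
}
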