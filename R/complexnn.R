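## Complex-valued network primitives.
##
## Feature maps are complex arrays of shape (H, W, C); kernels are complex
## arrays (kh, kw, Cin, Cout); biases complex vectors of length Cout. A
## complex convolution is four real convolutions:
##   C_r = w_r * x_r - w_i * x_i,   C_i = w_i * x_r + w_r * x_i
## realised here as an im2col patch matrix times a kernel matrix, so all the
## arithmetic runs through BLAS. "Convolution" follows the deep-learning
## convention (cross-correlation, s(t) = sum_a x(t+a) w(a)).
##
## Gradients: the loss is real, and for each tensor we propagate the packing
## g = dL/d(Re) + 1i * dL/d(Im). Complex-linear ops then back-propagate with
## their conjugate transpose (for Y = X W: gX = gY W^H, gW = X^H gY), and the
## unitary centred FFT back-propagates with its inverse.

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3) stop("feature map must be (H, W, C)")
  if (!is.complex(x)) x <- array(as.complex(x), dim(x))
  x
}

## patch matrix: (H*W) x (kh*kw*Cin), rows = output pixel (column-major),
## columns ordered channel-fastest, then kernel row, then kernel column
im2col <- function(x, kh, kw, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0i, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  cols <- vector("list", kh * kw)
  o <- 0L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      o <- o + 1L
      sl <- xp[ki:(ki + H - 1), kj:(kj + W - 1), , drop = FALSE]
      cols[[o]] <- matrix(sl, H * W, C)
    }
  }
  do.call(cbind, cols)
}

## adjoint of im2col: scatter-add patch-matrix gradients back to (H, W, C)
col2im <- function(gcols, H, W, C, kh, kw, pad) {
  gp <- array(0i, c(H + 2 * pad, W + 2 * pad, C))
  o <- 0L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      o <- o + 1L
      blk <- array(gcols[, ((o - 1) * C + 1):(o * C)], c(H, W, C))
      gp[ki:(ki + H - 1), kj:(kj + W - 1), ] <-
        gp[ki:(ki + H - 1), kj:(kj + W - 1), , drop = FALSE] + blk
    }
  }
  gp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

## kernel (kh, kw, Cin, Cout) -> (kh*kw*Cin) x Cout matrix matching im2col's
## column order
kernel_matrix <- function(w) {
  d <- dim(w)
  matrix(aperm(w, c(3, 1, 2, 4)), d[1] * d[2] * d[3], d[4])
}

kernel_unmatrix <- function(wm, d) {
  aperm(array(wm, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

#' Complex-valued 2D convolution
#'
#' Cross-correlates a complex feature map `(H, W, Cin)` with a complex
#' kernel `(kh, kw, Cin, Cout)` under zero padding (default "same"), adding
#' an optional complex per-channel bias. Two equivalent evaluation paths are
#' provided: `"component"` computes the four real convolutions of the
#' component form, `"matrix"` multiplies the stacked real block matrix
#' `[[Wr, Wi], [-Wi, Wr]]` against `[Xr, Xi]`.
#'
#' @param x complex matrix `(H, W)` or array `(H, W, Cin)`.
#' @param w complex kernel array `(kh, kw, Cin, Cout)`.
#' @param bias complex vector of length Cout, or `NULL`.
#' @param padding integer zero-padding; default keeps the spatial size for
#'   odd kernels.
#' @param method `"component"` or `"matrix"` (identical results).
#' @return Complex array `(H, W, Cout)`, dropped to a matrix when the input
#'   was a matrix and Cout = 1.
#' @export
complex_conv2d <- function(x, w, bias = NULL, padding = NULL,
                           method = c("component", "matrix")) {
  method <- match.arg(method)
  was_matrix <- is.matrix(x)
  x <- as_feature_map(x)
  if (length(dim(w)) != 4) stop("kernel must be (kh, kw, Cin, Cout)")
  if (!is.complex(w)) w <- array(as.complex(w), dim(w))
  d <- dim(w)
  if (d[3] != dim(x)[3]) {
    stop(sprintf("channel mismatch: input has %d channels, kernel expects %d",
                 dim(x)[3], d[3]))
  }
  pad <- padding %||% floor(d[1] / 2)
  H <- dim(x)[1]; W <- dim(x)[2]
  Xc <- im2col(x, d[1], d[2], pad)
  Wm <- kernel_matrix(w)
  Y <- if (method == "component") {
    Yr <- Re(Xc) %*% Re(Wm) - Im(Xc) %*% Im(Wm)
    Yi <- Re(Xc) %*% Im(Wm) + Im(Xc) %*% Re(Wm)
    matrix(complex(real = Yr, imaginary = Yi), nrow(Yr), ncol(Yr))
  } else {
    big_w <- rbind(cbind(Re(Wm), Im(Wm)), cbind(-Im(Wm), Re(Wm)))
    big_x <- cbind(Re(Xc), Im(Xc))
    YY <- big_x %*% big_w
    m <- ncol(Wm)
    matrix(complex(real = YY[, seq_len(m)], imaginary = YY[, m + seq_len(m)]),
           nrow(YY), m)
  }
  if (!is.null(bias)) Y <- sweep(Y, 2, as.complex(bias), "+")
  out <- array(Y, c(H, W, d[4]))
  if (was_matrix && d[4] == 1) out <- out[, , 1] else out
}

## --- internal training-path conv with cache ------------------------------

conv_fwd <- function(x, w, b, pad = NULL) {
  d <- dim(w)
  pad <- pad %||% floor(d[1] / 2)
  H <- dim(x)[1]; W <- dim(x)[2]
  Xc <- im2col(x, d[1], d[2], pad)
  Y <- Xc %*% kernel_matrix(w)
  if (!is.null(b)) Y <- sweep(Y, 2, b, "+")
  list(out = array(Y, c(H, W, d[4])),
       cache = list(Xc = Xc, xdim = dim(x), wdim = d, pad = pad))
}

conv_bwd <- function(cache, w, gout) {
  d <- cache$wdim
  Gm <- matrix(gout, prod(cache$xdim[1:2]), d[4])
  Wm <- kernel_matrix(w)
  gW <- kernel_unmatrix(Conj(t(cache$Xc)) %*% Gm, d)
  gb <- colSums(Gm)
  gXc <- Gm %*% Conj(t(Wm))
  gx <- col2im(gXc, cache$xdim[1], cache$xdim[2], cache$xdim[3],
               d[1], d[2], cache$pad)
  list(gx = gx, gw = gW, gb = gb)
}

#' Split (CReLU-style) complex activation
#'
#' Applies a rectifier independently to the real and imaginary parts:
#' `max(Re, 0) + 1i * max(Im, 0)`. Idempotent; the identity on inputs whose
#' components are already nonnegative.
#'
#' @param x complex array or matrix.
#' @return Same shape as `x`.
#' @export
complex_activation <- function(x) {
  if (!is.complex(x)) x <- x * (1 + 0i)
  out <- complex(real = pmax(Re(x), 0), imaginary = pmax(Im(x), 0))
  if (is.null(dim(x))) out else array(out, dim(x))
}

crelu_bwd <- function(x, gout) {
  g <- complex(real = Re(gout) * (Re(x) > 0), imaginary = Im(gout) * (Im(x) > 0))
  array(g, dim(x))
}

#' Complex L1 loss (mean absolute error on components)
#'
#' `mean(|Re(y) - Re(y_hat)| + |Im(y) - Im(y_hat)|)` over all voxels (and
#' samples, when given batches): the complex analogue of the L1 loss used to
#' train the reconstruction networks. Nonnegative; zero iff the inputs are
#' identical; invariant to adding the same constant to both arguments.
#'
#' @param y_hat predicted complex array/matrix (or list of them).
#' @param y ground-truth complex array/matrix (or list, paired with `y_hat`).
#' @return A single nonnegative number.
#' @export
complex_l1_loss <- function(y_hat, y) {
  if (is.list(y_hat) || is.list(y)) {
    if (!(is.list(y_hat) && is.list(y)) || length(y_hat) != length(y)) {
      stop("batch lists must be paired")
    }
    per <- mapply(function(a, b) {
      stopifnot_same_shape(a, b, "loss inputs")
      c(sum(abs(Re(b) - Re(a))) + sum(abs(Im(b) - Im(a))), length(a))
    }, y_hat, y)
    return(sum(per[1, ]) / sum(per[2, ]))
  }
  stopifnot_same_shape(y_hat, y, "loss inputs")
  (sum(abs(Re(y) - Re(y_hat))) + sum(abs(Im(y) - Im(y_hat)))) / length(y)
}

## gradient of complex_l1_loss w.r.t. y_hat (component packing)
complex_l1_grad <- function(y_hat, y) {
  g <- complex(real = -sign(Re(y) - Re(y_hat)),
               imaginary = -sign(Im(y) - Im(y_hat))) / length(y)
  array(g, dim(y) %||% length(y))
}

#' Random complex kernel initialisation
#'
#' Glorot-style independent real/imaginary Gaussian initialisation with the
#' per-component variance halved relative to the real-valued rule
#' (`sd = sqrt(1 / (fan_in + fan_out))`), so the expected complex magnitude
#' matches the real-valued Glorot scale.
#'
#' @param kh,kw kernel height/width.
#' @param cin,cout input/output channel counts.
#' @return Complex array `(kh, kw, cin, cout)`.
#' @export
init_complex_kernel <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin; fan_out <- kh * kw * cout
  sd <- sqrt(1 / (fan_in + fan_out))
  array(complex(real = stats::rnorm(kh * kw * cin * cout, sd = sd),
                imaginary = stats::rnorm(kh * kw * cin * cout, sd = sd)),
        c(kh, kw, cin, cout))
}
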