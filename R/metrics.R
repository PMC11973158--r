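## Image-quality metrics: SSIM, NRMSE, UIQI, applied separately to magnitude
## and phase images.

#' Structural similarity index (SSIM)
#'
#' Local mode (default) averages the SSIM statistic over all complete
#' `window x window` uniform local windows, with unbiased (n/(n-1))
#' variance/covariance estimates -- the common reference formulation, so
#' values are directly comparable to standard implementations. Global mode
#' evaluates the same statistic once from whole-image moments.
#'
#' @param x,y real matrices of identical shape.
#' @param L dynamic range of the pixel values (1 for min-max-scaled
#'   magnitudes, `2*pi` for phase maps on `[0, 2*pi)`).
#' @param k1,k2 stabilisation constants; `C1 = (k1*L)^2`, `C2 = (k2*L)^2`.
#' @param window odd local window side length (local mode).
#' @param mode `"local"` (windowed mean) or `"global"` (whole-image moments).
#' @return A single number in `[-1, 1]`.
#' @export
ssim <- function(x, y, L = 1, k1 = 0.01, k2 = 0.03, window = 7L,
                 mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot_same_shape(x, y, "images")
  if (k1 <= 0 || k2 <= 0 || L <= 0) stop("k1, k2 and L must be > 0")
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  if (mode == "global") {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / (n - 1); vy <- sum((y - my)^2) / (n - 1)
    cxy <- sum((x - mx) * (y - my)) / (n - 1)
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  w <- as.integer(window)
  if (w < 2 || w > min(dim(x))) stop("window must fit inside the image")
  nw <- w * w
  ux <- win_mean(x, w); uy <- win_mean(y, w)
  corr <- nw / (nw - 1)
  vx <- (win_mean(x * x, w) - ux^2) * corr
  vy <- (win_mean(y * y, w) - uy^2) * corr
  cxy <- (win_mean(x * y, w) - ux * uy) * corr
  S <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

## mean over all complete w x w windows ("valid" uniform filter), via
## summed-area table
win_mean <- function(x, w) {
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  pad[-1, -1] <- cs
  H <- nrow(x); W <- ncol(x)
  i2 <- (w + 1):(H + 1); i1 <- 1:(H - w + 1)
  j2 <- (w + 1):(W + 1); j1 <- 1:(W - w + 1)
  (pad[i2, j2] - pad[i1, j2] - pad[i2, j1] + pad[i1, j1]) / (w * w)
}

#' Normalized root-mean-square error
#'
#' `sqrt(mean((y - y_hat)^2)) / sqrt(mean(y^2))`: RMSE normalized by the
#' root-mean-square of the reference `y` (so it is scale-invariant but not
#' symmetric -- the first argument is the reference).
#'
#' @param y reference (fully sampled ground truth) real matrix.
#' @param y_hat comparison image, same shape.
#' @return A single nonnegative number.
#' @export
nrmse <- function(y, y_hat) {
  stopifnot_same_shape(y, y_hat, "images")
  denom <- sqrt(mean(as.numeric(y)^2))
  if (denom == 0) stop("nrmse undefined: reference image is identically zero")
  sqrt(mean((as.numeric(y) - as.numeric(y_hat))^2)) / denom
}

#' Universal image quality index (UIQI)
#'
#' Product of three components computed from whole-image moments: linear
#' correlation, luminance similarity `2*mx*my/(mx^2+my^2)`, and contrast
#' similarity `2*sx*sy/(sx^2+sy^2)`. Degenerate cases follow the components'
#' limits: equal zero means give luminance similarity 1; a constant image
#' (but not both) gives correlation 0; two constant images are an error.
#' The `normalizer` controls the second-moment denominator -- `"paper"` uses
#' `1/(M+N-1)`, `"standard"` the conventional `1/(M*N-1)`; the choice cancels
#' in the three-factor product, so Q itself is unaffected (both kept for
#' moment-level reporting).
#'
#' @param x,y real matrices of identical shape (M x N).
#' @param normalizer `"paper"` or `"standard"` second-moment normalizer.
#' @return A single number in `[-1, 1]`.
#' @export
uiqi <- function(x, y, normalizer = c("paper", "standard")) {
  normalizer <- match.arg(normalizer)
  stopifnot_same_shape(x, y, "images")
  M <- nrow(x); N <- ncol(x)
  f <- if (normalizer == "paper") 1 / (M + N - 1) else 1 / (M * N - 1)
  mx <- mean(x); my <- mean(y)
  sxx <- f * sum((x - mx)^2)
  syy <- f * sum((y - my)^2)
  sxy <- f * sum((x - mx) * (y - my))
  if (sxx == 0 && syy == 0) stop("uiqi undefined: both images are constant")
  corr <- if (sxx == 0 || syy == 0) 0 else sxy / sqrt(sxx * syy)
  lum <- if (mx == 0 && my == 0) 1 else 2 * mx * my / (mx^2 + my^2)
  con <- 2 * sqrt(sxx) * sqrt(syy) / (sxx + syy)
  corr * lum * con
}

#' Magnitude/phase image-quality report for a complex image pair
#'
#' Magnitudes are min-max scaled by the reference's range (the same affine
#' map applied to both images, L = 1); phases are mapped to `[0, 2*pi)`
#' with L = `2*pi`. SSIM, NRMSE and UIQI are evaluated per channel.
#'
#' @param truth reference complex image.
#' @param pred comparison complex image, same shape.
#' @return A data.frame with columns `channel`, `ssim`, `nrmse`, `uiqi`.
#' @export
eval_metric_pair <- function(truth, pred) {
  truth <- as_cplx_matrix(truth); pred <- as_cplx_matrix(pred)
  stopifnot_same_shape(truth, pred, "images")
  mt <- Mod(truth); mp <- Mod(pred)
  rng <- range(mt)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  mts <- (mt - rng[1]) / scale
  mps <- (mp - rng[1]) / scale
  pt <- (Arg(truth) + 2 * pi) %% (2 * pi)
  pp <- (Arg(pred) + 2 * pi) %% (2 * pi)
  data.frame(
    channel = c("magnitude", "phase"),
    ssim = c(ssim(mts, mps, L = 1), ssim(pt, pp, L = 2 * pi)),
    nrmse = c(nrmse(mts, mps), nrmse(pt, pp)),
    uiqi = c(uiqi(mts, mps), uiqi(pt, pp)),
    stringsAsFactors = FALSE
  )
}

#' Slice-wise metric report with mean and standard error
#'
#' @param truth_list,pred_list lists of complex images (paired by index).
#' @return List with `per_slice` (data.frame incl. `slice`) and `summary`
#'   (mean and SE of each metric per channel).
#' @export
metric_report <- function(truth_list, pred_list) {
  if (length(truth_list) != length(pred_list)) stop("lists must be paired")
  rows <- lapply(seq_along(truth_list), function(i) {
    d <- eval_metric_pair(truth_list[[i]], pred_list[[i]])
    d$slice <- i
    d
  })
  per_slice <- do.call(rbind, rows)
  agg <- function(v, ch) {
    vals <- per_slice[per_slice$channel == ch, v]
    c(mean = mean(vals), se = stats::sd(vals) / sqrt(length(vals)))
  }
  summary <- do.call(rbind, lapply(c("magnitude", "phase"), function(ch) {
    data.frame(channel = ch,
               ssim_mean = agg("ssim", ch)[1], ssim_se = agg("ssim", ch)[2],
               nrmse_mean = agg("nrmse", ch)[1], nrmse_se = agg("nrmse", ch)[2],
               uiqi_mean = agg("uiqi", ch)[1], uiqi_se = agg("uiqi", ch)[2],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_slice = per_slice[, c("slice", "channel", "ssim", "nrmse", "uiqi")],
       summary = summary)
}
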