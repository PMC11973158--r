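## Centred orthonormal Fourier transforms and variable-density Cartesian
## sampling masks. Conventions (used everywhere in the package):
##   * arrays are (row, col) = (phase-encode, readout), 1-based in R;
##   * the DC component sits at (floor(rows/2)+1, floor(cols/2)+1), i.e. the
##     0-based index rows%/%2 that centred-FFT conventions place it at;
##   * transforms are orthonormal (unitary), so Parseval holds exactly and the
##     adjoint of fft2c is ifft2c.

fftshift_idx <- function(n) ((seq_len(n) - 1 + ceiling(n / 2)) %% n) + 1
ifftshift_idx <- function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) + 1

fftshift2 <- function(x) x[fftshift_idx(nrow(x)), fftshift_idx(ncol(x)), drop = FALSE]
ifftshift2 <- function(x) x[ifftshift_idx(nrow(x)), ifftshift_idx(ncol(x)), drop = FALSE]

#' Centred orthonormal 2D Fourier transform
#'
#' `fft2c` maps image space to k-space with the DC component at the grid
#' centre and unitary scaling (`1/sqrt(N)`), so energy is preserved
#' (Parseval) and `ifft2c` is both the inverse and the adjoint.
#'
#' @param x complex matrix (image for `fft2c`, k-space grid for `ifft2c`).
#' @return A complex matrix of the same shape.
#' @examples
#' x <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
#' max(Mod(ifft2c(fft2c(x)) - x))  # ~ 1e-16
#' @export
fft2c <- function(x) {
  x <- as_cplx_matrix(x)
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  x <- as_cplx_matrix(x)
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' Variable-density Cartesian sampling masks
#'
#' `make_varden1d_mask` samples complete readout lines along the
#' phase-encoding (row) direction: a densely sampled block of
#' `centre_lines` contiguous central lines is always acquired, and the
#' remaining line budget is drawn without replacement with probability
#' proportional to a 1D normal density centred on the k-space centre
#' (sd = rows/6). `make_varden2d_mask` fully samples a central disc covering
#' `centre_fraction` of k-space and draws the remaining points without
#' replacement from a 2D normal density (sd = extent/6). Sampled-point
#' counts are exact: `round(fraction * rows)` lines (1D) and
#' `round(fraction * rows * cols)` points (2D), rounding half away from zero.
#'
#' @param shape integer length-2 `(rows, cols)`, or a single integer for a
#'   square grid.
#' @param fraction sampled fraction of k-space, in (0, 1].
#' @param centre_lines number of always-acquired contiguous central lines
#'   (1D masks).
#' @param centre_fraction fraction of k-space covered by the fully sampled
#'   central disc (2D masks); must not exceed `fraction`.
#' @param seed integer RNG seed; masks are pure functions of their arguments.
#' @return A `sampling_mask`: list with elements `grid` (0/1 matrix), `kind`,
#'   `fraction`, centre parameters, and `seed`.
#' @export
make_varden1d_mask <- function(shape, fraction, centre_lines = 8L, seed = 1L) {
  shape <- normalize_shape(shape)
  rows <- shape[1]; cols <- shape[2]
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  n_lines <- as.integer(round_half_up(fraction * rows))
  if (centre_lines < 0) stop("centre_lines must be >= 0")
  if (centre_lines > n_lines) {
    stop(sprintf("centre_lines (%d) exceeds the line budget round(fraction*rows) = %d",
                 centre_lines, n_lines))
  }
  dc <- floor(rows / 2) + 1L
  centre <- if (centre_lines > 0) {
    (dc - floor(centre_lines / 2)) + seq_len(centre_lines) - 1L
  } else integer(0)
  rest <- setdiff(seq_len(rows), centre)
  n_extra <- n_lines - length(centre)
  extra <- if (n_extra > 0) {
    w <- stats::dnorm(rest - dc, sd = rows / 6)
    with_seed(seed, sample_wor_weighted(rest, n_extra, w))
  } else integer(0)
  lines <- sort(c(centre, extra))
  grid <- matrix(0, rows, cols)
  grid[lines, ] <- 1
  new_sampling_mask(grid, "varden1d", fraction, seed,
                    centre_lines = as.integer(centre_lines))
}

#' @rdname make_varden1d_mask
#' @export
make_varden2d_mask <- function(shape, fraction, centre_fraction = 0.025, seed = 1L) {
  shape <- normalize_shape(shape)
  rows <- shape[1]; cols <- shape[2]
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (!(centre_fraction >= 0 && centre_fraction <= fraction)) {
    stop("centre_fraction must satisfy 0 <= centre_fraction <= fraction")
  }
  n_pts <- rows * cols
  n_total <- as.integer(round_half_up(fraction * n_pts))
  n_centre <- as.integer(round_half_up(centre_fraction * n_pts))
  dc_r <- floor(rows / 2) + 1L; dc_c <- floor(cols / 2) + 1L
  dr <- matrix(seq_len(rows) - dc_r, rows, cols)
  dcc <- matrix(seq_len(cols) - dc_c, rows, cols, byrow = TRUE)
  d2 <- dr^2 + dcc^2
  ## dense centre: the n_centre points closest to DC (a disc; ties broken by
  ## linear index so the mask is deterministic)
  ord <- order(d2, seq_len(n_pts))
  centre_idx <- ord[seq_len(n_centre)]
  rest_idx <- ord[-seq_len(n_centre)]
  n_extra <- n_total - n_centre
  extra_idx <- if (n_extra > 0) {
    sr <- rows / 6; sc <- cols / 6
    w <- exp(-(dr[rest_idx]^2 / (2 * sr^2) + dcc[rest_idx]^2 / (2 * sc^2)))
    with_seed(seed, sample_wor_weighted(rest_idx, n_extra, w))
  } else integer(0)
  grid <- matrix(0, rows, cols)
  grid[c(centre_idx, extra_idx)] <- 1
  new_sampling_mask(grid, "varden2d", fraction, seed,
                    centre_fraction = centre_fraction)
}

## Weighted sampling without replacement via the exponential-race construction
## (equivalent in distribution to sequential draws with renormalised weights,
## but O(n log n) for any draw count).
sample_wor_weighted <- function(x, k, w) {
  if (k == 0) return(x[0])
  if (k > length(x)) stop("cannot draw more elements than available")
  keys <- stats::rexp(length(x)) / w
  x[order(keys)[seq_len(k)]]
}

new_sampling_mask <- function(grid, kind, fraction, seed, ...) {
  structure(list(grid = grid, kind = kind, fraction = fraction,
                 seed = as.integer(seed), ...),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask %s %dx%d  fraction=%.3g  sampled=%d  seed=%d>\n",
              x$kind, nrow(x$grid), ncol(x$grid), x$fraction,
              sum(x$grid), x$seed))
  invisible(x)
}

normalize_shape <- function(shape) {
  if (length(shape) == 1) shape <- c(shape, shape)
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) stop("shape must be (rows, cols)")
  shape
}

mask_grid <- function(mask) {
  if (inherits(mask, "sampling_mask")) mask$grid else mask
}

#' Retrospective undersampling of a k-space grid
#'
#' Elementwise product of a k-space grid with a binary sampling mask;
#' unacquired locations become exactly zero ("zero-filled" k-space).
#'
#' @param k complex k-space matrix (DC at centre).
#' @param mask a `sampling_mask` or binary matrix of the same shape.
#' @return Complex matrix with zeros at unsampled locations.
#' @export
undersample <- function(k, mask) {
  g <- mask_grid(mask)
  k <- as_cplx_matrix(k)
  stopifnot_same_shape(k, g, "k-space and mask")
  k * g
}

#' Theoretical acceleration factor of a sampling mask
#'
#' Defined as `1 / fraction`: sampling 25% of k-space gives a factor of 4,
#' 10% a factor of 10.
#'
#' @param mask a `sampling_mask`, or a sampled fraction in (0, 1].
#' @return The acceleration factor, a single number.
#' @export
theoretical_acceleration <- function(mask) {
  f <- if (inherits(mask, "sampling_mask")) mask$fraction else mask
  if (!(is.numeric(f) && length(f) == 1 && f > 0)) {
    stop("sampled fraction must be a positive number")
  }
  1 / f
}
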