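## PRF-shift thermometry: wrap-robust complex phase difference, linear
## phase-to-temperature conversion, and the temperature-error statistic.

#' Physical constants for PRF-shift thermometry
#'
#' The PRF relation converts a gradient-echo phase difference into a
#' temperature difference: `dT = dphi / (gamma * alpha*1e-6 * B0 * TE)`,
#' where the product in the denominator is the phase accrued per degree
#' Celsius (rad/degC). Units matter: `gamma` in rad s^-1 T^-1, `alpha` in
#' ppm/degC (converted internally by 1e-6), `B0` in tesla, `TE` in seconds.
#'
#' @param gamma proton gyromagnetic ratio, rad s^-1 T^-1.
#' @param alpha PRF temperature sensitivity, ppm/degC (water: about -0.01).
#' @param B0 main magnetic field strength, tesla.
#' @param TE echo time, seconds.
#' @return A `thermo_constants` list.
#' @export
thermo_constants <- function(gamma = 2 * pi * 42.577e6, alpha = -0.01,
                             B0 = 1.5, TE = 19.1e-3) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (B0 <= 0) stop("B0 must be > 0")
  if (TE <= 0) stop("TE must be > 0")
  if (alpha == 0) stop("alpha must be nonzero")
  structure(list(gamma = gamma, alpha = alpha, B0 = B0, TE = TE),
            class = "thermo_constants")
}

#' Phase accrued per degree Celsius
#'
#' @param constants a [thermo_constants()].
#' @return `gamma * alpha*1e-6 * B0 * TE`, in rad/degC.
#' @export
prf_phase_per_degC <- function(constants) {
  constants$gamma * constants$alpha * 1e-6 * constants$B0 * constants$TE
}

#' Complex phase difference between two gradient-echo images
#'
#' Computes the four-quadrant arctangent of
#' `Im(Conj(I_ref) * I_H) / Re(Conj(I_ref) * I_H)`, i.e. the principal-value
#' phase of the complex ratio, in `(-pi, pi]`. Working on the complex product
#' rather than subtracting wrapped phase images avoids spurious 2*pi jumps;
#' only true differences beyond pi wrap (documented principal-value
#' behaviour). Voxels where both images vanish get 0 and are flagged in the
#' `valid` attribute.
#'
#' @param I_ref reference complex image.
#' @param I_H heated complex image, same shape.
#' @return Real matrix of phase differences in radians, with a logical
#'   `valid` attribute (FALSE where both inputs had zero magnitude).
#' @export
phase_difference <- function(I_ref, I_H) {
  a <- as_cplx_matrix(I_ref); b <- as_cplx_matrix(I_H)
  stopifnot_same_shape(a, b, "image pair")
  z <- Conj(a) * b
  num <- Im(z); den <- Re(z)
  dphi <- atan2(num, den)
  invalid <- num == 0 & den == 0
  dphi[invalid] <- 0
  attr(dphi, "valid") <- !invalid
  dphi
}

#' Convert a phase difference to a temperature map
#'
#' `dT = dphi / (gamma * alpha*1e-6 * B0 * TE)` (linear PRF relation).
#'
#' @param delta_phi real matrix of phase differences, radians.
#' @param constants a [thermo_constants()].
#' @return Matrix of temperature differences in degrees Celsius.
#' @export
temperature_map <- function(delta_phi, constants) {
  k <- prf_phase_per_degC(constants)
  if (!is.finite(k) || k == 0) stop("gamma*alpha*B0*TE must be nonzero")
  out <- delta_phi / k
  attr(out, "valid") <- attr(delta_phi, "valid")
  out
}

#' Temperature maps for a whole series
#'
#' Maps every frame against the first (reference) frame; the first map is
#' identically zero.
#'
#' @param frames list of complex images (time points), or a `heating_series`.
#' @param constants a [thermo_constants()]; defaults to the series' own
#'   constants when a `heating_series` is given.
#' @return List of temperature maps (matrices, degrees Celsius).
#' @export
temperature_series <- function(frames, constants = NULL) {
  if (inherits(frames, "heating_series")) {
    constants <- constants %||% frames$constants
    frames <- frames$frames
  }
  if (is.null(constants)) stop("constants required")
  ref <- frames[[1]]
  lapply(frames, function(f) temperature_map(phase_difference(ref, f), constants))
}

#' Temperature-error statistic between two map series
#'
#' `E_T = 100 / (V * tau) * sum_t sum_v (dT_x(v,t) - dT_y(v,t))^2`, where V
#' is the number of evaluated voxels and tau the number of time points. With
#' `roi`, both V and the sums restrict to the ROI voxels. Symmetric,
#' nonnegative, zero iff the series agree on the evaluated voxels.
#'
#' @param x_series,y_series lists of temperature maps (same shapes/lengths);
#'   conventionally x is derived from the fully sampled data.
#' @param roi optional logical/0-1 matrix restricting the evaluation.
#' @return A single number.
#' @export
temperature_error <- function(x_series, y_series, roi = NULL) {
  d2 <- temp_sq_diffs(x_series, y_series, roi)
  100 * mean(d2)
}

#' Root-mean-square temperature difference in degrees Celsius
#'
#' Companion statistic to [temperature_error()] on the natural temperature
#' scale: `sqrt(mean((dT_x - dT_y)^2))` over the evaluated voxels and time
#' points (ROI-restricted when `roi` is given).
#'
#' @inheritParams temperature_error
#' @return A single number, degrees Celsius.
#' @export
temperature_rmse <- function(x_series, y_series, roi = NULL) {
  sqrt(mean(temp_sq_diffs(x_series, y_series, roi)))
}

temp_sq_diffs <- function(x_series, y_series, roi = NULL) {
  if (length(x_series) != length(y_series) || length(x_series) == 0) {
    stop("series must be non-empty and have equal numbers of time points")
  }
  sel <- if (!is.null(roi)) which(roi != 0) else NULL
  unlist(lapply(seq_along(x_series), function(t) {
    a <- x_series[[t]]; b <- y_series[[t]]
    stopifnot_same_shape(a, b, "temperature maps")
    d <- a - b
    if (!is.null(sel)) d <- d[sel]
    as.numeric(d)^2
  }))
}
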