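## Synthetic complex gradient-echo phantoms with PRF-encoded heating.
##
## The generator stands in for the (non-public) clinical sarcoma acquisitions:
## piecewise-smooth ellipse anatomy for the magnitude (Shepp-Logan-like), a
## smooth low-order polynomial background phase emulating coil/susceptibility
## phase, optional circular complex Gaussian noise, and a Gaussian hotspot
## whose temperature rise enters the phase through the PRF relation.

#' Phantom generator configuration
#'
#' @param grid_size pixels per side (square grid), >= 16. Default 256; tests
#'   and desk-scale experiments use 64.
#' @param n_ellipses number of random tissue ellipses overlaid on the
#'   background ellipse.
#' @param magnitude_range range the background-ellipse intensity is drawn
#'   from (final magnitudes are clamped to `[0, 1]`).
#' @param background_phase_order polynomial order of the smooth background
#'   phase field.
#' @param noise_sd standard deviation of the added circular complex Gaussian
#'   noise, per real/imaginary component, as a fraction of the peak
#'   magnitude. 0 disables noise.
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   phantom bit-for-bit.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_size = 256L, n_ellipses = 6L,
                           magnitude_range = c(0.3, 0.7),
                           background_phase_order = 2L,
                           noise_sd = 0, seed = 1L) {
  if (!(is.numeric(grid_size) && length(grid_size) == 1 && grid_size >= 16)) {
    stop("grid_size must be a single integer >= 16")
  }
  if (!(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd >= 0)) {
    stop("noise_sd must be >= 0")
  }
  if (background_phase_order < 0) stop("background_phase_order must be >= 0")
  structure(list(grid_size = as.integer(grid_size),
                 n_ellipses = as.integer(n_ellipses),
                 magnitude_range = magnitude_range,
                 background_phase_order = as.integer(background_phase_order),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a complex gradient-echo phantom
#'
#' Magnitude is a piecewise-smooth overlay of random ellipses clamped to
#' `[0, 1]`; phase is a smooth random polynomial field scaled to lie inside
#' `(-pi, pi]`. With `noise_sd > 0`, i.i.d. circular complex Gaussian noise
#' (equivalent to k-space Gaussian noise under the orthonormal FFT) is added
#' in image space.
#'
#' @param config a [phantom_config()].
#' @return A [complex_image()] of side `config$grid_size`.
#' @export
make_complex_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stop("config must be a phantom_config")
  n <- config$grid_size
  with_seed(config$seed, {
    u <- matrix(seq(-1, 1, length.out = n), n, n)            # row coord
    v <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)

    mag <- matrix(0, n, n)
    base <- stats::runif(1, config$magnitude_range[1], config$magnitude_range[2])
    mag <- mag + base * ellipse_indicator(u, v, 0, 0, 0.88, 0.82,
                                          stats::runif(1, -pi, pi))
    for (i in seq_len(config$n_ellipses)) {
      mag <- mag + stats::runif(1, -0.25, 0.45) *
        ellipse_indicator(u, v,
                          stats::runif(1, -0.5, 0.5), stats::runif(1, -0.5, 0.5),
                          stats::runif(1, 0.08, 0.45), stats::runif(1, 0.08, 0.45),
                          stats::runif(1, -pi, pi))
    }
    mag <- pmin(pmax(mag, 0), 1)

    phase <- matrix(0, n, n)
    for (i in 0:config$background_phase_order) {
      for (j in 0:(config$background_phase_order - i)) {
        phase <- phase + stats::rnorm(1) * u^i * v^j
      }
    }
    pk <- max(abs(phase))
    if (pk > 0) phase <- phase / pk * stats::runif(1, 0.5, 0.9) * pi

    img <- mag * exp(1i * phase)
    if (config$noise_sd > 0) {
      s <- config$noise_sd * max(mag)
      img <- img + complex(real = stats::rnorm(n * n, sd = s),
                           imaginary = stats::rnorm(n * n, sd = s))
    }
    complex_image(img)
  })
}

ellipse_indicator <- function(u, v, cu, cv, a, b, theta) {
  du <- u - cu; dv <- v - cv
  ru <- du * cos(theta) + dv * sin(theta)
  rv <- -du * sin(theta) + dv * cos(theta)
  (ru / a)^2 + (rv / b)^2 <= 1
}

#' Heating scenario for a phantom time series
#'
#' Describes a localized Gaussian hotspot whose peak temperature rise per
#' time point follows a given profile. Time point 1 is the unheated
#' reference (its entry must be 0); by default the peak ramps linearly from
#' 0 to `peak_delta_T` across the series, emulating progressive heating over
#' a hyperthermia session.
#'
#' @param hotspot_center `(row, col)` centre of the hotspot, in pixels.
#' @param hotspot_sigma Gaussian width of the hotspot, in pixels.
#' @param n_timepoints number of frames including the reference; between 2
#'   and 17.
#' @param delta_T_peak_per_tp optional numeric vector of peak temperature
#'   rises in degrees Celsius, one per time point (first must be 0). If
#'   `NULL`, a linear ramp `seq(0, peak_delta_T, length.out = n_timepoints)`.
#' @param peak_delta_T peak rise of the default ramp, degrees Celsius.
#' @return A `heating_scenario` list.
#' @export
heating_scenario <- function(hotspot_center, hotspot_sigma, n_timepoints,
                             delta_T_peak_per_tp = NULL, peak_delta_T = 5) {
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 2 || n_timepoints > 17) {
    stop("n_timepoints must be between 2 (reference + 1 heated frame) and 17")
  }
  if (is.null(delta_T_peak_per_tp)) {
    delta_T_peak_per_tp <- seq(0, peak_delta_T, length.out = n_timepoints)
  }
  if (length(delta_T_peak_per_tp) != n_timepoints) {
    stop("delta_T_peak_per_tp must have one entry per time point")
  }
  if (delta_T_peak_per_tp[1] != 0) {
    stop("the first time point is the unheated reference; its peak must be 0")
  }
  if (hotspot_sigma <= 0) stop("hotspot_sigma must be > 0")
  structure(list(hotspot_center = hotspot_center,
                 hotspot_sigma = hotspot_sigma,
                 delta_T_peak_per_tp = delta_T_peak_per_tp,
                 n_timepoints = n_timepoints),
            class = "heating_scenario")
}

#' Injected temperature-rise map of a scenario at one time point
#'
#' @param scenario a [heating_scenario()].
#' @param grid_size image side length in pixels.
#' @param timepoint time point index (1 = reference, all zeros).
#' @return Matrix of temperature rises in degrees Celsius.
#' @export
scenario_delta_T <- function(scenario, grid_size, timepoint) {
  peak <- scenario$delta_T_peak_per_tp[timepoint]
  r0 <- scenario$hotspot_center[1]; c0 <- scenario$hotspot_center[2]
  dr <- matrix(seq_len(grid_size) - r0, grid_size, grid_size)
  dc <- matrix(seq_len(grid_size) - c0, grid_size, grid_size, byrow = TRUE)
  peak * exp(-(dr^2 + dc^2) / (2 * scenario$hotspot_sigma^2))
}

#' Hotspot region of interest
#'
#' Binary mask of voxels where the hotspot Gaussian exceeds half its peak,
#' a simple stand-in for a segmented tumour ROI on synthetic data.
#'
#' @inheritParams scenario_delta_T
#' @return Logical matrix.
#' @export
scenario_roi <- function(scenario, grid_size) {
  r0 <- scenario$hotspot_center[1]; c0 <- scenario$hotspot_center[2]
  dr <- matrix(seq_len(grid_size) - r0, grid_size, grid_size)
  dc <- matrix(seq_len(grid_size) - c0, grid_size, grid_size, byrow = TRUE)
  exp(-(dr^2 + dc^2) / (2 * scenario$hotspot_sigma^2)) >= 0.5
}

#' Simulate a PRF-encoded heating series
#'
#' Frame 1 is the unmodified reference phantom. Frame t multiplies the
#' phantom by `exp(1i * k * dT(v, t))` where `k = gamma * alpha*1e-6 * B0 *
#' TE` is the PRF phase-per-degree slope and `dT(v, t)` the scenario's
#' Gaussian hotspot at time t; magnitudes are unchanged. Phases are NOT
#' unwrapped here -- large rises may wrap, and handling that is the
#' thermometry module's job (complex phase difference).
#'
#' @param phantom a [complex_image()] (or complex matrix).
#' @param scenario a [heating_scenario()].
#' @param constants a [thermo_constants()].
#' @return A `heating_series`: list with `frames` (list of complex images),
#'   `scenario`, `constants`.
#' @export
simulate_heating_series <- function(phantom, scenario, constants) {
  if (!inherits(scenario, "heating_scenario")) stop("scenario must be a heating_scenario")
  if (!inherits(constants, "thermo_constants")) stop("constants must be thermo_constants")
  img <- as_cplx_matrix(phantom)
  if (nrow(img) != ncol(img)) stop("phantom must be square")
  n <- nrow(img)
  k <- prf_phase_per_degC(constants)
  frames <- vector("list", scenario$n_timepoints)
  frames[[1]] <- complex_image(img, TE = constants$TE, B0 = constants$B0)
  for (t in seq(2, scenario$n_timepoints)) {
    dT <- scenario_delta_T(scenario, n, t)
    frames[[t]] <- complex_image(img * exp(1i * k * dT),
                                 TE = constants$TE, B0 = constants$B0)
  }
  structure(list(frames = frames, scenario = scenario, constants = constants),
            class = "heating_series")
}

#' Add circular complex Gaussian noise to an image
#'
#' @param img complex matrix.
#' @param sd per-component standard deviation (absolute units).
#' @return Complex matrix with noise added.
#' @export
add_complex_noise <- function(img, sd) {
  img <- as_cplx_matrix(img)
  img + complex(real = stats::rnorm(length(img), sd = sd),
                imaginary = stats::rnorm(length(img), sd = sd))
}
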