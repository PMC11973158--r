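## Readers and writers.
##
## Complex images travel as NIfTI magnitude/phase pairs (phase stored as
## float radians -- the native dialect); sampling masks as PNG + JSON
## sidecar; heating series as per-timepoint NIfTI pairs + a JSON sidecar
## recording constants and scenario; measured k-space as a NIfTI real/imag
## pair + JSON (no single-channel raw standard exists for this, and the
## sidecar keeps every artifact reproducible from its metadata). Phase
## dialects are declared, never guessed: DICOM-style scaled-integer phase is
## converted with an explicit linear map to [-pi, pi].

#' Read a complex image from a magnitude/phase NIfTI pair
#'
#' `complex = magnitude * exp(1i * phase)`. Phase must be stored in float
#' radians (dialect `"radians"`) or as scaled integers with declared stored
#' range (dialect `"scaled_int"`, converted via [dicom_phase_rescale()]).
#'
#' @param magnitude_path,phase_path NIfTI file paths.
#' @param dialect phase storage dialect: `"radians"` or `"scaled_int"`.
#' @param stored_range length-2 stored-integer range (required for
#'   `"scaled_int"`).
#' @param TE,B0 optional acquisition metadata attached to the result.
#' @return A [complex_image()].
#' @export
read_complex <- function(magnitude_path, phase_path,
                         dialect = c("radians", "scaled_int"),
                         stored_range = NULL, TE = NULL, B0 = NULL) {
  dialect <- match.arg(dialect)
  mag <- drop(as.array(RNifti::readNifti(magnitude_path)))
  ph <- drop(as.array(RNifti::readNifti(phase_path)))
  if (!identical(dim(mag), dim(ph))) {
    stop("magnitude and phase images have different shapes")
  }
  if (dialect == "scaled_int") {
    if (is.null(stored_range)) {
      stop("dialect 'scaled_int' requires `stored_range` rescale metadata")
    }
    ph <- dicom_phase_rescale(ph, stored_range[1], stored_range[2])
  }
  complex_image(mag * exp(1i * ph), TE = TE, B0 = B0)
}

#' Write a complex image as a magnitude/phase NIfTI pair
#'
#' @param img complex image (matrix).
#' @param magnitude_path,phase_path output NIfTI paths.
#' @return Invisibly, the two paths.
#' @export
write_complex <- function(img, magnitude_path, phase_path) {
  img <- as_cplx_matrix(img)
  RNifti::writeNifti(RNifti::asNifti(Mod(img)), magnitude_path)
  RNifti::writeNifti(RNifti::asNifti(Arg(img)), phase_path)
  invisible(c(magnitude_path, phase_path))
}

#' Rescale DICOM-style stored-integer phase to radians
#'
#' Linear map of the declared stored range onto `[-pi, pi]`: the minimum
#' stored value maps to `-pi`, the maximum to `+pi`. The dialect (and its
#' stored range) must be declared by the caller -- vendor conventions differ
#' and are never auto-guessed.
#'
#' @param stored numeric array of stored phase values.
#' @param stored_min,stored_max declared stored-value range.
#' @return Phase in radians, same shape.
#' @export
dicom_phase_rescale <- function(stored, stored_min, stored_max) {
  if (stored_max <= stored_min) stop("stored_max must exceed stored_min")
  -pi + 2 * pi * (stored - stored_min) / (stored_max - stored_min)
}

#' Write / read a sampling mask as PNG + JSON sidecar
#'
#' The PNG holds the binary grid; the sidecar records kind, fraction, centre
#' parameters, shape and seed, so the mask is reproducible from its
#' metadata alone.
#'
#' @param mask a `sampling_mask`.
#' @param png_path,json_path output paths (`read_mask` takes the same pair).
#' @return `write_mask`: invisibly the paths; `read_mask`: a
#'   `sampling_mask`.
#' @export
write_mask <- function(mask, png_path, json_path) {
  png::writePNG(mask$grid, png_path)
  meta <- mask[setdiff(names(mask), "grid")]
  meta$shape <- dim(mask$grid)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, json_path))
}

#' @rdname write_mask
#' @export
read_mask <- function(png_path, json_path) {
  grid <- round(png::readPNG(png_path))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  m <- c(list(grid = grid), meta[setdiff(names(meta), "shape")])
  m$seed <- as.integer(m$seed)
  class(m) <- "sampling_mask"
  m
}

#' Write / read a heating series as NIfTI pairs plus a JSON sidecar
#'
#' One magnitude/phase NIfTI pair per time point (`tp001_mag.nii.gz`, ...)
#' plus `series.json` recording the thermometry constants and the heating
#' scenario.
#'
#' @param series a `heating_series` from [simulate_heating_series()].
#' @param dir output directory (created if needed).
#' @return `write_heating_series`: invisibly `dir`; `read_heating_series`:
#'   a `heating_series`.
#' @export
write_heating_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(series$frames)) {
    write_complex(series$frames[[t]],
                  file.path(dir, sprintf("tp%03d_mag.nii.gz", t)),
                  file.path(dir, sprintf("tp%03d_phase.nii.gz", t)))
  }
  side <- list(n_timepoints = length(series$frames),
               constants = unclass(series$constants),
               scenario = unclass(series$scenario))
  jsonlite::write_json(side, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_heating_series
#' @export
read_heating_series <- function(dir) {
  side_path <- file.path(dir, "series.json")
  if (!file.exists(side_path)) stop("missing series.json sidecar in ", dir)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  cst <- side$constants
  if (is.null(cst$TE) || is.null(cst$B0)) {
    stop("sidecar lacks TE/B0; thermometry is not permitted without them")
  }
  constants <- thermo_constants(gamma = cst$gamma, alpha = cst$alpha,
                                B0 = cst$B0, TE = cst$TE)
  frames <- lapply(seq_len(side$n_timepoints), function(t) {
    read_complex(file.path(dir, sprintf("tp%03d_mag.nii.gz", t)),
                 file.path(dir, sprintf("tp%03d_phase.nii.gz", t)),
                 TE = cst$TE, B0 = cst$B0)
  })
  scn <- side$scenario
  scenario <- heating_scenario(hotspot_center = scn$hotspot_center,
                               hotspot_sigma = scn$hotspot_sigma,
                               n_timepoints = scn$n_timepoints,
                               delta_T_peak_per_tp = scn$delta_T_peak_per_tp)
  structure(list(frames = frames, scenario = scenario, constants = constants),
            class = "heating_series")
}

#' Write / read measured k-space as a NIfTI real/imag pair + JSON sidecar
#'
#' @param measured_k complex k-space matrix.
#' @param mask the acquisition `sampling_mask`.
#' @param prefix output path prefix; writes `<prefix>_real.nii.gz`,
#'   `<prefix>_imag.nii.gz`, `<prefix>_mask.png`, `<prefix>.json`.
#' @return `write_kspace`: invisibly `prefix`; `read_kspace`: list with
#'   `measured_k` and `mask`.
#' @export
write_kspace <- function(measured_k, mask, prefix) {
  measured_k <- as_cplx_matrix(measured_k)
  RNifti::writeNifti(RNifti::asNifti(Re(measured_k)),
                     paste0(prefix, "_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(measured_k)),
                     paste0(prefix, "_imag.nii.gz"))
  write_mask(mask, paste0(prefix, "_mask.png"), paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(prefix) {
  re <- drop(as.array(RNifti::readNifti(paste0(prefix, "_real.nii.gz"))))
  im <- drop(as.array(RNifti::readNifti(paste0(prefix, "_imag.nii.gz"))))
  if (!identical(dim(re), dim(im))) stop("real/imag shapes differ")
  mask <- read_mask(paste0(prefix, "_mask.png"), paste0(prefix, ".json"))
  list(measured_k = matrix(complex(real = re, imaginary = im),
                           nrow(re), ncol(re)),
       mask = mask)
}
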