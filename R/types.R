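#' fourierpd: complex-valued unrolled reconstruction for MR thermometry
#'
#' Accelerated proton-resonance-frequency (PRF) shift thermometry from
#' undersampled Cartesian k-space: variable-density sampling masks, centred
#' orthonormal Fourier transforms, complex-valued unrolled primal-dual
#' networks (Fourier-PDNet / Fourier-PDUNet) with a k-space data-consistency
#' step, PRF temperature mapping, and image-quality metrics.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## round half away from zero (used for exact sampled-point budgets)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Complex-valued MR image
#'
#' A 2D complex matrix in image space, optionally carrying acquisition
#' metadata: voxel size (mm), echo time TE (s) and field strength B0 (T).
#' All package functions also accept a plain complex matrix.
#'
#' @param data complex (or numeric) matrix.
#' @param voxel_size numeric length-2 or length-3 voxel size in mm, or `NULL`.
#' @param TE echo time in seconds, or `NULL`.
#' @param B0 main field strength in tesla, or `NULL`.
#' @return A complex matrix of class `complex_image`.
#' @export
complex_image <- function(data, voxel_size = NULL, TE = NULL, B0 = NULL) {
  if (!is.matrix(data)) stop("complex_image: `data` must be a 2D matrix")
  if (!is.complex(data)) data <- matrix(as.complex(data), nrow(data), ncol(data))
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data)))) {
    stop("complex_image: non-finite values")
  }
  structure(data,
            voxel_size = voxel_size, TE = TE, B0 = B0,
            class = c("complex_image", "matrix"))
}

#' @export
print.complex_image <- function(x, ...) {
  cat(sprintf("<complex_image %d x %d>  |.| in [%.4g, %.4g]",
              nrow(x), ncol(x), min(Mod(x)), max(Mod(x))))
  if (!is.null(attr(x, "TE"))) cat(sprintf("  TE=%.4g s", attr(x, "TE")))
  if (!is.null(attr(x, "B0"))) cat(sprintf("  B0=%.3g T", attr(x, "B0")))
  cat("\n")
  invisible(x)
}

as_cplx_matrix <- function(x) {
  if (!is.matrix(x)) stop("expected a 2D matrix")
  if (!is.complex(x)) x <- matrix(as.complex(x), nrow(x), ncol(x))
  unclass_matrix(x)
}

unclass_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

stopifnot_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}
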