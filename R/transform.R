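#' Arcsinh intensity transform
#'
#' Standard cytometry transform mapping raw fluorescence intensity to
#' `asinh(x / cofactor)`. Near zero it is approximately linear, for large
#' intensities logarithmic, which makes threshold gates well-posed on both
#' dim and bright populations.
#'
#' @param x Numeric vector or matrix of raw intensities.
#' @param cofactor Positive scale parameter; default 150, typical for
#'   conventional (non-spectral) cytometers.
#' @return Transformed values (same shape as `x`).
#' @export
asinhTransform <- function(x, cofactor = 150) {
  stopifnot(cofactor > 0)
  asinh(x / cofactor)
}

#' @rdname asinhTransform
#' @export
asinhInverse <- function(x, cofactor = 150) {
  stopifnot(cofactor > 0)
  sinh(x) * cofactor
}

# Transform fluorescence channels of a raw event matrix, leave scatter as-is.
transformedMatrix <- function(mat, fluorescence, cofactor) {
  fl <- intersect(fluorescence, colnames(mat))
  if (length(fl)) mat[, fl] <- asinh(mat[, fl, drop = FALSE] / cofactor)
  mat
}

# Run code with a fixed RNG state, restoring the caller's state afterwards.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
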