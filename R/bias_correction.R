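# Estimation and removal of smooth multiplicative intensity inhomogeneity.

#' Estimate a multiplicative bias field on one slice
#'
#' The default `"polynomial"` method fits a low-order 2D polynomial to the
#' log-intensities over the supplied tissue mask and exponentiates the fit;
#' this captures the smooth coil-sensitivity inhomogeneity while ignoring
#' structure much finer than the slice (marbling, noise). The `"n4"` method
#' delegates to the N4 algorithm of SimpleITK through the system `python`
#' interpreter. Either way the returned field is normalized to mean 1 over
#' the mask, so correction preserves mean tissue intensity.
#'
#' Pixels outside the mask never influence the estimate; the polynomial (or
#' N4) field is evaluated over the full slice so the correction can be
#' applied everywhere.
#'
#' @param image numeric matrix, non-negative intensities.
#' @param mask logical matrix of the tissue region used for estimation
#'   (typically the leg or the muscle compartment); at least 50 pixels.
#' @param method `"polynomial"` (default) or `"n4"`.
#' @param order total polynomial degree for the polynomial method.
#' @return An object of class `bias_field`: a positive matrix with unit mean
#'   over `mask`, with attributes `method` and `mask_mean` (the normalization
#'   divisor).
#' @export
estimate_bias_field <- function(image, mask, method = c("polynomial", "n4"),
                                order = 3L) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), identical(dim(image), dim(mask)))
  mask <- mask & is.finite(image)
  if (sum(mask) < 50) {
    stop("degenerate mask: fewer than 50 pixels available for bias estimation")
  }
  if (any(image[mask] < 0)) stop("image must be non-negative")
  field <- switch(method,
    polynomial = polynomial_bias_field(image, mask, order),
    n4 = n4_bias_field(image, mask)
  )
  mm <- mean(field[mask])
  field <- field / mm
  structure(field, class = c("bias_field", "matrix", "array"),
            method = method, mask_mean = mm)
}

polynomial_bias_field <- function(image, mask, order) {
  n <- nrow(image)
  m <- ncol(image)
  u <- matrix(seq(-1, 1, length.out = n), n, m)
  v <- matrix(seq(-1, 1, length.out = m), n, m, byrow = TRUE)
  basis <- list()
  for (i in 0:order) {
    for (j in 0:(order - i)) {
      basis[[length(basis) + 1]] <- u^i * v^j
    }
  }
  X <- vapply(basis, function(bb) bb[mask], numeric(sum(mask)))
  eps <- max(image[mask]) * 1e-8 + .Machine$double.eps
  yy <- log(pmax(image[mask], eps))
  beta <- stats::lm.fit(X, yy)$coefficients
  beta[is.na(beta)] <- 0
  logf <- Reduce(`+`, Map(function(bb, b) bb * b, basis, as.list(beta)))
  exp(logf - mean(logf[mask]))
}

# Delegate to SimpleITK's N4 via the python interpreter on PATH; the slice
# and mask travel as NIfTI tempfiles.
n4_bias_field <- function(image, mask) {
  py <- Sys.which("python")
  if (py == "") stop("method 'n4' requires a python interpreter on PATH")
  script <- system.file("python", "n4_correct.py", package = "calfmfi")
  if (script == "") stop("n4_correct.py not found in the installed package")
  td <- tempfile("n4")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fi <- file.path(td, "image.nii.gz")
  fm <- file.path(td, "mask.nii.gz")
  ff <- file.path(td, "field.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(image), fi)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))), fm)
  status <- system2(py, c(script, fi, fm, ff), stdout = TRUE, stderr = TRUE)
  if (!file.exists(ff)) {
    stop("N4 delegation failed: ", paste(status, collapse = "\n"))
  }
  field <- matrix(as.numeric(RNifti::readNifti(ff)), nrow(image), ncol(image))
  field[!is.finite(field) | field <= 0] <- 1
  field
}

#' Apply a bias-field correction
#'
#' Divides the image by the field, element-wise.
#'
#' @param image numeric matrix.
#' @param field a `bias_field` (or positive matrix) of the same shape.
#' @return The corrected matrix.
#' @export
apply_correction <- function(image, field) {
  stopifnot(identical(dim(image), dim(field)))
  if (any(field <= 0)) stop("bias field must be strictly positive")
  out <- image / unclass(field)
  stopifnot(all(is.finite(out)))
  out
}

#' Bias-correct the central slices of a subject stack
#'
#' Estimates and removes the bias field on each requested slice, using the
#' muscle mask for estimation (the tissue whose histogram is analyzed
#' downstream).
#'
#' @param stack a `phantom_stack` (or compatible list with `image`, `masks`).
#' @param slices slice indices to correct (default 2-8, the central seven).
#' @param method,order passed to [estimate_bias_field()].
#' @param estimation_mask which mask layer drives the estimate
#'   (default `"muscle"`).
#' @return A list of corrected slice matrices named by slice index.
#' @export
correct_stack <- function(stack, slices = 2:8,
                          method = c("polynomial", "n4"), order = 3L,
                          estimation_mask = "muscle") {
  method <- match.arg(method)
  out <- lapply(slices, function(s) {
    img <- stack$image[, , s]
    msk <- stack$masks[[estimation_mask]][, , s]
    fld <- estimate_bias_field(img, msk, method = method, order = order)
    apply_correction(img, fld)
  })
  names(out) <- as.character(slices)
  out
}
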