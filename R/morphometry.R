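# Mask morphometry: subcutaneous fat thickness, marrow area, muscle ROI,
# and the segmentation-perturbation operator used for repeatability analysis.

# Sub-pixel closed-contour length (pixels) of a solid binary shape: the mask
# is lightly Gaussian-smoothed and traced at the 0.5 iso-level (marching
# squares with linear interpolation), which removes the staircase bias of
# pixel-edge perimeters.
contour_length_px <- function(mask, smooth_sigma = 1.5) {
  z <- as.matrix(EBImage::gblur(mask + 0, sigma = smooth_sigma))
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (!length(cl)) stop("no iso-contour found (shape too thin or empty)")
  lengths <- vapply(cl, function(co) {
    x <- c(co$x, co$x[1])
    y <- c(co$y, co$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1))
  max(lengths)
}

# Connected-component and hole counts of a binary mask.
mask_topology <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0)
  filled <- EBImage::fillHull(mask + 0)
  holes <- EBImage::bwlabel(filled - (mask + 0))
  list(components = max(lab), holes = max(holes),
       filled = filled > 0, hole_mask = (filled - (mask + 0)) > 0)
}

#' Inner and outer boundary lengths of an annular mask
#'
#' Traces the outer boundary on the hole-filled mask and the inner boundary
#' on the hole itself, both as sub-pixel iso-contours at the 0.5 level of a
#' lightly smoothed mask, and converts to mm.
#'
#' @param mask logical matrix; must be a single annular component with
#'   exactly one hole.
#' @param pixel_size pixel size, mm.
#' @return Named numeric `c(inner = L1, outer = L2)` in mm.
#' @export
boundary_lengths <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask) | is.array(mask))
  topo <- mask_topology(mask)
  if (topo$components != 1 || topo$holes != 1) {
    stop(sprintf("mask is not annular: %d component(s), %d hole(s)",
                 topo$components, topo$holes))
  }
  L2 <- contour_length_px(topo$filled) * pixel_size
  L1 <- contour_length_px(topo$hole_mask) * pixel_size
  c(inner = L1, outer = L2)
}

#' Subject subcutaneous fat thickness from the central seven slices
#'
#' Per slice, SFT_i = 2 A_i / (L1 + L2)_i with the area from the pixel count
#' and the boundary lengths from sub-pixel contours; the subject SFT is the
#' arithmetic mean over the seven central slices.
#'
#' @param sf_masks list of exactly 7 logical matrices (slices 2-8 of a
#'   9-slice stack, 1-based), each a single annulus.
#' @param pixel_size pixel size, mm.
#' @return A list with `sft` (mm), and per-slice vectors `sft_slice`,
#'   `area`, `inner_length`, `outer_length` (named by slice).
#' @export
compute_sft <- function(sf_masks, pixel_size) {
  stopifnot(length(sf_masks) == 7)
  if (is.null(names(sf_masks))) names(sf_masks) <- as.character(2:8)
  per <- lapply(names(sf_masks), function(s) {
    m <- sf_masks[[s]]
    L <- tryCatch(boundary_lengths(m, pixel_size),
                  error = function(e) stop(sprintf("slice %s: %s", s, conditionMessage(e)),
                                           call. = FALSE))
    A <- sum(m) * pixel_size^2
    c(area = A, inner = L[["inner"]], outer = L[["outer"]],
      sft = 2 * A / (L[["inner"]] + L[["outer"]]))
  })
  per <- do.call(rbind, per)
  rownames(per) <- names(sf_masks)
  list(sft = mean(per[, "sft"]),
       sft_slice = per[, "sft"],
       area = per[, "area"],
       inner_length = per[, "inner"],
       outer_length = per[, "outer"])
}

#' Subject fibula bone-marrow area from the central seven slices
#'
#' @param marrow_masks list of exactly 7 logical matrices, each a non-empty
#'   single component.
#' @param pixel_size pixel size, mm.
#' @return A list with `bma` (mm^2) and the per-slice vector `bma_slice`.
#' @export
compute_bma <- function(marrow_masks, pixel_size) {
  stopifnot(length(marrow_masks) == 7)
  if (is.null(names(marrow_masks))) names(marrow_masks) <- as.character(2:8)
  areas <- vapply(names(marrow_masks), function(s) {
    m <- marrow_masks[[s]]
    if (sum(m) == 0) stop(sprintf("slice %s: empty marrow mask", s), call. = FALSE)
    sum(m) * pixel_size^2
  }, numeric(1))
  list(bma = mean(areas), bma_slice = areas)
}

#' Peripheral calf-muscle ROI inferior to the fibula
#'
#' The ROI is the muscle mask restricted to rows strictly below a horizontal
#' line through the fibula centroid (rows grow inferiorly); the centroid row
#' is computed on the full fibula mask (cortex plus marrow) and rounded
#' half-down.
#'
#' @param muscle_mask logical matrix.
#' @param fibula_mask logical matrix (cortex and marrow), non-empty.
#' @param min_pixels below this ROI size a warning is recorded (result still
#'   returned).
#' @return Logical ROI matrix with attribute `centroid_row`.
#' @export
derive_muscle_roi <- function(muscle_mask, fibula_mask, min_pixels = 100L) {
  stopifnot(identical(dim(muscle_mask), dim(fibula_mask)))
  if (!any(fibula_mask)) stop("fibula mask is empty")
  cr <- mean(row(fibula_mask)[fibula_mask])
  r0 <- ceiling(cr - 0.5) # round half-down
  roi <- muscle_mask & (row(muscle_mask) > r0)
  if (sum(roi) < min_pixels) {
    warning(sprintf("muscle ROI has only %d pixels (< %d)", sum(roi), min_pixels))
  }
  attr(roi, "centroid_row") <- r0
  roi
}

#' Randomly perturb a segmentation mask boundary
#'
#' Emulates manual-redraw variability: the mask boundary is displaced by a
#' smooth zero-mean random field with standard deviation `magnitude` pixels,
#' applied through the signed Euclidean distance transform (so the local
#' boundary displacement equals the field value). Retries with fresh fields
#' if the perturbation changes the mask's topology.
#'
#' @param mask logical matrix.
#' @param magnitude boundary displacement sd, pixels; 0 returns the mask
#'   unchanged.
#' @param seed integer seed.
#' @param smooth_px correlation length of the displacement field, pixels.
#' @param max_retry attempts before giving up.
#' @return Perturbed logical matrix.
#' @export
perturb_mask <- function(mask, magnitude, seed = 1L, smooth_px = 6,
                         max_retry = 5L) {
  stopifnot(magnitude >= 0)
  mask <- mask > 0
  if (magnitude == 0) return(mask)
  d <- as.matrix(EBImage::distmap(mask + 0)) -
    as.matrix(EBImage::distmap(1 - mask))
  topo0 <- mask_topology(mask)
  for (attempt in seq_len(max_retry)) {
    disp <- with_seed(derive_seed(seed, "perturb", attempt),
                      smooth_random_field(nrow(mask), ncol(mask), smooth_px))
    out <- (d + magnitude * disp) > 0
    topo <- mask_topology(out)
    if (topo$components == topo0$components && topo$holes == topo0$holes) {
      return(out)
    }
  }
  stop(sprintf("perturbation destroyed mask topology in %d attempts", max_retry))
}
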