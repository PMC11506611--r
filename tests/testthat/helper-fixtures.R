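# Shared fixtures: small, fast phantom specs and analytic masks built in code.

# Compact phantom used by most tests: 128 px, small leg, mild noise.
small_spec <- function(...) {
  args <- utils::modifyList(
    list(image_size = 128L, leg_radius = 28, sf_thickness = 5,
         fibula_center = c(-8, 11), marrow_area = 30, noise_sigma = 4),
    list(...))
  do.call(phantom_spec, args)
}

small_truth <- function(id = "T001", sex = "F", age = 50, bmi = 30,
                        sft = 5, bma = 30, ff = 0.15,
                        severity = "mild", seed = 42L) {
  subject_truth(id, sex, age, bmi, sft, bma, ff, severity, seed = seed)
}

# Analytic circular annulus mask: inner radius rin_mm, thickness t_mm.
circle_annulus <- function(n = 192, rin_mm = 30, t_mm = 5, px = 0.7) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")) * px
  d > rin_mm & d <= rin_mm + t_mm
}

# Analytic disk mask of a given area (mm^2), optionally off-center.
circle_disk <- function(n = 96, area_mm2 = 36, px = 0.7, center = NULL) {
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  r <- sqrt(area_mm2 / pi)
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2) * px <= r
}

# Wrap a curve evaluated on a grid as a histogram_profile (integral 100).
as_profile <- function(x, y, bin_width = x[2] - x[1]) {
  structure(list(x = x, y = y * 100 / pracma::trapz(x, y),
                 bin_width = bin_width, n_slices_used = 1L,
                 provenance = "synthetic"),
            class = "histogram_profile")
}

# Noiseless lineshape profile on a grid.
lineshape_profile <- function(x0 = 200, fwhm = 80, h = 1, b = 0,
                              bin_width = 2, lo = 0, hi = 500) {
  x <- seq(lo, hi, by = bin_width)
  w <- pmax(fwhm + b * x, 1e-9)
  y <- h * exp(-4 * log(2) * (x - x0)^2 / w^2)
  as_profile(x, y, bin_width)
}
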