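# Internal helpers: seeded RNG scoping, seed derivation, truncated normals,
# smooth random fields, quota allocation.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
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
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and labels
#'
#' Deterministic 31-bit hash of the parent seed plus any mix of integer or
#' character labels (stage names, subject ids, slice indices). Decouples the
#' random streams of pipeline stages and subjects.
#'
#' @param seed parent integer seed.
#' @param ... integer or character labels folded into the stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483629 # prime < 2^31
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    ks <- if (is.character(part)) utf8ToInt(paste(part, collapse = "\r")) else as.numeric(part)
    for (k in ks) {
      h <- (h * 131 + (k %% m) + 17) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# Quantile function of a normal truncated to [lower, upper].
qtruncnorm <- function(p, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

# iid draws from a truncated normal via inverse transform.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  qtruncnorm(stats::runif(n), mean, sd, lower, upper)
}

# Stratified draw from a truncated normal: one value per quantile stratum
# (rank-randomized), so sample moments track the population's closely.
# method "random" falls back to iid sampling.
draw_truncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                           method = c("quantile", "random")) {
  method <- match.arg(method)
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  if (method == "random") {
    rtruncnorm(n, mean, sd, lower, upper)
  } else {
    p <- (sample.int(n) - 0.5) / n
    qtruncnorm(p, mean, sd, lower, upper)
  }
}

# Mean of a normal truncated below at `lower` (used for documentation of
# planted-cohort expectations, not for fitting).
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Largest-remainder (Hamilton) integer allocation of n among proportions p.
quota_allocation <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9, n >= 0)
  raw <- n * p
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Smooth zero-mean unit-sd Gaussian random field: white noise blurred with an
# isotropic Gaussian kernel of standard deviation sigma_px, then restandardized.
smooth_random_field <- function(nrow, ncol, sigma_px) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (sigma_px > 0) {
    z <- as.matrix(EBImage::gblur(z, sigma = sigma_px))
  }
  (z - mean(z)) / stats::sd(as.vector(z))
}

# Trapezoidal integral of y over x.
trapz_xy <- function(x, y) pracma::trapz(x, y)
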