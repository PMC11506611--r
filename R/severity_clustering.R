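# PCA-guided feature selection and Fuzzy C-Means severity clustering.

#' Assemble a standardized MFI feature table
#'
#' @param subject_id character ids.
#' @param features numeric matrix or data.frame with columns
#'   `mean_intensity`, `mode_intensity`, `fwhm`.
#' @return An object of class `feature_table`: list with `subject_id`, `raw`
#'   matrix and `z` (column-wise z-scored copy).
#' @export
feature_table <- function(subject_id, features) {
  m <- as.matrix(features)
  stopifnot(nrow(m) == length(subject_id), !anyNA(m))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(list(subject_id = as.character(subject_id), raw = m, z = z),
            class = "feature_table")
}

#' Rank features by PCA loading mass and select the top two
#'
#' PCA is run on the z-scored features; the number of components `k` is the
#' smallest count whose cumulative explained-variance ratio reaches 0.95;
#' each feature's importance is the sum of the absolute values of its
#' loadings over those `k` components. Loadings are sign-fixed (largest
#' magnitude entry positive) so the decomposition is deterministic.
#'
#' @param table a [feature_table()].
#' @param variance_target cumulative explained-variance threshold.
#' @return An object of class `pca_selection`: list with `loadings`,
#'   `explained_ratio`, `k`, `importance`, `ranking`, `top2`.
#' @export
select_features <- function(table, variance_target = 0.95) {
  stopifnot(inherits(table, "feature_table"), nrow(table$z) >= 3)
  n <- nrow(table$z)
  covz <- crossprod(table$z) / (n - 1) # correlation matrix of the raw features
  eg <- eigen(covz, symmetric = TRUE)
  rot <- eg$vectors
  dimnames(rot) <- list(colnames(table$z), paste0("PC", seq_len(ncol(rot))))
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ratio <- pmax(eg$values, 0) / sum(pmax(eg$values, 0))
  k <- which(cumsum(ratio) >= variance_target - 1e-12)[1]
  importance <- rowSums(abs(rot[, seq_len(k), drop = FALSE]))
  ranking <- names(sort(importance, decreasing = TRUE))
  structure(list(loadings = rot, explained_ratio = ratio, k = k,
                 importance = importance, ranking = ranking,
                 top2 = ranking[1:2]),
            class = "pca_selection")
}

# Squared Euclidean distances between rows of x (n x p) and v (c x p).
sqdist <- function(x, v) {
  outer(rowSums(x^2), rep(1, nrow(v))) +
    outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * x %*% t(v)
}

fcm_memberships <- function(d2, m) {
  d2 <- pmax(d2, 0)
  n <- nrow(d2)
  U <- matrix(0, n, ncol(d2))
  zero <- d2 < 1e-300
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  if (any(!hit)) {
    w <- d2[!hit, , drop = FALSE]^(-1 / (m - 1))
    U[!hit, ] <- w / rowSums(w)
  }
  U
}

#' Fuzzy C-Means clustering
#'
#' Alternating optimization of the fuzzy objective
#' `J = sum_i sum_j u_ij^m ||x_i - v_j||^2` with the standard membership and
#' centroid updates, run from `n_restarts` seeded random initializations and
#' keeping the solution with the lowest objective. A point coinciding with a
#' centroid receives full membership in that centroid.
#'
#' @param x numeric matrix (subjects x features).
#' @param c number of clusters, `2 <= c < n`.
#' @param m fuzzifier, `> 1`.
#' @param tol convergence threshold on `max |U - U_prev|`.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @param n_restarts random restarts.
#' @return An object of class `fcm_result`: list with `U` (n x c membership
#'   matrix), `V` (c x p centroids), `J`, `J_path` (objective per iteration of
#'   the winning restart), `iterations`, `c`, `m`, `seed`.
#' @export
fcm_cluster <- function(x, c, m = 2, tol = 1e-5, max_iter = 1000L, seed = 1L,
                        n_restarts = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n > c, c >= 2, m > 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    v0 <- with_seed(derive_seed(seed, "fcm-restart", r), {
      idx <- sample.int(n, c)
      x[idx, , drop = FALSE] + matrix(stats::rnorm(c * ncol(x), 0, 1e-6), c)
    })
    V <- v0
    U <- fcm_memberships(sqdist(x, V), m)
    J_path <- numeric(0)
    for (it in seq_len(max_iter)) {
      Um <- U^m
      V <- (t(Um) %*% x) / colSums(Um)
      d2 <- sqdist(x, V)
      U_new <- fcm_memberships(d2, m)
      J_path <- c(J_path, sum(U_new^m * pmax(d2, 0)))
      delta <- max(abs(U_new - U))
      U <- U_new
      if (delta < tol) break
    }
    J <- J_path[length(J_path)]
    if (is.null(best) || J < best$J) {
      best <- list(U = U, V = V, J = J, J_path = J_path, iterations = it)
    }
  }
  structure(c(best, list(c = c, m = m, seed = as.integer(seed))),
            class = "fcm_result")
}

# --- exact 2D linear separability -------------------------------------------

orient <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

hull_points <- function(p) {
  p <- unique(round(p, 12))
  if (nrow(p) <= 2) return(p)
  idx <- grDevices::chull(p)
  p[idx, , drop = FALSE]
}

segments_of <- function(h) {
  k <- nrow(h)
  if (k == 1) return(list(rbind(h[1, ], h[1, ])))
  lapply(seq_len(k), function(i) rbind(h[i, ], h[i %% k + 1, ]))
}

seg_intersect <- function(s1, s2) {
  p1 <- s1[1, ]; p2 <- s1[2, ]; p3 <- s2[1, ]; p4 <- s2[2, ]
  d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) {
    abs(orient(p, q, r)) < 1e-12 &&
      min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
      min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  on_seg(p3, p4, p1) || on_seg(p3, p4, p2) || on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
}

point_in_hull <- function(pt, h) {
  k <- nrow(h)
  if (k == 1) return(all(abs(pt - h[1, ]) < 1e-12))
  if (k == 2) {
    return(seg_intersect(rbind(pt, pt), h))
  }
  signs <- vapply(seq_len(k), function(i) orient(h[i, ], h[i %% k + 1, ], pt),
                  numeric(1))
  all(signs >= -1e-12) || all(signs <= 1e-12)
}

hulls_disjoint <- function(pa, pb) {
  ha <- hull_points(pa)
  hb <- hull_points(pb)
  for (sa in segments_of(ha)) {
    for (sb in segments_of(hb)) {
      if (seg_intersect(sa, sb)) return(FALSE)
    }
  }
  if (point_in_hull(ha[1, ], hb)) return(FALSE)
  if (point_in_hull(hb[1, ], ha)) return(FALSE)
  TRUE
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

# Exact distance between two disjoint convex hulls in 2D.
hull_distance <- function(pa, pb) {
  ha <- hull_points(pa)
  hb <- hull_points(pb)
  d <- Inf
  for (sb in segments_of(hb)) {
    for (i in seq_len(nrow(ha))) {
      d <- min(d, point_segment_distance(ha[i, ], sb[1, ], sb[2, ]))
    }
  }
  for (sa in segments_of(ha)) {
    for (i in seq_len(nrow(hb))) {
      d <- min(d, point_segment_distance(hb[i, ], sa[1, ], sa[2, ]))
    }
  }
  d
}

#' Pairwise linear separability of labeled 2D clusters
#'
#' Two clusters are called linearly separable when their convex hulls are
#' disjoint (decided exactly with orientation tests; no classifier is
#' trained) *and* the gap between the hulls exceeds a resolvable margin.
#' The margin qualifier is essential for hard labels derived from a fuzzy
#' (or any nearest-centroid) partition: those are Voronoi cells, which are
#' always zero-margin separable by construction, so the unqualified
#' feasibility test cannot reject any candidate clustering. A genuine
#' cluster structure leaves a gap between groups; an over-split cluster
#' does not. One-dimensional data are handled as disjoint intervals.
#'
#' @param x numeric matrix with 1 or 2 columns.
#' @param labels cluster labels, length `nrow(x)`.
#' @param margin required hull gap, in units of the data's root-mean
#'   per-coordinate variance (so 0.1 means a tenth of the pooled spread);
#'   `margin = 0` reduces to pure feasibility.
#' @return A list with `pairwise` (logical matrix), `distance` (pairwise
#'   hull gaps, 0 where hulls intersect), and `separable` (overall flag:
#'   all pairs separable).
#' @export
assess_separability <- function(x, labels, margin = 0.1) {
  x <- as.matrix(x)
  stopifnot(ncol(x) %in% c(1, 2), nrow(x) == length(labels), margin >= 0)
  labs <- sort(unique(labels))
  stopifnot(length(labs) >= 2)
  if (ncol(x) == 1) x <- cbind(x, 0)
  scale <- sqrt(mean(apply(x, 2, stats::var)))
  if (!is.finite(scale) || scale == 0) scale <- 1
  k <- length(labs)
  pw <- matrix(TRUE, k, k, dimnames = list(labs, labs))
  dist <- matrix(Inf, k, k, dimnames = list(labs, labs))
  diag(dist) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pa <- x[labels == labs[i], , drop = FALSE]
      pb <- x[labels == labs[j], , drop = FALSE]
      disjoint <- hulls_disjoint(pa, pb)
      gap <- if (disjoint) hull_distance(pa, pb) else 0
      ok <- disjoint && gap > margin * scale
      pw[i, j] <- pw[j, i] <- ok
      dist[i, j] <- dist[j, i] <- gap
    }
  }
  list(pairwise = pw, distance = dist, separable = all(pw[upper.tri(pw)]))
}

#' Choose the cluster count by the separability rule
#'
#' Runs FCM for each candidate count and keeps the largest candidate whose
#' hard-label solution is linearly separable; because the objective falls
#' with the cluster count, this is the separable solution with the lowest
#' objective. If no candidate is separable, the smallest candidate is
#' returned with a warning.
#'
#' @param x numeric matrix (subjects x 2 features).
#' @param candidates candidate cluster counts.
#' @param m fuzzifier.
#' @param seed integer seed.
#' @param ... passed to [fcm_cluster()].
#' @return A list with `c` (chosen count), `diagnostics` (data.frame with
#'   one row per candidate: `c`, `J`, `separable`), and `fits` (the
#'   `fcm_result`s, named by candidate).
#' @export
choose_cluster_count <- function(x, candidates = c(3L, 4L, 5L), m = 2,
                                 seed = 1L, ...) {
  x <- as.matrix(x)
  stopifnot(nrow(x) > 5)
  fits <- list()
  rows <- lapply(candidates, function(cc) {
    fit <- fcm_cluster(x, cc, m = m, seed = derive_seed(seed, "candidate", cc), ...)
    fits[[as.character(cc)]] <<- fit
    hard <- max.col(fit$U)
    sep <- assess_separability(x, hard)$separable
    data.frame(c = cc, J = fit$J, separable = sep)
  })
  diag <- do.call(rbind, rows)
  if (any(diag$separable)) {
    chosen <- max(diag$c[diag$separable])
  } else {
    chosen <- min(diag$c)
    warning("no candidate cluster count is linearly separable; returning the smallest")
  }
  list(c = chosen, diagnostics = diag, fits = fits)
}

#' Order clusters into severity labels
#'
#' Hard-assigns each subject to its maximum-membership cluster and renames
#' clusters in ascending order of the centroid's mean-intensity coordinate
#' (ties broken by the mode coordinate): normal, mild, moderate, severe
#' (and very_severe for 5 clusters). Optionally computes a population-average
#' histogram profile per severity group.
#'
#' @param fcm an `fcm_result` fitted on features whose first column is the
#'   (z-scored) mean intensity and second the mode intensity.
#' @param profiles optional list of `histogram_profile`s, one per subject.
#' @param subject_id optional ids (defaults to row numbers).
#' @return An object of class `severity_labels`: list with `label` (ordered
#'   factor per subject), `cluster_order`, `centroids` (ordered), and
#'   `group_profiles` (named list, possibly of `NULL`s).
#' @export
assign_severity <- function(fcm, profiles = NULL, subject_id = NULL) {
  stopifnot(inherits(fcm, "fcm_result"))
  hard <- max.col(fcm$U)
  V <- fcm$V
  tie <- if (ncol(V) >= 2) V[, 2] else rep(0, nrow(V))
  ord <- order(V[, 1], tie)
  lv <- severity_levels(fcm$c)
  rank_of <- match(seq_len(fcm$c), ord)
  label <- factor(lv[rank_of[hard]], levels = lv, ordered = TRUE)
  if (is.null(subject_id)) subject_id <- seq_along(hard)
  empty <- setdiff(lv, as.character(unique(label)))
  if (length(empty)) {
    warning("empty severity group(s): ", paste(empty, collapse = ", "))
  }
  group_profiles <- stats::setNames(vector("list", fcm$c), lv)
  if (!is.null(profiles)) {
    stopifnot(length(profiles) == length(hard))
    for (g in lv) {
      idx <- which(label == g)
      if (length(idx)) group_profiles[[g]] <- average_profiles(profiles[idx])
    }
  }
  structure(list(label = stats::setNames(label, subject_id),
                 cluster_order = ord,
                 centroids = V[ord, , drop = FALSE],
                 group_profiles = group_profiles),
            class = "severity_labels")
}

#' Population-average of histogram profiles
#'
#' Interpolates each profile onto the union grid (0 outside its support),
#' averages pointwise, and renormalizes the integral to 100.
#'
#' @param profiles list of `histogram_profile`s.
#' @return A `histogram_profile`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  bw <- min(vapply(profiles, function(p) p$bin_width, numeric(1)))
  lo <- min(vapply(profiles, function(p) min(p$x), numeric(1)))
  hi <- max(vapply(profiles, function(p) max(p$x), numeric(1)))
  x <- seq(lo, hi, by = bw)
  ys <- vapply(profiles, function(p) {
    stats::approx(p$x, p$y, xout = x, yleft = 0, yright = 0)$y
  }, numeric(length(x)))
  y <- rowMeans(as.matrix(ys))
  structure(list(x = x, y = y * 100 / trapz_xy(x, y), bin_width = bw,
                 n_slices_used = NA_integer_,
                 provenance = sprintf("population average of %d profiles",
                                      length(profiles))),
            class = "histogram_profile")
}
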