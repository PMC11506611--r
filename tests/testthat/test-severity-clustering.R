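# PCA feature selection, FCM clustering, separability, severity assignment.

# Angle-sweep separability oracle: project on many directions and look for an
# interval separation (sufficient check used on the separable fixtures).
sweep_separable <- function(a, b, n_angles = 3600) {
  for (th in seq(0, pi, length.out = n_angles)) {
    d <- c(cos(th), sin(th))
    pa <- a %*% d
    pb <- b %*% d
    if (max(pa) < min(pb) || max(pb) < min(pa)) return(TRUE)
  }
  FALSE
}

test_that("feature tables are z-scored exactly and reject constant columns", {
  set.seed(1)
  m <- cbind(mean_intensity = rnorm(30, 150, 20),
             mode_intensity = rnorm(30, 120, 10),
             fwhm = rnorm(30, 40, 5))
  ft <- feature_table(sprintf("s%02d", 1:30), m)
  expect_true(all(abs(colMeans(ft$z)) < 1e-10))
  expect_true(all(abs(apply(ft$z, 2, sd) - 1) < 1e-10))
  m2 <- m
  m2[, "fwhm"] <- 40
  expect_error(feature_table(sprintf("s%02d", 1:30), m2), "constant feature")
})

test_that("feature importance agrees with a brute-force PCA oracle", {
  set.seed(3)
  f <- rnorm(200)
  m <- cbind(mean_intensity = f + rnorm(200, 0, 0.01),
             mode_intensity = f + rnorm(200, 0, 0.01),
             fwhm = rnorm(200))
  ft <- feature_table(sprintf("s%03d", 1:200), m)
  sel <- select_features(ft)

  # independent oracle: svd-based PCA of the z-scored data, same importance rule
  pc <- prcomp(ft$z, center = FALSE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ratio) >= 0.95)[1]
  imp <- rowSums(abs(pc$rotation[, seq_len(k), drop = FALSE]))
  expect_equal(sel$k, k)
  expect_equal(unname(sel$importance[names(imp)]), unname(imp), tolerance = 1e-8)
  expect_equal(sel$top2, names(sort(imp, decreasing = TRUE))[1:2])
  expect_lt(abs(sum(sel$explained_ratio) - 1), 1e-12)
})

test_that("exchangeable features with a dominant shared factor get equal importance", {
  set.seed(4)
  f <- rnorm(400)
  m <- cbind(mean_intensity = f + rnorm(400, 0, 1e-3),
             mode_intensity = f + rnorm(400, 0, 1e-3),
             fwhm = f + rnorm(400, 0, 1e-3))
  sel <- select_features(feature_table(sprintf("s%03d", 1:400), m))
  expect_equal(sel$k, 1)
  expect_lt(diff(range(sel$importance)), 1e-6)
})

test_that("FCM recovers well-separated clouds and matches the k-means partition", {
  set.seed(6)
  x <- rbind(cbind(rnorm(40, -5), rnorm(40, -5)),
             cbind(rnorm(40, 5), rnorm(40, 5)))
  fit <- fcm_cluster(x, c = 2, m = 2, seed = 9L)
  expect_true(all(abs(rowSums(fit$U) - 1) < 1e-9))
  expect_true(all(fit$U >= 0 & fit$U <= 1))
  expect_true(all(apply(fit$U, 1, max) > 0.95))
  hard <- max.col(fit$U)
  km <- kmeans(x, centers = 2, nstart = 10)
  expect_true(abs(mean((hard == hard[1]) == (km$cluster == km$cluster[1]))) %in% c(0, 1))
  # independent FCM implementation agrees on the centroids
  cm <- e1071::cmeans(x, centers = 2, m = 2)
  v_ours <- fit$V[order(fit$V[, 1]), ]
  v_ref <- cm$centers[order(cm$centers[, 1]), ]
  expect_equal(unname(v_ours), unname(v_ref), tolerance = 1e-3)
})

test_that("a point equidistant from two symmetric clusters splits its membership", {
  x <- cbind(c(-1, -1.05, -0.95, 1, 1.05, 0.95, 0), rep(0, 7))
  fit <- fcm_cluster(x, c = 2, m = 2, seed = 2L)
  expect_equal(unname(fit$U[7, ]), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("the FCM objective is monotone non-increasing over iterations", {
  set.seed(13)
  x <- cbind(rnorm(60), rnorm(60))
  fit <- fcm_cluster(x, c = 3, m = 2, seed = 5L)
  expect_true(all(diff(fit$J_path) <= 1e-9))
})

test_that("a point coincident with a centroid takes full membership there", {
  d2 <- rbind(c(0, 4), c(1, 1), c(4, 0))
  U <- calfmfi:::fcm_memberships(d2, m = 2)
  expect_equal(U[1, ], c(1, 0))
  expect_equal(U[3, ], c(0, 1))
  expect_equal(U[2, ], c(0.5, 0.5))
})

test_that("near-crisp FCM reproduces the k-means partition on separated data", {
  set.seed(14)
  x <- rbind(cbind(rnorm(30, 0), rnorm(30, 0)),
             cbind(rnorm(30, 8), rnorm(30, 8)),
             cbind(rnorm(30, -8), rnorm(30, 8)))
  fit <- fcm_cluster(x, c = 3, m = 1.05, seed = 3L)
  hard <- max.col(fit$U)
  km <- kmeans(x, centers = 3, nstart = 20)
  expect_equal(length(unique(paste(hard, km$cluster))), 3)
})

test_that("linear separability is decided exactly", {
  # two disjoint intervals on a line
  x1 <- cbind(c(seq(0, 1, length.out = 10), seq(3, 4, length.out = 10)))
  lab1 <- rep(1:2, each = 10)
  s1 <- assess_separability(x1, lab1)
  expect_true(s1$separable)
  # interleaved XOR pattern
  xor <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  s2 <- assess_separability(xor, c(1, 1, 2, 2))
  expect_false(s2$separable)
  # random labels on one Gaussian cloud
  set.seed(15)
  cloud <- cbind(rnorm(100), rnorm(100))
  s3 <- assess_separability(cloud, sample(1:2, 100, replace = TRUE))
  expect_false(s3$separable)
  # separable 2D clouds: agree with the angle-sweep oracle
  a <- cbind(rnorm(40, 0, 0.5), rnorm(40, 0, 0.5))
  b <- cbind(rnorm(40, 4, 0.5), rnorm(40, 4, 0.5))
  s4 <- assess_separability(rbind(a, b), rep(1:2, each = 40))
  expect_true(s4$separable)
  expect_true(sweep_separable(a, b))
})

test_that("the cluster count follows the separability rule", {
  set.seed(16)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  x <- do.call(rbind, lapply(1:4, function(k) {
    cbind(rnorm(25, centers[k, 1], 0.4), rnorm(25, centers[k, 2], 0.4))
  }))
  pick <- choose_cluster_count(x, seed = 4L)
  expect_equal(pick$c, 4)
  expect_equal(nrow(pick$diagnostics), 3)
  expect_named(pick$diagnostics, c("c", "J", "separable"))
  expect_true(all(diff(pick$diagnostics$J) < 0)) # J falls with c

  # a dense single Gaussian cloud is not separable at any candidate
  y <- cbind(rnorm(300), rnorm(300))
  expect_warning(pick2 <- choose_cluster_count(y, seed = 4L), "no candidate")
  expect_equal(pick2$c, 3)
})

test_that("severity labels follow the ascending mean-intensity centroid order", {
  fake <- structure(list(
    U = rbind(c(0.9, 0.05, 0.03, 0.02), c(0.1, 0.7, 0.1, 0.1),
              c(0.05, 0.1, 0.85, 0), c(0.01, 0.04, 0.05, 0.9)),
    V = rbind(c(300, 1), c(150, 0), c(500, 2), c(220, 0.5)),
    J = 1, J_path = 1, iterations = 1, c = 4L, m = 2, seed = 1L),
    class = "fcm_result")
  sev <- assign_severity(fake)
  expect_equal(as.character(sev$label),
               c("moderate", "normal", "severe", "mild"))
  expect_true(all(diff(sev$centroids[, 1]) > 0))
})

test_that("planted 4-level feature clouds are recovered with >= 90% agreement", {
  set.seed(17)
  lv <- severity_levels(4)
  n_per <- c(45, 45, 15, 2)
  mu <- rbind(c(115, 105), c(144, 115), c(187, 130), c(263, 162))
  x <- do.call(rbind, lapply(1:4, function(k) {
    cbind(rnorm(n_per[k], mu[k, 1], 2), rnorm(n_per[k], mu[k, 2], 2))
  }))
  planted <- factor(rep(lv, n_per), levels = lv, ordered = TRUE)
  z <- scale(x)
  fit <- fcm_cluster(z, c = 4, m = 2, seed = 8L)
  sev <- assign_severity(fit)
  expect_gte(mean(as.character(sev$label) == as.character(planted)), 0.90)
})

test_that("severity labels are invariant to feature order and affine rescaling", {
  set.seed(18)
  x <- rbind(cbind(rnorm(30, 100, 3), rnorm(30, 90, 3)),
             cbind(rnorm(30, 200, 3), rnorm(30, 150, 3)))
  run <- function(m) {
    z <- scale(m)
    assign_severity(fcm_cluster(z, c = 2, m = 2, seed = 6L))$label
  }
  base <- run(x)
  rescaled <- run(cbind(10 * x[, 1] + 5, 10 * x[, 2] + 5))
  expect_equal(as.character(base), as.character(rescaled))
})

test_that("mean-only (single feature) clustering yields comparable groups", {
  set.seed(19)
  n_per <- c(45, 45, 15, 2)
  mu <- c(115, 144, 187, 263)
  x1 <- matrix(unlist(lapply(1:4, function(k) rnorm(n_per[k], mu[k], 2.5))),
               ncol = 1)
  z <- scale(x1)
  fit <- fcm_cluster(z, c = 4, m = 2, seed = 12L)
  hard <- max.col(fit$U)
  ord <- order(fit$V[, 1])
  counts <- as.vector(table(factor(match(hard, ord), levels = 1:4)))
  expect_equal(counts, n_per, tolerance = 0.15)
})
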