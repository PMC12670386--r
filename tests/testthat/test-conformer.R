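# O-O distance descriptor, cis/trans classification, conformer PCA and
# k-means clustering with medoid centroids.

make_lig_traj <- function(frames, times = seq_along(frames) - 1) {
  atoms <- data.frame(serial = 1:6,
                      name = c("C1", "C2", "C3", "C4", "O1", "O2"),
                      element = c("C", "C", "C", "C", "O", "O"),
                      resid = 1L, resname = "DKE", chain = "L",
                      stringsAsFactors = FALSE)
  trajectory(topology(atoms), frames, times = times)
}

base_lig <- function() {
  rbind(c(-0.2, -0.1, 0), c(-0.07, 0, 0), c(0.07, 0, 0), c(0.2, -0.1, 0),
        c(-0.1, 0.12, 0), c(0.1, 0.12, 0.02))
}

test_that("oo_distance_series matches direct norms", {
  f1 <- base_lig(); f1[5, ] <- c(0, 0, 0); f1[6, ] <- c(0, 0, 0.35)
  f2 <- base_lig(); f2[6, ] <- f2[5, ]
  set.seed(20)
  f3 <- matrix(rnorm(18), ncol = 3)
  traj <- make_lig_traj(list(f1, f2, f3))
  d <- oo_distance_series(traj, c(5, 6))
  expect_equal(d[1], 0.35)
  expect_equal(d[2], 0)
  expect_equal(d[3], sqrt(sum((f3[5, ] - f3[6, ])^2)))
  expect_error(oo_distance_series(traj, c(5, 99)), "not found")
})

test_that("cis/trans classification uses the inclusive 0.32 nm boundary", {
  expect_equal(classify_cis_trans(0.35), "trans")
  expect_equal(classify_cis_trans(0.32), "cis")
  expect_equal(classify_cis_trans(0.10), "cis")
  expect_error(classify_cis_trans(-0.1), "negative")

  # threshold monotonicity: d1 <= d2 cis implies d1 cis
  set.seed(21)
  d <- sort(runif(50, 0, 0.6))
  lab <- classify_cis_trans(d)
  last_cis <- max(which(lab == "cis"))
  expect_true(all(lab[seq_len(last_cis)] == "cis"))
})

test_that("cis and trans fractions are complementary and recover truth", {
  f <- base_lig()
  trans_frames <- replicate(10, {
    g <- f; g[5, ] <- c(0, 0, 0); g[6, ] <- c(0, 0, 0.35); g
  }, simplify = FALSE)
  s <- conformer_series(make_lig_traj(trans_frames), c(5, 6))
  expect_equal(cis_fraction(s), 0)
  expect_identical(cis_fraction(s) + trans_fraction(s), 100)

  # generator at cis probability 0.40, n = 5000: binomial +/- 2%
  spec <- synth_spec(n_frames = 5000, seed = 22, cis_probability = 0.40,
                     contact_schedule = stats::setNames(0.5, 15))
  traj <- make_trajectory(spec)
  keys <- atom_residue_keys(traj$topology)
  ox <- which(keys == "L:1" & traj$topology$atoms$element == "O")
  s <- conformer_series(traj, ox)
  expect_lt(abs(cis_fraction(s) - 40), 2)
  expect_identical(cis_fraction(s) + trans_fraction(s), 100)
  expect_error(cis_fraction(character(0)), "empty")
})

test_that("conformer_pca finds the configured mode structure", {
  f <- base_lig()
  # one linear mode: a symmetric x-stretch (orthogonal to rigid motions, so
  # the alignment leaves it untouched and the ensemble is exactly rank 1)
  oct0 <- rbind(c(0.2, 0, 0), c(-0.2, 0, 0), c(0, 0.2, 0), c(0, -0.2, 0),
                c(0, 0, 0.2), c(0, 0, -0.2))
  frames <- lapply(seq(-0.1, 0.1, length.out = 21), function(a) {
    g <- oct0; g[1, 1] <- g[1, 1] + a; g[2, 1] <- g[2, 1] - a; g
  })
  m <- conformer_pca(make_lig_traj(frames), 1:6)
  expect_equal(m$explained_variance[1], 1, tolerance = 1e-8)

  # two orthogonal modes of equal amplitude: ~50% each at large n.
  # symmetric stretch modes on an octahedral base are orthogonal to the
  # rigid-body subspace, so the alignment step does not mix them
  oct <- rbind(c(0.2, 0, 0), c(-0.2, 0, 0), c(0, 0.2, 0), c(0, -0.2, 0),
               c(0, 0, 0.2), c(0, 0, -0.2))
  set.seed(23)
  frames <- lapply(1:2000, function(i) {
    g <- oct
    a <- rnorm(1, 0, 0.02); b <- rnorm(1, 0, 0.02)
    g[1, 1] <- g[1, 1] + a; g[2, 1] <- g[2, 1] - a
    g[3, 2] <- g[3, 2] + b; g[4, 2] <- g[4, 2] - b
    g
  })
  m <- conformer_pca(make_lig_traj(frames), 1:6)
  expect_equal(m$explained_variance[1], 0.5, tolerance = 0.05)
  expect_equal(m$explained_variance[2], 0.5, tolerance = 0.05)

  # spectral properties on arbitrary input
  set.seed(24)
  frames <- replicate(30, base_lig() + matrix(rnorm(18, 0, 0.02), ncol = 3),
                      simplify = FALSE)
  m <- conformer_pca(make_lig_traj(frames), 1:6)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_lte(sum(m$explained_variance), 1 + 1e-12)
  expect_true(all(m$explained_variance >= 0))

  expect_warning(conformer_pca(make_lig_traj(list(f, f, f)), 1:6),
                 "degenerate")
})

test_that("PCA embedding is invariant to a global rigid transform", {
  set.seed(25)
  frames <- replicate(40, base_lig() + matrix(rnorm(18, 0, 0.02), ncol = 3),
                      simplify = FALSE)
  m1 <- conformer_pca(make_lig_traj(frames), 1:6)
  R <- random_rotation_matrix(); t0 <- rnorm(3)
  moved <- lapply(frames, function(f) sweep(f %*% t(R), 2, t0, "+"))
  m2 <- conformer_pca(make_lig_traj(moved), 1:6)
  expect_equal(m2$explained_variance, m1$explained_variance,
               tolerance = 1e-8)
  for (j in 1:2) {
    expect_equal(abs(stats::cor(m1$scores[, j], m2$scores[, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("kmeans_cluster recovers blobs and honours edge cases", {
  set.seed(26)
  blob <- function(center, n) {
    sweep(matrix(rnorm(2 * n, 0, 0.05), ncol = 2), 2, center, "+")
  }
  X <- rbind(blob(c(0, 0), 40), blob(c(5, 0), 30), blob(c(0, 5), 30))
  truth <- rep(1:3, c(40, 30, 30))
  fit <- kmeans_cluster(X, 3, seed = 99)
  # exact partition recovery up to label permutation
  expect_equal(length(unique(paste(truth, fit$assignments))), 3)

  f1 <- kmeans_cluster(X, 1, seed = 1)
  expect_equal(f1$centroids[1, ], colMeans(X), tolerance = 1e-10)

  fn <- kmeans_cluster(X[1:8, ], 8, seed = 1, restarts = 5)
  expect_equal(fn$inertia, 0, tolerance = 1e-10)

  expect_error(kmeans_cluster(X[1:3, ], 4, seed = 1), "exceeds")

  # deterministic given seed
  f2 <- kmeans_cluster(X, 3, seed = 99)
  expect_identical(fit$assignments, f2$assignments)
  expect_identical(fit$centroids, f2$centroids)
})

test_that("medoid conformer is the frame nearest the centroid", {
  f <- base_lig()
  # embeddable structure: atom 1 x-offsets define three tight groups
  offsets <- c(-0.2, -0.19, 0.0, 0.01, 0.02, 0.2, 0.21)
  frames <- lapply(offsets, function(a) {
    g <- f; g[1, 1] <- g[1, 1] + a; g
  })
  traj <- make_lig_traj(frames)
  m <- conformer_pca(traj, 1:6)
  m <- conformer_clusters(m, k = 3, seed = 7)

  for (cl in 1:3) {
    cc <- cluster_centroid_conformer(m, traj, 1:6, cl)
    members <- which(m$assignments == cl)
    d <- ncol(m$centroids)
    d2 <- rowSums(sweep(m$scores[members, seq_len(d), drop = FALSE], 2,
                        m$centroids[cl, ])^2)
    expect_equal(cc$frame, members[which.min(d2)])
    if (length(members) == 1) expect_equal(cc$frame, members)
  }
  expect_error(cluster_centroid_conformer(m, traj, 1:6, 99), "empty cluster")

  # symmetric two-point cluster: tie broken to the lower frame index
  X <- rbind(c(-1, 0), c(1, 0))
  fit <- kmeans_cluster(X, 1, seed = 1)
  m2 <- list(scores = X, explained_variance = c(1),
             k = 1, assignments = fit$assignments, centroids = fit$centroids)
  class(m2) <- "ClusterModel"
  traj2 <- make_lig_traj(list(f, f + 0.01))
  expect_equal(cluster_centroid_conformer(m2, traj2, 1:6, 1)$frame, 1)
})
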