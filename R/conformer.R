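# Diketone conformer descriptors: oxygen-oxygen distance series, cis/trans
# classification at the 0.32 nm threshold, PCA embedding of aligned ligand
# coordinates, k-means clustering (k-means++ seeding, Lloyd iterations,
# best-of-restarts) and medoid centroid conformers.

#' Oxygen-oxygen distance series
#'
#' Euclidean distance between the two carbonyl oxygens per frame; this single
#' scalar separates the diketone's cis (oxygens close) and trans (oxygens
#' apart) conformers.
#'
#' @param traj a `Trajectory`
#' @param oxygen_atoms integer atom indices of the two oxygens
#' @return numeric vector of distances (nm), one per frame
#' @export
oo_distance_series <- function(traj, oxygen_atoms) {
  if (length(oxygen_atoms) != 2) stop("need exactly two oxygen atom indices")
  if (any(oxygen_atoms < 1 | oxygen_atoms > n_atoms(traj$topology))) {
    stop("oxygen atom index not found in topology")
  }
  d <- traj$coords[, oxygen_atoms[1], , drop = FALSE] -
       traj$coords[, oxygen_atoms[2], , drop = FALSE]
  sqrt(rowSums(matrix(d, ncol = 3)^2))
}

#' Classify cis/trans by oxygen-oxygen distance
#'
#' A frame is cis iff the O-O distance is at or below the threshold
#' (inclusive; the boundary value 0.32 nm classifies as cis).
#'
#' @param d distance(s), nm, non-negative
#' @param threshold classification threshold, nm (default 0.32)
#' @return character vector `"cis"`/`"trans"`
#' @export
classify_cis_trans <- function(d, threshold = 0.32) {
  if (any(d < 0)) stop("negative distance")
  if (threshold <= 0) stop("threshold must be > 0")
  ifelse(d <= threshold, "cis", "trans")
}

#' Conformer series
#'
#' @param traj a `Trajectory`
#' @param oxygen_atoms the two oxygen atom indices
#' @param threshold cis/trans threshold (nm)
#' @return data.frame of class `ConformerSeries`: `frame`, `time`,
#'   `oo_distance`, `label`; attribute `threshold`
#' @export
conformer_series <- function(traj, oxygen_atoms, threshold = 0.32) {
  d <- oo_distance_series(traj, oxygen_atoms)
  out <- data.frame(frame = seq_len(n_frames(traj)), time = traj$times,
                    oo_distance = d,
                    label = classify_cis_trans(d, threshold),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("ConformerSeries", "data.frame")
  out
}

#' Cis population percentage
#' @param series a `ConformerSeries` (or character vector of labels)
#' @return percentage of cis frames (0-100)
#' @export
cis_fraction <- function(series) {
  lab <- if (is.data.frame(series)) series$label else series
  if (!length(lab)) stop("empty conformer series")
  100 * mean(lab == "cis")
}

#' Trans population percentage
#' @param series a `ConformerSeries` (or character vector of labels)
#' @return percentage of trans frames; `cis_fraction + trans_fraction == 100`
#' @export
trans_fraction <- function(series) 100 - cis_fraction(series)

#' PCA embedding of ligand conformations
#'
#' Each frame's ligand coordinates are Kabsch-aligned to the reference
#' frame's ligand coordinates (removing global rotation/translation), then
#' flattened and mean-centred; the principal components of the resulting
#' coordinate covariance give the embedding. Heavy atoms only is the
#' recommended selection.
#'
#' @param traj a `Trajectory` with >= 2 frames
#' @param ligand_atoms at least 3 atom indices of the ligand
#' @param reference_frame frame the conformers are aligned to
#' @return object of class `ClusterModel`: list with `scores` (frames x
#'   components), `explained_variance` (fractions, non-increasing, sum <= 1),
#'   `k`, `assignments`, `centroids` (the latter three `NULL` until
#'   [conformer_clusters()])
#' @export
conformer_pca <- function(traj, ligand_atoms, reference_frame = 1) {
  nf <- n_frames(traj)
  if (nf < 2) stop("PCA needs >= 2 frames")
  if (length(ligand_atoms) < 3) stop("need >= 3 ligand atoms")
  ref <- frame_coords(traj, reference_frame)[ligand_atoms, , drop = FALSE]
  X <- matrix(NA_real_, nf, 3 * length(ligand_atoms))
  for (i in seq_len(nf)) {
    m <- frame_coords(traj, i)[ligand_atoms, , drop = FALSE]
    sp <- kabsch(m, ref)
    X[i, ] <- as.numeric(t(apply_superposition(sp, m)))
  }
  Xc <- sweep(X, 2, colMeans(X))
  if (max(abs(Xc)) < 1e-12) {
    warning("degenerate ensemble: all frames identical, zero variances")
    return(structure(list(scores = Xc[, 1:2, drop = FALSE] * 0,
                          explained_variance = numeric(0),
                          k = NULL, assignments = NULL, centroids = NULL),
                     class = "ClusterModel"))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = unname(pc$x), explained_variance = ev,
                 k = NULL, assignments = NULL, centroids = NULL),
            class = "ClusterModel")
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = p)
    nd <- rowSums(sweep(X, 2, X[centers[j + 1], ])^2)
    d2 <- pmin(d2, nd)
  }
  X[centers, , drop = FALSE]
}

.lloyd <- function(X, C, max_iter = 100) {
  k <- nrow(C)
  n <- nrow(X)
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    # squared distances to all centers: n x k
    D <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(C) +
      outer(rep(1, n), rowSums(C^2))
    a <- max.col(-D, ties.method = "first")
    if (all(a == assign_old)) break
    assign_old <- a
    for (j in seq_len(k)) {
      idx <- which(a == j)
      if (length(idx)) C[j, ] <- colMeans(X[idx, , drop = FALSE])
      else C[j, ] <- X[sample.int(n, 1), ]  # re-seed empty cluster
    }
  }
  D <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(C) +
    outer(rep(1, n), rowSums(C^2))
  a <- max.col(-D, ties.method = "first")
  inertia <- sum(pmax(D[cbind(seq_len(n), a)], 0))
  list(assignments = a, centroids = C, inertia = inertia)
}

#' k-means clustering (k-means++, Lloyd, restarts)
#'
#' Deterministic given `seed`: k-means++ seeding followed by Lloyd
#' iterations, keeping the lowest-inertia solution over `restarts` runs.
#'
#' @param points n x d matrix of embedded points
#' @param k number of clusters, `1 <= k <= n`
#' @param seed RNG seed
#' @param restarts number of independent restarts
#' @param max_iter Lloyd iteration cap per restart
#' @return list with `assignments` (length n), `centroids` (k x d),
#'   `inertia`
#' @export
kmeans_cluster <- function(points, k, seed = 1234, restarts = 50,
                           max_iter = 100) {
  X <- as.matrix(points)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(X)) stop("k exceeds number of points")
  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    fit <- .lloyd(X, .kmeanspp_init(X, k), max_iter)
    if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
  }
  best
}

#' Cluster a conformer PCA embedding
#'
#' Runs [kmeans_cluster()] on the first `n_components` PCA scores and stores
#' the result in the model.
#'
#' @param model a `ClusterModel` from [conformer_pca()]
#' @param k number of clusters (default 3, the visible cluster count of the
#'   diketone ensemble)
#' @param n_components number of leading components to cluster on
#' @param seed,restarts passed to [kmeans_cluster()]
#' @return the `ClusterModel` with `k`, `assignments`, `centroids` filled
#' @export
conformer_clusters <- function(model, k = 3, n_components = 2, seed = 1234,
                               restarts = 50) {
  X <- model$scores[, seq_len(min(n_components, ncol(model$scores))),
                    drop = FALSE]
  fit <- kmeans_cluster(X, k, seed = seed, restarts = restarts)
  model$k <- k
  model$assignments <- fit$assignments
  model$centroids <- fit$centroids
  model
}

#' Medoid conformer of a cluster
#'
#' Returns the real trajectory frame whose embedding is nearest the cluster
#' centroid (medoid convention, guaranteeing a physically valid
#' conformation); ties break to the lower frame index.
#'
#' @param model a clustered `ClusterModel`
#' @param traj the `Trajectory` the model was built from
#' @param ligand_atoms ligand atom indices
#' @param cluster cluster id
#' @return list with `frame` (index) and `coords` (ligand atoms x 3, nm)
#' @export
cluster_centroid_conformer <- function(model, traj, ligand_atoms, cluster) {
  if (is.null(model$assignments)) stop("model has no cluster assignments")
  members <- which(model$assignments == cluster)
  if (!length(members)) stop("empty cluster ", cluster)
  d <- ncol(model$centroids)
  emb <- model$scores[members, seq_len(d), drop = FALSE]
  d2 <- rowSums(sweep(emb, 2, model$centroids[cluster, ])^2)
  frame <- members[which.min(d2)]  # which.min ties -> first (lower index)
  list(frame = frame,
       coords = frame_coords(traj, frame)[ligand_atoms, , drop = FALSE])
}
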