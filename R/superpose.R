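# Rigid-body superposition (Kabsch), RMSD time series with independent fit
# and measure selections, region-excluded RMSD-share attribution, and
# per-residue RMSF.

.centroid <- function(x, w) colSums(x * w) / sum(w)

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference` via the SVD
#' of the weighted cross-covariance, with the determinant correction that
#' excludes reflections. The optimal map is
#' `x -> rotation %*% (x - centroid(mobile)) + centroid(reference)`.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3,
#'   not all collinear
#' @param weights optional per-atom weights (default uniform)
#' @return object of class `Superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length-3, nm), `rmsd` (nm)
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3) stop("need >= 3 points")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) stop("bad weights")
  cm <- .centroid(mobile, w); cr <- .centroid(reference, w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sp <- svd(P)
  if (sp$d[2] <= 1e-10 * max(sp$d[1], 1e-300)) {
    stop("degenerate geometry: points are collinear")
  }
  H <- crossprod(P * w, Q)  # 3 x 3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)) / sum(w))
  structure(
    list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd),
    class = "Superposition"
  )
}

#' Apply a Superposition to coordinates
#' @param sp a `Superposition`
#' @param coords n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

.rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series
#'
#' Per frame: superpose on `fit_selection` against the reference frame, then
#' measure RMSD on `measure_selection` (default: the fit selection, the
#' convention of standard MD-suite RMSD tools).
#'
#' @param traj a `Trajectory`
#' @param reference_frame index of the reference frame
#' @param fit_selection integer atom indices used for the superposition
#' @param measure_selection atom indices the RMSD is measured on
#' @param weights optional per-atom weights over `fit_selection`
#' @return numeric vector, one RMSD (nm) per frame
#' @export
rmsd_series <- function(traj, reference_frame = 1, fit_selection,
                        measure_selection = fit_selection, weights = NULL) {
  if (!length(fit_selection) || !length(measure_selection)) {
    stop("empty selection")
  }
  ref <- frame_coords(traj, reference_frame)
  rf <- ref[fit_selection, , drop = FALSE]
  rm_ <- ref[measure_selection, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(i) {
    m <- frame_coords(traj, i)
    sp <- kabsch(m[fit_selection, , drop = FALSE], rf, weights)
    .rmsd_between(apply_superposition(sp, m[measure_selection, , drop = FALSE]),
                  rm_)
  }, numeric(1))
}

#' Region RMSD-share series
#'
#' Attribution metric for a region's contribution to overall deviation: per
#' frame, `share = 100 * (1 - RMSD(backbone without region) / RMSD(backbone))`.
#' Both RMSDs use the fit-on-measured-set convention of [rmsd_series()].
#' Frames whose full-backbone RMSD is below `tol` (e.g. the reference frame
#' itself) are skipped (share `NA`) and counted in the `skipped` attribute.
#'
#' @param traj a `Trajectory`
#' @param reference_frame reference frame index
#' @param backbone integer atom indices of the full backbone selection
#' @param region_residues residue keys (see [residue_key()]) of the region to
#'   exclude; must not cover the whole backbone
#' @param tol RMSD tolerance (nm) below which a frame is skipped
#' @return data.frame of class `RmsdShareSeries` with columns `frame`,
#'   `time`, `rmsd_full`, `rmsd_excl`, `share` (percent); attribute `skipped`
#' @export
rmsd_share <- function(traj, reference_frame = 1, backbone,
                       region_residues, tol = 1e-6) {
  rk <- atom_residue_keys(traj$topology)[backbone]
  excl <- backbone[!(rk %in% region_residues)]
  if (!length(excl)) stop("region covers all backbone atoms")
  full <- rmsd_series(traj, reference_frame, backbone)
  part <- if (length(excl) == length(backbone)) full
          else rmsd_series(traj, reference_frame, excl)
  skip <- full < tol
  share <- ifelse(skip, NA_real_, 100 * (1 - part / full))
  out <- data.frame(frame = seq_len(n_frames(traj)), time = traj$times,
                    rmsd_full = full, rmsd_excl = part, share = share)
  attr(out, "skipped") <- sum(skip)
  class(out) <- c("RmsdShareSeries", "data.frame")
  out
}

#' Per-residue RMSF
#'
#' Each frame is first superposed on the reference frame over
#' `fit_selection`; the RMSF of an atom is the root-mean-square deviation
#' from its time-average (fitted) position, and residue values are the
#' unweighted mean over the residue's atoms in `selection`.
#'
#' @param traj a `Trajectory` with >= 2 frames
#' @param selection atom indices the RMSF is computed on
#' @param fit_selection atom indices used for the per-frame superposition
#' @param reference_frame reference frame for the fit
#' @return data.frame with `chain`, `resid`, `resname`, `region`, `rmsf` (nm)
#' @export
rmsf <- function(traj, selection, fit_selection = selection,
                 reference_frame = 1) {
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF needs >= 2 frames")
  if (!length(selection) || !length(fit_selection)) stop("empty selection")
  ref <- frame_coords(traj, reference_frame)[fit_selection, , drop = FALSE]
  ns <- length(selection)
  fitted <- array(NA_real_, c(nf, ns, 3))
  for (i in seq_len(nf)) {
    m <- frame_coords(traj, i)
    sp <- kabsch(m[fit_selection, , drop = FALSE], ref)
    fitted[i, , ] <- apply_superposition(sp, m[selection, , drop = FALSE])
  }
  mean_pos <- apply(fitted, c(2, 3), mean)
  dev2 <- matrix(0, nf, ns)
  for (k in 1:3) {
    dev2 <- dev2 + sweep(matrix(fitted[, , k], nf, ns), 2, mean_pos[, k])^2
  }
  atom_rmsf <- sqrt(colMeans(dev2))
  rk <- atom_residue_keys(traj$topology)[selection]
  per_res <- tapply(atom_rmsf, rk, mean)
  res <- traj$topology$residues
  keep <- res$key %in% names(per_res)
  data.frame(
    res[keep, c("chain", "resid", "resname")],
    region = unname(traj$topology$region[res$key[keep]]),
    rmsf = unname(per_res[res$key[keep]]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
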