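# Docking-box construction from transmembrane/extracellular C-alpha
# centroids, principal-axis alignment, docking-pose ingestion (PDBQT-style
# multi-pose files with affinity remarks), affinity filtering and
# representative-pose selection by mean contact-set similarity.

#' Rotate coordinates so the principal axis lies on z
#'
#' The direction of maximal coordinate variance is rotated onto the z axis
#' (rotation about the centroid, det +1). With an annotated topology, the
#' sign convention points positive z toward the extracellular centroid.
#'
#' @param coords n x 3 matrix (nm), n >= 3, non-degenerate
#' @param top optional annotated `Topology` (for the sign convention)
#' @param ec_label extracellular region label
#' @return list with `coords` (rotated) and `rotation` (3 x 3, applied as
#'   `centered %*% t(rotation)`)
#' @export
principal_axis_to_z <- function(coords, top = NULL,
                                ec_label = "extracellular") {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need >= 3 points")
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  ei <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  if (ei$values[1] < 1e-12) stop("degenerate geometry")
  # columns: new x, y from the minor axes, z = principal axis
  V <- cbind(ei$vectors[, 2], ei$vectors[, 3], ei$vectors[, 1])
  if (det(V) < 0) V[, 1] <- -V[, 1]
  R <- t(V)  # maps old coords -> frame with principal axis on z
  rotated <- X %*% t(R)
  if (!is.null(top) && any(top$region %in% ec_label, na.rm = TRUE)) {
    ec_idx <- select_atoms(top, region = ec_label)
    if (length(ec_idx)) {
      ec_z <- mean(rotated[ec_idx, 3])
      if (ec_z < 0) {
        flip <- diag(c(1, -1, -1))  # proper rotation reversing z
        R <- flip %*% R
        rotated <- X %*% t(R)
      }
    }
  }
  list(coords = sweep(rotated, 2, ctr, "+"), rotation = R)
}

#' Construct the docking search box
#'
#' Two-centroid protocol: the box center is the midpoint of the line
#' connecting the C-alpha centroid of the transmembrane residues and the
#' C-alpha centroid of the extracellular residues; box edge lengths default
#' to 15 x 15 x 25 A (total extents, the docking-engine convention;
#' `half_extent = TRUE` doubles them for the half-extent reading).
#'
#' @param top annotated `Topology`
#' @param coords receptor coordinates, atoms x 3 (nm)
#' @param tm_label,ec_label region labels of the two centroids
#' @param dims box edge lengths in Angstrom
#' @param half_extent if `TRUE`, `dims` are half-extents (box = 2 * dims)
#' @return object of class `DockingBox`: list with `center` (A) and `dims`
#'   (A)
#' @export
build_box <- function(top, coords, tm_label = "transmembrane",
                      ec_label = "extracellular", dims = c(15, 15, 25),
                      half_extent = FALSE) {
  if (any(dims <= 0)) stop("box dims must be > 0")
  tm_ca <- select_atoms(top, name = "CA", region = tm_label)
  ec_ca <- select_atoms(top, name = "CA", region = ec_label)
  if (!length(tm_ca)) stop("no CA atoms in region ", tm_label)
  if (!length(ec_ca)) stop("no CA atoms in region ", ec_label)
  c_tm <- colMeans(coords[tm_ca, , drop = FALSE])
  c_ec <- colMeans(coords[ec_ca, , drop = FALSE])
  center_nm <- (c_tm + c_ec) / 2
  structure(
    list(center = as.numeric(center_nm * 10),  # nm -> Angstrom
         dims = as.numeric(if (half_extent) 2 * dims else dims)),
    class = "DockingBox"
  )
}

#' @export
print.DockingBox <- function(x, ...) {
  cat(sprintf("DockingBox: center (%.2f, %.2f, %.2f) A, size %g x %g x %g A\n",
              x$center[1], x$center[2], x$center[3],
              x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Emit a Vina-style box configuration block
#' @param box a `DockingBox`
#' @return character vector of `center_*` / `size_*` lines (Angstrom)
#' @export
vina_config <- function(box) {
  c(sprintf("center_x = %.3f", box$center[1]),
    sprintf("center_y = %.3f", box$center[2]),
    sprintf("center_z = %.3f", box$center[3]),
    sprintf("size_x = %.3f", box$dims[1]),
    sprintf("size_y = %.3f", box$dims[2]),
    sprintf("size_z = %.3f", box$dims[3]))
}

#' Construct a PoseSet
#'
#' @param atoms data.frame describing the ligand atoms (columns as in
#'   [topology()])
#' @param coords array poses x atoms x 3 (nm), or list of atom x 3 matrices
#' @param affinity predicted affinity per pose, kcal/mol, finite
#' @param source source-structure identifier per pose
#' @return object of class `PoseSet`
#' @export
pose_set <- function(atoms, coords, affinity,
                     source = rep(NA_character_, length(affinity))) {
  if (is.list(coords)) {
    arr <- array(NA_real_, c(length(coords), nrow(coords[[1]]), 3))
    for (i in seq_along(coords)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  if (dim(coords)[1] != length(affinity)) stop("affinity length != pose count")
  if (dim(coords)[2] != nrow(atoms)) stop("coords atom count != atoms table")
  if (any(!is.finite(affinity))) stop("affinity must be finite")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 coords = coords, affinity = as.numeric(affinity),
                 source = source),
            class = "PoseSet")
}

#' Number of poses
#' @param poses a `PoseSet`
#' @return integer
#' @export
n_poses <- function(poses) dim(poses$coords)[1]

#' @export
print.PoseSet <- function(x, ...) {
  cat("PoseSet:", n_poses(x), "poses,", nrow(x$atoms), "ligand atoms,",
      sprintf("affinity %.1f..%.1f kcal/mol\n",
              min(x$affinity), max(x$affinity)))
  invisible(x)
}

#' Read a multi-pose docking output file
#'
#' PDBQT-style: `MODEL` blocks with a `REMARK VINA RESULT: <affinity> ...`
#' line and ATOM/HETATM records (Angstrom, converted to nm). Poses are
#' returned in file order; a pose without an affinity remark is an error.
#'
#' @param path file path
#' @return a `PoseSet`
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) stop("no poses in ", path)
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL in ", path)
  coords <- vector("list", length(starts))
  affinity <- numeric(length(starts))
  source <- rep(NA_character_, length(starts))
  atoms <- NULL
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    rem <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (!length(rem)) stop("pose ", k, " has no affinity remark")
    affinity[k] <- as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "",
                                                  rem[1])), "[[:space:]]+")[[1]][1])
    if (is.na(affinity[k])) stop("pose ", k, " has a malformed affinity")
    src <- grep("^REMARK SOURCE:", block, value = TRUE)
    if (length(src)) source[k] <- trimws(sub("^REMARK SOURCE:", "", src[1]))
    p <- .parse_pdb_atoms(block, path)
    if (is.null(atoms)) atoms <- p$atoms
    if (nrow(p$coords) != nrow(atoms)) {
      stop("pose ", k, " atom count differs from pose 1")
    }
    coords[[k]] <- p$coords
  }
  pose_set(atoms, coords, affinity, source)
}

#' Write a PoseSet in the multi-pose format read by [read_poses()]
#' @param poses a `PoseSet`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_poses <- function(poses, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_len(n_poses(poses))) {
    writeLines(sprintf("MODEL %8d", k), con)
    writeLines(sprintf("REMARK VINA RESULT:    %6.1f      0.000      0.000",
                       poses$affinity[k]), con)
    if (!is.na(poses$source[k])) {
      writeLines(paste("REMARK SOURCE:", poses$source[k]), con)
    }
    writeLines(.pdb_atom_lines(poses$atoms,
                               matrix(poses$coords[k, , ], ncol = 3)), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Filter poses by affinity
#'
#' Keeps poses with affinity strictly below `max_affinity` (the "better than
#' -2 kcal/mol" rule) and, if given, strictly above `min_affinity` (the
#' positive-affinity negative-control group). Order-preserving and
#' idempotent.
#'
#' @param poses a `PoseSet`
#' @param max_affinity upper cutoff, kcal/mol (strict; default `Inf`)
#' @param min_affinity lower cutoff, kcal/mol (strict; default `-Inf`)
#' @return the filtered `PoseSet`
#' @export
filter_poses <- function(poses, max_affinity = Inf, min_affinity = -Inf) {
  keep <- which(poses$affinity < max_affinity & poses$affinity > min_affinity)
  pose_set(poses$atoms, poses$coords[keep, , , drop = FALSE],
           poses$affinity[keep], poses$source[keep])
}

#' Contact set of every pose
#'
#' @param poses a `PoseSet`
#' @param top receptor `Topology`
#' @param coords receptor coordinates (atoms x 3, nm)
#' @param cutoff contact cutoff, nm
#' @return list of residue-key character vectors, one per pose
#' @export
pose_contact_sets <- function(poses, top, coords, cutoff = 0.4) {
  lapply(seq_len(n_poses(poses)), function(k) {
    residue_contacts(top, coords, ligand = NULL,
                     ligand_coords = matrix(poses$coords[k, , ], ncol = 3),
                     ligand_elements = poses$atoms$element, cutoff = cutoff)
  })
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 1 else length(intersect(a, b)) / u
}

#' Most representative pose by contact-set similarity
#'
#' Each pose's residue-contact set is computed against the receptor; the
#' representative pose maximizes the mean Jaccard similarity of its contact
#' set to all other poses' sets. Ties break to the best (lowest) affinity,
#' then to file order.
#'
#' @param poses a non-empty `PoseSet` (apply [filter_poses()] first to
#'   restrict to an affinity class)
#' @param top receptor `Topology`
#' @param coords receptor coordinates (atoms x 3, nm)
#' @param cutoff contact cutoff, nm
#' @return list with `index`, `affinity`, `contacts`, `mean_jaccard`
#' @export
representative_pose <- function(poses, top, coords, cutoff = 0.4) {
  np <- n_poses(poses)
  if (np < 1) stop("empty pose set")
  sets <- pose_contact_sets(poses, top, coords, cutoff)
  if (np == 1) {
    return(list(index = 1L, affinity = poses$affinity[1],
                contacts = sets[[1]], mean_jaccard = 1))
  }
  J <- matrix(1, np, np)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      J[i, j] <- J[j, i] <- .jaccard(sets[[i]], sets[[j]])
    }
  }
  score <- (rowSums(J) - 1) / (np - 1)  # mean over the other poses
  best <- which(score >= max(score) - 1e-12)
  if (length(best) > 1) {
    best <- best[order(poses$affinity[best], best)]  # affinity, then order
  }
  idx <- best[1]
  list(index = idx, affinity = poses$affinity[idx], contacts = sets[[idx]],
       mean_jaccard = score[idx])
}

#' Pose summary table
#'
#' @inheritParams representative_pose
#' @return data.frame: `pose`, `affinity`, `n_contacts`, `contacts`
#'   (semicolon-joined residue keys)
#' @export
pose_summary <- function(poses, top, coords, cutoff = 0.4) {
  sets <- pose_contact_sets(poses, top, coords, cutoff)
  data.frame(pose = seq_len(n_poses(poses)), affinity = poses$affinity,
             n_contacts = lengths(sets),
             contacts = vapply(sets, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}
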