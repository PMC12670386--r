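# Residue-ligand contact detection and occupancy/retention statistics:
# the 4 A (0.4 nm) minimum-atom-distance contact rule, per-residue
# interaction probability over a frame window, conserved-contact fraction
# against a reference contact set, hydrophobic (C-C within 0.4 nm) and
# geometric hydrogen-bond occurrence, and pose contact-count histograms.
#
# Distance scans are vectorized whole-array arithmetic; the plain double
# loop is kept in the test suite as the independent oracle.

.heavy <- function(elements) toupper(elements) != "H"

# min distance from each receptor atom group (residue) to any ligand atom,
# one frame: returns named vector of per-residue minima (nm)
.residue_min_dist <- function(rec_xyz, rec_keys, lig_xyz) {
  nr <- nrow(rec_xyz); nl <- nrow(lig_xyz)
  d2 <- matrix(0, nr, nl)
  for (k in 1:3) {
    d2 <- d2 + (rec_xyz[, k] %o% rep(1, nl) - rep(1, nr) %o% lig_xyz[, k])^2
  }
  amin <- sqrt(apply(d2, 1, min))
  out <- tapply(amin, rec_keys, min)
  out[unique(rec_keys)]
}

.resolve_ligand_atoms <- function(top, ligand) {
  if (is.character(ligand) && length(ligand) == 1) {
    idx <- which(atom_residue_keys(top) == ligand)
    if (!length(idx)) stop("ligand residue not found: ", ligand)
    idx
  } else as.integer(ligand)
}

#' Residues in contact with the ligand
#'
#' A residue is in contact when at least one of its atoms is within `cutoff`
#' of any ligand atom (minimum-distance rule, default 0.4 nm / 4 A). The
#' default atom policy considers heavy atoms only on both sides.
#'
#' @param top a `Topology` describing the receptor atoms
#' @param coords receptor coordinates, atoms x 3 (nm)
#' @param ligand either a residue key within `top` (ligand coordinates then
#'   come from `coords`) or, with `ligand_coords`, a set of external ligand
#'   atoms
#' @param ligand_coords optional external ligand coordinates (atoms x 3, nm)
#' @param ligand_elements elements for `ligand_coords`
#' @param cutoff contact cutoff, nm
#' @param atom_policy `"heavy"` (default) or `"all"`
#' @param candidates optional residue keys to restrict the receptor side
#' @return character vector of residue keys in contact
#' @export
residue_contacts <- function(top, coords, ligand, ligand_coords = NULL,
                             ligand_elements = NULL, cutoff = 0.4,
                             atom_policy = c("heavy", "all"),
                             candidates = NULL) {
  atom_policy <- match.arg(atom_policy)
  keys <- atom_residue_keys(top)
  if (is.null(ligand_coords)) {
    lidx <- .resolve_ligand_atoms(top, ligand)
    ligand_coords <- coords[lidx, , drop = FALSE]
    ligand_elements <- top$atoms$element[lidx]
    lig_keys <- unique(keys[lidx])
  } else {
    if (is.null(ligand_elements)) {
      ligand_elements <- rep("C", nrow(ligand_coords))
    }
    lig_keys <- character(0)
  }
  if (!nrow(ligand_coords)) stop("ligand is empty")
  lab <- top$region[keys]
  rec <- !(keys %in% lig_keys) &
    !(!is.na(lab) & lab %in% c("solvent", "ligand"))
  if (!is.null(candidates)) rec <- rec & keys %in% candidates
  if (atom_policy == "heavy") {
    rec <- rec & .heavy(top$atoms$element)
    lsel <- .heavy(ligand_elements)
    ligand_coords <- ligand_coords[lsel, , drop = FALSE]
  }
  ridx <- which(rec)
  if (!length(ridx) || !nrow(ligand_coords)) return(character(0))
  dmin <- .residue_min_dist(coords[ridx, , drop = FALSE], keys[ridx],
                            ligand_coords)
  names(dmin)[dmin <= cutoff]
}

# frames x residues matrix of min receptor-residue/ligand distances across a
# trajectory, vectorized over frames
.traj_residue_min_dist <- function(traj, rec_idx, lig_idx, frames) {
  keys <- atom_residue_keys(traj$topology)[rec_idx]
  rc <- traj$coords[frames, rec_idx, , drop = FALSE]
  lc <- traj$coords[frames, lig_idx, , drop = FALSE]
  nf <- length(frames); nr <- length(rec_idx); nl <- length(lig_idx)
  d2 <- matrix(0, nf, nr * nl)
  for (k in 1:3) {
    d2 <- d2 + (matrix(rc[, , k], nf, nr)[, rep(seq_len(nr), nl)] -
                matrix(lc[, , k], nf, nl)[, rep(seq_len(nl), each = nr)])^2
  }
  # min over ligand atoms -> frames x receptor atoms
  amin <- matrix(Inf, nf, nr)
  for (j in seq_len(nl)) {
    amin <- pmin(amin, d2[, ((j - 1) * nr + 1):(j * nr), drop = FALSE])
  }
  # min over each residue's atoms -> frames x residues
  ukeys <- unique(keys)
  out <- matrix(Inf, nf, length(ukeys), dimnames = list(NULL, ukeys))
  for (j in seq_along(ukeys)) {
    cols <- which(keys == ukeys[j])
    m <- amin[, cols, drop = FALSE]
    out[, j] <- sqrt(do.call(pmin, lapply(seq_len(ncol(m)),
                                          function(c) m[, c])))
  }
  out
}

.window_frames <- function(traj, window) {
  if (is.null(window)) {
    # equilibrium default: discard the first 25% of frames
    seq.int(floor(n_frames(traj) * 0.25) + 1L, n_frames(traj))
  } else as.integer(window)
}

#' Per-residue interaction probability
#'
#' For each receptor residue, the percentage of window frames in which the
#' residue is in contact with the ligand (minimum heavy-atom distance within
#' `cutoff`). The default window discards the first 25% of frames as
#' equilibration.
#'
#' @param traj a `Trajectory` containing both receptor and ligand
#' @param ligand ligand residue key (or atom indices)
#' @param cutoff contact cutoff, nm
#' @param window frame indices to analyse (default: last 75%)
#' @param atom_policy `"heavy"` or `"all"`
#' @return named numeric vector: percentage per receptor residue key
#' @export
interaction_probability <- function(traj, ligand, cutoff = 0.4,
                                    window = NULL,
                                    atom_policy = c("heavy", "all")) {
  atom_policy <- match.arg(atom_policy)
  frames <- .window_frames(traj, window)
  if (!length(frames)) stop("empty frame window")
  top <- traj$topology
  keys <- atom_residue_keys(top)
  lidx <- .resolve_ligand_atoms(top, ligand)
  lig_keys <- unique(keys[lidx])
  rec <- !(keys %in% lig_keys) &
    !(!is.na(top$region[keys]) & top$region[keys] %in% c("solvent", "ligand"))
  if (atom_policy == "heavy") {
    rec <- rec & .heavy(top$atoms$element)
    lidx <- lidx[.heavy(top$atoms$element[lidx])]
  }
  dmin <- .traj_residue_min_dist(traj, which(rec), lidx, frames)
  100 * colMeans(dmin <= cutoff)
}

#' Conserved-contact fraction
#'
#' Percentage of a reference contact set still present in a frame's contact
#' set: `100 * |frame intersect reference| / |reference|`. Used to validate a
#' docking pose in MD by taking the pose's initial contacts as reference.
#'
#' @param frame_contacts residue keys in contact in the frame
#' @param reference_contacts non-empty reference residue keys
#' @return percentage (0-100)
#' @export
conserved_contact_fraction <- function(frame_contacts, reference_contacts) {
  if (!length(reference_contacts)) stop("empty reference contact set")
  100 * length(intersect(frame_contacts, reference_contacts)) /
    length(unique(reference_contacts))
}

#' Contact-retention series over a trajectory
#'
#' Per window frame, the [conserved_contact_fraction()] of the frame's
#' contact set against `reference_contacts`. Supplying the initial contacts
#' of a different pose gives the cross-pose variant.
#'
#' @param traj a `Trajectory`
#' @param ligand ligand residue key
#' @param reference_contacts reference residue keys
#' @param cutoff contact cutoff, nm
#' @param window frame indices (default all frames)
#' @return data.frame: `frame`, `time`, `retained` (percent)
#' @export
retention_series <- function(traj, ligand, reference_contacts, cutoff = 0.4,
                             window = seq_len(n_frames(traj))) {
  if (!length(reference_contacts)) stop("empty reference contact set")
  top <- traj$topology
  keys <- atom_residue_keys(top)
  lidx <- .resolve_ligand_atoms(top, ligand)
  heavy <- .heavy(top$atoms$element)
  rec <- which(keys %in% reference_contacts & heavy)
  if (!length(rec)) {
    return(data.frame(frame = window, time = traj$times[window], retained = 0))
  }
  dmin <- .traj_residue_min_dist(traj, rec, lidx[heavy[lidx]], window)
  nref <- length(unique(reference_contacts))
  data.frame(frame = window, time = traj$times[window],
             retained = 100 * rowSums(dmin <= cutoff) / nref)
}

#' Hydrophobic-contact occurrence
#'
#' Percentage of window frames with at least one carbon-carbon pair within
#' `cutoff` (default 0.4 nm) between the residue and the ligand.
#'
#' @param traj a `Trajectory`
#' @param residue residue key of the receptor residue
#' @param ligand ligand residue key (or atom indices)
#' @param cutoff C-C cutoff, nm
#' @param window frame indices (default: last 75%)
#' @return percentage (0-100)
#' @export
hydrophobic_occurrence <- function(traj, residue, ligand, cutoff = 0.4,
                                   window = NULL) {
  frames <- .window_frames(traj, window)
  top <- traj$topology
  keys <- atom_residue_keys(top)
  carbon <- toupper(top$atoms$element) == "C"
  ridx <- which(keys == residue & carbon)
  lidx <- .resolve_ligand_atoms(top, ligand)
  lidx <- lidx[carbon[lidx]]
  if (!length(ridx) || !length(lidx)) return(0)
  dmin <- .traj_residue_min_dist(traj, ridx, lidx, frames)
  100 * mean(apply(dmin, 1, min) <= cutoff)
}

#' Hydrogen-bond occurrence (geometric criterion)
#'
#' A frame counts as hydrogen-bonded iff the donor-acceptor distance is at
#' most `d_cut` and the hydrogen-donor-acceptor angle is at most
#' `angle_cut` (the standard geometric criterion of MD-suite H-bond tools:
#' 0.35 nm / 30 degrees).
#'
#' @param traj a `Trajectory`
#' @param donor length-2 integer vector: (donor heavy atom, its hydrogen)
#' @param acceptor acceptor atom index
#' @param d_cut donor-acceptor distance cutoff, nm
#' @param angle_cut H-D-A angle cutoff, degrees
#' @param window frame indices (default: last 75%)
#' @return percentage of window frames with the H-bond present
#' @export
hbond_occurrence <- function(traj, donor, acceptor, d_cut = 0.35,
                             angle_cut = 30, window = NULL) {
  if (length(donor) != 2) stop("donor must be (heavy atom, hydrogen) indices")
  els <- toupper(traj$topology$atoms$element)
  if (els[donor[2]] != "H") stop("donor has no attached hydrogen")
  frames <- .window_frames(traj, window)
  D <- traj$coords[frames, donor[1], , drop = FALSE]
  H <- traj$coords[frames, donor[2], , drop = FALSE]
  A <- traj$coords[frames, acceptor, , drop = FALSE]
  da <- matrix(A - D, ncol = 3)
  dh <- matrix(H - D, ncol = 3)
  dist_da <- sqrt(rowSums(da^2))
  cosang <- rowSums(da * dh) / (dist_da * sqrt(rowSums(dh^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  100 * mean(dist_da <= d_cut & ang <= angle_cut)
}

#' Contact-count histogram over docking poses
#'
#' For each pose, the number of receptor residues in contact with the
#' ligand; returned as the distribution of contact-set sizes.
#'
#' @param poses a `PoseSet`
#' @param top receptor `Topology`
#' @param coords receptor coordinates (atoms x 3, nm)
#' @param cutoff contact cutoff, nm
#' @return list with `counts` (per pose) and `histogram` (a `table`)
#' @export
contact_count_histogram <- function(poses, top, coords, cutoff = 0.4) {
  sets <- pose_contact_sets(poses, top, coords, cutoff)
  counts <- lengths(sets)
  list(counts = counts, histogram = table(counts))
}

#' Per-residue occurrence across docking poses
#'
#' Percentage of poses in which each receptor residue contacts the ligand
#' (binary per pose).
#'
#' @inheritParams contact_count_histogram
#' @return named numeric vector: percentage per residue key
#' @export
pose_residue_occurrence <- function(poses, top, coords, cutoff = 0.4) {
  sets <- pose_contact_sets(poses, top, coords, cutoff)
  all_res <- unique(unlist(sets))
  if (!length(all_res)) return(stats::setNames(numeric(0), character(0)))
  occ <- vapply(all_res, function(r) {
    100 * mean(vapply(sets, function(s) r %in% s, logical(1)))
  }, numeric(1))
  sort(occ, decreasing = TRUE)
}

#' Occupancy table for a set of residues
#'
#' Generic interaction, hydrophobic-contact and (optionally) hydrogen-bond
#' occurrence per residue over a trajectory window, mirroring the three-row
#' per-residue summary of a binding-site characterization.
#'
#' @param traj a `Trajectory`
#' @param ligand ligand residue key
#' @param residues residue keys to report
#' @param hbonds optional named list: residue key -> list(donor = c(D, H),
#'   acceptor = A) atom indices
#' @param cutoff generic/hydrophobic cutoff, nm
#' @param window frame indices (default: last 75%)
#' @return data.frame: `residue`, `int_occurrence`, `hydrophobic_occurrence`,
#'   `hbond_occurrence` (percent)
#' @export
occupancy_table <- function(traj, ligand, residues, hbonds = list(),
                            cutoff = 0.4, window = NULL) {
  ip <- interaction_probability(traj, ligand, cutoff, window)
  hy <- vapply(residues, function(r) {
    hydrophobic_occurrence(traj, r, ligand, cutoff, window)
  }, numeric(1))
  hb <- vapply(residues, function(r) {
    if (!is.null(hbonds[[r]])) {
      hbond_occurrence(traj, hbonds[[r]]$donor, hbonds[[r]]$acceptor,
                       window = window)
    } else 0
  }, numeric(1))
  data.frame(residue = residues,
             int_occurrence = unname(ifelse(residues %in% names(ip),
                                            ip[residues], 0)),
             hydrophobic_occurrence = unname(hy),
             hbond_occurrence = unname(hb),
             stringsAsFactors = FALSE, row.names = NULL)
}
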