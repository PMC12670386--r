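# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately written as plain double loops, sharing no code with the
# package's vectorized implementations.

# --- brute-force contact rules -----------------------------------------

# residues whose minimum atom distance to any ligand atom is <= cutoff
brute_contacts <- function(rec_xyz, rec_keys, lig_xyz, cutoff,
                           rec_elements = NULL, lig_elements = NULL,
                           heavy_only = TRUE) {
  keep_r <- rep(TRUE, nrow(rec_xyz))
  keep_l <- rep(TRUE, nrow(lig_xyz))
  if (heavy_only && !is.null(rec_elements)) keep_r <- rec_elements != "H"
  if (heavy_only && !is.null(lig_elements)) keep_l <- lig_elements != "H"
  hits <- character(0)
  for (i in which(keep_r)) {
    for (j in which(keep_l)) {
      if (sqrt(sum((rec_xyz[i, ] - lig_xyz[j, ])^2)) <= cutoff) {
        hits <- c(hits, rec_keys[i])
        break
      }
    }
  }
  unique(hits)
}

# is there any C-C pair within cutoff between the two atom sets?
brute_cc_contact <- function(a_xyz, a_el, b_xyz, b_el, cutoff) {
  for (i in seq_len(nrow(a_xyz))) {
    if (a_el[i] != "C") next
    for (j in seq_len(nrow(b_xyz))) {
      if (b_el[j] != "C") next
      if (sqrt(sum((a_xyz[i, ] - b_xyz[j, ])^2)) <= cutoff) return(TRUE)
    }
  }
  FALSE
}

# geometric H-bond criterion on one frame
brute_hbond <- function(d_xyz, h_xyz, a_xyz, d_cut, angle_cut) {
  da <- a_xyz - d_xyz
  dh <- h_xyz - d_xyz
  dd <- sqrt(sum(da^2))
  ang <- acos(max(-1, min(1, sum(da * dh) / (dd * sqrt(sum(dh^2)))))) * 180 / pi
  dd <= d_cut && ang <= angle_cut
}

# --- quaternion-grid RMSD oracle ---------------------------------------

# rotation matrices (K x 9, column-major layout) from a 4D lattice of
# quaternions with spacing h over [-1, 1]^4
quaternion_grid_rotations <- function(h) {
  g <- seq(-1, 1, by = h)
  q <- as.matrix(expand.grid(w = g, x = g, y = g, z = g))
  nrm <- sqrt(rowSums(q^2))
  q <- q[nrm > 1e-8, ] / nrm[nrm > 1e-8]
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
}

# minimum RMSD over the rotation grid after centroid removal, using
# rmsd^2(R) = (sum|p|^2 + sum|q|^2 - 2 tr(R M)) / n with M = P^T Q
grid_rmsd_min <- function(mobile, reference, rotmats) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)
  tr <- as.numeric(rotmats %*% as.vector(t(M)))
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * max(tr)) / nrow(P)))
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# --- fixture builders ---------------------------------------------------

# topology of n_res single-chain protein residues, atoms_per_res atoms each
# (first atom CA, carbon; others alternating C/N/O), plus optionally a
# 6-atom diketone ligand residue
toy_topology <- function(n_res, atoms_per_res = 4, ligand = FALSE,
                         resname = "LEU") {
  nm <- c("CA", "C", "N", "O", "CB", "CG", "CD", "CE")[seq_len(atoms_per_res)]
  el <- c("C", "C", "N", "O", "C", "C", "C", "C")[seq_len(atoms_per_res)]
  atoms <- data.frame(
    serial = seq_len(n_res * atoms_per_res),
    name = rep(nm, n_res), element = rep(el, n_res),
    resid = rep(seq_len(n_res), each = atoms_per_res),
    resname = resname, chain = "A", stringsAsFactors = FALSE
  )
  if (ligand) {
    lig <- data.frame(serial = max(atoms$serial) + 1:6,
                      name = c("C1", "C2", "C3", "C4", "O1", "O2"),
                      element = c("C", "C", "C", "C", "O", "O"),
                      resid = 1L, resname = "DKE", chain = "L",
                      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, lig)
  }
  topology(atoms)
}

# a static trajectory from one coordinate set
static_trajectory <- function(top, coords, n = 3, dt = 0.1) {
  trajectory(top, replicate(n, coords, simplify = FALSE),
             times = (seq_len(n) - 1) * dt)
}

# text of a minimal 2-residue PDB (coordinates in Angstrom)
minimal_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.000   1.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.000   0.000   1.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      12.500   1.000   2.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2      13.000   2.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2      14.000   3.000   1.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2      15.000   2.500   2.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2      15.500   3.000   3.000  1.00  0.00           O",
    "END")
}

# the antisymmetric two-domain fixture of the RMSD-share closed form:
# 6 static "A" atoms on the axes, 4 "B" atoms at height h, the B atoms
# displaced by d along z in frame 2; chosen so the optimal superposition is
# exactly the identity for both the full set and the documented subsets
two_domain_fixture <- function(b = 0.8, h = 0.5, d = 0.3) {
  base <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
    c(b, 0, h), c(-b, 0, h), c(0, b, h), c(0, -b, h)
  )
  moved <- base
  moved[7:10, 3] <- moved[7:10, 3] + d
  top <- toy_topology(10, atoms_per_res = 1)
  traj <- trajectory(top, list(base, moved), times = c(0, 0.1))
  list(traj = traj, d = d, movers = 7:10)
}
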