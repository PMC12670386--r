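# Synthetic receptor-ligand world with known ground truth: a coarse
# helical-bundle receptor (N, CA, C, O per residue) with a region layout, a
# stable core and one mobile region; a 6-heavy-atom diketone ligand with
# cis/trans templates on either side of the 0.32 nm O-O threshold; per-frame
# Bernoulli contact schedules with guaranteed contact/no-contact geometry;
# and seeded pose sets. Every statistic the pipeline measures is configured
# here, so recovery is testable without any deposited data.

# diketone templates, nm: atoms C1 C2 C3 C4 O1 O2; carbonyl carbons C2/C3
# central. O-O ~0.345 nm (trans) and ~0.272 nm (cis), safely on either side
# of the 0.32 nm classification threshold.
.diketone_template <- function(conformer = c("trans", "cis")) {
  conformer <- match.arg(conformer)
  cc <- 0.15; co <- 0.122
  c2 <- c(0, 0, 0); c3 <- c(cc, 0, 0)
  o1 <- c2 + co * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  c1 <- c2 + cc * c(cos(4 * pi / 3), sin(4 * pi / 3), 0)
  if (conformer == "trans") {
    o2 <- c3 + co * c(cos(-pi / 3), sin(-pi / 3), 0)
    c4 <- c3 + cc * c(cos(pi / 3), sin(pi / 3), 0)
  } else {
    o2 <- c3 + co * c(cos(pi / 3), sin(pi / 3), 0)
    c4 <- c3 + cc * c(cos(-pi / 3), sin(-pi / 3), 0)
  }
  m <- rbind(C1 = c1, C2 = c2, C3 = c3, C4 = c4, O1 = o1, O2 = o2)
  sweep(m, 2, colMeans(m))  # centred on the heavy-atom centroid
}

.ligand_atom_table <- function() {
  data.frame(serial = 1:6, name = c("C1", "C2", "C3", "C4", "O1", "O2"),
             element = c("C", "C", "C", "C", "O", "O"),
             resid = 1L, resname = "DKE", chain = "L",
             stringsAsFactors = FALSE)
}

# fixed per-residue backbone offsets from CA, nm (lab frame; coarse model)
.BB_OFFSETS <- rbind(N = c(-0.10, 0.05, 0), CA = c(0, 0, 0),
                     C = c(0.10, 0.05, 0), O = c(0.14, 0.16, 0))

# deterministic unit directions (Fibonacci sphere), no RNG
.sphere_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Synthetic-world specification
#'
#' Defaults encode the study conditions the pipeline is meant to recover: a
#' receptor with extracellular / transmembrane / cytoplasmic / H8 regions,
#' one mobile region (the H8 analogue), ten pocket residues whose contact
#' occupancies copy the bound-complex occupancy table (0.960 ... 0.992), and
#' a bound-ligand cis population of 69%. Geometry constants: pocket residues
#' sit 0.2 nm from the ligand centroid when in contact and 1.2 nm when not,
#' which guarantees the 0.4 nm contact rule fires exactly per the Bernoulli
#' draws under the default positional noise of 0.01 nm.
#'
#' @param n_residues number of receptor residues
#' @param region_layout a [region_spec()] for the receptor
#' @param n_frames number of trajectory frames (>= 2)
#' @param seed RNG seed (reproducibility is bitwise)
#' @param noise_sigma per-coordinate Gaussian jitter, nm
#' @param mobile_region residue sequence numbers displaced coherently
#' @param mobile_amplitude in-plane oscillation amplitude of the mobile
#'   region, nm
#' @param contact_schedule named numeric: residue seq -> contact occupancy
#'   probability in `[0, 1]`
#' @param contact_persistence Markov persistence of the contact state in
#'   `[0, 1)`; 0 (default) gives independent Bernoulli frames, where
#'   binomial tolerances are exact
#' @param cis_probability per-frame probability of the cis ligand template
#' @param contact_cutoff contact rule the geometry must honour, nm
#' @param dt_ns frame spacing, ns
#' @return object of class `SynthSpec`
#' @export
synth_spec <- function(n_residues = 60,
                       region_layout = NULL,
                       n_frames = 500,
                       seed = 1,
                       noise_sigma = 0.01,
                       mobile_region = 53:60,
                       mobile_amplitude = 0.1,
                       contact_schedule = NULL,
                       contact_persistence = 0,
                       cis_probability = 0.69,
                       contact_cutoff = 0.4,
                       dt_ns = 0.1) {
  if (is.null(region_layout)) {
    region_layout <- region_spec(
      label = c("extracellular", "transmembrane", "H8"),
      first = c(1, 11, 53), last = c(10, 40, 60)
    )
  }
  if (is.null(contact_schedule)) {
    contact_schedule <- stats::setNames(
      c(0.960, 0.918, 0.995, 0.989, 0.995, 0.999, 0.949, 0.975, 0.987, 0.992),
      seq(15, 33, 2)
    )
  }
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (any(contact_schedule < 0 | contact_schedule > 1)) {
    stop("occupancy probabilities must be in [0, 1]")
  }
  if (cis_probability < 0 || cis_probability > 1) {
    stop("cis_probability must be in [0, 1]")
  }
  if (contact_persistence < 0 || contact_persistence >= 1) {
    stop("contact_persistence must be in [0, 1)")
  }
  sched_resid <- as.integer(names(contact_schedule))
  if (any(sched_resid > n_residues) || any(mobile_region > n_residues)) {
    stop("inconsistent layout: residue index beyond n_residues")
  }
  if (length(intersect(sched_resid, mobile_region))) {
    stop("inconsistent layout: contact-schedule residues overlap the ",
         "mobile region")
  }
  structure(
    list(n_residues = as.integer(n_residues), region_layout = region_layout,
         n_frames = as.integer(n_frames), seed = as.integer(seed),
         noise_sigma = noise_sigma, mobile_region = as.integer(mobile_region),
         mobile_amplitude = mobile_amplitude,
         contact_schedule = contact_schedule,
         contact_persistence = contact_persistence,
         cis_probability = cis_probability,
         contact_cutoff = contact_cutoff, dt_ns = dt_ns,
         # geometry constants of the stated world
         d_contact = 0.2, d_far = 1.2, helix_radius = 1.2),
    class = "SynthSpec"
  )
}

.schedule_resids <- function(spec) as.integer(names(spec$contact_schedule))

.residue_names <- function(spec) {
  nm <- rep("LEU", spec$n_residues)
  pocket <- c("MET", "PHE", "LEU", "TYR", "CYS", "PHE", "TRP", "TYR",
              "THR", "PHE")
  sched <- .schedule_resids(spec)
  nm[sched] <- rep_len(pocket, length(sched))
  nm
}

# CA positions of the receptor reference structure (pocket residues at the
# contact position)
.receptor_ca <- function(spec) {
  n <- spec$n_residues
  sched <- .schedule_resids(spec)
  ca <- matrix(NA_real_, n, 3)
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  z <- -1.5 + 3 * (seq_len(n) - 1) / max(1, n - 1)
  ca[, 1] <- spec$helix_radius * cos(theta)
  ca[, 2] <- spec$helix_radius * sin(theta)
  ca[, 3] <- z
  if (length(sched)) {
    dirs <- .sphere_dirs(length(sched))
    ca[sched, ] <- dirs * spec$d_contact
  }
  ca
}

#' Build the synthetic receptor
#'
#' Coarse helical-bundle backbone (N, CA, C, O per residue) with region
#' labels from the layout; the pocket locus for ligand placement is the
#' origin, and contact-schedule residues sit at their in-contact positions
#' in the reference structure.
#'
#' @param spec a [synth_spec()]
#' @return list with `topology` (annotated) and `coords` (atoms x 3, nm)
#' @export
make_receptor <- function(spec) {
  n <- spec$n_residues
  ca <- .receptor_ca(spec)
  resnames <- .residue_names(spec)
  an <- rownames(.BB_OFFSETS)
  atoms <- data.frame(
    serial = seq_len(4 * n),
    name = rep(an, n),
    element = rep(c("N", "C", "C", "O"), n),
    resid = rep(seq_len(n), each = 4),
    resname = rep(resnames, each = 4),
    chain = "A", stringsAsFactors = FALSE
  )
  coords <- ca[rep(seq_len(n), each = 4), ] +
    .BB_OFFSETS[rep(seq_len(4), n), ]
  top <- assign_regions(topology(atoms), spec$region_layout)
  list(topology = top, coords = unname(coords))
}

# combined receptor+ligand topology
.complex_topology <- function(spec, receptor) {
  lig <- .ligand_atom_table()
  lig$serial <- max(receptor$topology$atoms$serial) + seq_len(nrow(lig))
  top <- topology(rbind(receptor$topology$atoms, lig))
  assign_regions(top, spec$region_layout)
}

.rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# feasibility of the guaranteed contact / no-contact geometry
.check_contact_geometry <- function(spec, receptor) {
  tmpl <- .diketone_template("trans")
  r_in <- min(sqrt(rowSums(tmpl^2)))   # an atom always this close to centre
  r_out <- max(sqrt(rowSums(tmpl^2)))  # no atom ever farther than this
  margin <- 6 * spec$noise_sigma * sqrt(2)
  sched <- .schedule_resids(spec)
  # in-contact: the CA itself sits at d_contact from the ligand centre
  if (spec$d_contact + r_in > spec$contact_cutoff - margin) {
    stop("contact geometry infeasible for residue ", sched[1],
         ": noise_sigma too large for the contact margin")
  }
  keys <- atom_residue_keys(receptor$topology)
  dist0 <- sqrt(rowSums(receptor$coords^2))
  for (r in seq_len(spec$n_residues)) {
    idx <- which(keys == residue_key("A", r))
    lo <- min(dist0[idx])
    mobile <- r %in% spec$mobile_region
    need <- spec$contact_cutoff + r_out + margin +
      if (mobile) spec$mobile_amplitude else 0
    if (r %in% sched) {
      lo_far <- lo - spec$d_contact + spec$d_far  # CA moved to d_far
      if (lo_far - 0.3 < need) {  # 0.3 > max backbone offset norm
        stop("contact geometry infeasible for residue ", r,
             ": far position too close to the pocket")
      }
    } else if (lo < need) {
      stop("contact geometry infeasible for residue ", r,
           ": bystander residue encroaches on the pocket")
    }
  }
  invisible(TRUE)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a synthetic receptor-ligand trajectory
#'
#' Per frame: Gaussian jitter on all atoms; the mobile region additionally
#' displaced in the xy plane by a random-phase oscillation of the stated
#' amplitude; each contact-schedule residue placed at its in-contact or far
#' position by an (independent or Markov) Bernoulli draw of its occupancy;
#' the ligand drawn cis with `cis_probability`, randomly rotated and placed
#' at the pocket locus. The geometry guarantees the 0.4 nm contact rule
#' matches the Bernoulli draws exactly; infeasible configurations (noise too
#' large for the margins) error naming the residue.
#'
#' The realized ground truth is attached as attribute `truth`: per-residue
#' contact draws, cis/trans draws and mobile phases.
#'
#' @param spec a [synth_spec()]
#' @param receptor output of [make_receptor()] (built from `spec` if `NULL`)
#' @return a [trajectory()] of the receptor-ligand complex
#' @export
make_trajectory <- function(spec, receptor = NULL) {
  if (is.null(receptor)) receptor <- make_receptor(spec)
  .check_contact_geometry(spec, receptor)
  top <- .complex_topology(spec, receptor)
  nf <- spec$n_frames
  na_rec <- nrow(receptor$coords)
  na <- n_atoms(top)
  keys_rec <- atom_residue_keys(receptor$topology)
  sched <- .schedule_resids(spec)
  tmpl <- list(trans = .diketone_template("trans"),
               cis = .diketone_template("cis"))
  .with_seed(spec$seed, {
    noise <- array(stats::rnorm(nf * na * 3, 0, spec$noise_sigma),
                   c(nf, na, 3))
    phases <- stats::runif(nf, 0, 2 * pi)
    contact <- matrix(FALSE, nf, length(sched),
                      dimnames = list(NULL, as.character(sched)))
    for (j in seq_along(sched)) {
      p <- spec$contact_schedule[[j]]
      rho <- spec$contact_persistence
      u <- stats::runif(nf)
      if (rho == 0) {
        contact[, j] <- u < p
      } else {
        s <- logical(nf)
        s[1] <- u[1] < p
        for (i in 2:nf) {
          pt <- if (s[i - 1]) rho + (1 - rho) * p else (1 - rho) * p
          s[i] <- u[i] < pt
        }
        contact[, j] <- s
      }
    }
    is_cis <- stats::runif(nf) < spec$cis_probability
    rots <- lapply(seq_len(nf), function(i) .rand_rotation())
  })
  coords <- array(NA_real_, c(nf, na, 3))
  base <- receptor$coords
  mob_atoms <- which(receptor$topology$atoms$resid %in% spec$mobile_region)
  far_shift <- spec$d_far - spec$d_contact
  sched_dirs <- if (length(sched)) .sphere_dirs(length(sched)) else NULL
  sched_atoms <- lapply(sched, function(r) which(keys_rec == residue_key("A", r)))
  for (i in seq_len(nf)) {
    fr <- base
    if (length(mob_atoms)) {
      disp <- spec$mobile_amplitude * c(cos(phases[i]), sin(phases[i]), 0)
      fr[mob_atoms, ] <- sweep(fr[mob_atoms, , drop = FALSE], 2, disp, "+")
    }
    for (j in seq_along(sched)) {
      if (!contact[i, j]) {
        fr[sched_atoms[[j]], ] <- sweep(fr[sched_atoms[[j]], , drop = FALSE],
                                        2, sched_dirs[j, ] * far_shift, "+")
      }
    }
    lig <- tmpl[[if (is_cis[i]) "cis" else "trans"]] %*% t(rots[[i]])
    coords[i, , ] <- rbind(fr, lig) + matrix(noise[i, , ], na, 3)
  }
  traj <- trajectory(top, coords, times = (seq_len(nf) - 1) * spec$dt_ns)
  attr(traj, "truth") <- list(contact = contact, is_cis = is_cis,
                              phases = phases)
  traj
}

#' Generate a synthetic docking pose set
#'
#' Pose k anchors the ligand centroid on a pocket residue's reference CA
#' (contact with the anchor is then guaranteed), with the cis template drawn
#' at `cis_probability` and affinities drawn Normal(-2.5, 2.0) kcal/mol
#' unless supplied -- a shape giving roughly 78% of poses below 0 and 60%
#' below -2 kcal/mol. Deterministic given the spec seed.
#'
#' @param spec a [synth_spec()]
#' @param receptor output of [make_receptor()] (built from `spec` if `NULL`)
#' @param n_poses number of poses
#' @param affinities optional explicit affinities (kcal/mol)
#' @param anchors optional residue seq numbers (recycled) the poses anchor
#'   on; default: sampled from the contact schedule
#' @param cis_probability per-pose cis template probability (default 0.40,
#'   the near-equal split seen across docking poses)
#' @return a `PoseSet`; attribute `truth` holds anchors and cis draws
#' @export
make_pose_set <- function(spec, receptor = NULL, n_poses = 50,
                          affinities = NULL, anchors = NULL,
                          cis_probability = 0.40) {
  if (is.null(receptor)) receptor <- make_receptor(spec)
  sched <- .schedule_resids(spec)
  if (!length(sched)) stop("contact schedule is empty: no pocket to anchor on")
  ca_idx <- which(receptor$topology$atoms$name == "CA")
  tmpl <- list(trans = .diketone_template("trans"),
               cis = .diketone_template("cis"))
  .with_seed(spec$seed + 1L, {
    if (is.null(affinities)) affinities <- stats::rnorm(n_poses, -2.5, 2.0)
    if (is.null(anchors)) {
      anchors <- sched[sample.int(length(sched), n_poses, replace = TRUE)]
    }
    is_cis <- stats::runif(n_poses) < cis_probability
  })
  anchors <- rep_len(anchors, n_poses)
  coords <- vector("list", n_poses)
  for (k in seq_len(n_poses)) {
    ca <- receptor$coords[ca_idx[anchors[k]], ]
    coords[[k]] <- sweep(tmpl[[if (is_cis[k]) "cis" else "trans"]], 2, ca, "+")
  }
  ps <- pose_set(.ligand_atom_table(), coords, affinities,
                 source = paste0("anchor_", anchors))
  attr(ps, "truth") <- list(anchors = anchors, is_cis = is_cis)
  ps
}
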