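# Contact detection and occupancy/retention statistics against brute-force
# oracles and constructed ground truth.

test_that("residue_contacts applies the 0.4 nm minimum-distance rule", {
  top <- toy_topology(2, atoms_per_res = 1, ligand = TRUE)
  # residue 1 CA at 0.39 nm from a ligand atom; residue 2 at 0.41 nm
  xyz <- matrix(0, n_atoms(top), 3)
  xyz[1, ] <- c(0.39, 0, 0)
  xyz[2, ] <- c(-0.41, 0, 0)
  xyz[3:8, ] <- 0  # ligand atoms at the origin
  hits <- residue_contacts(top, xyz, "L:1")
  expect_true(residue_key("A", 1) %in% hits)
  expect_false(residue_key("A", 2) %in% hits)
})

test_that("residue_contacts equals the brute-force all-pairs scan", {
  set.seed(40)
  top <- toy_topology(11, atoms_per_res = 4, ligand = TRUE)
  keys <- atom_residue_keys(top)
  rec_idx <- which(top$atoms$chain == "A")
  lig_idx <- which(top$atoms$chain == "L")
  for (i in 1:30) {
    xyz <- matrix(runif(n_atoms(top) * 3, 0, 1.2), ncol = 3)
    got <- residue_contacts(top, xyz, "L:1")
    want <- brute_contacts(xyz[rec_idx, ], keys[rec_idx], xyz[lig_idx, ],
                           0.4, top$atoms$element[rec_idx],
                           top$atoms$element[lig_idx])
    expect_setequal(got, want)
  }
})

test_that("contact rule is symmetric under role exchange", {
  set.seed(41)
  top <- toy_topology(4, atoms_per_res = 3, ligand = TRUE)
  xyz <- matrix(runif(n_atoms(top) * 3, 0, 0.8), ncol = 3)
  keys <- atom_residue_keys(top)
  lig_idx <- which(top$atoms$chain == "L")
  hits <- residue_contacts(top, xyz, "L:1")
  for (r in unique(keys[top$atoms$chain == "A"])) {
    ridx <- which(keys == r)
    rev_hit <- length(brute_contacts(xyz[lig_idx, ], rep("L:1", 6),
                                     xyz[ridx, ], 0.4,
                                     top$atoms$element[lig_idx],
                                     top$atoms$element[ridx])) > 0
    expect_equal(r %in% hits, rev_hit)
  }
})

test_that("interaction_probability recovers configured occupancy", {
  # all-frames contact
  spec <- synth_spec(n_frames = 50, seed = 42, noise_sigma = 0,
                     mobile_amplitude = 0,
                     contact_schedule = stats::setNames(1.0, 15))
  traj <- make_trajectory(spec)
  ip <- interaction_probability(traj, "L:1", window = seq_len(50))
  expect_equal(unname(ip["A:15"]), 100)

  # configured 0.75 at n = 2000: within 2%
  spec <- synth_spec(n_frames = 2000, seed = 43,
                     contact_schedule = stats::setNames(0.75, 15))
  traj <- make_trajectory(spec)
  ip <- interaction_probability(traj, "L:1", window = seq_len(2000))
  expect_lt(abs(ip[["A:15"]] - 75), 2)
  # and exactly equal to the realized Bernoulli draws
  expect_equal(ip[["A:15"]], 100 * mean(attr(traj, "truth")$contact[, "15"]))

  expect_error(interaction_probability(traj, "L:1", window = integer(0)),
               "empty")
})

test_that("interaction_probability is bounded and monotone in cutoff", {
  spec <- synth_spec(n_frames = 200, seed = 44)
  traj <- make_trajectory(spec)
  ip1 <- interaction_probability(traj, "L:1", cutoff = 0.3)
  ip2 <- interaction_probability(traj, "L:1", cutoff = 0.45)
  expect_true(all(ip1 >= 0 & ip1 <= 100))
  expect_true(all(ip2[names(ip1)] >= ip1 - 1e-12))
})

test_that("occupancy estimates are unbiased over seeds", {
  p_true <- 0.6
  est <- vapply(1:50, function(s) {
    spec <- synth_spec(n_residues = 20, n_frames = 2000, seed = s,
                       region_layout = region_spec(
                         c("extracellular", "transmembrane", "H8"),
                         c(1, 5, 18), c(4, 17, 20)),
                       mobile_region = 18:20,
                       contact_schedule = stats::setNames(p_true, 10))
    traj <- make_trajectory(spec)
    interaction_probability(traj, "L:1", window = seq_len(2000))[["A:10"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - 100 * p_true), 0.5)
})

test_that("conserved_contact_fraction arithmetic and bounds", {
  expect_equal(conserved_contact_fraction(c("A", "B"), c("A", "B")), 100)
  expect_equal(conserved_contact_fraction(c("A", "B", "X"),
                                          c("A", "B", "C", "D")), 50)
  expect_equal(conserved_contact_fraction(c("A", "B", "C", "D", "E"),
                                          c("A", "B")), 100)  # superset
  expect_equal(conserved_contact_fraction(c("X", "Y"), c("A", "B")), 0)
  expect_error(conserved_contact_fraction(c("A"), character(0)), "empty")
})

test_that("retention_series computes the per-frame conserved fraction", {
  spec <- synth_spec(n_frames = 300, seed = 45,
                     contact_schedule = stats::setNames(c(0.9, 0.5), c(15, 17)))
  traj <- make_trajectory(spec)
  ref <- c("A:15", "A:17")
  ret <- retention_series(traj, "L:1", ref)
  truth <- attr(traj, "truth")$contact
  expect_equal(ret$retained, 100 * rowMeans(truth))
  # cross-pose variant is the same formula with a different reference
  ret1 <- retention_series(traj, "L:1", "A:15")
  expect_equal(ret1$retained, 100 * as.numeric(truth[, "15"]))
})

test_that("hydrophobic_occurrence counts only C-C pairs, matches brute force", {
  top <- toy_topology(1, atoms_per_res = 4, ligand = TRUE)
  # frame 1: residue O atom 0.2 nm from ligand C (not C-C); C atoms far
  # frame 2: residue CA (C) 0.39 nm from ligand C1
  f1 <- matrix(2, n_atoms(top), 3); f2 <- matrix(2, n_atoms(top), 3)
  lig <- which(top$atoms$chain == "L")
  f1[lig, ] <- 0; f2[lig, ] <- 0
  f1[which(top$atoms$name == "O"), ] <- c(0.2, 0, 0)
  f2[1, ] <- c(0.39, 0, 0)  # CA carbon
  traj <- trajectory(top, list(f1, f2), times = c(0, 1))
  expect_equal(hydrophobic_occurrence(traj, "A:1", "L:1",
                                      window = 1:2), 50)
  expect_equal(hydrophobic_occurrence(traj, "A:1", "L:1", window = 1), 0)
  expect_equal(hydrophobic_occurrence(traj, "A:1", "L:1", window = 2), 100)

  set.seed(46)
  frames <- replicate(40, matrix(runif(n_atoms(top) * 3, 0, 0.9), ncol = 3),
                      simplify = FALSE)
  rtraj <- trajectory(top, frames, times = seq_len(40))
  got <- hydrophobic_occurrence(rtraj, "A:1", "L:1", window = seq_len(40))
  ridx <- which(top$atoms$chain == "A")
  want <- 100 * mean(vapply(frames, function(f) {
    brute_cc_contact(f[ridx, ], top$atoms$element[ridx],
                     f[lig, ], top$atoms$element[lig], 0.4)
  }, logical(1)))
  expect_equal(got, want)
})

test_that("hbond_occurrence applies the distance-and-angle criterion", {
  atoms <- data.frame(serial = 1:3, name = c("NE1", "HE1", "O1"),
                      element = c("N", "H", "O"), resid = c(1, 1, 2),
                      resname = c("TRP", "TRP", "DKE"),
                      chain = c("A", "A", "L"), stringsAsFactors = FALSE)
  top <- topology(atoms)
  geom <- function(dist, angle_deg) {
    a <- angle_deg * pi / 180
    rbind(c(0, 0, 0),                        # donor N
          0.1 * c(cos(a), sin(a), 0),        # H at the given H-D-A angle
          c(dist, 0, 0))                     # acceptor along x
  }
  mk <- function(...) {
    gs <- list(...)
    trajectory(top, gs, times = seq_along(gs))
  }
  expect_equal(hbond_occurrence(mk(geom(0.30, 10)), c(1, 2), 3,
                                window = 1), 100)
  expect_equal(hbond_occurrence(mk(geom(0.40, 0)), c(1, 2), 3,
                                window = 1), 0)
  expect_equal(hbond_occurrence(mk(geom(0.30, 40)), c(1, 2), 3,
                                window = 1), 0)
  expect_error(hbond_occurrence(mk(geom(0.3, 0)), c(1, 3), 3, window = 1),
               "hydrogen")

  # grid sweep against the brute criterion
  ds <- seq(0.2, 0.5, by = 0.05); as_ <- seq(0, 60, by = 10)
  for (d in ds) for (a in as_) {
    tr <- mk(geom(d, a))
    want <- 100 * brute_hbond(c(0, 0, 0), 0.1 * c(cos(a * pi / 180),
                                                  sin(a * pi / 180), 0),
                              c(d, 0, 0), 0.35, 30)
    expect_equal(hbond_occurrence(tr, c(1, 2), 3, window = 1), want)
  }
})

test_that("contact_count_histogram matches per-pose brute-force counts", {
  spec <- synth_spec(n_frames = 2, seed = 47)
  rec <- make_receptor(spec)
  ps <- make_pose_set(spec, rec, n_poses = 12)
  hist <- contact_count_histogram(ps, rec$topology, rec$coords)
  keys <- atom_residue_keys(rec$topology)
  want <- vapply(seq_len(n_poses(ps)), function(k) {
    length(brute_contacts(rec$coords, keys,
                          matrix(ps$coords[k, , ], ncol = 3), 0.4,
                          rec$topology$atoms$element,
                          ps$atoms$element))
  }, numeric(1))
  expect_equal(unname(hist$counts), want)
  expect_equal(sum(hist$histogram), 12)

  # single pose: all mass at its count
  one <- filter_poses(ps, max_affinity = sort(ps$affinity)[1] + 1e-9)
  h1 <- contact_count_histogram(one, rec$topology, rec$coords)
  expect_equal(as.integer(h1$histogram), 1L)
})
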