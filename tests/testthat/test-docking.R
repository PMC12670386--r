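# Principal-axis alignment, docking-box construction, pose I/O, affinity
# filtering, representative-pose selection.

test_that("principal_axis_to_z concentrates variance on z", {
  set.seed(30)
  rod_z <- cbind(rnorm(50, 0, 0.1), rnorm(50, 0, 0.1), seq(-2, 2, length.out = 50))
  out <- principal_axis_to_z(rod_z)
  v <- apply(out$coords, 2, stats::var)
  expect_equal(which.max(v), 3L)

  rod_x <- rod_z[, c(3, 1, 2)]
  out <- principal_axis_to_z(rod_x)
  v <- apply(out$coords, 2, stats::var)
  expect_equal(which.max(v), 3L)
  # eigenvector check: variance-maximizing axis of the rotated cloud is z
  ctr <- sweep(out$coords, 2, colMeans(out$coords))
  ev <- eigen(crossprod(ctr), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(ev[3]), 1, tolerance = 1e-8)
  expect_equal(det(out$rotation), 1, tolerance = 1e-10)

  # rigidity: pairwise distances unchanged
  expect_equal(as.numeric(dist(out$coords)), as.numeric(dist(rod_x)),
               tolerance = 1e-10)

  expect_error(principal_axis_to_z(rod_x[1:2, ]), ">= 3")
})

test_that("principal axis sign convention points z toward the EC side", {
  spec <- synth_spec(n_frames = 2)
  rec <- make_receptor(spec)
  out <- principal_axis_to_z(rec$coords, rec$topology)
  ec <- select_atoms(rec$topology, region = "extracellular")
  ctr <- sweep(out$coords, 2, colMeans(out$coords))
  expect_gt(mean(ctr[ec, 3]), 0)
})

test_that("build_box midpoint construction and defaults", {
  # toy: TM CA centroid at origin, EC CA centroid at (0,0,20) A = 2 nm
  atoms <- data.frame(serial = 1:6, name = "CA", element = "C",
                      resid = 1:6, resname = "LEU", chain = "A",
                      stringsAsFactors = FALSE)
  top <- topology(atoms)
  top <- assign_regions(top, region_spec(c("transmembrane", "extracellular"),
                                         c(1, 4), c(3, 6)))
  xyz <- rbind(c(0.1, 0, 0), c(-0.1, 0, 0), c(0, 0, 0),
               c(0.2, 0, 2), c(-0.2, 0, 2), c(0, 0, 2))
  box <- build_box(top, xyz)
  expect_equal(box$center, c(0, 0, 10))
  expect_equal(box$dims, c(15, 15, 25))
  expect_equal(build_box(top, xyz, half_extent = TRUE)$dims, c(30, 30, 50))

  # brute-force centroid arithmetic
  c_tm <- colMeans(xyz[1:3, ]); c_ec <- colMeans(xyz[4:6, ])
  expect_equal(box$center, as.numeric((c_tm + c_ec) / 2 * 10))

  top_no_ec <- assign_regions(topology(atoms),
                              region_spec("transmembrane", 1, 6))
  expect_error(build_box(top_no_ec, xyz), "extracellular")

  cfg <- vina_config(box)
  expect_match(cfg[3], "center_z = 10.000")
  expect_match(cfg[6], "size_z = 25.000")
})

test_that("box center is rigid-transform equivariant", {
  atoms <- data.frame(serial = 1:6, name = "CA", element = "C",
                      resid = 1:6, resname = "LEU", chain = "A",
                      stringsAsFactors = FALSE)
  top <- assign_regions(topology(atoms),
                        region_spec(c("transmembrane", "extracellular"),
                                    c(1, 4), c(3, 6)))
  set.seed(31)
  xyz <- matrix(rnorm(18), ncol = 3)
  R <- random_rotation_matrix(); t0 <- rnorm(3)
  moved <- sweep(xyz %*% t(R), 2, t0, "+")
  c1 <- build_box(top, xyz)$center / 10
  c2 <- build_box(top, moved)$center / 10
  expect_equal(c2, as.numeric(R %*% c1 + t0), tolerance = 1e-10)
})

test_that("pose files round-trip with affinities in order", {
  atoms <- data.frame(serial = 1:6,
                      name = c("C1", "C2", "C3", "C4", "O1", "O2"),
                      element = c("C", "C", "C", "C", "O", "O"),
                      resid = 1L, resname = "DKE", chain = "L",
                      stringsAsFactors = FALSE)
  set.seed(32)
  coords <- replicate(3, matrix(rnorm(18, sd = 0.3), ncol = 3),
                      simplify = FALSE)
  ps <- pose_set(atoms, coords, affinity = c(-4.5, -1.0, 0.5))
  p <- withr::local_tempfile(fileext = ".pdbqt")
  write_poses(ps, p)
  rt <- read_poses(p)
  expect_equal(n_poses(rt), 3)
  expect_equal(rt$affinity, c(-4.5, -1.0, 0.5), tolerance = 0.05)
  expect_equal(rt$coords, ps$coords, tolerance = 1e-3)

  empty <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines("", empty)
  expect_error(read_poses(empty), "no poses")

  lines <- readLines(p)
  writeLines(lines[!grepl("VINA RESULT", lines)][1:8], p)
  expect_error(read_poses(p), "affinity")

  expect_error(pose_set(atoms, coords, c(-1, NA, 0)), "finite")
})

test_that("filter_poses is strict, idempotent and order-preserving", {
  atoms <- data.frame(serial = 1:3, name = c("C1", "C2", "O1"),
                      element = c("C", "C", "O"), resid = 1L,
                      resname = "DKE", chain = "L", stringsAsFactors = FALSE)
  coords <- replicate(5, matrix(0, 3, 3), simplify = FALSE)
  ps <- pose_set(atoms, coords, c(-4.5, -1.0, 0.5, -2.0, -3.0))

  kept <- filter_poses(ps, max_affinity = -2)
  expect_equal(kept$affinity, c(-4.5, -3.0))  # -2.0 excluded: strict
  expect_equal(filter_poses(kept, max_affinity = -2)$affinity, kept$affinity)
  expect_equal(filter_poses(ps, max_affinity = Inf)$affinity, ps$affinity)
  expect_equal(filter_poses(ps, min_affinity = 0)$affinity, 0.5)
  expect_equal(n_poses(filter_poses(c1 <- ps, max_affinity = -10)), 0)
})

test_that("representative_pose maximizes mean Jaccard with stated ties", {
  # receptor: three single-atom residues far apart
  atoms <- data.frame(serial = 1:3, name = "CA", element = "C",
                      resid = 1:3, resname = "LEU", chain = "A",
                      stringsAsFactors = FALSE)
  top <- topology(atoms)
  rec_xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  lig_atoms <- data.frame(serial = 1, name = "C1", element = "C",
                          resid = 1L, resname = "DKE", chain = "L",
                          stringsAsFactors = FALSE)
  at_res <- function(i) matrix(rec_xyz[i, ] + c(0.1, 0, 0), 1, 3)

  # contact sets {1}, {1}, {3}: one of the first two wins, tie -> lower
  # affinity
  ps <- pose_set(lig_atoms, list(at_res(1), at_res(1), at_res(3)),
                 affinity = c(-3, -5, -9))
  rp <- representative_pose(ps, top, rec_xyz)
  expect_equal(rp$index, 2L)
  expect_equal(rp$contacts, residue_key("A", 1))

  # all poses identical: lowest affinity, then file order
  ps2 <- pose_set(lig_atoms, list(at_res(2), at_res(2), at_res(2)),
                  affinity = c(-4, -4, -4))
  expect_equal(representative_pose(ps2, top, rec_xyz)$index, 1L)

  # single pose
  ps3 <- pose_set(lig_atoms, list(at_res(1)), affinity = -1)
  expect_equal(representative_pose(ps3, top, rec_xyz)$index, 1L)

  # invariance to pose order up to the tie-break chain
  ord <- c(3, 1, 2)
  ps4 <- pose_set(lig_atoms, list(at_res(3), at_res(1), at_res(1)),
                  affinity = c(-9, -3, -5))
  expect_equal(representative_pose(ps4, top, rec_xyz)$index, 3L)
})
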