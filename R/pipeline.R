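# Staged pipeline driver: orchestrates the study stages (synthetic
# simulation, unbound-receptor stability, ligand conformers, docking prep,
# pose statistics, complex contact analysis, alanine scan) from a single
# config, writing TSV tables plus a machine-readable JSON summary per stage.
# Outputs are deterministic given config + seeds; every threshold actually
# used is recorded in the summary.

.default_thresholds <- function() {
  list(contact_cutoff = 0.4,      # nm, generic residue-ligand contact
       cis_threshold = 0.32,      # nm, O-O cis/trans boundary
       affinity_max = -2,         # kcal/mol, high-affinity filter (strict <)
       affinity_favorable = -4,   # kcal/mol, favorable-pose class
       affinity_unfavorable = 0,  # kcal/mol, negative-control class (strict >)
       hbond_d_cut = 0.35,        # nm, donor-acceptor distance
       hbond_angle_cut = 30)      # degrees, H-D-A angle
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config$thresholds <- utils::modifyList(.default_thresholds(),
                                         as.list(config$thresholds))
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.cfg_region_spec <- function(cfg) {
  if (!is.null(cfg$regions)) {
    region_spec(cfg$regions$label, cfg$regions$first, cfg$regions$last)
  } else {
    odr10_region_spec()
  }
}

.cfg_synth_spec <- function(cfg) {
  args <- as.list(cfg$synth)
  if (!is.null(args$region_layout)) {
    args$region_layout <- region_spec(args$region_layout$label,
                                      args$region_layout$first,
                                      args$region_layout$last)
  }
  if (!is.null(args$contact_schedule)) {
    args$contact_schedule <- unlist(args$contact_schedule)
  }
  if (is.null(args$seed)) args$seed <- cfg$seed
  do.call(synth_spec, args)
}

.write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  path
}

.require_inputs <- function(cfg, fields) {
  for (f in fields) {
    v <- cfg[[f]]
    if (is.null(v)) stop("config missing required input: ", f)
    if (is.character(v) && !all(file.exists(v))) {
      stop("input path does not exist: ", v[!file.exists(v)][1])
    }
  }
}

.ligand_key <- function(cfg, top) {
  if (!is.null(cfg$ligand_residue)) return(cfg$ligand_residue)
  lig <- names(top$region)[top$region %in% "ligand"]
  if (!length(lig)) stop("no ligand residue in topology")
  lig[1]
}

.stage_simulate <- function(cfg, out) {
  spec <- .cfg_synth_spec(cfg)
  receptor <- make_receptor(spec)
  traj <- make_trajectory(spec, receptor)
  poses <- make_pose_set(spec, receptor,
                         n_poses = if (is.null(cfg$n_poses)) 50 else cfg$n_poses)
  files <- c(
    structure = write_structure(receptor$topology, receptor$coords,
                                file.path(out, "receptor.pdb")),
    complex = write_structure(traj$topology, frame_coords(traj, 1),
                              file.path(out, "complex.pdb")),
    trajectory = write_frames(traj, file.path(out, "complex.frames")),
    poses = write_poses(poses, file.path(out, "poses.pdbqt")),
    regions = .write_tsv(region_table(receptor$topology),
                         file.path(out, "regions.tsv"),
                         "receptor region labels")
  )
  summary <- list(
    stage = "simulate", seed = spec$seed,
    n_frames = spec$n_frames, n_residues = spec$n_residues,
    n_poses = n_poses(poses),
    configured = list(contact_schedule = as.list(spec$contact_schedule),
                      cis_probability = spec$cis_probability,
                      noise_sigma_nm = spec$noise_sigma,
                      mobile_amplitude_nm = spec$mobile_amplitude)
  )
  list(files = files, summary = summary)
}

.stage_unbound <- function(cfg, out) {
  st <- read_structure(cfg$structure)
  top <- assign_regions(st$topology, .cfg_region_spec(cfg))
  traj <- read_trajectory(cfg$trajectory, top, format = "frames")
  traj$topology <- top
  bb <- backbone_atoms(top)
  tm <- select_atoms(top, name = c("N", "CA", "C", "O"),
                     region = "transmembrane")
  share_regions <- cfg$share_regions
  if (is.null(share_regions)) {
    share_regions <- list(H8 = "H8",
                          nonmembrane = c("extracellular", "cytoplasmic", "H8"))
  }
  rmsd_tab <- data.frame(time = traj$times,
                         backbone = rmsd_series(traj, 1, bb))
  if (length(tm)) rmsd_tab$transmembrane <- rmsd_series(traj, 1, tm)
  shares <- list()
  for (nm in names(share_regions)) {
    keys <- top$residues$key[top$region[top$residues$key] %in%
                               share_regions[[nm]]]
    sh <- rmsd_share(traj, 1, bb, keys)
    .write_tsv(sh, file.path(out, paste0("share_", nm, ".tsv")),
               sprintf("RMSD share of region '%s' (percent); RMSD nm", nm))
    shares[[nm]] <- list(mean_share = mean(sh$share, na.rm = TRUE),
                         skipped_frames = attr(sh, "skipped"))
  }
  rf <- rmsf(traj, selection = bb)
  files <- c(
    rmsd = .write_tsv(rmsd_tab, file.path(out, "rmsd.tsv"),
                      "backbone RMSD vs frame 1, nm; time ns"),
    rmsf = .write_tsv(rf, file.path(out, "rmsf.tsv"),
                      "per-residue backbone RMSF, nm")
  )
  summary <- list(stage = "unbound", n_frames = n_frames(traj),
                  shares = shares,
                  mean_rmsd_backbone = mean(rmsd_tab$backbone))
  list(files = files, summary = summary)
}

.stage_ligand <- function(cfg, out) {
  st <- read_structure(cfg$structure)
  top <- assign_regions(st$topology, .cfg_region_spec(cfg))
  traj <- read_trajectory(cfg$trajectory, top, format = "frames")
  traj$topology <- top
  lig <- .ligand_key(cfg, top)
  keys <- atom_residue_keys(top)
  ox <- which(keys == lig & toupper(top$atoms$element) == "O")
  if (length(ox) != 2) stop("ligand must have exactly two oxygens")
  th <- cfg$thresholds
  series <- conformer_series(traj, ox, threshold = th$cis_threshold)
  lig_heavy <- which(keys == lig & .heavy(top$atoms$element))
  model <- conformer_pca(traj, lig_heavy)
  k <- if (is.null(cfg$k_clusters)) 3 else cfg$k_clusters
  model <- conformer_clusters(model, k = k, seed = cfg$seed)
  clus <- data.frame(frame = seq_len(n_frames(traj)),
                     PC1 = model$scores[, 1], PC2 = model$scores[, 2],
                     cluster = model$assignments)
  files <- c(
    conformers = .write_tsv(series, file.path(out, "conformers.tsv"),
                            sprintf("O-O distance nm; cis iff d <= %.2f nm",
                                    th$cis_threshold)),
    clusters = .write_tsv(clus, file.path(out, "clusters.tsv"),
                          "PCA scores and k-means cluster per frame")
  )
  medoids <- list()
  for (cl in seq_len(k)) {
    cc <- cluster_centroid_conformer(model, traj, lig_heavy, cl)
    sub <- top$atoms[lig_heavy, , drop = FALSE]
    p <- file.path(out, sprintf("centroid_cluster%d.pdb", cl))
    write_structure(topology(sub), cc$coords, p)
    medoids[[as.character(cl)]] <- cc$frame
  }
  summary <- list(
    stage = "ligand", cis_threshold_nm = th$cis_threshold,
    cis_fraction_pct = cis_fraction(series),
    explained_variance = model$explained_variance[1:min(2, length(model$explained_variance))],
    k = k, medoid_frames = medoids,
    cluster_sizes = as.list(table(model$assignments))
  )
  list(files = files, summary = summary)
}

.stage_dockprep <- function(cfg, out) {
  st <- read_structure(cfg$structure)
  top <- assign_regions(st$topology, .cfg_region_spec(cfg))
  rot <- principal_axis_to_z(st$coords, top)
  box <- build_box(top, rot$coords,
                   dims = if (is.null(cfg$box_dims)) c(15, 15, 25)
                          else cfg$box_dims)
  files <- c(
    rotated = write_structure(top, rot$coords,
                              file.path(out, "receptor_zaligned.pdb")),
    box = {
      p <- file.path(out, "box.txt")
      writeLines(vina_config(box), p)
      p
    }
  )
  summary <- list(stage = "dockprep", center_angstrom = box$center,
                  dims_angstrom = box$dims)
  list(files = files, summary = summary)
}

.stage_posestats <- function(cfg, out) {
  st <- read_structure(cfg$structure)
  top <- assign_regions(st$topology, .cfg_region_spec(cfg))
  poses <- read_poses(cfg$poses)
  th <- cfg$thresholds
  high <- filter_poses(poses, max_affinity = th$affinity_max)
  hist <- contact_count_histogram(high, top, st$coords, th$contact_cutoff)
  occ <- pose_residue_occurrence(high, top, st$coords, th$contact_cutoff)
  fav <- filter_poses(poses, max_affinity = th$affinity_favorable)
  unf <- filter_poses(poses, min_affinity = th$affinity_unfavorable)
  rep_fav <- if (n_poses(fav)) {
    representative_pose(fav, top, st$coords, th$contact_cutoff)
  }
  rep_unf <- if (n_poses(unf)) {
    representative_pose(unf, top, st$coords, th$contact_cutoff)
  }
  files <- c(
    summary_tsv = .write_tsv(pose_summary(poses, top, st$coords,
                                          th$contact_cutoff),
                             file.path(out, "pose_summary.tsv"),
                             "affinity kcal/mol; contacts at 0.4 nm rule"),
    histogram = .write_tsv(
      data.frame(n_contacts = as.integer(names(hist$histogram)),
                 n_poses = as.integer(hist$histogram)),
      file.path(out, "contact_count_histogram.tsv"),
      sprintf("poses with affinity < %g kcal/mol", th$affinity_max)),
    occurrence = .write_tsv(
      data.frame(residue = names(occ), occurrence_pct = unname(occ)),
      file.path(out, "residue_occurrence.tsv"),
      "percent of high-affinity poses contacting each residue")
  )
  summary <- list(
    stage = "posestats", n_poses = n_poses(poses),
    thresholds = th[c("affinity_max", "affinity_favorable",
                      "affinity_unfavorable", "contact_cutoff")],
    n_high_affinity = n_poses(high),
    pct_below_zero = 100 * mean(poses$affinity < 0),
    pct_below_max = 100 * mean(poses$affinity < th$affinity_max),
    representative_favorable = if (!is.null(rep_fav)) {
      list(pose = rep_fav$index, affinity = rep_fav$affinity,
           contacts = rep_fav$contacts)
    },
    representative_unfavorable = if (!is.null(rep_unf)) {
      list(pose = rep_unf$index, affinity = rep_unf$affinity,
           contacts = rep_unf$contacts)
    }
  )
  list(files = files, summary = summary)
}

.stage_complex <- function(cfg, out) {
  st <- read_structure(cfg$structure)
  top <- assign_regions(st$topology, .cfg_region_spec(cfg))
  traj <- read_trajectory(cfg$trajectory, top, format = "frames")
  traj$topology <- top
  lig <- .ligand_key(cfg, top)
  th <- cfg$thresholds
  ip <- interaction_probability(traj, lig, th$contact_cutoff,
                                window = cfg$window)
  ref <- residue_contacts(top, frame_coords(traj, 1), lig,
                          cutoff = th$contact_cutoff)
  ret <- retention_series(traj, lig, ref, th$contact_cutoff)
  keys <- atom_residue_keys(top)
  ox <- which(keys == lig & toupper(top$atoms$element) == "O")
  cisf <- if (length(ox) == 2) {
    cis_fraction(conformer_series(traj, ox, th$cis_threshold))
  } else NA_real_
  site <- names(sort(ip, decreasing = TRUE))
  site <- site[seq_len(min(10, sum(ip > 0)))]
  occ_tab <- occupancy_table(traj, lig, site, cutoff = th$contact_cutoff,
                             window = cfg$window)
  files <- c(
    occupancy = .write_tsv(
      data.frame(residue = names(ip), interaction_probability_pct = unname(ip)),
      file.path(out, "interaction_probability.tsv"),
      sprintf("contact rule: min heavy-atom distance <= %g nm; window: %s",
              th$contact_cutoff,
              if (is.null(cfg$window)) "last 75% of frames" else "config")),
    retention = .write_tsv(ret, file.path(out, "retention.tsv"),
                           "percent of frame-1 contacts retained per frame"),
    site = .write_tsv(occ_tab, file.path(out, "site_occupancy.tsv"),
                      "per-residue occurrence over the analysis window")
  )
  summary <- list(
    stage = "complex",
    thresholds = th[c("contact_cutoff", "cis_threshold")],
    reference_contacts = ref,
    mean_retention_pct = mean(ret$retained),
    cis_fraction_pct = cisf,
    site_residues = site
  )
  list(files = files, summary = summary)
}

.stage_alascan <- function(cfg, out) {
  st <- read_structure(cfg$structure)
  top <- assign_regions(st$topology, .cfg_region_spec(cfg))
  wt <- read_trajectory(cfg$trajectory, top, format = "frames")
  wt$topology <- top
  lig <- .ligand_key(cfg, top)
  th <- cfg$thresholds
  muts <- cfg$mutant_trajectories  # named list: position -> path
  if (is.null(muts) || !length(muts)) {
    stop("config missing required input: mutant_trajectories")
  }
  positions <- names(muts)
  chain <- if (is.null(cfg$chain)) "A" else cfg$chain
  site_keys <- residue_key(chain, as.integer(positions))
  wt_ip <- interaction_probability(wt, lig, th$contact_cutoff,
                                   window = cfg$window)
  wt_counts <- site_contact_counts(wt, lig, site_keys, th$contact_cutoff,
                                   window = cfg$window)
  rows <- list(); mut_files <- character(0)
  for (p in positions) {
    m <- mutate_to_alanine(top, st$coords, as.integer(p), chain)
    mp <- file.path(out, sprintf("mutant_%sA.pdb", p))
    write_structure(m$topology, m$coords, mp)
    mut_files <- c(mut_files, mp)
    mtraj <- read_trajectory(muts[[p]], format = "pdb")
    if (dim(mtraj$coords)[2] == n_atoms(top)) mtraj$topology <- top
    mut_ip <- interaction_probability(mtraj, lig, th$contact_cutoff,
                                      window = cfg$window)
    key <- residue_key(chain, as.integer(p))
    mut_counts <- site_contact_counts(mtraj, lig, site_keys,
                                      th$contact_cutoff, window = cfg$window)
    wt_at <- if (key %in% names(wt_ip)) wt_ip[[key]] else 0
    mut_at <- if (key %in% names(mut_ip)) mut_ip[[key]] else 0
    rows[[p]] <- data.frame(
      position = as.integer(p),
      wt_name = top$residues$resname[top$residues$key == key],
      wt_occupancy = wt_at, mut_occupancy = mut_at,
      position_loss = position_contact_loss(wt_at, mut_at),
      site_loss = site_contact_loss(wt_counts, mut_counts),
      stringsAsFactors = FALSE
    )
  }
  report <- do.call(rbind, rows)
  if (!is.null(cfg$energy_table)) {
    en <- ingest_energy_table(cfg$energy_table)
    .write_tsv(en, file.path(out, "energy_summary.tsv"),
               "external MM/PBSA per-run boxplot statistics, kcal/mol")
    med <- stats::setNames(en$median, en$run)
    report$median_energy <- ifelse(report$position %in% names(med),
                                   med[as.character(report$position)],
                                   NA_real_)
  }
  files <- c(mut_files,
             scan = .write_tsv(report, file.path(out, "alanine_scan.tsv"),
                               "contact-loss percentages, WT vs mutants"))
  summary <- list(stage = "alascan",
                  thresholds = th["contact_cutoff"],
                  site_residues = site_keys,
                  report = report)
  list(files = files, summary = summary)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic world generation), `unbound` (RMSD /
#' RMSD-share / RMSF), `ligand` (conformer descriptors, PCA, clustering),
#' `dockprep` (principal-axis alignment, docking box), `posestats`
#' (affinity filtering, contact histograms, representative poses),
#' `complex` (interaction probability, contact retention, site occupancy),
#' `alascan` (mutant construction and contact-loss report).
#'
#' Inputs are validated before the output directory is created; outputs are
#' deterministic given config and seed, and each stage writes a
#' `<stage>_summary.json` recording every threshold used.
#'
#' @param stage stage name
#' @param config config list or path to a JSON config; recognized fields
#'   include `output_dir`, `seed`, `structure`, `trajectory`, `poses`,
#'   `regions`, `synth`, `thresholds`, `window`, `ligand_residue`,
#'   `mutant_trajectories`, `energy_table`
#' @return invisibly, list with `files` and `summary`
#' @export
run_stage <- function(stage = c("simulate", "unbound", "ligand", "dockprep",
                                "posestats", "complex", "alascan"),
                      config) {
  stage <- match.arg(stage)
  cfg <- .load_config(config)
  if (is.null(cfg$output_dir)) stop("config missing required input: output_dir")
  needs <- switch(stage,
                  simulate = character(0),
                  unbound = c("structure", "trajectory"),
                  ligand = c("structure", "trajectory"),
                  dockprep = "structure",
                  posestats = c("structure", "poses"),
                  complex = c("structure", "trajectory"),
                  alascan = c("structure", "trajectory"))
  .require_inputs(cfg, needs)
  out <- file.path(cfg$output_dir, stage)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- switch(stage,
                simulate = .stage_simulate(cfg, out),
                unbound = .stage_unbound(cfg, out),
                ligand = .stage_ligand(cfg, out),
                dockprep = .stage_dockprep(cfg, out),
                posestats = .stage_posestats(cfg, out),
                complex = .stage_complex(cfg, out),
                alascan = .stage_alascan(cfg, out))
  res$files <- c(res$files,
                 summary = .write_summary(res$summary,
                                          file.path(out,
                                                    paste0(stage,
                                                           "_summary.json"))))
  invisible(res)
}
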