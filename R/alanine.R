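# Computational alanine scanning: side-chain-truncation mutants,
# WT-vs-mutant contact-loss metrics at the mutated position and over the
# whole binding site, and ingestion of external MM/PBSA energy tables for
# joint reporting.

#' Mutate one residue to alanine by side-chain truncation
#'
#' Removes all side-chain atoms beyond CB, retains CB (placing it at ideal
#' tetrahedral geometry from N/CA/C when absent, e.g. glycine), renames the
#' residue ALA and leaves every other atom, including the whole backbone,
#' untouched.
#'
#' @param top a `Topology`
#' @param coords atoms x 3 coordinate matrix (nm)
#' @param position residue sequence number to mutate
#' @param chain chain of the residue
#' @return list with mutated `topology` and `coords`
#' @export
mutate_to_alanine <- function(top, coords, position, chain = "A") {
  key <- residue_key(chain, position)
  rk <- atom_residue_keys(top)
  ridx <- which(rk == key)
  if (!length(ridx)) stop("residue ", key, " not found")
  names_r <- top$atoms$name[ridx]
  bb <- c("N", "CA", "C", "O")
  if (!all(bb %in% names_r)) {
    stop("residue ", key, " has an incomplete backbone (need N, CA, C, O)")
  }
  keep_names <- c(bb, "CB", "H", "HA", "HN", "OXT")
  drop <- ridx[!(names_r %in% keep_names)]
  has_cb <- "CB" %in% names_r
  if (length(drop)) {
    keep <- setdiff(seq_len(n_atoms(top)), drop)
    atoms <- top$atoms[keep, , drop = FALSE]
    coords <- coords[keep, , drop = FALSE]
  } else {
    atoms <- top$atoms
  }
  sel <- residue_key(atoms$chain, atoms$resid) == key
  atoms$resname[sel] <- "ALA"
  if (!has_cb) {
    # ideal tetrahedral CB from the backbone frame: equal ~109.5 deg angles
    # to the N and C directions, out of the N-CA-C plane
    g <- function(nm) coords[which(sel)[atoms$name[sel] == nm], ]
    ca <- g("CA"); nn <- g("N"); cc <- g("C")
    u <- (nn - ca) / sqrt(sum((nn - ca)^2))
    v <- (cc - ca) / sqrt(sum((cc - ca)^2))
    bis <- u + v; bis <- bis / sqrt(sum(bis^2))
    perp <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
    perp <- perp / sqrt(sum(perp^2))
    cosphi <- min(1, -cos(109.47 * pi / 180) / sum(bis * u))
    sinphi <- sqrt(max(0, 1 - cosphi^2))
    dir <- -bis * cosphi + perp * sinphi
    cb <- ca + 0.153 * dir / sqrt(sum(dir^2))  # C-C bond 1.53 A
    ca_pos <- which(sel)[atoms$name[sel] == "CA"]
    new_atom <- atoms[ca_pos, , drop = FALSE]
    new_atom$name <- "CB"; new_atom$element <- "C"
    new_atom$serial <- max(atoms$serial) + 1L
    atoms <- rbind(atoms[seq_len(ca_pos), , drop = FALSE], new_atom,
                   atoms[-seq_len(ca_pos), , drop = FALSE])
    coords <- rbind(coords[seq_len(ca_pos), , drop = FALSE], cb,
                    coords[-seq_len(ca_pos), , drop = FALSE])
  }
  rownames(coords) <- NULL
  list(topology = topology(atoms), coords = coords)
}

#' Contact loss at the mutated position
#'
#' Percent reduction of contact occupancy at the mutated position:
#' `100 * (wt - mut) / wt`. Undefined (`NA` with a warning) when the WT
#' occupancy is not positive.
#'
#' @param wt_occupancy WT occupancy at the position, percent
#' @param mut_occupancy mutant occupancy at the position, percent
#' @return percent reduction (positive = contact loss)
#' @export
position_contact_loss <- function(wt_occupancy, mut_occupancy) {
  if (wt_occupancy <= 0) {
    warning("WT occupancy is zero: position contact loss undefined")
    return(NA_real_)
  }
  100 * (wt_occupancy - mut_occupancy) / wt_occupancy
}

#' Contact loss over the binding site
#'
#' Percent reduction of the mean per-frame contact count summed over the
#' binding-site residues: `100 * (mean(wt) - mean(mut)) / mean(wt)`. Means
#' make WT and mutant runs of different lengths comparable.
#'
#' @param wt_counts per-frame site contact counts, WT run
#' @param mut_counts per-frame site contact counts, mutant run
#' @return percent reduction, or `NA` when the WT mean is not positive
#' @export
site_contact_loss <- function(wt_counts, mut_counts) {
  mw <- mean(wt_counts)
  if (!is.finite(mw) || mw <= 0) {
    warning("WT mean site contact count is zero: site contact loss undefined")
    return(NA_real_)
  }
  100 * (mw - mean(mut_counts)) / mw
}

#' Per-frame site contact counts
#'
#' Number of binding-site residues in contact with the ligand in each window
#' frame.
#'
#' @param traj a `Trajectory`
#' @param ligand ligand residue key
#' @param site_residues residue keys of the binding site
#' @param cutoff contact cutoff, nm
#' @param window frame indices (default: last 75%)
#' @return integer vector, one count per window frame
#' @export
site_contact_counts <- function(traj, ligand, site_residues, cutoff = 0.4,
                                window = NULL) {
  frames <- .window_frames(traj, window)
  top <- traj$topology
  keys <- atom_residue_keys(top)
  heavy <- .heavy(top$atoms$element)
  lidx <- .resolve_ligand_atoms(top, ligand)
  lidx <- lidx[heavy[lidx]]
  rec <- which(keys %in% site_residues & heavy)
  if (!length(rec)) return(rep(0L, length(frames)))
  dmin <- .traj_residue_min_dist(traj, rec, lidx, frames)
  as.integer(rowSums(dmin <= cutoff))
}

#' Assemble an alanine-scan report
#'
#' One row per mutant: the mutated position's occupancy loss
#' ([position_contact_loss()]) and the site-wide mean-count loss
#' ([site_contact_loss()]), with an optional external energy summary column.
#'
#' @param positions residue keys of the mutated positions
#' @param wt_occ named WT occupancies (percent) covering `positions`
#' @param mut_occ named mutant occupancies at the mutated position, one per
#'   mutant run
#' @param wt_counts per-frame WT site contact counts
#' @param mut_counts named list: position -> per-frame mutant site counts
#' @param energy optional named numeric: position -> median interaction
#'   energy from an external MM/PBSA table
#' @return data.frame of class `ScanReport`: `position`, `wt_name`,
#'   `position_loss`, `site_loss`, `median_energy`
#' @export
scan_report <- function(positions, wt_occ, mut_occ, wt_counts, mut_counts,
                        energy = NULL) {
  rows <- lapply(positions, function(p) {
    data.frame(
      position = p,
      position_loss = position_contact_loss(wt_occ[[p]], mut_occ[[p]]),
      site_loss = site_contact_loss(wt_counts, mut_counts[[p]]),
      median_energy = if (!is.null(energy) && p %in% names(energy))
        energy[[p]] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ScanReport", "data.frame")
  out
}

#' Ingest an external interaction-energy table
#'
#' Reads a whitespace- or tab-separated numeric table of per-frame energies
#' (one column per run or per contribution; header and comment lines
#' allowed). Non-numeric data rows are skipped with a count. Summaries are
#' the boxplot statistics per column: median, quartiles and 1.5 IQR
#' whiskers. Recognized contribution columns (van der Waals, electrostatic,
#' polar, nonpolar) keep their labels.
#'
#' @param path tabular file path
#' @return data.frame: `run`, `n`, `median`, `q1`, `q3`, `lower_whisker`,
#'   `upper_whisker`; attribute `skipped` = number of skipped rows
#' @export
ingest_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^[#@;]", lines)]
  if (!length(lines)) stop("empty energy table: ", path)
  split1 <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(split1)))
  header <- if (has_header) split1 else paste0("run", seq_along(split1))
  body <- if (has_header) lines[-1] else lines
  if (!length(body)) stop("empty energy table: ", path)
  parsed <- lapply(body, function(l) {
    suppressWarnings(as.numeric(strsplit(trimws(l), "[\t ]+")[[1]]))
  })
  ok <- vapply(parsed, function(v) length(v) == length(header) && !anyNA(v),
               logical(1))
  skipped <- sum(!ok)
  rows <- parsed[ok]
  if (!length(rows)) stop("no numeric rows in energy table: ", path)
  M <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(seq_along(header), function(j) {
    v <- M[, j]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lw <- min(v[v >= q[1] - 1.5 * iqr])
    uw <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(run = header[j], n = length(v), median = q[2], q1 = q[1],
               q3 = q[3], lower_whisker = lw, upper_whisker = uw,
               stringsAsFactors = FALSE)
  }))
  attr(out, "skipped") <- skipped
  out
}
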