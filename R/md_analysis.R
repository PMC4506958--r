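#' Per-frame protein-ligand contact counts
#'
#' For every frame, counts the heavy-atom protein-ligand pairs with
#' interatomic distance not greater than `cutoff` (each pair counted once).
#' This is the time-series view of ligand engagement: frames with zero
#' contacts indicate transient dissociation.
#'
#' @param traj an [md_trajectory()].
#' @param protein_sel,ligand_sel non-empty atom selections on the shared
#'   roster.
#' @param cutoff contact distance bound (Angstrom), default 3.4.
#' @return A data.frame of class `contact_timeseries` with columns `frame`
#'   (original 1-based frame id), `time` (ps), `count`.
#' @export
contact_timeseries <- function(traj, protein_sel, ligand_sel, cutoff = 3.4) {
  sel <- heavy_selections(traj, protein_sel, ligand_sel)
  n <- n_frames(traj)
  counts <- integer(n)
  for (i in seq_len(n)) {
    d <- cross_distances(frame_coords(traj, i, sel$protein),
                         frame_coords(traj, i, sel$ligand))
    counts[i] <- sum(d <= cutoff)
  }
  structure(data.frame(frame = traj$frame_ids, time = traj$times,
                       count = counts),
            class = c("contact_timeseries", "data.frame"))
}

heavy_selections <- function(traj, protein_sel, ligand_sel) {
  if (!length(protein_sel) || !length(ligand_sel))
    stop_bad("empty protein or ligand selection")
  el <- traj$atoms$element
  list(protein = protein_sel[el[protein_sel] != "H"],
       ligand = ligand_sel[el[ligand_sel] != "H"])
}

#' Extract a frame window from a trajectory
#'
#' Returns the subtrajectory from frame `first` to frame `last` (positions in
#' this trajectory, 1-based), preserving frame times and original frame ids.
#' The analysis window of a production run (e.g. frames 501-1000 of a
#' 1000-frame, 20-ns trajectory) is taken this way.
#'
#' @param x an [md_trajectory()].
#' @param first,last 1-based frame positions, `1 <= first <= last <= n`.
#' @param ... unused.
#' @return An [md_trajectory()] with `last - first + 1` frames.
#' @export
window.md_trajectory <- function(x, first, last, ...) {
  n <- n_frames(x)
  if (first < 1 || last > n || first > last)
    stop_bad("invalid window [%s, %s] for %d frames", first, last, n)
  subset_frames(x, first:last)
}

subset_frames <- function(traj, idx) {
  structure(list(atoms = traj$atoms,
                 coords = traj$coords[, , idx, drop = FALSE],
                 times = traj$times[idx], frame_ids = traj$frame_ids[idx]),
            class = "md_trajectory")
}

#' Default flip-ambiguous atom exclusions
#'
#' Atoms whose names can swap under aromatic ring flips or carboxylate
#' rotation during MD, making their identity ambiguous across frames:
#' CD1/CD2/CE1/CE2 of tyrosine and phenylalanine, and the ligand carboxylate
#' oxygens OAA/OAC.
#'
#' @return A list with `protein` (data.frame `resname`, `name`) and `ligand`
#'   (atom-name vector).
#' @export
default_flip_exclusions <- function() {
  list(protein = data.frame(
         resname = rep(c("TYR", "PHE"), each = 4),
         name = rep(c("CD1", "CD2", "CE1", "CE2"), 2),
         stringsAsFactors = FALSE),
       ligand = c("OAA", "OAC"))
}

#' Select superposition atoms from persistent contacts
#'
#' A protein-ligand atom pair qualifies when its shortest interatomic
#' distance over the window is not greater than `cutoff`. The superposition
#' atom set is the union of the atoms in qualifying pairs, minus the
#' flip-ambiguous exclusions ([default_flip_exclusions()]). Hydrogens are
#' ignored.
#'
#' @param traj_window an [md_trajectory()] (typically the analysis window).
#' @inheritParams contact_timeseries
#' @param flip_exclusions exclusion set as produced by
#'   [default_flip_exclusions()].
#' @return A list of class `superposition_spec` with `pairs` (data.frame of
#'   qualifying atom index pairs with their minimum distances) and `atoms`
#'   (sorted atom indices to superpose on; may be empty when no pair
#'   qualifies).
#' @export
derive_superposition_atoms <- function(traj_window, protein_sel, ligand_sel,
                                       cutoff = 3.4,
                                       flip_exclusions = default_flip_exclusions()) {
  if (!n_frames(traj_window)) stop_bad("empty trajectory window")
  sel <- heavy_selections(traj_window, protein_sel, ligand_sel)
  dmin <- min_distance_matrix(traj_window, sel$protein, sel$ligand)
  hits <- which(dmin <= cutoff, arr.ind = TRUE)
  a <- traj_window$atoms
  pairs <- data.frame(protein_idx = sel$protein[hits[, 1]],
                      ligand_idx = sel$ligand[hits[, 2]],
                      min_distance = dmin[hits])
  atoms <- sort(unique(c(pairs$protein_idx, pairs$ligand_idx)))
  excl_p <- paste(flip_exclusions$protein$resname, flip_exclusions$protein$name)
  drop <- (paste(a$resname[atoms], a$name[atoms]) %in% excl_p &
             !a$is_het[atoms]) |
          (a$is_het[atoms] & a$name[atoms] %in% flip_exclusions$ligand)
  structure(list(pairs = pairs, atoms = atoms[!drop]),
            class = "superposition_spec")
}

min_distance_matrix <- function(traj, prot_idx, lig_idx) {
  dmin <- NULL
  for (i in seq_len(n_frames(traj))) {
    d <- cross_distances(frame_coords(traj, i, prot_idx),
                         frame_coords(traj, i, lig_idx))
    dmin <- if (is.null(dmin)) d else pmin(dmin, d)
  }
  dmin
}

#' Per-pair contact statistics over a trajectory window
#'
#' For each protein-ligand heavy-atom pair that comes within `cutoff` in at
#' least one frame: the number of frames in contact, the mean distance over
#' those frames, and the appearance frequency as a percentage of the window.
#' Pairs are sorted by count (descending), ties broken by mean distance
#' (ascending) then protein atom index, and filtered at `min_frequency`.
#' Values are kept at full precision; round only for reporting.
#'
#' @inheritParams derive_superposition_atoms
#' @param min_frequency report filter in percent (default 20); pairs below it
#'   are dropped.
#' @return A data.frame of class `contact_pair_stats` with columns `resname`,
#'   `resseq`, `protein_atom`, `ligand_atom`, `mean_distance`, `n_frames`,
#'   `frequency`.
#' @export
pair_stats <- function(traj_window, protein_sel, ligand_sel, cutoff = 3.4,
                       min_frequency = 20) {
  if (!n_frames(traj_window)) stop_bad("empty trajectory window")
  sel <- heavy_selections(traj_window, protein_sel, ligand_sel)
  nw <- n_frames(traj_window)
  cnt <- NULL; dsum <- NULL
  for (i in seq_len(nw)) {
    d <- cross_distances(frame_coords(traj_window, i, sel$protein),
                         frame_coords(traj_window, i, sel$ligand))
    inc <- d <= cutoff
    if (is.null(cnt)) { cnt <- matrix(0L, nrow(d), ncol(d)); dsum <- cnt * 0 }
    cnt <- cnt + inc
    dsum <- dsum + d * inc
  }
  hits <- which(cnt > 0, arr.ind = TRUE)
  a <- traj_window$atoms
  pi_ <- sel$protein[hits[, 1]]; li <- sel$ligand[hits[, 2]]
  out <- data.frame(
    resname = a$resname[pi_], resseq = a$resseq[pi_],
    protein_atom = a$name[pi_], ligand_atom = a$name[li],
    mean_distance = dsum[hits] / cnt[hits],
    n_frames = as.integer(cnt[hits]),
    frequency = 100 * cnt[hits] / nw,
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_frames, out$mean_distance, pi_), , drop = FALSE]
  out <- out[out$frequency >= min_frequency, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_pair_stats", "data.frame")
  out
}

#' Format contact-pair statistics at report precision
#'
#' Rounds mean distances to 2 decimals and frequencies to 1 decimal, the
#' precision used in published contact tables.
#'
#' @param stats a `contact_pair_stats` data.frame.
#' @return The data.frame with rounded `mean_distance` and `frequency`.
#' @export
format_pair_stats <- function(stats) {
  stats$mean_distance <- round(stats$mean_distance, 2)
  stats$frequency <- round(stats$frequency, 1)
  stats
}
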