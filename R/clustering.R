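#' All-pair fitted RMSD matrix over a trajectory window
#'
#' Entry (i, j) is the RMSD after least-squares superposition
#' ([kabsch_fit()]) of frame j's selected atoms onto frame i's. The matrix is
#' symmetric with zero diagonal.
#'
#' @param traj_window an [md_trajectory()].
#' @param sel atom selection (>= 3 atoms): either an integer vector or a
#'   `superposition_spec` from [derive_superposition_atoms()].
#' @return An `n x n` numeric matrix of class `rmsd_matrix`.
#' @export
pairwise_rmsd <- function(traj_window, sel) {
  if (inherits(sel, "superposition_spec")) sel <- sel$atoms
  if (length(sel) < 3) stop_bad("need at least 3 superposition atoms")
  n <- n_frames(traj_window)
  coords <- lapply(seq_len(n), function(i) frame_coords(traj_window, i, sel))
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- fit_rmsd(coords[[i]], coords[[j]])
  }
  class(m) <- c("rmsd_matrix", class(m))
  m
}

mean_offdiag <- function(matrix) {
  n <- nrow(matrix)
  if (n < 2) stop_bad("need at least 2 frames")
  mean(matrix[upper.tri(matrix)])
}

#' Clustering cutoff from the mean intratrajectory RMSD
#'
#' The default cutoff heuristic: a stated fraction (default 0.70) of the mean
#' of all off-diagonal pairwise RMSDs, snapped to the nearest multiple of
#' `grid` (default 0.1 Angstrom). The heuristic approximates a search around
#' 70 percent of the average intratrajectory RMSD; an explicitly chosen
#' cutoff can always be passed to [daura_cluster()] instead.
#'
#' @param matrix an `rmsd_matrix` (or any symmetric matrix), `n >= 2`.
#' @param fraction fraction of the mean RMSD, in (0, 1).
#' @param grid snap grid in Angstrom.
#' @return A list with `cutoff` (snapped), `exact` (unsnapped
#'   `fraction * mean`), `mean_rmsd`, and `degenerate` (`TRUE` when the mean
#'   RMSD is zero, e.g. identical frames, and the snapped cutoff is 0).
#' @examples
#' m <- matrix(c(0, 1.232, 1.232, 0), 2)
#' cutoff_from_mean(m)$cutoff  # 0.9
#' @export
cutoff_from_mean <- function(matrix, fraction = 0.70, grid = 0.1) {
  stopifnot(fraction > 0, fraction < 1, grid > 0)
  mu <- mean_offdiag(matrix)
  exact <- fraction * mu
  snapped <- round(exact / grid) * grid
  list(cutoff = snapped, exact = exact, mean_rmsd = mu,
       degenerate = snapped <= 0)
}

#' Greedy neighbour-count (Daura) clustering of an RMSD matrix
#'
#' Iteratively: among unassigned frames, count for each frame the other
#' unassigned frames with RMSD strictly less than `cutoff` (its neighbours);
#' the frame with the most neighbours becomes a cluster centre (ties broken
#' by lowest frame index) and is removed together with its neighbours;
#' repeat until every frame is assigned. The result is a partition of all
#' frames into non-overlapping clusters, listed in order of extraction
#' (sizes non-increasing); singletons are allowed.
#'
#' @param matrix an `rmsd_matrix`.
#' @param cutoff neighbour cutoff in Angstrom (> 0); frames at RMSD exactly
#'   equal to the cutoff are not neighbours.
#' @return An object of class `daura_clustering`: list with `clusters` (each
#'   a list with `center` and sorted `members`, the centre included) and `n`.
#' @export
daura_cluster <- function(matrix, cutoff) {
  if (cutoff <= 0) stop_bad("cutoff must be positive")
  n <- nrow(matrix)
  unassigned <- rep(TRUE, n)
  adj <- matrix < cutoff
  diag(adj) <- FALSE
  clusters <- list()
  while (any(unassigned)) {
    idx <- which(unassigned)
    sub <- adj[idx, idx, drop = FALSE]
    counts <- colSums(sub)
    ci <- which.max(counts)  # which.max takes the first maximum: lowest index
    center <- idx[ci]
    members <- sort(c(center, idx[sub[, ci]]))
    clusters[[length(clusters) + 1L]] <- list(center = center,
                                              members = members)
    unassigned[members] <- FALSE
  }
  structure(list(clusters = clusters, n = n), class = "daura_clustering")
}

#' @export
print.daura_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 1L)
  cat(sprintf("<daura_clustering> %d frames in %d clusters; sizes: %s\n",
              x$n, length(sizes), paste(utils::head(sizes, 10), collapse = " ")))
  invisible(x)
}

#' Clustering report parameters
#'
#' @param cutoff neighbour cutoff used for the clustering (Angstrom).
#' @param fraction cutoff-heuristic fraction (recorded for reference).
#' @param min_report_fraction smallest cluster reported, as a fraction of the
#'   window (default 0.10).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(cutoff, fraction = 0.70,
                           min_report_fraction = 0.10) {
  stopifnot(cutoff > 0, fraction > 0, fraction < 1)
  structure(list(cutoff = cutoff, fraction = fraction,
                 min_report_fraction = min_report_fraction),
            class = "cluster_params")
}

#' Per-cluster report of binding-mode statistics
#'
#' For each cluster holding at least `min_report_fraction` of the window:
#' size, centre frame id and time, mean intracluster RMSD, the per-cluster
#' protein-ligand contact statistics ([pair_stats()]), and — when a crystal
#' reference with the same atom roster is supplied — the mean RMSD of
#' members to the crystal, the RMSD of the crystal to the cluster centre,
#' and whether the crystal structure would join the cluster (RMSD to centre
#' strictly below the cutoff).
#'
#' @param clustering a [daura_cluster()] result over `traj_window`.
#' @param traj_window the clustered [md_trajectory()] window.
#' @param sel superposition atom selection used for the RMSD matrix.
#' @param protein_sel,ligand_sel selections for the contact statistics.
#' @param matrix the `rmsd_matrix` the clustering was computed from.
#' @param crystal optional [atom_model()] sharing the trajectory roster.
#' @param params a [cluster_params()] object.
#' @param contact_cutoff contact distance bound for the statistics.
#' @param min_frequency report filter for the per-cluster contact table.
#' @return A list of class `cluster_report`: window-level block (`n_frames`,
#'   `total_contacts`, `mean_contacts_per_structure`, `mean_intra_rmsd`) and
#'   `clusters`, one entry per reported cluster.
#' @export
cluster_report <- function(clustering, traj_window, sel, protein_sel,
                           ligand_sel, matrix, crystal = NULL, params,
                           contact_cutoff = 3.4, min_frequency = 20) {
  if (inherits(sel, "superposition_spec")) sel <- sel$atoms
  nw <- n_frames(traj_window)
  ts <- contact_timeseries(traj_window, protein_sel, ligand_sel,
                           cutoff = contact_cutoff)
  crystal_rmsd_to <- function(i) {
    fit_rmsd(frame_coords(traj_window, i, sel), model_coords(crystal, sel))
  }
  min_size <- params$min_report_fraction * nw
  out <- list()
  for (cl in clustering$clusters) {
    size <- length(cl$members)
    if (size < min_size) next
    sub <- matrix[cl$members, cl$members, drop = FALSE]
    entry <- list(
      size = size,
      fraction = size / nw,
      center_frame = traj_window$frame_ids[cl$center],
      center_time = traj_window$times[cl$center],
      mean_intra_rmsd = if (size > 1) mean(sub[upper.tri(sub)]) else 0,
      total_contacts = sum(ts$count[cl$members]),
      mean_contacts_per_structure = mean(ts$count[cl$members]),
      stats = pair_stats(subset_frames(traj_window, cl$members),
                         protein_sel, ligand_sel, cutoff = contact_cutoff,
                         min_frequency = min_frequency))
    if (!is.null(crystal)) {
      member_rmsd <- vapply(cl$members, crystal_rmsd_to, numeric(1))
      entry$mean_rmsd_to_crystal <- mean(member_rmsd)
      entry$crystal_center_rmsd <- crystal_rmsd_to(cl$center)
      entry$crystal_in_cluster <- entry$crystal_center_rmsd < params$cutoff
    }
    out[[length(out) + 1L]] <- entry
  }
  structure(list(
    n_frames = nw,
    total_contacts = sum(ts$count),
    mean_contacts_per_structure = mean(ts$count),
    mean_intra_rmsd = mean_offdiag(matrix),
    mean_rmsd_to_crystal = if (!is.null(crystal))
      mean(vapply(seq_len(nw), crystal_rmsd_to, numeric(1))) else NULL,
    cutoff = params$cutoff,
    n_superposition_atoms = length(sel),
    clusters = out), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d structures, %d contacts (%.2f/structure), <Rmsd> %.3f A, cutoff %.1f A\n",
              x$n_frames, x$total_contacts, x$mean_contacts_per_structure,
              x$mean_intra_rmsd, x$cutoff))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d structures (%.0f%%), center frame %d at %g ps, <Rmsd> %.3f A%s\n",
                i, cl$size, 100 * cl$fraction, cl$center_frame,
                cl$center_time, cl$mean_intra_rmsd,
                if (!is.null(cl$crystal_in_cluster))
                  sprintf(", crystal %s", if (cl$crystal_in_cluster)
                    "inside" else "outside") else ""))
  }
  invisible(x)
}
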