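test_that("identical frames give an all-zero matrix and one all-member cluster", {
  sim <- simulate_trajectory(trajectory_sim_spec(
    n_frames = 6, seed = 1, modes = list(mode_spec(weight = 1,
                                                   noise_sigma = 0))))
  m <- pairwise_rmsd(sim$trajectory, select_atoms(sim$trajectory, het = TRUE,
                                                  element = c("C", "N", "O")))
  expect_equal(max(abs(m)), 0, tolerance = 1e-9)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(m), rep(0, 6))
  cl <- daura_cluster(m, 0.5)
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]]$center, 1L)
  expect_equal(cl$clusters[[1]]$members, 1:6)
})

test_that("frames differing by a rigid motion have zero pairwise RMSD", {
  sim <- simulate_trajectory(trajectory_sim_spec(
    n_frames = 2, seed = 3, modes = list(mode_spec(weight = 1,
                                                   noise_sigma = 0))))
  tr <- sim$trajectory
  tr$coords[, , 2] <- tcrossprod(tr$coords[, , 1], random_rotation()) +
    rep(c(4, 5, 6), each = nrow(tr$atoms))
  m <- pairwise_rmsd(tr, seq_len(nrow(tr$atoms)))
  expect_equal(m[1, 2], 0, tolerance = 1e-9)
  expect_error(pairwise_rmsd(tr, 1:2), "at least 3")
})

test_that("pairwise RMSD entries match the quaternion oracle", {
  sim <- simulate_trajectory(trajectory_sim_spec(n_frames = 5, seed = 21))
  tr <- sim$trajectory
  sel <- select_atoms(tr, het = TRUE, element = c("C", "N", "O"))
  m <- pairwise_rmsd(tr, sel)
  for (i in 1:4) for (j in (i + 1):5) {
    a <- tr$coords[sel, , i]; b <- tr$coords[sel, , j]
    expect_equal(m[i, j], quaternion_rmsd(a, b), tolerance = 1e-6)
  }
})

test_that("the cutoff heuristic takes the snapped fraction of the mean RMSD", {
  m <- matrix(c(0, 1.232, 1.232, 0), 2)
  co <- cutoff_from_mean(m, fraction = 0.70, grid = 0.1)
  expect_equal(co$cutoff, 0.9)
  expect_equal(co$exact, 0.8624)
  expect_equal(co$mean_rmsd, 1.232)
  expect_false(co$degenerate)
  expect_equal(cutoff_from_mean(matrix(c(0, 2, 2, 0), 2),
                                fraction = 0.5)$cutoff, 1.0)
  z <- cutoff_from_mean(matrix(0, 3, 3))
  expect_equal(z$cutoff, 0)
  expect_true(z$degenerate)
  expect_error(cutoff_from_mean(matrix(0, 1, 1)), "at least 2")
})

test_that("two planted RMSD blocks are recovered as exactly two clusters", {
  n1 <- 6; n2 <- 4
  m <- matrix(5.0, n1 + n2, n1 + n2)
  m[1:n1, 1:n1] <- 0.2
  m[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- 0.2
  diag(m) <- 0
  cl <- daura_cluster(m, 0.9)
  expect_length(cl$clusters, 2)
  expect_equal(cl$clusters[[1]]$members, 1:n1)
  expect_equal(cl$clusters[[2]]$members, (n1 + 1):(n1 + n2))
})

test_that("greedy clustering equals the exhaustive oracle for small frame sets", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    m <- random_rmsd_matrix(n)
    cutoff <- runif(1, 0.5, 2.5)
    got <- daura_cluster(m, cutoff)
    want <- daura_oracle(m, cutoff)
    expect_equal(lapply(got$clusters, `[[`, "members"), want)
  }
})

test_that("every clustering is a partition with optimal centres at extraction", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    m <- random_rmsd_matrix(n)
    cutoff <- runif(1, 0.3, 2.8)
    cl <- daura_cluster(m, cutoff)
    members <- unlist(lapply(cl$clusters, `[[`, "members"))
    expect_equal(sort(members), 1:n)        # partition, no overlap
    expect_length(members, n)
    sizes <- vapply(cl$clusters, function(c2) length(c2$members), 1L)
    expect_true(all(diff(sizes) <= 0))      # non-increasing sizes
    # centre optimality: replay the extraction
    remaining <- 1:n
    for (c2 in cl$clusters) {
      counts <- vapply(remaining, function(i)
        sum(m[i, remaining] < cutoff) - 1L, 1L)
      expect_equal(max(counts),
                   sum(m[c2$center, remaining] < cutoff) - 1L)
      expect_true(c2$center %in% c2$members)
      remaining <- setdiff(remaining, c2$members)
    }
  }
  expect_error(daura_cluster(matrix(0, 2, 2), 0), "positive")
})

test_that("neighbourhood uses strict inequality at the cutoff", {
  m <- matrix(c(0, 1, 1, 0), 2)
  cl <- daura_cluster(m, 1)
  expect_length(cl$clusters, 2)  # RMSD exactly at the cutoff: not neighbours
  cl2 <- daura_cluster(m, 1 + 1e-9)
  expect_length(cl2$clusters, 1)
})

test_that("planted modes are recovered with their occupancies and the crystal flagged outside", {
  sim <- simulate_trajectory(trajectory_sim_spec(
    n_frames = 150, seed = 5,
    modes = list(mode_spec(weight = 0.55),
                 mode_spec(translation = c(0, 8, 0), weight = 0.25),
                 mode_spec(translation = c(0, 0, 8), weight = 0.15),
                 mode_spec(translation = c(0, -8, 0), weight = 0.05))))
  tr <- sim$trajectory
  psel <- select_atoms(tr, het = FALSE)
  lsel <- select_atoms(tr, het = TRUE)
  ss <- derive_superposition_atoms(tr, psel, lsel)
  expect_gte(length(ss$atoms), 3)
  m <- pairwise_rmsd(tr, ss)
  cl <- daura_cluster(m, 0.9)
  expect_gte(clustering_purity(cl, sim$mode), 0.99)
  sizes <- vapply(cl$clusters, function(c2) length(c2$members), 1L)
  truth <- sort(as.integer(table(sim$mode)), decreasing = TRUE)
  expect_equal(sort(sizes[1:3], decreasing = TRUE), truth[1:3])
  # a "crystal" pose far from every planted mode never joins a cluster
  crystal <- frame_model(tr, 1)
  lig_rows <- crystal$atoms$is_het
  crystal$atoms[lig_rows, c("x", "y", "z")] <-
    crystal$atoms[lig_rows, c("x", "y", "z")] + rep(c(0, -20, 14),
                                                    each = sum(lig_rows))
  rep_ <- cluster_report(cl, tr, ss, psel, lsel, m, crystal = crystal,
                         params = cluster_params(0.9))
  expect_gte(length(rep_$clusters), 3)
  for (c2 in rep_$clusters) {
    expect_false(c2$crystal_in_cluster)
    expect_gt(c2$crystal_center_rmsd, 0.9)
  }
  # the 5% mode is below the 10% report threshold
  expect_true(all(vapply(rep_$clusters, `[[`, 1, "size") >= 0.10 * 150))
  expect_lt(length(rep_$clusters), length(cl$clusters))
})

test_that("the cluster report aggregates sizes, times and contact statistics", {
  sim <- simulate_trajectory(trajectory_sim_spec(
    n_frames = 30, seed = 8,
    modes = list(mode_spec(weight = 0.7),
                 mode_spec(translation = c(0, 8, 0), weight = 0.3))))
  tr <- sim$trajectory
  psel <- select_atoms(tr, het = FALSE)
  lsel <- select_atoms(tr, het = TRUE)
  ss <- derive_superposition_atoms(tr, psel, lsel)
  m <- pairwise_rmsd(tr, ss)
  cl <- daura_cluster(m, 0.9)
  rep_ <- cluster_report(cl, tr, ss, psel, lsel, m,
                         params = cluster_params(0.9))
  expect_equal(rep_$n_frames, 30)
  ts <- contact_timeseries(tr, psel, lsel)
  expect_equal(rep_$total_contacts, sum(ts$count))
  expect_equal(rep_$mean_contacts_per_structure, mean(ts$count))
  for (c2 in rep_$clusters) {
    expect_equal(c2$center_time, tr$times[c2$center_frame])
    expect_gte(c2$mean_intra_rmsd, 0)
    expect_lte(max(c2$stats$frequency), 100)
  }
  # a cluster of identical frames has zero intracluster RMSD
  sim0 <- simulate_trajectory(trajectory_sim_spec(
    n_frames = 5, seed = 2, modes = list(mode_spec(weight = 1,
                                                   noise_sigma = 0))))
  m0 <- pairwise_rmsd(sim0$trajectory,
                      select_atoms(sim0$trajectory, het = TRUE,
                                   element = c("C", "N", "O")))
  cl0 <- daura_cluster(m0, 0.5)
  r0 <- cluster_report(cl0, sim0$trajectory,
                       select_atoms(sim0$trajectory, het = TRUE,
                                    element = c("C", "N", "O")),
                       select_atoms(sim0$trajectory, het = FALSE),
                       select_atoms(sim0$trajectory, het = TRUE),
                       m0, params = cluster_params(0.5))
  expect_equal(r0$clusters[[1]]$mean_intra_rmsd, 0, tolerance = 1e-9)
})
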