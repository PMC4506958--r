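# Independent oracles and small fixture builders used across test files.

# Horn quaternion RMSD: largest eigenvalue of the 4x4 key matrix gives the
# optimal superposition RMSD without constructing the rotation. Independent
# of the SVD/Kabsch route used by the package.
quaternion_rmsd <- function(ref, mov) {
  a <- sweep(as.matrix(mov), 2, colMeans(mov))
  b <- sweep(as.matrix(ref), 2, colMeans(ref))
  S <- crossprod(a, b)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a * a) + sum(b * b) - 2 * lambda) / nrow(a)
  sqrt(max(0, msd))
}

# Exhaustive packing-contact enumeration over all operators x lattice shifts
# in +/-2 cells (sufficient for the toy cells used in tests).
brute_force_packing <- function(model, lig_sel, cutoff) {
  mats <- cell_matrices(model$cell)
  a <- model$atoms
  lig <- as.matrix(a[lig_sel, c("x", "y", "z")])
  lig <- lig[a$element[lig_sel] != "H", , drop = FALSE]
  prot <- as.matrix(a[!a$is_het & !a$is_water & a$element != "H",
                      c("x", "y", "z")])
  dist2 <- function(p, q) {
    d <- 0 * outer(rowSums(p^2), rowSums(q^2))
    for (i in seq_len(nrow(p))) for (j in seq_len(nrow(q)))
      d[i, j] <- sqrt(sum((p[i, ] - q[j, ])^2))
    d
  }
  frac <- t(mats$frac %*% t(prot))
  n_asu <- sum(dist2(lig, prot) <= cutoff)
  n_sym <- 0L
  for (k in seq_along(model$spacegroup$ops)) {
    op <- model$spacegroup$ops[[k]]
    fo <- t(op$R %*% t(frac)) + rep(op$t, each = nrow(frac))
    for (sa in -2:2) for (sb in -2:2) for (sc in -2:2) {
      if (k == 1 && sa == 0 && sb == 0 && sc == 0) next
      cart <- t(mats$orth %*% t(fo + rep(c(sa, sb, sc), each = nrow(fo))))
      n_sym <- n_sym + sum(dist2(lig, cart) <= cutoff)
    }
  }
  c(asu = n_asu, sym = n_sym)
}

# Plain-loop re-derivation of the greedy neighbour-count clustering,
# recomputing every neighbour count from scratch at each extraction.
daura_oracle <- function(m, cutoff) {
  remaining <- seq_len(nrow(m))
  clusters <- list()
  while (length(remaining)) {
    best <- remaining[1]; best_n <- -1L
    for (i in remaining) {
      ni <- 0L
      for (j in remaining) if (j != i && m[i, j] < cutoff) ni <- ni + 1L
      if (ni > best_n) { best <- i; best_n <- ni }
    }
    members <- best
    for (j in remaining) if (j != best && m[best, j] < cutoff)
      members <- c(members, j)
    clusters[[length(clusters) + 1L]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  clusters
}

# Fraction of frames whose cluster's majority ground-truth label they share.
clustering_purity <- function(clustering, labels) {
  hit <- sum(vapply(clustering$clusters, function(cl)
    max(table(labels[cl$members])), numeric(1)))
  hit / length(labels)
}

# Random symmetric RMSD-like matrix with zero diagonal.
random_rmsd_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, 3)
  m + t(m)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# A bare CA-only chain model covering a residue range.
ca_chain_model <- function(resseq) {
  n <- length(resseq)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", altloc = "", resname = "GLY",
    chain = "A", resseq = as.integer(resseq), icode = "",
    x = 3.8 * seq_len(n), y = sin(seq_len(n)), z = cos(seq_len(n)),
    occupancy = 1, bfactor = 10, element = "C", is_het = FALSE,
    is_water = FALSE, stringsAsFactors = FALSE)
  atom_model(atoms)
}

# Minimal hand-built trajectory: one protein CA and one ligand atom whose
# distance per frame is given.
two_atom_trajectory <- function(distances, ligand_name = "OAB") {
  atoms <- data.frame(
    serial = 1:2, name = c("CA", ligand_name), altloc = "",
    resname = c("GLY", "LG1"), chain = "A", resseq = c(1L, 700L), icode = "",
    x = 0, y = 0, z = 0, occupancy = 1, bfactor = 10,
    element = c("C", substr(ligand_name, 1, 1)),
    is_het = c(FALSE, TRUE), is_water = FALSE, stringsAsFactors = FALSE)
  n <- length(distances)
  coords <- array(0, dim = c(2, 3, n))
  for (i in seq_len(n)) coords[2, 1, i] <- distances[i]
  md_trajectory(atoms, coords, times = 20 * seq_len(n))
}

toy_cell <- function() list(a = 40, b = 50, c = 60, alpha = 90, beta = 90,
                            gamma = 90)
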