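#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `t(R %*% t(mov)) + t` onto `ref` over paired points, using the SVD form of
#' the Kabsch algorithm with the reflection branch corrected so that
#' `det(R) = +1`.
#'
#' @param ref,mov numeric matrices `n x 3` with `n >= 3` paired points.
#' @return A list of class `superposition` with `rotation` (3x3), `translation`
#'   (length 3, Angstrom), `rmsd` (Angstrom) and `n_atoms`.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' kabsch_fit(p, p)$rmsd  # 0
#' @export
kabsch_fit <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!all(dim(ref) == dim(mov)))
    stop_bad("point sets differ in size (%d vs %d)", nrow(ref), nrow(mov))
  n <- nrow(ref)
  if (n < 3) stop_bad("superposition needs at least 3 points, got %d", n)
  cr <- colMeans(ref); cm <- colMeans(mov)
  refc <- sweep(ref, 2, cr); movc <- sweep(mov, 2, cm)
  H <- crossprod(movc, refc)
  s <- svd(H)
  # collinear (or fully degenerate) point sets leave the rotation about the
  # line undetermined
  spread_ref <- svd(refc, nu = 0, nv = 0)$d
  spread_mov <- svd(movc, nu = 0, nv = 0)$d
  if (spread_ref[2] < 1e-8 * max(spread_ref[1], 1) ||
      spread_mov[2] < 1e-8 * max(spread_mov[1], 1))
    stop_bad("degenerate (collinear) point configuration")
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- as.numeric(cr - R %*% cm)
  fitted <- tcrossprod(mov, R) + rep(t, each = n)
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, rmsd %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords numeric matrix `n x 3`.
#' @param transform a `superposition` (or any list with `rotation` and
#'   `translation`).
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as.matrix(coords)
  tcrossprod(coords, transform$rotation) +
    rep(transform$translation, each = nrow(coords))
}

# Bare RMSD core used in tight loops (no validity checks, no spread test).
fit_rmsd <- function(ref, mov) {
  cr <- colMeans(ref); cm <- colMeans(mov)
  refc <- sweep(ref, 2, cr); movc <- sweep(mov, 2, cm)
  s <- svd(crossprod(movc, refc))
  d <- sign(det(s$v %*% t(s$u))); if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- tcrossprod(movc, R)
  sqrt(mean(rowSums((fitted - refc)^2)))
}

#' RMSD between two models after optimal superposition
#'
#' Superposes the selected atoms of `modelB` onto those of `modelA` and
#' returns the fitted RMSD. With `match_by = "order"` atoms correspond by
#' list position (selections must be equal length). With
#' `match_by = "identity"` atoms are paired by (residue number, atom name);
#' atoms without a counterpart are dropped pairwise, and residues listed in
#' `exclude_resseq` are removed before pairing, which is how differently
#' modelled terminal residues are excluded when comparing crystal forms.
#'
#' @param modelA,modelB [atom_model()] objects.
#' @param selA,selB integer atom selections (see [select_atoms()]).
#' @param match_by `"order"` or `"identity"`.
#' @param exclude_resseq residue numbers dropped before pairing
#'   (`"identity"` matching only).
#' @return The fitted RMSD in Angstrom.
#' @export
rmsd_after_fit <- function(modelA, modelB, selA, selB,
                           match_by = c("order", "identity"),
                           exclude_resseq = NULL) {
  match_by <- match.arg(match_by)
  if (match_by == "identity") {
    aA <- modelA$atoms[selA, , drop = FALSE]
    aB <- modelB$atoms[selB, , drop = FALSE]
    if (!is.null(exclude_resseq)) {
      aA <- aA[!aA$resseq %in% exclude_resseq, , drop = FALSE]
      aB <- aB[!aB$resseq %in% exclude_resseq, , drop = FALSE]
    }
    kA <- paste(aA$resseq, aA$name)
    kB <- paste(aB$resseq, aB$name)
    common <- intersect(kA, kB)
    cA <- as.matrix(aA[match(common, kA), c("x", "y", "z")])
    cB <- as.matrix(aB[match(common, kB), c("x", "y", "z")])
  } else {
    if (length(selA) != length(selB))
      stop_bad("selections differ in length (%d vs %d)",
               length(selA), length(selB))
    cA <- model_coords(modelA, selA)
    cB <- model_coords(modelB, selB)
  }
  kabsch_fit(cA, cB)$rmsd
}

#' Compare binding-pose mimicry by anchored superposition
#'
#' Superposes a query complex onto a reference complex using corresponding
#' protein anchor atoms (typically C-alpha atoms), applies the fitted
#' transform to a small probe atom group of the query ligand (e.g. its
#' carboxylate heavy atoms), and returns the centroid-centroid distance from
#' the transformed query probe to each reference probe group (e.g. the
#' carboxylates of substrate-peptide glutamates). The smaller the distance,
#' the closer the positional mimicry of that reference group.
#'
#' @param complex_ref,complex_query [atom_model()] objects.
#' @param ref_anchor_sel,query_anchor_sel equal-length anchor selections,
#'   corresponding 1:1 by order.
#' @param ref_probe_groups list of non-empty selections into `complex_ref`.
#' @param query_probe_group non-empty selection into `complex_query`.
#' @return Numeric vector of distances (Angstrom), one per reference probe
#'   group, in the order given.
#' @export
mimicry_overlap <- function(complex_ref, complex_query, ref_anchor_sel,
                            query_anchor_sel, ref_probe_groups,
                            query_probe_group) {
  if (!length(query_probe_group) || any(!vapply(ref_probe_groups, length, 1L)))
    stop_bad("probe groups must be non-empty")
  fit <- kabsch_fit(model_coords(complex_ref, ref_anchor_sel),
                    model_coords(complex_query, query_anchor_sel))
  probe <- apply_transform(model_coords(complex_query, query_probe_group), fit)
  qc <- colMeans(probe)
  vapply(ref_probe_groups, function(g) {
    vec_norm(colMeans(model_coords(complex_ref, g)) - qc)
  }, numeric(1))
}
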