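#' Fractional/orthogonal conversion matrices for a unit cell
#'
#' Standard PDB convention: `a` along x, `b` in the xy plane.
#'
#' @param cell list with `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @return A list with `orth` (fractional -> cartesian, 3x3) and `frac`
#'   (its inverse).
#' @export
cell_matrices <- function(cell) {
  validate_cell(cell)
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  orth <- matrix(c(cell$a, cell$b * cg, cell$c * cb,
                   0, cell$b * sg, cell$c * (ca - cb * cg) / sg,
                   0, 0, cell$c * v / sg),
                 3, 3, byrow = TRUE)
  list(orth = orth, frac = solve(orth))
}

#' Expand crystallographic symmetry around a centre selection
#'
#' Generates every symmetry image (space-group operator plus integer lattice
#' shift) of the model's protein atoms that brings at least one image atom
#' within `radius` of the atoms in `center_sel`. The identity operator with
#' zero shift (the asymmetric unit itself) is never returned. The lattice
#' shift search range is derived from the fractional extents of the centre
#' and the transformed molecule plus a `radius`-dependent margin, so no
#' qualifying image is missed.
#'
#' @param model an [atom_model()] with `cell` and `spacegroup` set.
#' @param radius contact search radius in Angstrom.
#' @param center_sel non-empty atom selection defining the search centre
#'   (typically the ligand).
#' @param include_waters should crystallographic waters be part of the
#'   expanded images? Default `FALSE` (protein atoms only).
#' @return A list of symmetry mates, each a list with `op_index` (1-based
#'   index into the space-group operator list), `lattice_shift` (integer
#'   3-vector), and `coords` (cartesian matrix of the image atoms); the
#'   corresponding source atom indices are in attribute `atom_idx`.
#' @export
expand_symmetry <- function(model, radius, center_sel,
                            include_waters = FALSE) {
  if (is.null(model$cell) || is.null(model$spacegroup))
    stop_bad("model needs a unit cell and space group for symmetry expansion")
  if (!length(center_sel)) stop_bad("empty centre selection")
  a <- model$atoms
  keep <- !a$is_het & !a$is_water & a$element != "H"
  if (include_waters) keep <- keep | a$is_water
  atom_idx <- which(keep)
  if (!length(atom_idx)) return(list())
  mats <- cell_matrices(model$cell)
  frac <- t(mats$frac %*% t(as.matrix(a[atom_idx, c("x", "y", "z")])))
  center <- as.matrix(a[center_sel, c("x", "y", "z")])
  cf <- t(mats$frac %*% t(center))
  # fractional margin: radius expressed on each axis, padded by one cell
  axis_len <- sqrt(colSums(mats$orth^2))
  margin <- radius / axis_len + 1
  ops <- model$spacegroup$ops
  mates <- list()
  for (k in seq_along(ops)) {
    fo <- t(ops[[k]]$R %*% t(frac)) + rep(ops[[k]]$t, each = nrow(frac))
    lo <- floor(apply(cf, 2, min) - apply(fo, 2, max) - margin)
    hi <- ceiling(apply(cf, 2, max) - apply(fo, 2, min) + margin)
    for (sa in lo[1]:hi[1]) for (sb in lo[2]:hi[2]) for (sc in lo[3]:hi[3]) {
      shift <- c(sa, sb, sc)
      if (k == 1L && all(shift == 0L)) next
      shifted <- fo + rep(shift, each = nrow(fo))
      cart <- t(mats$orth %*% t(shifted))
      # bounding-box prefilter before full distance computation
      if (any(apply(cart, 2, min) - apply(center, 2, max) > radius) ||
          any(apply(center, 2, min) - apply(cart, 2, max) > radius)) next
      if (min(cross_distances(cart, center)) <= radius) {
        mates[[length(mates) + 1L]] <-
          structure(list(op_index = k, lattice_shift = as.integer(shift),
                         coords = cart),
                    atom_idx = atom_idx)
      }
    }
  }
  mates
}

#' Count ligand packing contacts inside and across the asymmetric unit
#'
#' Counts ligand-protein atom pairs at distance not greater than `cutoff`,
#' split between the asymmetric unit (the deposited protein chain) and
#' symmetry-related images of it. Each atom pair is counted once. By default
#' both counts consider protein atoms only; crystallographic waters can be
#' included in the symmetry images via `include_waters`.
#'
#' @inheritParams expand_symmetry
#' @param ligand_sel non-empty selection of the ligand atoms.
#' @param cutoff contact distance bound (Angstrom), default 3.4.
#' @return An object of class `packing_report`: list with `n_asu_contacts`,
#'   `n_sym_contacts`, `per_mate` (data.frame `op_index`, `shift_a`,
#'   `shift_b`, `shift_c`, `count`), and `cutoff`.
#' @export
count_packing_contacts <- function(model, ligand_sel, cutoff = 3.4,
                                   include_waters = FALSE) {
  if (!length(ligand_sel)) stop_bad("empty ligand selection")
  a <- model$atoms
  lig <- as.matrix(a[ligand_sel, c("x", "y", "z")])
  lig <- lig[a$element[ligand_sel] != "H", , drop = FALSE]
  prot <- as.matrix(a[!a$is_het & !a$is_water & a$element != "H",
                      c("x", "y", "z")])
  n_asu <- if (nrow(prot)) sum(cross_distances(lig, prot) <= cutoff) else 0L
  mates <- expand_symmetry(model, cutoff, ligand_sel,
                           include_waters = include_waters)
  per_mate <- data.frame(op_index = integer(), shift_a = integer(),
                         shift_b = integer(), shift_c = integer(),
                         count = integer())
  for (m in mates) {
    cnt <- sum(cross_distances(lig, m$coords) <= cutoff)
    if (cnt > 0)
      per_mate <- rbind(per_mate, data.frame(
        op_index = m$op_index, shift_a = m$lattice_shift[1],
        shift_b = m$lattice_shift[2], shift_c = m$lattice_shift[3],
        count = cnt))
  }
  rownames(per_mate) <- NULL
  structure(list(n_asu_contacts = as.integer(n_asu),
                 n_sym_contacts = as.integer(sum(per_mate$count)),
                 per_mate = per_mate, cutoff = cutoff),
            class = "packing_report")
}

#' @export
print.packing_report <- function(x, ...) {
  cat(sprintf("<packing_report> cutoff %.2f A: %d contacts to the asymmetric unit, %d to symmetry mates (%d mates)\n",
              x$cutoff, x$n_asu_contacts, x$n_sym_contacts, nrow(x$per_mate)))
  invisible(x)
}

#' Apply a space-group operator to a whole model
#'
#' Maps every atom of the model through operator `op_index` (plus an optional
#' lattice shift) in fractional space and back to cartesian. Used to check
#' that packing counts do not depend on which symmetry copy was deposited as
#' the asymmetric unit.
#'
#' @param model an [atom_model()] with cell and space group.
#' @param op_index operator index (1-based).
#' @param shift integer lattice shift.
#' @return A new `atom_model` with transformed coordinates.
#' @export
apply_symmetry_op <- function(model, op_index, shift = c(0L, 0L, 0L)) {
  if (is.null(model$cell) || is.null(model$spacegroup))
    stop_bad("model needs a unit cell and space group")
  op <- model$spacegroup$ops[[op_index]]
  mats <- cell_matrices(model$cell)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  frac <- t(op$R %*% mats$frac %*% t(xyz)) +
    rep(op$t + shift, each = nrow(xyz))
  cart <- t(mats$orth %*% t(frac))
  out <- model
  out$atoms$x <- cart[, 1]; out$atoms$y <- cart[, 2]; out$atoms$z <- cart[, 3]
  out
}
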