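#' Coordinate models and trajectories
#'
#' `atom_model()` is the package's in-memory form of a single-model PDB file:
#' an ordered atom table plus the optional unit cell and space group from the
#' CRYST1 record. `md_trajectory()` holds an ordered stack of frames sharing
#' one atom roster, with a time (ps) per frame, which is how multi-model PDB
#' trajectories are represented throughout the MD analysis.
#'
#' The atom table has one row per atom with columns `serial`, `name`
#' (trimmed PDB atom name, e.g. `"OG"`, `"OAC"`), `altloc`, `resname`,
#' `chain`, `resseq`, `icode`, `x`, `y`, `z` (Angstrom), `occupancy`,
#' `bfactor`, `element`, `is_het`, `is_water`. Residue numbering is kept
#' verbatim from the file; no renumbering is ever applied.
#'
#' @param atoms data.frame as described above.
#' @param cell optional list with `a`, `b`, `c` (Angstrom) and `alpha`,
#'   `beta`, `gamma` (degrees).
#' @param spacegroup optional [space_group()] object.
#' @param model_id integer model number.
#' @return `atom_model()` returns an object of class `atom_model`.
#' @name atom_model
NULL

WATER_RESNAMES <- c("HOH", "WAT", "DOD")

#' @rdname atom_model
#' @export
atom_model <- function(atoms, cell = NULL, spacegroup = NULL, model_id = 1L) {
  required <- c("serial", "name", "altloc", "resname", "chain", "resseq",
                "icode", "x", "y", "z", "occupancy", "bfactor", "element",
                "is_het", "is_water")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop_bad("atom table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (nrow(atoms)) {
    if (anyDuplicated(atoms$serial))
      stop_bad("duplicate atom serial numbers within one model")
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop_bad("non-finite coordinates in atom table")
    if (any(!nzchar(atoms$element)))
      stop_bad("empty element symbols in atom table")
  }
  if (!is.null(cell)) validate_cell(cell)
  structure(list(atoms = atoms, cell = cell, spacegroup = spacegroup,
                 model_id = as.integer(model_id)),
            class = "atom_model")
}

validate_cell <- function(cell) {
  vals <- unlist(cell[c("a", "b", "c", "alpha", "beta", "gamma")])
  if (length(vals) != 6 || any(!is.finite(vals)) || any(vals[1:3] <= 0) ||
      any(vals[4:6] <= 0) || any(vals[4:6] >= 180))
    stop_bad("invalid unit cell: need positive axes and angles in (0, 180)")
  invisible(cell)
}

#' @export
print.atom_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<atom_model> %d atoms (%d protein, %d hetero, %d water)\n",
              nrow(a), sum(!a$is_het & !a$is_water), sum(a$is_het & !a$is_water),
              sum(a$is_water)))
  if (!is.null(x$cell))
    cat(sprintf("  cell: a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f\n",
                x$cell$a, x$cell$b, x$cell$c, x$cell$alpha, x$cell$beta,
                x$cell$gamma))
  if (!is.null(x$spacegroup)) cat("  space group:", x$spacegroup$symbol, "\n")
  invisible(x)
}

#' Read a single-model PDB file
#'
#' Parses ATOM/HETATM/CRYST1 records into an [atom_model()]. HETATM rows are
#' flagged `is_het`; waters (resnames HOH/WAT/DOD) are flagged `is_water`.
#' The element symbol is taken from columns 77-78 when present and otherwise
#' derived from the atom-name columns 13-14 following the PDB alignment
#' convention. Alternate locations are filtered by `altloc_policy`.
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @param altloc_policy `"first"` keeps blank or `"A"` altlocs and drops the
#'   rest; `"all"` keeps everything.
#' @return An [atom_model()]. When a CRYST1 record is present, `cell` and
#'   (for supported symbols) `spacegroup` are populated.
#' @examples
#' lines <- c("CRYST1  200.000  200.000  200.000  90.00  90.00  90.00 P 1",
#'            "END")
#' m <- read_pdb(lines)
#' nrow(m$atoms)  # 0
#' @export
read_pdb <- function(source, altloc_policy = c("first", "all")) {
  altloc_policy <- match.arg(altloc_policy)
  lines <- pdb_lines(source)
  if (sum(grepl("^MODEL ", lines)) > 1L)
    stop_bad("multiple MODEL blocks: use read_multimodel_pdb() for trajectories")
  parse_pdb_block(lines, model_id = 1L, altloc_policy = altloc_policy,
                  line_offset = 0L)
}

pdb_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    readLines(source, warn = FALSE)
  else if (is.character(source))
    unlist(strsplit(source, "\n", fixed = TRUE))
  else stop_bad("source must be a file path or character vector of PDB lines")
}

# Parse one model's worth of PDB lines. line_offset is added to local line
# numbers so parse errors in multi-model files name the file line.
parse_pdb_block <- function(lines, model_id, altloc_policy, line_offset) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  cell <- NULL; sg <- NULL
  cry <- which(startsWith(lines, "CRYST1"))
  if (length(cry)) {
    ln <- lines[cry[1]]
    cell <- list(a = as.numeric(substr(ln, 7, 15)),
                 b = as.numeric(substr(ln, 16, 24)),
                 c = as.numeric(substr(ln, 25, 33)),
                 alpha = as.numeric(substr(ln, 34, 40)),
                 beta = as.numeric(substr(ln, 41, 47)),
                 gamma = as.numeric(substr(ln, 48, 54)))
    validate_cell(cell)
    sym <- trimws(substr(ln, 56, 66))
    if (nzchar(sym)) sg <- space_group(sym)
  }
  idx <- which(is_atom)
  if (!length(idx)) {
    atoms <- empty_atom_table()
    return(atom_model(atoms, cell, sg, model_id))
  }
  al <- lines[idx]
  num_field <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop_bad("malformed %s field in ATOM/HETATM record at line %d",
               what, idx[bad[1]] + line_offset)
    v
  }
  name_raw <- substr(al, 13, 16)
  element <- trimws(substr(al, 77, 78))
  infer <- !nzchar(element)
  if (any(infer))
    element[infer] <- infer_element(name_raw[infer])
  resname <- trimws(substr(al, 18, 20))
  atoms <- data.frame(
    serial = as.integer(num_field(7, 11, "serial")),
    name = trimws(name_raw),
    altloc = trimws(substr(al, 17, 17)),
    resname = resname,
    chain = trimws(substr(al, 22, 22)),
    resseq = as.integer(num_field(23, 26, "residue number")),
    icode = trimws(substr(al, 27, 27)),
    x = num_field(31, 38, "x"),
    y = num_field(39, 46, "y"),
    z = num_field(47, 54, "z"),
    occupancy = num_field(55, 60, "occupancy"),
    bfactor = num_field(61, 66, "B-factor"),
    element = toupper(element),
    is_het = startsWith(al, "HETATM"),
    is_water = resname %in% WATER_RESNAMES,
    stringsAsFactors = FALSE)
  if (altloc_policy == "first")
    atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  rownames(atoms) <- NULL
  atom_model(atoms, cell, sg, model_id)
}

empty_atom_table <- function() {
  data.frame(serial = integer(), name = character(), altloc = character(),
             resname = character(), chain = character(), resseq = integer(),
             icode = character(), x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), bfactor = numeric(), element = character(),
             is_het = logical(), is_water = logical(), stringsAsFactors = FALSE)
}

# PDB alignment rule: columns 13-14 carry the element, right-justified, so a
# one-letter element atom name starts at column 14 (" CA " = C-alpha) while a
# two-letter element fills both (e.g. "FE  ").
infer_element <- function(name_raw) {
  two <- toupper(substr(name_raw, 1, 2))
  out <- character(length(name_raw))
  known2 <- c("FE", "ZN", "MG", "MN", "CU", "NI", "CO", "NA", "CL", "BR",
              "SE", "CA", "CD", "HG")
  is2 <- substr(name_raw, 1, 1) != " " & two %in% known2
  out[is2] <- two[is2]
  rest <- !is2
  first_char <- toupper(substr(trimws(name_raw[rest]), 1, 1))
  digit <- grepl("[0-9]", first_char)
  # names like "1HB " start with a digit; the element is the next letter
  second <- toupper(substr(trimws(name_raw[rest]), 2, 2))
  first_char[digit] <- second[digit]
  out[rest] <- first_char
  out
}

#' Write coordinates as PDB
#'
#' Writes an [atom_model()] (one model, with CRYST1 when the cell is set) or
#' an [md_trajectory()] (MODEL/ENDMDL blocks) in fixed-column PDB format.
#' Coordinates are written to 3 decimals, so `read_pdb(write_pdb(m))` is the
#' identity on identity fields and on coordinates to 3 decimals.
#'
#' @param x an `atom_model` or `md_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  lines <- if (inherits(x, "md_trajectory")) {
    n <- n_frames(x)
    unlist(lapply(seq_len(n), function(i) {
      c(sprintf("MODEL     %4d", i),
        format_atom_lines(frame_model(x, i)$atoms),
        "ENDMDL")
    }))
  } else if (inherits(x, "atom_model")) {
    c(format_cryst1(x), format_atom_lines(x$atoms))
  } else stop_bad("write_pdb() needs an atom_model or md_trajectory")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

format_cryst1 <- function(model) {
  if (is.null(model$cell)) return(character())
  sg <- if (!is.null(model$spacegroup)) model$spacegroup$symbol else "P 1"
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
          model$cell$a, model$cell$b, model$cell$c,
          model$cell$alpha, model$cell$beta, model$cell$gamma, sg)
}

format_atom_lines <- function(a) {
  if (!nrow(a)) return(character())
  name_fmt <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
                     paste0(" ", a$name), a$name)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$is_het, "HETATM", "ATOM"), a$serial, name_fmt, a$altloc,
          a$resname, a$chain, a$resseq, a$icode, a$x, a$y, a$z,
          a$occupancy, a$bfactor, a$element)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Splits the file on MODEL/ENDMDL blocks, parses each model and verifies
#' that all models share one atom roster (name, residue name/number, chain,
#' element, in order). Frame times are `start_time + (i - 1) * stride`.
#'
#' @inheritParams read_pdb
#' @param start_time time of the first frame (ps).
#' @param stride time between frames (ps); must be positive.
#' @return An [md_trajectory()].
#' @export
read_multimodel_pdb <- function(source, start_time = 20, stride = 20,
                                altloc_policy = c("first", "all")) {
  altloc_policy <- match.arg(altloc_policy)
  lines <- pdb_lines(source)
  starts <- which(grepl("^MODEL ", lines))
  if (!length(starts)) {
    m <- parse_pdb_block(lines, 1L, altloc_policy, 0L)
    return(trajectory_from_models(list(m), start_time, stride))
  }
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(ends) != length(starts))
    stop_bad("unbalanced MODEL/ENDMDL records")
  models <- lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    parse_pdb_block(block, model_id = i, altloc_policy = altloc_policy,
                    line_offset = starts[i])
  })
  trajectory_from_models(models, start_time, stride)
}

roster_key <- function(atoms)
  paste(atoms$name, atoms$resname, atoms$chain, atoms$resseq, atoms$element)

trajectory_from_models <- function(models, start_time, stride) {
  ref <- models[[1]]
  key <- roster_key(ref$atoms)
  for (i in seq_along(models)) {
    ki <- roster_key(models[[i]]$atoms)
    if (length(ki) != length(key) || any(ki != key))
      stop_bad("atom roster of model %d does not match model 1", i)
  }
  coords <- vapply(models, function(m) as.matrix(m$atoms[, c("x", "y", "z")]),
                   matrix(0, nrow(ref$atoms), 3))
  md_trajectory(ref$atoms, coords,
                times = start_time + (seq_along(models) - 1) * stride)
}

#' @rdname atom_model
#' @param coords numeric array `n_atoms x 3 x n_frames` of coordinates.
#' @param times strictly increasing frame times (ps).
#' @param frame_ids 1-based original frame indices (kept through windowing).
#' @export
md_trajectory <- function(atoms, coords, times, frame_ids = NULL) {
  coords <- array(coords, dim = c(nrow(atoms), 3L, length(times)))
  if (any(diff(times) <= 0))
    stop_bad("frame times must be strictly increasing")
  frame_ids <- frame_ids %||% seq_along(times)
  structure(list(atoms = atoms[, setdiff(names(atoms), c("x", "y", "z"))],
                 coords = coords, times = as.numeric(times),
                 frame_ids = as.integer(frame_ids)),
            class = "md_trajectory")
}

#' @rdname atom_model
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

#' @rdname atom_model
#' @param i frame number (1-based position in this trajectory).
#' @export
frame_model <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  a <- traj$atoms
  a$x <- traj$coords[, 1, i]; a$y <- traj$coords[, 2, i]
  a$z <- traj$coords[, 3, i]
  atom_model(a[, c("serial", "name", "altloc", "resname", "chain", "resseq",
                   "icode", "x", "y", "z", "occupancy", "bfactor", "element",
                   "is_het", "is_water")],
             model_id = traj$frame_ids[i])
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              n_frames(x), nrow(x$atoms), x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Select atoms from a model or trajectory roster
#'
#' Deterministic, order-stable atom selection. All supplied criteria are
#' combined with AND; an empty result is returned as an empty index vector,
#' not an error.
#'
#' @param x an [atom_model()] or [md_trajectory()].
#' @param chain,resname,name optional character vectors to match.
#' @param resseq optional integer vector of residue numbers (use `a:b` for a
#'   range).
#' @param het,water optional logicals filtering on the HETATM/water flags.
#' @param element optional character vector of element symbols.
#' @return Strictly increasing integer indices into the atom table.
#' @examples
#' m <- synthetic_receptor()
#' ca <- select_atoms(m, name = "CA")
#' @export
select_atoms <- function(x, chain = NULL, resseq = NULL, name = NULL,
                         resname = NULL, het = NULL, water = NULL,
                         element = NULL) {
  a <- if (inherits(x, "md_trajectory")) x$atoms
       else if (inherits(x, "atom_model")) x$atoms
       else stop_bad("select_atoms() needs an atom_model or md_trajectory")
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(resseq))  keep <- keep & a$resseq %in% resseq
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(het))     keep <- keep & a$is_het == het
  if (!is.null(water))   keep <- keep & a$is_water == water
  if (!is.null(element)) keep <- keep & a$element %in% element
  which(keep)
}

# Coordinate matrix (n x 3) of selected atoms of a model.
model_coords <- function(model, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Coordinates of selected atoms in frame i of a trajectory.
frame_coords <- function(traj, i, sel = NULL) {
  m <- traj$coords[, , i]
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}
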