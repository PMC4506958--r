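#' Deterministic pseudo-protein receptor
#'
#' A helix-like backbone trace (N, CA, C, O per residue, CB and named
#' side-chain pseudo-atoms for non-glycine residues) cycling through residue
#' types that include tyrosine/phenylalanine ring carbons (so the
#' flip-ambiguous-atom logic is exercised), arginine guanidinium nitrogens,
#' serine/threonine hydroxyls, asparagine amide and glutamate carboxylate
#' atoms. Entirely deterministic; no randomness.
#'
#' @param n_res number of residues (default 24).
#' @param chain chain identifier.
#' @return An [atom_model()] of the pseudo-receptor.
#' @export
synthetic_receptor <- function(n_res = 24, chain = "A") {
  cycle <- c("TYR", "ARG", "SER", "ASN", "ALA", "PHE", "LYS", "GLY",
             "GLU", "THR", "LEU", "ALA")
  rows <- list()
  add <- function(name, resname, resseq, xyz, element = substr(name, 1, 1)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resname = resname, resseq = resseq,
      x = xyz[1], y = xyz[2], z = xyz[3], element = element,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    resname <- cycle[(i - 1L) %% length(cycle) + 1L]
    theta <- (i - 1) * 100 * pi / 180
    er <- c(cos(theta), sin(theta), 0)
    et <- c(-sin(theta), cos(theta), 0)
    ez <- c(0, 0, 1)
    ca <- 2.3 * er + c(0, 0, 1.5 * i)
    add("N", resname, i, ca - 1.2 * et - 0.8 * ez)
    add("CA", resname, i, ca, element = "C")
    add("C", resname, i, ca + 1.2 * et - 0.8 * ez)
    add("O", resname, i, ca + 1.2 * et - 0.8 * ez + 1.23 * er)
    if (resname != "GLY") add("CB", resname, i, ca + 1.53 * er)
    cb <- ca + 1.53 * er
    rot <- function(deg) {  # rotate er toward et in the radial plane
      a <- deg * pi / 180
      cos(a) * er + sin(a) * et
    }
    sidechain <- switch(resname,
      SER = { add("OG", resname, i, cb + 1.42 * er); NULL },
      THR = { add("OG1", resname, i, cb + 1.42 * rot(40))
              add("CG2", resname, i, cb + 1.53 * rot(-40)); NULL },
      TYR = , PHE = {
        cg <- cb + 1.51 * er
        cc <- cg + 1.39 * er  # ring centre
        add("CG", resname, i, cg)
        add("CD1", resname, i, cc + 1.39 * rot(120))
        add("CD2", resname, i, cc + 1.39 * rot(-120))
        add("CE1", resname, i, cc + 1.39 * rot(60))
        add("CE2", resname, i, cc + 1.39 * rot(-60))
        add("CZ", resname, i, cc + 1.39 * er)
        if (resname == "TYR") add("OH", resname, i, cc + (1.39 + 1.36) * er)
        NULL
      },
      ARG = {
        cg <- cb + 1.52 * rot(20); cd <- cg + 1.52 * rot(-20)
        ne <- cd + 1.46 * er; cz <- ne + 1.33 * er
        add("CG", resname, i, cg); add("CD", resname, i, cd)
        add("NE", resname, i, ne); add("CZ", resname, i, cz)
        add("NH1", resname, i, cz + 1.33 * rot(60))
        add("NH2", resname, i, cz + 1.33 * rot(-60))
        NULL
      },
      ASN = {
        cg <- cb + 1.52 * er
        add("CG", resname, i, cg)
        add("OD1", resname, i, cg + 1.23 * rot(60))
        add("ND2", resname, i, cg + 1.33 * rot(-60))
        NULL
      },
      LYS = {
        p <- cb
        for (nm in c("CG", "CD", "CE")) {
          p <- p + 1.52 * rot(15 * (nm == "CD") - 15 * (nm != "CD"))
          add(nm, resname, i, p)
        }
        add("NZ", resname, i, p + 1.49 * er)
        NULL
      },
      GLU = {
        cg <- cb + 1.52 * rot(15); cd <- cg + 1.52 * rot(-15)
        add("CG", resname, i, cg); add("CD", resname, i, cd)
        add("OE1", resname, i, cd + 1.25 * rot(60))
        add("OE2", resname, i, cd + 1.25 * rot(-60))
        NULL
      },
      LEU = {
        cg <- cb + 1.52 * er
        add("CG", resname, i, cg)
        add("CD1", resname, i, cg + 1.52 * rot(55))
        add("CD2", resname, i, cg + 1.52 * rot(-55))
        NULL
      },
      NULL)
  }
  df <- do.call(rbind, rows)
  finish_atom_table(df, chain = chain, het = FALSE)
}

# Largest-remainder apportionment of n among weights (ties: earlier first).
apportion_counts <- function(w, n) {
  base <- floor(w * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- w * n - base
    extra <- order(-frac, seq_along(w))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

finish_atom_table <- function(df, chain, het, serial_start = 1L) {
  n <- nrow(df)
  atom_model(data.frame(
    serial = seq.int(serial_start, length.out = n),
    name = df$name, altloc = "", resname = df$resname, chain = chain,
    resseq = df$resseq, icode = "", x = df$x, y = df$y, z = df$z,
    occupancy = 1, bfactor = 20, element = df$element,
    is_het = het, is_water = df$resname %in% WATER_RESNAMES,
    stringsAsFactors = FALSE))
}

#' Deterministic synthetic ligand
#'
#' A 39-atom rigid ligand template: 26 named heavy atoms mirroring the
#' oxyacetic-acid/ureido/oxadiazole naming of a Keap1 Kelch-domain ligand
#' (including OAA, OAB, OAC, CAT, NAM, OAQ, ...) plus 13 hydrogens, so
#' heavy-atom filtering and the carboxylate flip exclusion are exercised.
#' Atoms lie on a smooth 3D curve with 1.5-Angstrom steps, giving every atom
#' a bonded antecedent.
#'
#' @param resname ligand residue name (HETATM), default `"LG1"`.
#' @param resseq ligand residue number.
#' @return An [atom_model()] with 39 atoms.
#' @export
synthetic_ligand <- function(resname = "LG1", resseq = 701L) {
  heavy <- c("OAA", "CAT", "OAC", "CAX", "OAQ", "CAD", "CAF", "CAI", "CAK",
             "CAL", "CAY", "CAZ", "CAV", "NAM", "CAU", "OAB", "NAN", "CAG",
             "NAO", "NAP", "CAJ", "OAR", "CAB", "CAC", "CAE", "CAH")
  n <- length(heavy)
  # smooth space curve with constant 1.5 A arc steps
  dirs <- vapply(seq_len(n - 1), function(k) {
    th <- 0.45 * k; ph <- 0.23 * k
    c(cos(th) * cos(ph), sin(th) * cos(ph), sin(ph))
  }, numeric(3))
  pos <- rbind(c(0, 0, 0), apply(1.5 * t(dirs), 2, cumsum))
  df <- data.frame(name = heavy, resname = resname, resseq = resseq,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   element = substr(heavy, 1, 1), stringsAsFactors = FALSE)
  for (k in seq_len(13)) {  # hydrogens off the first 13 carbons
    ci <- which(df$element == "C")[k]
    df <- rbind(df, data.frame(name = sprintf("HA%s", LETTERS[k]),
                               resname = resname, resseq = resseq,
                               x = df$x[ci] + 0.7, y = df$y[ci] + 0.7,
                               z = df$z[ci], element = "H",
                               stringsAsFactors = FALSE))
  }
  finish_atom_table(df, chain = "A", het = TRUE, serial_start = 1001L)
}

#' Specify a planted binding mode
#'
#' @param rotation 3x3 proper rotation applied to the ligand template about
#'   its centroid.
#' @param translation length-3 translation (Angstrom).
#' @param weight occupancy fraction of the mode.
#' @param noise_sigma isotropic Gaussian positional noise per atom (Angstrom).
#' @return A list of class `mode_spec`.
#' @export
mode_spec <- function(rotation = diag(3), translation = c(0, 0, 0),
                      weight, noise_sigma = 0.18) {
  stopifnot(weight >= 0, weight <= 1, noise_sigma >= 0,
            abs(det(rotation) - 1) < 1e-6)
  structure(list(rotation = rotation, translation = translation,
                 weight = weight, noise_sigma = noise_sigma),
            class = "mode_spec")
}

#' Specify a planted-mode trajectory simulation
#'
#' The generator emulates the statistical structure the binding-mode
#' analysis assumes: a rigid receptor, a ligand whose pose per frame is
#' drawn i.i.d. from a few planted modes (rigid transform of a template plus
#' isotropic Gaussian noise) with stated occupancies, and optional
#' dissociation frames in which the ligand is displaced far enough to have
#' zero contacts. Defaults follow the conditions of the analysis
#' window: 500 frames recorded every 20 ps, three modes with occupancies
#' 0.60/0.25/0.15, and per-atom noise of 0.18 Angstrom.
#'
#' @param receptor receptor [atom_model()] (default [synthetic_receptor()]).
#' @param ligand ligand template [atom_model()] (default
#'   [synthetic_ligand()]), positioned next to the receptor before modes are
#'   applied.
#' @param modes list of [mode_spec()]; weights must sum to at most 1, the
#'   remainder being dissociated frames.
#' @param n_frames number of frames.
#' @param seed mandatory RNG seed (reproducibility).
#' @param start_time,stride frame times in ps.
#' @param sigma_receptor optional receptor jitter (Angstrom).
#' @param dissociation_displacement how far (Angstrom, >= 20) beyond the
#'   receptor surface the ligand is placed in dissociated frames.
#' @return A list of class `trajectory_sim_spec`.
#' @export
trajectory_sim_spec <- function(receptor = synthetic_receptor(),
                                ligand = NULL,
                                modes = default_modes(),
                                n_frames = 500L, seed,
                                start_time = 20, stride = 20,
                                sigma_receptor = 0,
                                dissociation_displacement = 50) {
  stopifnot(n_frames >= 1, dissociation_displacement >= 20)
  if (missing(seed)) stop_bad("a seed is mandatory for simulation")
  w <- vapply(modes, function(m) m$weight, numeric(1))
  if (sum(w) > 1 + 1e-12) stop_bad("mode weights sum to %.3f > 1", sum(w))
  if (is.null(ligand)) {
    ligand <- synthetic_ligand()
    # park the template against the receptor surface
    rc <- colMeans(model_coords(receptor))
    lc <- colMeans(model_coords(ligand))
    # park against the receptor surface: close enough for a realistic
    # engaged-mode contact count (~10 per frame), no steric clash
    shift <- rc + c(9.5, 0, 0) - lc
    ligand$atoms$x <- ligand$atoms$x + shift[1]
    ligand$atoms$y <- ligand$atoms$y + shift[2]
    ligand$atoms$z <- ligand$atoms$z + shift[3]
  }
  structure(list(receptor = receptor, ligand = ligand, modes = modes,
                 n_frames = as.integer(n_frames), seed = seed,
                 start_time = start_time, stride = stride,
                 sigma_receptor = sigma_receptor,
                 dissociation_displacement = dissociation_displacement),
            class = "trajectory_sim_spec")
}

#' @rdname trajectory_sim_spec
#' @export
default_modes <- function() {
  rot_z <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  list(mode_spec(weight = 0.60),
       mode_spec(rotation = rot_z(25), translation = c(0, 8, 0),
                 weight = 0.25),
       mode_spec(rotation = rot_z(-25), translation = c(0, 0, 8),
                 weight = 0.15))
}

#' Simulate a planted-binding-mode trajectory
#'
#' Per frame, a mode is drawn by occupancy weight (or dissociation, with the
#' leftover probability); the ligand template is rotated about its centroid,
#' translated, and perturbed with per-atom isotropic Gaussian noise; the
#' receptor is optionally jittered. Dissociated frames displace the ligand
#' radially beyond any contact range. Fully reproducible from the seed: the
#' caller's RNG state is untouched.
#'
#' @param spec a [trajectory_sim_spec()].
#' @return A list with `trajectory` (an [md_trajectory()]; receptor atoms
#'   first, ligand atoms flagged `is_het`) and `mode` (integer ground-truth
#'   label per frame; 0 means dissociated).
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_sim_spec"))
  rec <- spec$receptor$atoms
  lig <- spec$ligand$atoms
  roster <- rbind(rec, lig)
  roster$serial <- seq_len(nrow(roster))
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  lig_c <- colMeans(lig_xyz)
  rec_c <- colMeans(rec_xyz)
  w <- vapply(spec$modes, function(m) m$weight, numeric(1))
  n <- spec$n_frames
  with_local_seed(spec$seed, {
    # occupancies realised by largest-remainder apportionment (category 0 =
    # dissociated, weight 1 - sum(w)), then a random permutation of frame
    # order: realised mode sizes match the stated occupancies exactly
    labels <- sample(rep.int(c(seq_along(w), 0L),
                             apportion_counts(c(w, 1 - sum(w)), n)))
    coords <- array(0, dim = c(nrow(roster), 3L, n))
    far <- max(cross_distances(matrix(rec_c, 1), rec_xyz)) +
      max(cross_distances(matrix(lig_c, 1), lig_xyz)) +
      spec$dissociation_displacement
    for (i in seq_len(n)) {
      k <- labels[i]
      if (k >= 1L) {
        m <- spec$modes[[k]]
        pose <- tcrossprod(sweep(lig_xyz, 2, lig_c), m$rotation)
        pose <- sweep(pose, 2, lig_c + m$translation, "+")
        if (m$noise_sigma > 0)
          pose <- pose + matrix(stats::rnorm(length(pose), 0, m$noise_sigma),
                                ncol = 3)
      } else {
        dir <- stats::rnorm(3); dir <- dir / vec_norm(dir)
        pose <- sweep(lig_xyz, 2, rec_c + far * dir - lig_c, "+")
      }
      rxyz <- rec_xyz
      if (spec$sigma_receptor > 0)
        rxyz <- rxyz + matrix(stats::rnorm(length(rxyz), 0,
                                           spec$sigma_receptor), ncol = 3)
      coords[, , i] <- rbind(rxyz, pose)
    }
    list(trajectory = md_trajectory(
           roster, coords,
           times = spec$start_time + (seq_len(n) - 1) * spec$stride),
         mode = labels)
  })
}

#' Build a toy crystal realising requested packing contacts
#'
#' Constructs a single-asymmetric-unit model (a sparse line of protein
#' pseudo-atoms plus a HETATM ligand) inside the given cell such that
#' [count_packing_contacts()] finds exactly `n_asu_contacts` ligand-protein
#' pairs within the asymmetric unit and exactly `n_sym_contacts` pairs to
#' one chosen symmetry image. Protein atoms are spaced 6 Angstrom apart so
#' each placed ligand atom touches exactly one protein atom at
#' `contact_distance`; the construction is verified geometrically and an
#' error is raised if the placement is infeasible in the given cell.
#'
#' @param cell unit cell list.
#' @param spacegroup a [space_group()] (or symbol).
#' @param n_asu_contacts,n_sym_contacts requested contact counts (>= 0).
#' @param contact_distance distance of each planted contact (Angstrom,
#'   default 3.0; must be below the 3.4 cutoff).
#' @param op_index symmetry operator used for the mate (default: the last
#'   operator, or the identity with a +a lattice shift for P1).
#' @param cutoff the audit cutoff the fixture is built for (default 3.4).
#' @return An [atom_model()] with cell and space group set.
#' @export
make_crystal_fixture <- function(cell, spacegroup, n_asu_contacts,
                                 n_sym_contacts, contact_distance = 3.0,
                                 op_index = NULL, cutoff = 3.4) {
  stopifnot(n_asu_contacts >= 0, n_sym_contacts >= 0,
            contact_distance < cutoff)
  if (!inherits(spacegroup, "space_group")) spacegroup <- space_group(spacegroup)
  n_ops <- length(spacegroup$ops)
  if (is.null(op_index)) op_index <- n_ops
  shift <- if (op_index == 1L) c(1L, 0L, 0L) else c(0L, 0L, 0L)
  mats <- cell_matrices(cell)
  n_prot <- max(n_asu_contacts + n_sym_contacts, 2L)
  # protein: line of CA pseudo-atoms along x, 6 A apart, at a generic
  # fractional position (away from special positions of common groups)
  base <- as.numeric(mats$orth %*% c(0.13, 0.21, 0.29))
  prot_xyz <- cbind(base[1] + 6 * (seq_len(n_prot) - 1), base[2], base[3])
  op <- spacegroup$ops[[op_index]]
  image_of <- function(xyz) {
    frac <- t(op$R %*% mats$frac %*% t(xyz)) + rep(op$t + shift,
                                                   each = nrow(xyz))
    t(mats$orth %*% t(frac))
  }
  img_xyz <- image_of(prot_xyz)
  lig <- matrix(0, 0, 3)
  # asu contacts: one ligand atom per protein atom, offset along +y
  for (k in seq_len(n_asu_contacts))
    lig <- rbind(lig, prot_xyz[k, ] + c(0, contact_distance, 0))
  # mate contacts hang off the image of the *remaining* protein atoms
  for (k in seq_len(n_sym_contacts))
    lig <- rbind(lig, img_xyz[n_asu_contacts + k, ] +
                   c(0, contact_distance, 0))
  model <- assemble_crystal_model(prot_xyz, lig, cell, spacegroup)
  verify_crystal_fixture(model, n_asu_contacts, n_sym_contacts, cutoff)
  model
}

assemble_crystal_model <- function(prot_xyz, lig_xyz, cell, spacegroup) {
  prot <- data.frame(name = "CA", resname = "GLY",
                     resseq = seq_len(nrow(prot_xyz)),
                     x = prot_xyz[, 1], y = prot_xyz[, 2], z = prot_xyz[, 3],
                     element = "C", stringsAsFactors = FALSE)
  n_l <- nrow(lig_xyz)
  atoms <- prot
  het <- rep(FALSE, nrow(prot))
  if (n_l) {
    lig <- data.frame(name = sprintf("C%02d", seq_len(n_l)), resname = "LIG",
                      resseq = 900L, x = lig_xyz[, 1], y = lig_xyz[, 2],
                      z = lig_xyz[, 3], element = "C",
                      stringsAsFactors = FALSE)
    atoms <- rbind(prot, lig)
    het <- c(het, rep(TRUE, n_l))
  }
  m <- finish_atom_table(atoms, chain = "A", het = FALSE)
  m$atoms$is_het <- het
  m$cell <- cell
  m$spacegroup <- spacegroup
  m
}

verify_crystal_fixture <- function(model, n_asu, n_sym, cutoff) {
  lig_sel <- select_atoms(model, het = TRUE)
  rep_ <- count_packing_contacts(model, lig_sel, cutoff = cutoff)
  if (rep_$n_asu_contacts != n_asu || rep_$n_sym_contacts != n_sym)
    stop_bad(paste0("infeasible placement in this cell: realised %d/%d ",
                    "contacts instead of %d/%d; use a larger cell"),
             rep_$n_asu_contacts, rep_$n_sym_contacts, n_asu, n_sym)
  invisible(model)
}

#' Build a complex realising requested interaction counts
#'
#' Constructs a synthetic protein-fragment/ligand/water model for which
#' [build_interaction_table()] under default rules reports exactly the
#' requested numbers of hydrogen bonds, nonpolar contacts, electrostatic
#' interactions and water bridges. Each interaction unit is an isolated
#' serine (HB: OG donor to a ligand OAB-type acceptor at 2.8 A, ideal
#' antecedent angle), alanine (NP: CB to a ligand carbon at 3.2 A), arginine
#' (ES: NH1 to a carboxylate OAA at 3.7 A) or serine-water-ligand triad
#' (bridge: two 2.7 A legs bent so the direct distance exceeds 4 A); units
#' are placed 50 Angstrom apart so they cannot cross-talk.
#'
#' @param n_hb,n_np,n_es,n_bridges requested counts (>= 0).
#' @return A list with `model` (an [atom_model()]) and `ligand_sel`.
#' @export
make_interaction_fixture <- function(n_hb = 0, n_np = 0, n_es = 0,
                                     n_bridges = 0) {
  stopifnot(n_hb >= 0, n_np >= 0, n_es >= 0, n_bridges >= 0)
  rows <- list()
  res <- 0L
  wat <- 800L
  add <- function(name, resname, resseq, xyz, element, het, water = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resname = resname, resseq = resseq, x = xyz[1],
      y = xyz[2], z = xyz[3], element = element, het = het, water = water,
      stringsAsFactors = FALSE)
  }
  unit_origin <- function() {
    res <<- res + 1L
    c(50 * res, 0, 0)
  }
  for (k in seq_len(n_hb)) {
    o <- unit_origin()
    add("CB", "SER", res, o + c(-1.4, 0, 0), "C", FALSE)
    add("OG", "SER", res, o, "O", FALSE)
    add("OAB", "LG1", 700L, o + c(2.8, 0, 0), "O", TRUE)  # angle CB-OG-OAB = 180
  }
  for (k in seq_len(n_np)) {
    o <- unit_origin()
    add("CB", "ALA", res, o, "C", FALSE)
    add("CAZ", "LG1", 700L, o + c(3.2, 0, 0), "C", TRUE)
  }
  for (k in seq_len(n_es)) {
    o <- unit_origin()
    add("CZ", "ARG", res, o + c(-1.33, 0, 0), "C", FALSE)
    add("NH1", "ARG", res, o, "N", FALSE)
    add("OAA", "LG1", 700L, o + c(3.7, 0, 0), "O", TRUE)
  }
  for (k in seq_len(n_bridges)) {
    o <- unit_origin()
    wat <- wat + 1L
    add("CB", "SER", res, o + c(-1.4, 0, 0), "C", FALSE)
    add("OG", "SER", res, o, "O", FALSE)
    add("O", "HOH", wat, o + c(2.7, 0, 0), "O", TRUE, water = TRUE)
    # 115 degrees at the water vertex: direct protein-ligand distance ~4.6 A
    add("OAC", "LG1", 700L, o + c(2.7, 0, 0) +
          2.7 * c(cos(65 * pi / 180), sin(65 * pi / 180), 0), "O", TRUE)
  }
  if (!length(rows)) {
    model <- atom_model(empty_atom_table())
    return(list(model = model, ligand_sel = integer()))
  }
  df <- do.call(rbind, rows)
  m <- finish_atom_table(df[, c("name", "resname", "resseq", "x", "y", "z",
                                "element")], chain = "A", het = FALSE)
  m$atoms$is_het <- df$het
  m$atoms$is_water <- df$water
  list(model = m, ligand_sel = select_atoms(m, resname = "LG1"))
}
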