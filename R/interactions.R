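#' Interaction classification rules
#'
#' Distance thresholds and heavy-atom chemistry tables used to classify
#' protein-ligand contacts. The scheme distinguishes three contact types:
#' \describe{
#'   \item{HB}{hydrogen bond: distance not greater than `hb_max` between a
#'     donor/acceptor-complementary N/O pair, with the antecedent-donor-
#'     acceptor angle at least `hb_angle_min` degrees when the donor's bonded
#'     antecedent is available (hydrogens are absent in crystal models, so
#'     the angle is evaluated on heavy atoms).}
#'   \item{NP}{nonpolar interaction: any other pair at distance not greater
#'     than `contact_max`.}
#'   \item{ES}{electrostatic interaction: a formally charged positive/negative
#'     pair at distance greater than `hb_max` but not greater than `es_max`.}
#' }
#' Precedence is HB over NP over ES, with ES reserved for the
#' `(hb_max, es_max]` shell: charged pairs inside `hb_max` already count as
#' HB or NP.
#'
#' Donor/acceptor/charge typing covers the 20 standard amino acids plus a
#' per-ligand typing block. The built-in ligand block matches the oxyacetic-
#' acid/ureido/oxadiazole Keap1 Kelch-domain ligand: carboxylate oxygens
#' OAA/OAC are acceptors and formally negative, the ureido oxygen OAB and
#' the oxadiazole ring nitrogen NAO are acceptors, NAM/NAN/NAP are donors,
#' and ether/ring oxygens (OAQ/OAR/OAO) are treated as non-acceptors (weak
#' ether oxygens). All of it can be overridden via arguments or a YAML file
#' ([read_interaction_rules()]).
#'
#' @param contact_max,hb_max,es_max distance bounds in Angstrom; the
#'   invariant `hb_max <= contact_max <= es_max` is enforced.
#' @param hb_angle_min minimum antecedent-donor-acceptor angle in degrees.
#' @param his_charged should histidine ring nitrogens count as formally
#'   positive? Default `FALSE`.
#' @param ligand optional list overriding the ligand typing block; elements
#'   `donors`, `acceptors`, `negative`, `positive` (atom-name vectors).
#' @return A list of class `interaction_rules`.
#' @export
interaction_rules <- function(contact_max = 3.4, hb_max = 3.4, es_max = 4.0,
                              hb_angle_min = 90, his_charged = FALSE,
                              ligand = NULL) {
  if (!(hb_max <= contact_max && contact_max <= es_max))
    stop_bad("need hb_max <= contact_max <= es_max")
  lig <- list(
    donors = c("NAM", "NAN", "NAP"),
    acceptors = c("OAA", "OAB", "OAC", "NAO"),
    negative = c("OAA", "OAC"),
    positive = character())
  if (!is.null(ligand)) lig[names(ligand)] <- ligand
  pos <- c("ARG NE", "ARG NH1", "ARG NH2", "LYS NZ")
  if (his_charged) pos <- c(pos, "HIS ND1", "HIS NE2")
  structure(list(
    contact_max = contact_max, hb_max = hb_max, es_max = es_max,
    hb_angle_min = hb_angle_min,
    protein_donors = c("* N",
      "ARG NE", "ARG NH1", "ARG NH2", "LYS NZ", "HIS ND1", "HIS NE2",
      "TRP NE1", "ASN ND2", "GLN NE2", "SER OG", "THR OG1", "TYR OH"),
    protein_acceptors = c("* O", "* OXT",
      "ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2", "ASN OD1", "GLN OE1",
      "HIS ND1", "HIS NE2", "SER OG", "THR OG1", "TYR OH"),
    protein_positive = pos,
    protein_negative = c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2"),
    ligand = lig), class = "interaction_rules")
}

#' Read interaction rules from a YAML file
#'
#' The YAML file may set any scalar threshold (`contact_max`, `hb_max`,
#' `es_max`, `hb_angle_min`), `his_charged`, and a `ligand` block with
#' `donors`/`acceptors`/`negative`/`positive` atom-name lists.
#'
#' @param path YAML file path.
#' @return An [interaction_rules()] object.
#' @export
read_interaction_rules <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("contact_max", "hb_max", "es_max",
                                  "hb_angle_min", "his_charged", "ligand"))]
  do.call(interaction_rules, args)
}

match_typed <- function(resname, name, patterns) {
  paste(resname, name) %in% patterns | paste("*", name) %in% patterns
}

atom_roles <- function(atoms, rules, side = c("protein", "ligand")) {
  side <- match.arg(side)
  if (side == "protein") {
    water <- atoms$is_water
    list(
      donor = (match_typed(atoms$resname, atoms$name, rules$protein_donors) &
                 atoms$resname != "PRO") | water,
      acceptor = match_typed(atoms$resname, atoms$name,
                             rules$protein_acceptors) | water,
      positive = match_typed(atoms$resname, atoms$name, rules$protein_positive),
      negative = match_typed(atoms$resname, atoms$name, rules$protein_negative))
  } else {
    list(donor = atoms$name %in% rules$ligand$donors,
         acceptor = atoms$name %in% rules$ligand$acceptors,
         positive = atoms$name %in% rules$ligand$positive,
         negative = atoms$name %in% rules$ligand$negative)
  }
}

#' Classify one protein-ligand atom pair
#'
#' Decision procedure for a precomputed heavy-atom distance: hydrogen bond if
#' the pair is donor/acceptor-complementary N/O within `hb_max` and the angle
#' criterion passes; else nonpolar within `contact_max`; else electrostatic
#' for a charged pair within `es_max`; else `NA`.
#'
#' @param protein_atom,ligand_atom single-row atom data.frames (rows of an
#'   [atom_model()] atom table).
#' @param distance precomputed interatomic distance (Angstrom).
#' @param rules an [interaction_rules()] object.
#' @param protein_antecedent,ligand_antecedent optional length-3 coordinates
#'   of the bonded antecedent of each atom, used for the donor-angle check;
#'   when absent the angle criterion is taken as satisfied.
#' @return `"HB"`, `"NP"`, `"ES"`, or `NA_character_`.
#' @examples
#' r <- interaction_rules()
#' ser_og <- data.frame(resname = "SER", name = "OG", element = "O",
#'                      is_water = FALSE)
#' oac <- data.frame(resname = "LIG", name = "OAC", element = "O")
#' classify_pair(ser_og, oac, 2.74, r)  # "HB"
#' @export
classify_pair <- function(protein_atom, ligand_atom, distance, rules,
                          protein_antecedent = NULL, ligand_antecedent = NULL) {
  pr <- atom_roles(protein_atom, rules, "protein")
  lr <- atom_roles(ligand_atom, rules, "ligand")
  both_no <- protein_atom$element %in% c("N", "O") &&
             ligand_atom$element %in% c("N", "O")
  if (distance <= rules$hb_max && both_no) {
    pc <- c(protein_atom$x, protein_atom$y, protein_atom$z)
    lc <- c(ligand_atom$x, ligand_atom$y, ligand_atom$z)
    ok_angle <- function(donor_xyz, ante, acceptor_xyz) {
      if (is.null(ante) || any(is.na(ante))) return(TRUE)
      angle_deg(ante, donor_xyz, acceptor_xyz) >= rules$hb_angle_min
    }
    hb <- (pr$donor && lr$acceptor &&
             ok_angle(pc, protein_antecedent, lc)) ||
          (lr$donor && pr$acceptor &&
             ok_angle(lc, ligand_antecedent, pc))
    if (hb) return("HB")
  }
  if (distance <= rules$contact_max) return("NP")
  if (distance <= rules$es_max &&
      ((pr$positive && lr$negative) || (pr$negative && lr$positive)))
    return("ES")
  NA_character_
}

# Nearest bonded heavy-atom antecedent within the same residue; NA row if none
# within bonding distance (2.0 A).
antecedent_coords <- function(atoms, idx) {
  out <- matrix(NA_real_, length(idx), 3)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname)
  for (k in seq_along(idx)) {
    i <- idx[k]
    same <- which(key == key[i] & seq_len(nrow(atoms)) != i &
                    atoms$element != "H")
    if (!length(same)) next
    d <- cross_distances(atoms[i, c("x", "y", "z")],
                         atoms[same, c("x", "y", "z")])[1, ]
    j <- same[which.min(d)]
    if (min(d) <= 2.0) out[k, ] <- as.numeric(atoms[j, c("x", "y", "z")])
  }
  out
}

#' Build the protein-ligand interaction table of a complex
#'
#' Enumerates every protein-atom/ligand-atom pair within `es_max`, classifies
#' each with [classify_pair()] (supplying bonded antecedents for the angle
#' check), and detects water-mediated hydrogen bonds: a water bridging the
#' protein and the ligand through two hydrogen-bond legs, each leg within
#' `hb_max` and donor/acceptor-complementary. Hydrogens are ignored; each
#' heavy-atom pair appears at most once, and each (protein atom, water,
#' ligand atom) triple is one bridge.
#'
#' @param model an [atom_model()] containing protein, ligand and (optionally)
#'   waters.
#' @param ligand_sel non-empty selection of the ligand atoms.
#' @param rules an [interaction_rules()] object.
#' @param form_label free-text label stored with the table.
#' @return An object of class `interaction_table`: list with `contacts`
#'   (data.frame: `resname`, `resseq`, `protein_atom`, `ligand_atom`,
#'   `distance`, `type`), `bridges` (data.frame: `resname`, `resseq`,
#'   `protein_atom`, `water_resseq`, `ligand_atom`, `d_protein_water`,
#'   `d_water_ligand`) and `form_label`.
#' @export
build_interaction_table <- function(model, ligand_sel,
                                    rules = interaction_rules(),
                                    form_label = "") {
  if (!length(ligand_sel)) stop_bad("empty ligand selection")
  a <- model$atoms
  prot_idx <- which(!a$is_het & !a$is_water & a$element != "H")
  lig_idx <- ligand_sel[a$element[ligand_sel] != "H"]
  wat_idx <- which(a$is_water & a$element != "H")
  contacts <- empty_contacts()
  if (length(prot_idx) && length(lig_idx)) {
    d <- cross_distances(a[prot_idx, c("x", "y", "z")],
                         a[lig_idx, c("x", "y", "z")])
    hits <- which(d <= rules$es_max, arr.ind = TRUE)
    if (nrow(hits)) {
      pi_ <- prot_idx[hits[, 1]]; li <- lig_idx[hits[, 2]]
      p_ante <- antecedent_coords(a, pi_)
      l_ante <- antecedent_coords(a, li)
      type <- character(nrow(hits))
      for (k in seq_len(nrow(hits))) {
        type[k] <- classify_pair(a[pi_[k], ], a[li[k], ],
                                 d[hits[k, 1], hits[k, 2]], rules,
                                 protein_antecedent = p_ante[k, ],
                                 ligand_antecedent = l_ante[k, ])
      }
      keep <- !is.na(type)
      contacts <- data.frame(
        resname = a$resname[pi_][keep], resseq = a$resseq[pi_][keep],
        protein_atom = a$name[pi_][keep], ligand_atom = a$name[li][keep],
        distance = d[hits][keep], type = type[keep],
        stringsAsFactors = FALSE)
      contacts <- contacts[order(contacts$resseq, contacts$protein_atom,
                                 contacts$ligand_atom), , drop = FALSE]
      rownames(contacts) <- NULL
    }
  }
  bridges <- find_water_bridges(a, prot_idx, lig_idx, wat_idx, rules)
  structure(list(contacts = contacts, bridges = bridges,
                 form_label = form_label),
            class = "interaction_table")
}

empty_contacts <- function()
  data.frame(resname = character(), resseq = integer(),
             protein_atom = character(), ligand_atom = character(),
             distance = numeric(), type = character(), stringsAsFactors = FALSE)

empty_bridges <- function()
  data.frame(resname = character(), resseq = integer(),
             protein_atom = character(), water_resseq = integer(),
             ligand_atom = character(), d_protein_water = numeric(),
             d_water_ligand = numeric(), stringsAsFactors = FALSE)

find_water_bridges <- function(a, prot_idx, lig_idx, wat_idx, rules) {
  bridges <- empty_bridges()
  if (!length(wat_idx) || !length(prot_idx) || !length(lig_idx))
    return(bridges)
  hb_leg <- function(wi, oi, side) {
    # water is donor and acceptor, so one complementary direction suffices
    d <- cross_distances(a[wi, c("x", "y", "z")], a[oi, c("x", "y", "z")])[1, ]
    roles <- atom_roles(a[oi, , drop = FALSE], rules, side)
    ok <- d <= rules$hb_max & a$element[oi] %in% c("N", "O") &
      (roles$donor | roles$acceptor)
    list(idx = oi[ok], d = d[ok])
  }
  for (wi in wat_idx) {
    pl <- hb_leg(wi, prot_idx, "protein")
    if (!length(pl$idx)) next
    ll <- hb_leg(wi, lig_idx, "ligand")
    if (!length(ll$idx)) next
    for (k in seq_along(pl$idx)) for (m in seq_along(ll$idx)) {
      bridges <- rbind(bridges, data.frame(
        resname = a$resname[pl$idx[k]], resseq = a$resseq[pl$idx[k]],
        protein_atom = a$name[pl$idx[k]], water_resseq = a$resseq[wi],
        ligand_atom = a$name[ll$idx[m]],
        d_protein_water = pl$d[k], d_water_ligand = ll$d[m],
        stringsAsFactors = FALSE))
    }
  }
  rownames(bridges) <- NULL
  bridges
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table>%s %d contacts (%d HB, %d NP, %d ES), %d water bridges\n",
              if (nzchar(x$form_label)) paste0(" [", x$form_label, "]") else "",
              nrow(x$contacts), sum(x$contacts$type == "HB"),
              sum(x$contacts$type == "NP"), sum(x$contacts$type == "ES"),
              nrow(x$bridges)))
  invisible(x)
}

#' Summarise ligand recognition from an interaction table
#'
#' Lists the unique recognising residues (over direct contacts and the
#' protein side of water bridges, ordered by residue number) and counts the
#' interactions per type. A water bridge counts once as one water-mediated
#' hydrogen bond, regardless of its two printed legs.
#'
#' @param table an `interaction_table` from [build_interaction_table()] or
#'   [read_contact_table()].
#' @return A list of class `recognition_summary` with `residues` (data.frame
#'   `resname`, `resseq`), `n_residues`, `n_hb`, `n_water_hb`, `n_np`, `n_es`.
#' @export
summarize_recognition <- function(table) {
  res <- rbind(table$contacts[, c("resname", "resseq")],
               table$bridges[, c("resname", "resseq")])
  res <- unique(res)
  res <- res[order(res$resseq), , drop = FALSE]
  rownames(res) <- NULL
  bridges_unique <- unique(table$bridges[, c("protein_atom", "resseq",
                                             "water_resseq", "ligand_atom")])
  structure(list(residues = res, n_residues = nrow(res),
                 n_hb = sum(table$contacts$type == "HB"),
                 n_water_hb = nrow(bridges_unique),
                 n_np = sum(table$contacts$type == "NP"),
                 n_es = sum(table$contacts$type == "ES")),
            class = "recognition_summary")
}

#' @export
print.recognition_summary <- function(x, ...) {
  cat(sprintf("<recognition_summary> %d residues; %d HB, %d water-mediated HB, %d NP, %d ES\n",
              x$n_residues, x$n_hb, x$n_water_hb, x$n_np, x$n_es))
  invisible(x)
}

#' Write / read an interaction table as TSV
#'
#' The TSV mirrors a published contact-table layout: columns `residue`
#' (e.g. `Tyr334`), `protein_atom` (PDB atom name), `water` (e.g. `W445`, or
#' empty), `ligand_atom`, `type`, `distance`. Direct contacts occupy one row;
#' a water bridge occupies two consecutive rows (protein-to-water leg, then
#' water-to-ligand leg, both typed HB) sharing the water label. Output is
#' byte-deterministic for identical inputs.
#'
#' @param table an `interaction_table`.
#' @param path TSV file path.
#' @return `write_contact_table()` returns `path` invisibly;
#'   `read_contact_table()` returns an `interaction_table`.
#' @export
write_contact_table <- function(table, path) {
  fmt_res <- function(resname, resseq)
    paste0(substr(resname, 1, 1), tolower(substr(resname, 2, 3)), resseq)
  rows <- character()
  co <- table$contacts
  for (i in seq_len(nrow(co)))
    rows <- c(rows, paste(fmt_res(co$resname[i], co$resseq[i]),
                          co$protein_atom[i], "", co$ligand_atom[i],
                          co$type[i], sprintf("%.2f", co$distance[i]),
                          sep = "\t"))
  br <- table$bridges
  for (i in seq_len(nrow(br))) {
    w <- paste0("W", br$water_resseq[i])
    rows <- c(rows,
              paste(fmt_res(br$resname[i], br$resseq[i]), br$protein_atom[i],
                    w, "", "HB", sprintf("%.2f", br$d_protein_water[i]),
                    sep = "\t"),
              paste("", "", w, br$ligand_atom[i], "HB",
                    sprintf("%.2f", br$d_water_ligand[i]), sep = "\t"))
  }
  writeLines(c(paste("residue", "protein_atom", "water", "ligand_atom",
                     "type", "distance", sep = "\t"), rows), path)
  invisible(path)
}

#' @rdname write_contact_table
#' @param form_label label stored with the parsed table.
#' @export
read_contact_table <- function(path, form_label = "") {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  tb$distance <- as.numeric(tb$distance)
  parse_res <- function(s) {
    list(resname = toupper(sub("([A-Za-z]+)[0-9]+", "\\1", s)),
         resseq = as.integer(sub("[A-Za-z]+([0-9]+)", "\\1", s)))
  }
  has_water <- nzchar(tb$water)
  direct <- tb[!has_water, , drop = FALSE]
  pr <- parse_res(direct$residue)
  contacts <- data.frame(resname = pr$resname, resseq = pr$resseq,
                         protein_atom = direct$protein_atom,
                         ligand_atom = direct$ligand_atom,
                         distance = direct$distance, type = direct$type,
                         stringsAsFactors = FALSE)
  wb <- tb[has_water, , drop = FALSE]
  bridges <- empty_bridges()
  if (nrow(wb)) {
    pleg <- wb[nzchar(wb$protein_atom), , drop = FALSE]
    lleg <- wb[nzchar(wb$ligand_atom), , drop = FALSE]
    for (i in seq_len(nrow(pleg))) {
      m <- lleg[lleg$water == pleg$water[i], , drop = FALSE]
      pr <- parse_res(pleg$residue[i])
      for (j in seq_len(nrow(m))) {
        bridges <- rbind(bridges, data.frame(
          resname = pr$resname, resseq = pr$resseq,
          protein_atom = pleg$protein_atom[i],
          water_resseq = as.integer(sub("W", "", pleg$water[i])),
          ligand_atom = m$ligand_atom[j],
          d_protein_water = pleg$distance[i],
          d_water_ligand = m$distance[j], stringsAsFactors = FALSE))
      }
    }
  }
  rownames(contacts) <- rownames(bridges) <- NULL
  structure(list(contacts = contacts, bridges = bridges,
                 form_label = form_label),
            class = "interaction_table")
}
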