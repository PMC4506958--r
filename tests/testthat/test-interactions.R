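rules <- interaction_rules()

atom_row <- function(resname, name, element = substr(name, 1, 1),
                     xyz = c(0, 0, 0), water = FALSE) {
  data.frame(resname = resname, name = name, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3], is_water = water,
             stringsAsFactors = FALSE)
}

test_that("single pairs classify by distance shell and chemistry", {
  # serine hydroxyl donating to a carboxylate oxygen: hydrogen bond
  expect_equal(classify_pair(atom_row("SER", "OG", "O"),
                             atom_row("LG1", "OAC", "O"), 2.74, rules), "HB")
  # guanidinium to carboxylate beyond the HB shell: electrostatic
  expect_equal(classify_pair(atom_row("ARG", "NH1", "N"),
                             atom_row("LG1", "OAA", "O"), 3.51, rules), "ES")
  expect_equal(classify_pair(atom_row("ARG", "NE", "N"),
                             atom_row("LG1", "OAC", "O"), 3.47, rules), "ES")
  # the same chemistry inside the HB shell is a hydrogen bond, not ES
  expect_equal(classify_pair(atom_row("ARG", "NE", "N"),
                             atom_row("LG1", "OAC", "O"), 2.88, rules), "HB")
  # two carbons within contact range: nonpolar; beyond: nothing
  expect_equal(classify_pair(atom_row("ALA", "CB", "C"),
                             atom_row("LG1", "CAZ", "C"), 3.2, rules), "NP")
  expect_true(is.na(classify_pair(atom_row("ALA", "CB", "C"),
                                  atom_row("LG1", "CAZ", "C"), 3.5, rules)))
  # donor-donor N pair cannot hydrogen bond: nonpolar
  expect_equal(classify_pair(atom_row("ARG", "NH2", "N"),
                             atom_row("LG1", "NAP", "N"), 3.08, rules), "NP")
  # ether oxygen is not an acceptor under the default ligand typing
  expect_equal(classify_pair(atom_row("ARG", "NH1", "N"),
                             atom_row("LG1", "OAQ", "O"), 3.05, rules), "NP")
})

test_that("a failed donor-angle check demotes a polar pair to nonpolar", {
  # antecedent nearly in line between donor and acceptor: angle ~40 degrees
  ante <- c(1.05, 0.9, 0)
  expect_equal(classify_pair(atom_row("SER", "OG", "O", xyz = c(0, 0, 0)),
                             atom_row("LG1", "OAB", "O", xyz = c(2.8, 0, 0)),
                             2.8, rules, protein_antecedent = ante), "NP")
  # antecedent behind the donor: angle 180, hydrogen bond stands
  expect_equal(classify_pair(atom_row("SER", "OG", "O", xyz = c(0, 0, 0)),
                             atom_row("LG1", "OAB", "O", xyz = c(2.8, 0, 0)),
                             2.8, rules, protein_antecedent = c(-1.4, 0, 0)),
               "HB")
})

test_that("constructed fixtures yield exactly the requested interaction profile", {
  for (req in list(c(1, 1, 1, 1), c(0, 0, 0, 0), c(2, 3, 1, 2),
                   c(1, 19, 3, 1), c(5, 11, 0, 3))) {
    fx <- make_interaction_fixture(req[1], req[2], req[3], req[4])
    if (sum(req) == 0) {
      expect_length(fx$ligand_sel, 0)
      next
    }
    tb <- build_interaction_table(fx$model, fx$ligand_sel, rules)
    s <- summarize_recognition(tb)
    expect_equal(c(s$n_hb, s$n_np, s$n_es, s$n_water_hb), req,
                 label = paste("profile", paste(req, collapse = "/")))
  }
})

test_that("a far-away ligand produces an empty table and empty summary", {
  rec <- synthetic_receptor(n_res = 6)
  lig <- synthetic_ligand()
  lig$atoms[, c("x", "y", "z")] <- lig$atoms[, c("x", "y", "z")] + 500
  m <- rec
  m$atoms <- rbind(rec$atoms, lig$atoms)
  m$atoms$serial <- seq_len(nrow(m$atoms))
  tb <- build_interaction_table(m, select_atoms(m, het = TRUE), rules)
  expect_equal(nrow(tb$contacts), 0)
  expect_equal(nrow(tb$bridges), 0)
  s <- summarize_recognition(tb)
  expect_equal(s$n_residues, 0)
  expect_equal(s$n_hb + s$n_np + s$n_es + s$n_water_hb, 0)
  expect_error(build_interaction_table(m, integer(), rules), "empty ligand")
})

test_that("the table partitions into types and is monotone in contact_max", {
  fx <- make_interaction_fixture(3, 4, 2, 1)
  tb <- build_interaction_table(fx$model, fx$ligand_sel, rules)
  expect_equal(sum(tb$contacts$type == "HB") + sum(tb$contacts$type == "NP") +
                 sum(tb$contacts$type == "ES"), nrow(tb$contacts))
  expect_false(any(duplicated(
    tb$contacts[, c("resseq", "protein_atom", "ligand_atom")])))
  tight <- interaction_rules(contact_max = 3.0, hb_max = 3.0)
  tb_tight <- build_interaction_table(fx$model, fx$ligand_sel, tight)
  expect_lte(nrow(tb_tight$contacts), nrow(tb$contacts))
})

test_that("the classification is invariant under a rigid motion of the complex", {
  fx <- make_interaction_fixture(2, 2, 1, 1)
  m2 <- fx$model
  xyz <- tcrossprod(as.matrix(m2$atoms[, c("x", "y", "z")]),
                    random_rotation()) + rep(c(11, -4, 7), each = nrow(m2$atoms))
  m2$atoms[, c("x", "y", "z")] <- xyz
  t1 <- build_interaction_table(fx$model, fx$ligand_sel, rules)
  t2 <- build_interaction_table(m2, fx$ligand_sel, rules)
  expect_equal(t2$contacts$type, t1$contacts$type)
  expect_equal(t2$contacts$distance, t1$contacts$distance, tolerance = 1e-9)
  expect_equal(nrow(t2$bridges), nrow(t1$bridges))
})

test_that("contact-table TSV output is byte-deterministic and round-trips", {
  fx <- make_interaction_fixture(2, 3, 1, 2)
  tb <- build_interaction_table(fx$model, fx$ligand_sel, rules)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_contact_table(tb, f1)
  write_contact_table(tb, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_contact_table(f1)
  s0 <- summarize_recognition(tb); s1 <- summarize_recognition(back)
  expect_equal(s1$n_hb, s0$n_hb)
  expect_equal(s1$n_water_hb, s0$n_water_hb)
  expect_equal(s1$residues, s0$residues)
})

test_that("published contact tables summarise to the reported recognition profile", {
  soak <- read_contact_table(
    system.file("extdata", "keap1_ligand1_contacts_soaking.tsv",
                package = "bindmode"), form_label = "soaking")
  s <- summarize_recognition(soak)
  expect_equal(s$n_residues, 10)
  expect_equal(c(s$n_hb, s$n_water_hb, s$n_es, s$n_np), c(1, 1, 3, 19))
  expect_equal(s$residues$resseq,
               c(334, 363, 380, 382, 414, 415, 483, 508, 556, 603))
  coc <- read_contact_table(
    system.file("extdata", "keap1_ligand1_contacts_cocrystallization.tsv",
                package = "bindmode"), form_label = "cocrystallization")
  sc <- summarize_recognition(coc)
  expect_equal(sc$n_residues, 7)
  expect_equal(c(sc$n_hb, sc$n_water_hb, sc$n_np, sc$n_es), c(5, 3, 11, 0))
})

test_that("rules read from YAML override defaults and enforce threshold order", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("hb_max: 3.2", "es_max: 4.5", "hb_angle_min: 100",
               "ligand:", "  donors: [NX1]", "  acceptors: [OX1]",
               "  negative: [OX1]"), f)
  r2 <- read_interaction_rules(f)
  expect_equal(r2$hb_max, 3.2)
  expect_equal(r2$es_max, 4.5)
  expect_equal(r2$ligand$donors, "NX1")
  expect_error(interaction_rules(hb_max = 3.6, contact_max = 3.4), "hb_max")
})
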