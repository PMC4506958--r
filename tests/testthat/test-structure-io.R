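test_that("PDB write/read round-trips identity fields and coordinates", {
  m <- synthetic_receptor(n_res = 6)
  m$cell <- list(a = 85.368, b = 85.368, c = 145.903,
                 alpha = 90, beta = 90, gamma = 120)
  m$spacegroup <- space_group("P6522")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, tf)
  m2 <- read_pdb(tf)
  expect_equal(m2$atoms$name, m$atoms$name)
  expect_equal(m2$atoms$resname, m$atoms$resname)
  expect_equal(m2$atoms$resseq, m$atoms$resseq)
  expect_equal(m2$atoms$element, m$atoms$element)
  expect_equal(m2$atoms$is_het, m$atoms$is_het)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 5e-4)
  expect_equal(m2$atoms$z, m$atoms$z, tolerance = 5e-4)
  expect_equal(m2$cell$a, 85.368)
  expect_equal(m2$spacegroup$symbol, "P 65 2 2")
})

test_that("an atom-free file with CRYST1 yields an empty model with a cell", {
  m <- read_pdb(c("CRYST1  200.000  100.000   50.000  90.00  90.00  90.00 P 1",
                  "END"))
  expect_equal(nrow(m$atoms), 0)
  expect_equal(m$cell$b, 100)
  expect_equal(m$spacegroup$symbol, "P 1")
})

test_that("waters and hetero flags are recognised on read", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
    "HETATM    2  O   HOH A 445       3.000   0.000   0.000  1.00 10.00           O",
    "HETATM    3  OAB LG1 A 700       6.000   0.000   0.000  1.00 10.00           O")
  m <- read_pdb(lines)
  expect_equal(m$atoms$is_water, c(FALSE, TRUE, FALSE))
  expect_equal(m$atoms$is_het, c(FALSE, TRUE, TRUE))
})

test_that("malformed ATOM records fail with the offending line number", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CB  GLY A   1       bad..   0.000   0.000  1.00 10.00           C")
  expect_error(read_pdb(lines), "line 2")
})

test_that("element symbols are inferred from the name columns when absent", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00",
    "ATOM      2  NH1 ARG A   2       3.000   0.000   0.000  1.00 10.00",
    "HETATM    3 FE   HEM A 500       9.000   0.000   0.000  1.00 10.00")
  m <- read_pdb(lines)
  expect_equal(m$atoms$element, c("C", "N", "FE"))
})

test_that("altloc policy keeps blank/A and drops the rest by default", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.50 10.00           C",
    "ATOM      2  CA BGLY A   1       0.500   0.000   0.000  0.50 10.00           C",
    "ATOM      3  CB  GLY A   1       1.500   0.000   0.000  1.00 10.00           C")
  expect_equal(nrow(read_pdb(lines)$atoms), 2)
  expect_equal(nrow(read_pdb(lines, altloc_policy = "all")$atoms), 3)
})

test_that("multi-model files become trajectories with arithmetic frame times", {
  m <- synthetic_receptor(n_res = 3)
  sim <- simulate_trajectory(trajectory_sim_spec(
    receptor = m, n_frames = 4, seed = 11,
    modes = list(mode_spec(weight = 1, noise_sigma = 0.1))))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sim$trajectory, tf)
  tr <- read_multimodel_pdb(tf, start_time = 20, stride = 20)
  expect_equal(n_frames(tr), 4)
  expect_equal(tr$times, c(20, 40, 60, 80))
  expect_equal(tr$atoms$name, sim$trajectory$atoms$name)
})

test_that("a roster mismatch between models is reported with the model number", {
  l1 <- "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C"
  l2 <- "ATOM      2  CB  GLY A   1       1.500   0.000   0.000  1.00 10.00           C"
  lines <- c("MODEL     1", l1, l2, "ENDMDL",
             "MODEL     2", l1, "ENDMDL")
  expect_error(read_multimodel_pdb(lines), "model 2")
})

test_that("selection is deterministic, idempotent and supports the CA-range idiom", {
  m <- ca_chain_model(300:620)
  sel <- select_atoms(m, name = "CA", resseq = 325:609)
  expect_length(sel, 285)
  expect_identical(sel, select_atoms(m, name = "CA", resseq = 325:609))
  expect_true(all(diff(sel) > 0))
  # name-list and het/water criteria
  lig <- synthetic_ligand()
  expect_length(select_atoms(lig, name = c("OAA", "OAC")), 2)
  expect_length(select_atoms(lig, het = TRUE, water = FALSE),
                nrow(lig$atoms))
  expect_length(select_atoms(m, chain = "Z"), 0)
})

test_that("tabulated space-group operators are proper and close under composition", {
  for (sym in c("P1", "P212121", "P6522")) {
    sg <- space_group(sym)
    n <- length(sg$ops)
    expect_equal(n, c(P1 = 1, P212121 = 4, P6522 = 12)[[sym]])
    expect_equal(sg$ops[[1]]$R, diag(3))
    expect_equal(sg$ops[[1]]$t, c(0, 0, 0))
    key <- function(R, t) paste(c(round(R), round(t %% 1, 6)), collapse = ",")
    have <- vapply(sg$ops, function(o) key(o$R, o$t), "")
    for (i in seq_len(n)) {
      expect_equal(det(sg$ops[[i]]$R), 1)
      for (j in seq_len(n)) {
        R <- sg$ops[[i]]$R %*% sg$ops[[j]]$R
        t <- as.numeric(sg$ops[[i]]$R %*% sg$ops[[j]]$t) + sg$ops[[i]]$t
        expect_true(key(R, t) %in% have,
                    label = sprintf("%s: op%d o op%d closed", sym, i, j))
      }
    }
  }
  expect_error(space_group("P 41"), "supported")
})

test_that("parsed atom fields agree with the bio3d reader on a shared fixture", {
  skip_if_not_installed("bio3d")
  m <- synthetic_receptor(n_res = 5)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(trimws(ref$atom$elety), read_pdb(tf)$atoms$name)
  expect_equal(ref$atom$resno, read_pdb(tf)$atoms$resseq)
  expect_equal(ref$atom$x, read_pdb(tf)$atoms$x)
})
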