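# Structure parsing and symmetry expansion.

test_that("fixture PDB files round-trip through read_structure", {
  fx <- scenario_pipeline("isolated", seed = 1)
  st <- fx$st
  expect_s3_class(st, "crystal_structure")
  expect_length(st$ops, 1L)               # P1: identity only
  expect_setequal(st$asu_chain_ids, c("A", "B"))
  expect_true(all(st$atoms$chain %in% st$asu_chain_ids))
  expect_true(all(is.finite(cart2frac(
    cbind(st$atoms$x, st$atoms$y, st$atoms$z), st$cell))))
  p2 <- scenario_pipeline("lattice-contact-F-strand", seed = 1)$st
  expect_length(p2$ops, 2L)               # P2: identity + two-fold
})

test_that("hydrogens, waters and lower-occupancy altlocs are dropped", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N  AALA A   1      10.000  10.000  10.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1      11.000  10.000  10.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1      12.000  10.000  10.000  1.00  0.00           C",
    "ATOM      4  H   ALA A   1      13.000  10.000  10.000  1.00  0.00           H",
    "HETATM    5  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "END"), tmp)
  st <- read_structure(tmp)
  expect_equal(nrow(st$atoms), 2L)        # altloc B (higher occupancy) + CA
  expect_equal(st$atoms$alt[st$atoms$elety == "N"], "B")
  expect_false(any(st$atoms$resid == "HOH"))
  expect_false(any(st$atoms$elesy == "H"))
})

test_that("a missing unit cell raises a no-crystal-context error", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      12.000  10.000  10.000  1.00  0.00           C",
    "END"), tmp)
  expect_error(read_structure(tmp), class = "tcrlattice_no_crystal_context")
  st <- read_structure(tmp, require_cell = FALSE)
  expect_null(st$cell)
})

test_that("an isolated molecule in a huge P1 cell has no nearby mates", {
  fx <- scenario_pipeline("isolated", seed = 1)
  expect_length(fx$mates, 0L)
})

test_that("symmetry expansion equals the brute-force enumeration oracle", {
  for (sc in c("isolated", "lattice-contact-F-strand",
               "upright-2fold-dimer")) {
    fx <- scenario_pipeline(sc, seed = 1)
    oracle <- brute_force_mates(fx$st, radius = 5)
    got <- vapply(fx$mates, `[[`, "", "label")
    expect_setequal(got, oracle$label[oracle$within])
    # every excluded (op, shift) is genuinely farther than the radius
    expect_true(all(oracle$min_distance[!oracle$label %in% got] > 5))
  }
})

test_that("shrinking a P1 cell brings translation mates into range", {
  fx <- scenario_pipeline("isolated", seed = 1)
  st <- fx$st
  # shrink the cell along x until the +x translation copy approaches
  xspan <- max(st$atoms$x) - min(st$atoms$x)
  st$cell[1] <- xspan + 4
  mates <- expand_symmetry(st, 5)
  oracle <- brute_force_mates(st, radius = 5)
  expect_setequal(vapply(mates, `[[`, "", "label"),
                  oracle$label[oracle$within])
  expect_true(any(grepl("op1\\+\\(-?1,0,0\\)", oracle$label[oracle$within])))
})

test_that("mate generation is monotone in the contact radius", {
  fx <- scenario_pipeline("lattice-contact-F-strand", seed = 1)
  small <- vapply(expand_symmetry(fx$st, 5), `[[`, "", "label")
  large <- vapply(expand_symmetry(fx$st, 10), `[[`, "", "label")
  expect_true(all(small %in% large))
})

test_that("expansion is invariant to atom order and chain relabeling", {
  fx <- scenario_pipeline("lattice-contact-F-strand", seed = 1)
  st <- fx$st
  set.seed(5)
  perm <- sample(nrow(st$atoms))
  st2 <- st
  st2$atoms <- st$atoms[perm, ]
  st3 <- st
  st3$atoms$chain <- chartr("AB", "XY", st3$atoms$chain)
  st3$asu_chain_ids <- c("X", "Y")
  base <- expand_symmetry(st, 5)
  for (alt in list(expand_symmetry(st2, 5), expand_symmetry(st3, 5))) {
    expect_equal(vapply(alt, `[[`, "", "label"),
                 vapply(base, `[[`, "", "label"))
    expect_equal(vapply(alt, `[[`, 1, "min_distance"),
                 vapply(base, `[[`, 1, "min_distance"), tolerance = 1e-9)
  }
})

test_that("mate transforms reproduce fractional-space application exactly", {
  fx <- scenario_pipeline("lattice-contact-F-strand", seed = 1)
  st <- fx$st
  m <- fx$mates[[1]]
  op <- st$ops[[m$op_index]]
  frac <- cart2frac(cbind(st$atoms$x, st$atoms$y, st$atoms$z), st$cell)
  expected <- frac2cart(sweep(frac %*% t(op$R), 2,
                              op$t + m$shift, `+`), st$cell)
  expect_equal(cbind(m$atoms$x, m$atoms$y, m$atoms$z), expected,
               tolerance = 1e-6)
})

test_that("debug mate PDB writer records the mate label and coordinates", {
  fx <- scenario_pipeline("lattice-contact-F-strand", seed = 1)
  out <- tempfile(fileext = ".pdb")
  write_mate_pdb(fx$st, fx$mates[[1]], out)
  lines <- readLines(out)
  expect_true(grepl(fx$mates[[1]]$label, lines[1], fixed = TRUE))
  reread <- read_structure(out, entry_id = "mate")
  expect_equal(nrow(reread$atoms), nrow(fx$mates[[1]]$atoms))
  expect_equal(sort(reread$atoms$x), sort(fx$mates[[1]]$atoms$x),
               tolerance = 1e-3)
})

test_that("canonical mmCIF files parse with cell and space group", {
  tmp <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_TOYC",
    "_cell.length_a           50.000",
    "_cell.length_b           60.000",
    "_cell.length_c           70.000",
    "_cell.angle_alpha        90.00",
    "_cell.angle_beta         90.00",
    "_cell.angle_gamma        90.00",
    "_symmetry.space_group_name_H-M   'P 21 21 21'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 10.000 10.000 10.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.400 10.000 10.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 O O . HOH B 2 . ? 30.000 30.000 30.000 1.00 0.00 ? 201 HOH B O 1",
    "#"), tmp)
  st <- read_structure(tmp, format = "mmcif")
  expect_equal(nrow(st$atoms), 2L)           # water excluded
  expect_equal(st$cell, c(50, 60, 70, 90, 90, 90))
  expect_length(st$ops, 4L)
  expect_setequal(st$atoms$elety, c("N", "CA"))
})
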