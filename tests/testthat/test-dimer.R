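# Two-fold symmetry detection, membrane orientation and interface makeup.

# assemble a two-complex structure from a base complex and a transformed
# copy, with matching manifest
pair_structure <- function(seed = 1, R, center = c(0, 40, 0),
                           shift = c(0, 0, 0)) {
  cpx <- tcrlattice:::make_toy_complex(seed)
  a2 <- tcrlattice:::transform_atoms(cpx$atoms, R, center, shift)
  a2$chain <- c(A = "C", B = "D")[a2$chain]
  atoms <- rbind(cpx$atoms, a2)
  atoms$insert <- ""; atoms$alt <- ""; atoms$o <- 1
  atoms$type <- "ATOM"; atoms$elesy <- substr(atoms$elety, 1, 1)
  st <- structure(list(entry_id = "pairtoy", atoms = atoms,
                       cell = c(500, 500, 500, 90, 90, 90),
                       sg_symbol = "P 1", ops = spacegroup_ops("P 1"),
                       asu_chain_ids = c("A", "B", "C", "D")),
                  class = "crystal_structure")
  mrows <- cpx$manifest
  mrows <- data.frame(entry_id = "pairtoy", complex_index = 1L, mrows,
                      species = "toy", stringsAsFactors = FALSE)
  m2 <- mrows; m2$complex_index <- 2L
  m2$chain_id <- c(A = "C", B = "D")[m2$chain_id]
  list(st = st, manifest = rbind(mrows, m2))
}

annotated_instances <- function(ps) {
  ann <- annotate(ps$st, ps$manifest)
  list(ann = ann,
       a1 = tcrlattice:::instance_atoms(ps$st, ann, 1L),
       a2 = tcrlattice:::instance_atoms(ps$st, ann, 2L))
}

test_that("an exact 180-degree copy is recognized with angle and screw ~0", {
  ps <- pair_structure(R = tcrlattice:::rot_about(c(0, 0, 1), 180))
  ai <- annotated_instances(ps)
  sym <- assess_symmetry(ai$a1, ai$a2, ai$ann, 1L, 2L)
  expect_true(sym$is_symmetric)
  expect_lt(abs(sym$rotation_angle - 180), 1e-3)
  expect_lt(sym$screw_translation, 1e-3)
  expect_lt(sym$rmsd, 1e-6)
})

test_that("a 90-degree copy is not symmetric and reports the true angle", {
  ps <- pair_structure(R = tcrlattice:::rot_about(c(0, 0, 1), 90))
  ai <- annotated_instances(ps)
  sym <- assess_symmetry(ai$a1, ai$a2, ai$ann, 1L, 2L)
  expect_false(sym$is_symmetric)
  expect_lt(abs(sym$rotation_angle - 90), 1e-3)
})

test_that("a screw-displaced two-fold is rejected beyond the threshold", {
  # 180-degree rotation about z plus 8 A translation along z: a screw axis
  ps <- pair_structure(R = tcrlattice:::rot_about(c(0, 0, 1), 180),
                       shift = c(0, 0, 8))
  ai <- annotated_instances(ps)
  sym <- assess_symmetry(ai$a1, ai$a2, ai$ann, 1L, 2L)
  expect_lt(abs(sym$rotation_angle - 180), 1e-3)
  expect_lt(abs(sym$screw_translation - 8), 1e-3)
  expect_false(sym$is_symmetric)
})

test_that("swapping the two complexes leaves the assessment unchanged", {
  ps <- pair_structure(R = tcrlattice:::rot_about(c(1, 0, 0), 180),
                       center = c(0, 30, 0))
  ai <- annotated_instances(ps)
  s12 <- assess_symmetry(ai$a1, ai$a2, ai$ann, 1L, 2L)
  s21 <- assess_symmetry(ai$a2, ai$a1, ai$ann, 2L, 1L)
  expect_equal(s12$rotation_angle, s21$rotation_angle, tolerance = 1e-6)
  expect_equal(s12$screw_translation, s21$screw_translation,
               tolerance = 1e-6)
  expect_equal(s12$is_symmetric, s21$is_symmetric)
  o12 <- assess_orientation(ai$a1, ai$a2, ai$ann, 1L, 2L, s12)
  o21 <- assess_orientation(ai$a2, ai$a1, ai$ann, 2L, 1L, s21)
  expect_equal(o12$orientation_class, o21$orientation_class)
  expect_equal(o12$two_fold_axis_tilt, o21$two_fold_axis_tilt,
               tolerance = 1e-6)
})

test_that("under-resolved Ca instances raise insufficient-coordinates", {
  ps <- pair_structure(R = tcrlattice:::rot_about(c(0, 0, 1), 180))
  ai <- annotated_instances(ps)
  # drop 30% of instance 1's Ca residues
  ca_res <- unique(ai$a1$resno[ai$a1$domain == "Ca"])
  drop <- ca_res[seq_len(ceiling(0.3 * length(ca_res)))]
  a1 <- ai$a1[!(ai$a1$domain == "Ca" & ai$a1$resno %in% drop), ]
  expect_error(assess_symmetry(a1, ai$a2, ai$ann, 1L, 2L),
               class = "tcrlattice_insufficient_coordinates")
})

test_that("tilt sweep crosses the upright/flat boundary exactly once at 45", {
  # rotation-algebra oracle: for an exact two-fold the sign-aligned mean of
  # the two membrane axes is the bisector, which is parallel to the axis
  # while the per-complex inclination theta stays below 45 degrees and
  # perpendicular beyond it; the class therefore switches exactly once, at
  # the 45-degree family boundary
  membrane <- c(0, 0, -1)
  classes <- character(0)
  for (theta in seq(0, 90, by = 5)) {
    axis <- c(0, sin(theta * pi / 180), cos(theta * pi / 180))
    ps <- pair_structure(R = tcrlattice:::rot_about(axis, 180),
                         center = c(0, 40, 0))
    ai <- annotated_instances(ps)
    sym <- assess_symmetry(ai$a1, ai$a2, ai$ann, 1L, 2L)
    ori <- assess_orientation(ai$a1, ai$a2, ai$ann, 1L, 2L, sym)
    expect_true(sym$is_symmetric)
    expected_tilt <- if (theta <= 45) 0 else 90
    expect_equal(ori$two_fold_axis_tilt, expected_tilt, tolerance = 0.2,
                 info = paste("theta =", theta))
    classes <- c(classes, ori$orientation_class)
  }
  expect_equal(classes[1:10], rep("upright-side-by-side", 10))  # 0..45
  expect_equal(classes[11:19], rep("flat-on-membrane", 9))      # 50..90
  expect_equal(sum(classes[-1] != classes[-length(classes)]), 1L)
})

test_that("orientation is undetermined without a resolved V module", {
  ps <- pair_structure(R = tcrlattice:::rot_about(c(0, 0, 1), 180))
  ai <- annotated_instances(ps)
  sym <- assess_symmetry(ai$a1, ai$a2, ai$ann, 1L, 2L)
  a1_cv <- ai$a1[!(ai$a1$domain %in% c("Va", "Vb")), ]
  ori <- assess_orientation(a1_cv, ai$a2, ai$ann, 1L, 2L, sym)
  expect_equal(ori$orientation_class, "undetermined")
})

test_that("interface fractions are normalized and F-dominant when planted", {
  fx <- scenario_pipeline("upright-2fold-dimer", seed = 1)
  caca <- fx$rec[fx$rec$partner_domain == "Ca", ]
  ifc <- interface_elements(caca, symmetric = TRUE, upright = TRUE)
  expect_equal(sum(ifc$fractions), 1, tolerance = 1e-9)
  expect_gte(ifc$fractions[["F"]], 0.9)
  expect_true(ifc$model2_consistent)
  # same interface under a flat orientation can never satisfy the model
  expect_false(interface_elements(caca, symmetric = TRUE,
                                  upright = FALSE)$model2_consistent)
})

test_that("orientation classification survives global rigid motion", {
  fx <- scenario_pipeline("flat-2fold-dimer", seed = 1)
  st2 <- fx$st
  R <- tcrlattice:::rot_about(c(1, 2, 3), 37)
  xyz <- cbind(st2$atoms$x, st2$atoms$y, st2$atoms$z) %*% t(R)
  st2$atoms$x <- xyz[, 1] + 5; st2$atoms$y <- xyz[, 2] - 11
  st2$atoms$z <- xyz[, 3] + 2
  ann2 <- map_strands(annotate(st2, fx$fx$manifest), fx$sm)
  rec2 <- find_ca_contacts(st2, ann2, list())
  asmt2 <- assess_dimers(st2, ann2, rec2, list())
  expect_equal(asmt2$orientation_class, fx$asmt$orientation_class)
  expect_equal(asmt2$two_fold_axis_tilt, fx$asmt$two_fold_axis_tilt,
               tolerance = 1e-3)
  expect_equal(asmt2$rotation_angle, fx$asmt$rotation_angle,
               tolerance = 1e-3)
})
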