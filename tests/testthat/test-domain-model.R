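# Manifest-driven annotation and strand-element transfer.

human_ref <- read_strand_map("human")

test_that("manifest validation enforces the documented invariants", {
  good <- make_seq_structure(human_ref$reference)$manifest
  expect_silent(validate_manifest(good))
  bad <- good
  bad$start <- bad$end + 1L
  expect_error(validate_manifest(bad), "start > end")
  dup <- rbind(good, good)          # overlapping Ca segments on one chain
  expect_error(validate_manifest(dup), "overlap")
  nocols <- good[, -1]
  expect_error(validate_manifest(nocols), "lacks columns")
})

test_that("a single all-covering segment labels every residue", {
  ms <- make_seq_structure(human_ref$reference)
  ann <- annotate(ms$structure, ms$manifest)
  expect_true(all(ann$domain == "Ca"))
  expect_true(all(ann$complex_index == 1L))
  expect_true(all(ann$molecule == "TCRa"))
})

test_that("annotation is idempotent and independent of manifest row order", {
  fx <- scenario_pipeline("upright-2fold-dimer", seed = 1)
  m <- fx$fx$manifest
  ann1 <- annotate(fx$st, m)
  set.seed(3)
  ann2 <- annotate(fx$st, m[sample(nrow(m)), ])
  expect_equal(as.data.frame(ann1), as.data.frame(ann2))
  # four distinct complexes never arise from two; two chains per complex
  expect_setequal(unique(stats::na.omit(ann1$complex_index)), 1:2)
})

test_that("residues outside declared segments become 'other'", {
  ms <- make_seq_structure(human_ref$reference)
  ms$manifest$end <- ms$manifest$end - 10L   # leave a tail uncovered
  ann <- annotate(ms$structure, ms$manifest)
  expect_equal(sum(ann$domain == "other"), 10L)
})

test_that("declaring a chain absent from the structure is a hard error", {
  ms <- make_seq_structure(human_ref$reference)
  ms$manifest$chain_id <- "Z"
  expect_error(annotate(ms$structure, ms$manifest), "absent")
})

test_that("a zero-residue segment warns and is recorded", {
  ms <- make_seq_structure(human_ref$reference)
  extra <- ms$manifest
  extra$domain_name <- "Va"
  extra$start <- 1L; extra$end <- 50L      # no residues numbered below 108
  m <- rbind(ms$manifest, extra)
  expect_warning(ann <- annotate(ms$structure, m), "zero resolved")
  expect_length(attr(ann, "empty_segments"), 1L)
})

test_that("the reference aligned to itself reproduces the strand tiling", {
  ms <- make_seq_structure(human_ref$reference)
  ann <- map_strands(annotate(ms$structure, ms$manifest), human_ref)
  expected <- tcrlattice:::element_at_offset(
    human_ref, seq_len(nchar(human_ref$reference)))
  expect_equal(ann$element[order(ann$resno)], expected)
})

test_that("point substitutions outside element boundaries keep the mapping", {
  # oracle: a gap-free alignment of two same-length sequences maps position
  # i to position i, so elements must be unchanged
  seq <- human_ref$reference
  substr(seq, 16, 16) <- "G"   # AB loop
  substr(seq, 41, 41) <- "G"   # CD loop
  ms <- make_seq_structure(seq)
  ann <- map_strands(annotate(ms$structure, ms$manifest), human_ref)
  expected <- tcrlattice:::element_at_offset(
    human_ref, seq_len(nchar(human_ref$reference)))
  expect_equal(ann$element[order(ann$resno)], expected)
})

test_that("up to 5% substitutions never change the element assignment", {
  set.seed(42)
  n <- nchar(human_ref$reference)
  loop_offsets <- which(tcrlattice:::element_at_offset(human_ref,
                                                       seq_len(n)) %in%
                          c("AB", "BC", "CD", "DE", "EF", "FG"))
  for (rep in 1:5) {
    seq <- human_ref$reference
    k <- max(1L, floor(0.05 * n))
    at <- sample(loop_offsets, k)
    for (p in at) substr(seq, p, p) <- sample(c("G", "A", "Q"), 1)
    ms <- make_seq_structure(seq)
    ann <- map_strands(annotate(ms$structure, ms$manifest), human_ref)
    expect_equal(ann$element[order(ann$resno)],
                 tcrlattice:::element_at_offset(human_ref, seq_len(n)))
  }
})

test_that("low-identity alignment warns and leaves elements empty", {
  ms <- make_seq_structure(paste(rep("G", 95), collapse = ""))
  expect_warning(
    ann <- map_strands(annotate(ms$structure, ms$manifest), human_ref),
    "strand-transfer-unreliable")
  expect_true(all(ann$element == ""))
})

test_that("residue 186 of the human reference maps onto the F strand", {
  ms <- make_seq_structure(human_ref$reference)  # author numbering from 108
  ann <- map_strands(annotate(ms$structure, ms$manifest), human_ref)
  expect_equal(ann$element[ann$resno == 186], "F")
  expect_equal(ann$element[ann$resno == 141], "C")
  expect_equal(ann$element[ann$resno == 175], "EF")
})

test_that("bundled strand maps tile their references and contain C and F", {
  for (sp in c("human", "mouse")) {
    sm <- read_strand_map(sp)
    expect_equal(sm$elements$start[1], 1L)
    expect_equal(sm$elements$end[nrow(sm$elements)],
                 nchar(sm$reference))
    expect_true(all(c("C", "F") %in% sm$elements$element))
  }
})
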