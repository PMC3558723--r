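# Independent oracles and shared fixture plumbing for the test suite.

# ---- brute-force symmetry-mate oracle -------------------------------------
# enumerate every operator x integer shift in a fixed window and measure the
# exact minimum inter-atom distance with a plain distance matrix
brute_force_mates <- function(structure, radius, window = 2L) {
  cell <- structure$cell
  xyz <- cbind(structure$atoms$x, structure$atoms$y, structure$atoms$z)
  frac <- cart2frac(xyz, cell)
  M <- cell_orth_matrix(cell)
  out <- list()
  for (i in seq_along(structure$ops)) {
    op <- structure$ops[[i]]
    for (u in -window:window) for (v in -window:window)
      for (w in -window:window) {
        ident <- all(op$R == diag(3)) && all(abs(op$t) < 1e-9)
        if (ident && u == 0 && v == 0 && w == 0) next
        tf <- sweep(frac %*% t(op$R), 2, op$t + c(u, v, w), `+`)
        txyz <- t(M %*% t(tf))
        d2 <- outer(rowSums(xyz^2), rowSums(txyz^2), `+`) -
          2 * (xyz %*% t(txyz))
        dmin <- sqrt(max(min(d2), 0))
        out[[length(out) + 1L]] <- data.frame(
          label = sprintf("op%d+(%d,%d,%d)", i, u, v, w),
          min_distance = dmin, within = dmin <= radius)
      }
  }
  do.call(rbind, out)
}

# ---- all-pairs contact oracle ---------------------------------------------
# plain full distance-matrix contact enumeration, no spatial prefiltering
oracle_ca_contacts <- function(structure, annotation, mates, cutoff) {
  std <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL", "MSE")
  ann_key <- paste(annotation$chain, annotation$resno, annotation$insert)
  decorate <- function(atoms) {
    idx <- match(paste(atoms$chain, atoms$resno, atoms$insert), ann_key)
    atoms$cx <- annotation$complex_index[idx]
    atoms$domain <- annotation$domain[idx]
    atoms
  }
  asu <- decorate(structure$atoms)
  asu <- asu[asu$resid %in% std, ]
  pairs <- character(0)
  for (cx in unique(asu$cx[asu$domain %in% "Ca" & !is.na(asu$cx)])) {
    ca <- asu[asu$domain %in% "Ca" & !is.na(asu$cx) & asu$cx == cx, ]
    targets <- list(list(lab = "ASU",
                         at = asu[is.na(asu$cx) | asu$cx != cx, ]))
    for (m in mates) {
      at <- decorate(m$atoms)
      targets[[length(targets) + 1L]] <-
        list(lab = m$label, at = at[at$resid %in% std, ])
    }
    for (tg in targets) {
      if (nrow(tg$at) == 0L) next
      A <- cbind(ca$x, ca$y, ca$z)
      B <- cbind(tg$at$x, tg$at$y, tg$at$z)
      d <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), `+`) -
                       2 * (A %*% t(B)), 0))
      hit <- which(d <= cutoff, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      pairs <- c(pairs, sprintf("%s|%d|%s|%s|%s|%d|%s", cx,
                                ca$resno[hit[, 1]], ca$elety[hit[, 1]],
                                tg$lab, tg$at$chain[hit[, 2]],
                                tg$at$resno[hit[, 2]],
                                tg$at$elety[hit[, 2]]))
    }
  }
  sort(pairs)
}

contact_keys <- function(records) {
  sort(sprintf("%s|%d|%s|%s|%s|%d|%s", records$ca_complex_index,
               records$ca_resno, records$ca_atom, records$partner_label,
               records$partner_chain, records$partner_resno,
               records$partner_atom))
}

# ---- regex sequon oracle ---------------------------------------------------
regex_sequons <- function(sequence) {
  m <- gregexpr("N(?=[^P][ST])", toupper(sequence), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# ---- cached scenario pipeline ----------------------------------------------
.pipeline_cache <- new.env(parent = emptyenv())

scenario_pipeline <- function(scenario, seed = 1, config = survey_config()) {
  key <- paste(scenario, seed, digest_config(config))
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  dir <- tempfile("fx")
  fx <- make_crystal_scenario(scenario, seed = seed, dir = dir)
  st <- read_structure(fx$paths$structure, entry_id = fx$entry_id)
  ann <- annotate(st, fx$manifest)
  sm <- read_strand_map(map_path = fx$paths$strand_map,
                        reference_path = fx$paths$reference)
  ann <- map_strands(ann, sm)
  mates <- expand_symmetry(st, config$mate_radius)
  rec <- find_ca_contacts(st, ann, mates,
                          contact_cutoff = config$contact_cutoff)
  asmt <- assess_dimers(st, ann, rec, mates, config)
  summ <- summarize_ca_contacts(rec, ann, asmt)
  res <- list(fx = fx, st = st, ann = ann, sm = sm, mates = mates,
              rec = rec, asmt = asmt, summ = summ, dir = dir)
  .pipeline_cache[[key]] <- res
  res
}

digest_config <- function(config) paste(unlist(config), collapse = ",")

# ---- sequence-only structure builder ---------------------------------------
# CA-only chain carrying an arbitrary amino-acid sequence, for alignment and
# sequon-mapping tests without any crystal packing
make_seq_structure <- function(seq, author_start = 108L,
                               entry_id = "seqtoy", species = "human") {
  aa1 <- strsplit(seq, "")[[1]]
  aa3 <- vapply(aa1, function(a) {
    r <- bio3d::aa123(a)
    if (is.na(r)) "UNK" else r
  }, "")
  n <- length(aa1)
  atoms <- data.frame(elety = "CA", alt = "", resid = aa3, chain = "A",
                      resno = seq_len(n) + author_start - 1L, insert = "",
                      x = seq_len(n) * 3.8, y = 0, z = 0, o = 1,
                      type = "ATOM", elesy = "C", stringsAsFactors = FALSE)
  st <- structure(list(entry_id = entry_id, atoms = atoms,
                       cell = c(500, 500, 500, 90, 90, 90),
                       sg_symbol = "P 1",
                       ops = spacegroup_ops("P 1"),
                       asu_chain_ids = "A"),
                  class = "crystal_structure")
  manifest <- data.frame(entry_id = entry_id, complex_index = 1L,
                         chain_id = "A", molecule = "TCRa",
                         domain_name = "Ca", start = author_start,
                         end = author_start + n - 1L, species = species,
                         stringsAsFactors = FALSE)
  list(structure = st, manifest = manifest)
}
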