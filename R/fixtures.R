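# Synthetic fixtures: toy pseudo-Ig domains, planted crystal scenarios and
# sequon-bearing sequences with exactly known ground truth. These are
# first-class generators (not test helpers): every pipeline stage can be
# exercised against planted truth without any deposited structure.

TOY_ELEMENT_ORDER <- c("A", "AB", "B", "BC", "C", "CD", "D", "DE",
                       "E", "EF", "F", "FG", "G")
TOY_STRANDS <- c("A", "B", "C", "D", "E", "F", "G")

# chain-order element lengths tiling exactly n residues
toy_element_lengths <- function(n) {
  w <- ifelse(TOY_ELEMENT_ORDER %in% TOY_STRANDS, 2, 1)
  len <- pmax(1L, floor(n * w / sum(w)))
  i <- 1L
  while (sum(len) < n) {   # pad strands round-robin
    idx <- which(TOY_ELEMENT_ORDER %in% TOY_STRANDS)[(i - 1L) %% 7L + 1L]
    len[idx] <- len[idx] + 1L
    i <- i + 1L
  }
  while (sum(len) > n) {
    idx <- which(len > 1L)
    len[idx[length(idx)]] <- len[idx[length(idx)]] - 1L
  }
  stats::setNames(len, TOY_ELEMENT_ORDER)
}

#' Build a rigid pseudo-immunoglobulin toy domain
#'
#' Generates a backbone-only (N, CA, C, O) point cloud arranged as two
#' stacked four-strand beta sheets with A-G strand and loop labels, plus the
#' matching strand map. The geometry is idealized, not physical: strands are
#' straight rods, sheet 2 (strands C, F, G) forms the "outer face" with
#' normal +y, and the F strand can be pushed outward so that planted
#' face-to-face crystal contacts are carried by F-strand atoms only.
#'
#' @param n_residues number of residues (>= 20).
#' @param seed integer; output is deterministic given the seed.
#' @param f_protrusion Angstrom by which the F strand protrudes beyond the
#'   outer-face plane (default 0).
#' @return list of class `toy_domain`: `atoms` (data frame: elety, resid,
#'   resno, element, x, y, z), `strand_map` (element, start, end tiling
#'   1..n_residues), `face_normal` (outer-face unit vector), `n_residues`,
#'   `seed`.
#' @export
make_toy_domain <- function(n_residues = 48, seed = 1, f_protrusion = 0) {
  stopifnot(n_residues >= 20)
  set.seed(as.integer(seed))
  len <- toy_element_lengths(n_residues)
  bounds <- cumsum(len)
  starts <- c(1L, utils::head(bounds, -1) + 1L)
  element_of <- rep(TOY_ELEMENT_ORDER, len)

  slot_x <- c(A = 0, B = 4.8, E = 9.6, D = 14.4, G = 2.4, F = 7.2, C = 12.0)
  slot_y <- c(A = 0, B = 0, E = 0, D = 0, G = 9, F = 9, C = 9)
  dir <- c(A = 1, B = -1, C = 1, D = -1, E = 1, F = -1, G = 1)

  ca <- matrix(NA_real_, n_residues, 3)
  for (k in seq_along(TOY_ELEMENT_ORDER)) {
    el <- TOY_ELEMENT_ORDER[k]
    idx <- starts[k]:bounds[k]
    L <- len[k]
    if (el %in% TOY_STRANDS) {
      z <- dir[el] * (seq_len(L) - (L + 1) / 2) * 3.8
      y <- slot_y[el] + if (el == "F") f_protrusion else 0
      ca[idx, ] <- cbind(rep(slot_x[el], L), rep(y, L), z)
    }
  }
  # loops: linear interpolation between flanking strand ends, bulged in z
  for (k in seq_along(TOY_ELEMENT_ORDER)) {
    el <- TOY_ELEMENT_ORDER[k]
    if (el %in% TOY_STRANDS) next
    idx <- starts[k]:bounds[k]
    L <- len[k]
    p1 <- ca[starts[k] - 1L, ]
    p2 <- ca[bounds[k] + 1L, ]
    tt <- seq_len(L) / (L + 1)
    base <- outer(1 - tt, p1) + outer(tt, p2)
    zsgn <- if (p1[3] + p2[3] >= 0) 1 else -1
    base[, 3] <- base[, 3] + zsgn * 3.0 * sin(pi * tt)
    # loops dip below the sheet faces so that planted face-to-face crystal
    # contacts are carried by strand atoms only
    base[, 2] <- min(p1[2], p2[2]) - 1.0
    ca[idx, ] <- base
  }

  offs <- rbind(N = c(-1.2, 0.20, -0.9),
                CA = c(0, 0, 0),
                C = c(1.2, 0.25, 0.8),
                O = c(1.4, 0.80, 1.4))
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    data.frame(elety = rownames(offs), resid = "ALA", resno = i,
               element = element_of[i],
               x = ca[i, 1] + offs[, 1], y = ca[i, 2] + offs[, 2],
               z = ca[i, 3] + offs[, 3], stringsAsFactors = FALSE)
  }))
  jit <- matrix(stats::runif(nrow(atoms) * 3, -0.03, 0.03), ncol = 3)
  atoms$x <- atoms$x + jit[, 1]
  atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]
  rownames(atoms) <- NULL

  out <- list(atoms = atoms,
              strand_map = data.frame(element = TOY_ELEMENT_ORDER,
                                      start = starts, end = bounds,
                                      stringsAsFactors = FALSE),
              face_normal = c(0, 1, 0),
              n_residues = n_residues, seed = seed)
  class(out) <- "toy_domain"
  out
}

TOY_CA_AUTHOR_START <- 118L

# one toy TCR-like complex: Va/Ca on the alpha chain, Vb/Cb on the beta
# chain, V module above C module so the membrane axis is -z, Ca outer face
# normal +y.
make_toy_complex <- function(seed, n_res = 48, chains = c("A", "B"),
                             f_protrusion = 2.5) {
  slots <- list(Va = list(chain = chains[1], origin = c(0, 0, 34),
                          resno0 = 0L),
                Ca = list(chain = chains[1], origin = c(0, 0, 0),
                          resno0 = TOY_CA_AUTHOR_START - 1L),
                Vb = list(chain = chains[2], origin = c(22, 0, 34),
                          resno0 = 0L),
                Cb = list(chain = chains[2], origin = c(22, 0, 0),
                          resno0 = TOY_CA_AUTHOR_START - 1L))
  atoms <- NULL
  strand_map <- NULL
  for (k in seq_along(slots)) {
    dom <- make_toy_domain(n_res, seed = seed * 10 + k,
                           f_protrusion = f_protrusion)
    a <- dom$atoms
    ctr <- colMeans(cbind(a$x, a$y, a$z))
    a$x <- a$x - ctr[1] + slots[[k]]$origin[1]
    a$y <- a$y - ctr[2] + slots[[k]]$origin[2]
    a$z <- a$z - ctr[3] + slots[[k]]$origin[3]
    a$chain <- slots[[k]]$chain
    a$resno <- a$resno + slots[[k]]$resno0
    a$domain <- names(slots)[k]
    atoms <- rbind(atoms, a)
    if (names(slots)[k] == "Ca") strand_map <- dom$strand_map
  }
  molecule <- c(Va = "TCRa", Ca = "TCRa", Vb = "TCRb", Cb = "TCRb")
  manifest <- do.call(rbind, lapply(names(slots), function(d) {
    data.frame(chain_id = slots[[d]]$chain, molecule = molecule[[d]],
               domain_name = d,
               start = 1L + slots[[d]]$resno0,
               end = n_res + slots[[d]]$resno0,
               stringsAsFactors = FALSE)
  }))
  list(atoms = atoms, manifest = manifest, strand_map = strand_map,
       n_res = n_res,
       membrane_axis = c(0, 0, -1), face_normal = c(0, 1, 0))
}

rot_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_atoms <- function(atoms, R, center = c(0, 0, 0),
                            shift = c(0, 0, 0)) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center + shift, `+`)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

min_set_distance <- function(a, b) {
  A <- cbind(a$x, a$y, a$z)
  B <- cbind(b$x, b$y, b$z)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * (A %*% t(B))
  sqrt(max(min(d2), 0))
}

write_fixture_pdb <- function(atoms, cell, sg_symbol, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(cbind(atoms$x, atoms$y, atoms$z))),
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = atoms$chain,
                   o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)),
                   elesy = substr(atoms$elety, 1, 1))
  body <- readLines(tmp, warn = FALSE)
  writeLines(c(cryst1_line(cell, sg_symbol), body), path)
  invisible(path)
}

FIXTURE_SCENARIOS <- c("isolated", "lattice-contact-F-strand",
                       "upright-2fold-dimer", "flat-2fold-dimer",
                       "asymmetric-touch")

#' Generate a planted crystal-packing scenario
#'
#' Writes a small synthetic crystal (PDB with CRYST1), its annotation
#' manifest, a matching toy strand map/reference, and a JSON ground-truth
#' record. Scenarios:
#' \describe{
#'   \item{isolated}{one complex, P1 cell three molecular diameters wide:
#'     no inter-molecular contact exists.}
#'   \item{lattice-contact-F-strand}{one complex in P2 placed with its Ca
#'     outer face toward the crystallographic two-fold axis: the symmetry
#'     mate touches through F-strand atoms only, forming an upright
#'     two-fold Ca-Ca pair.}
#'   \item{upright-2fold-dimer}{two complexes in the asymmetric unit (P1)
#'     related by an exact 180 degree rotation about an axis parallel to
#'     the membrane axis, F faces touching: the geometry the putative
#'     C/F-strand dimerization model predicts.}
#'   \item{flat-2fold-dimer}{exact two-fold perpendicular to the membrane
#'     axes: a symmetric dimer lying flat, membrane axes antiparallel.}
#'   \item{asymmetric-touch}{two complexes related by a 90 degree rotation,
#'     touching without any two-fold symmetry.}
#' }
#'
#' @param scenario scenario name, see above.
#' @param seed integer seed; outputs are deterministic given the seed.
#' @param dir output directory (created if needed).
#' @param n_res residues per toy domain.
#' @return list with `entry_id`, `paths` (structure, manifest, strand_map,
#'   reference, truth), `manifest` data frame, and `truth` (scenario name,
#'   planted symmetry angle/screw, orientation class, contact elements,
#'   seed).
#' @export
make_crystal_scenario <- function(scenario, seed = 1,
                                  dir = tempfile("fixture"),
                                  n_res = 48) {
  scenario <- match.arg(scenario, FIXTURE_SCENARIOS)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entry_id <- paste0("toy_", gsub("-", "_", scenario))
  cpx1 <- make_toy_complex(seed, n_res = n_res, chains = c("A", "B"))
  contact_target <- 3.9

  place_second <- function(R, center, axis) {
    # rotate a copy, then slide it toward the first Ca along a direction
    # perpendicular to the planted rotation axis (so the relating
    # transformation keeps an exactly zero screw component) until the
    # closest Ca-Ca distance equals contact_target
    ca1 <- cpx1$atoms[cpx1$atoms$domain == "Ca", ]
    ctr <- function(a) colMeans(cbind(a$x, a$y, a$z))
    ca2_0 <- transform_atoms(ca1, R, center)
    dirvec <- ctr(ca1) - ctr(ca2_0)
    axis <- axis / sqrt(sum(axis^2))
    dirvec <- dirvec - axis * sum(dirvec * axis)
    gap <- sqrt(sum(dirvec^2))
    dirvec <- dirvec / gap
    f <- function(t) {
      ca2 <- transform_atoms(ca1, R, center, shift = dirvec * t)
      min_set_distance(ca1, ca2) - contact_target
    }
    t0 <- stats::uniroot(f, c(-60, gap), tol = 1e-9)$root
    atoms2 <- transform_atoms(cpx1$atoms, R, center, shift = dirvec * t0)
    atoms2$chain <- c(A = "C", B = "D")[atoms2$chain]
    atoms2
  }

  truth <- list(scenario_name = scenario, seed = seed,
                expected_contacts = NULL, expected_symmetry = NULL,
                expected_orientation_class = NULL)
  sg <- "P 1"
  atoms <- cpx1$atoms
  two_complexes <- FALSE

  if (scenario == "isolated") {
    truth$expected_orientation_class <- "none"
  } else if (scenario == "upright-2fold-dimer") {
    atoms2 <- place_second(rot_about(c(0, 0, 1), 180), c(0, 24, 0), c(0, 0, 1))
    atoms <- rbind(atoms, atoms2)
    two_complexes <- TRUE
    truth$expected_symmetry <- list(angle = 180, screw = 0)
    truth$expected_orientation_class <- "upright-side-by-side"
    truth$expected_contacts <- list(ca_elements = "F")
    truth$model2_consistent <- TRUE
  } else if (scenario == "flat-2fold-dimer") {
    atoms2 <- place_second(rot_about(c(1, 0, 0), 180), c(0, 24, 0), c(1, 0, 0))
    atoms <- rbind(atoms, atoms2)
    two_complexes <- TRUE
    truth$expected_symmetry <- list(angle = 180, screw = 0)
    truth$expected_orientation_class <- "flat-on-membrane"
    truth$expected_contacts <- list(ca_elements = "F")
    truth$model2_consistent <- FALSE
  } else if (scenario == "asymmetric-touch") {
    atoms2 <- place_second(rot_about(c(0, 0, 1), 90), c(0, 24, 0), c(0, 0, 1))
    atoms <- rbind(atoms, atoms2)
    two_complexes <- TRUE
    truth$expected_symmetry <- list(angle = 90, screw = NA)
    truth$expected_orientation_class <- "asymmetric-touch"
    truth$model2_consistent <- FALSE
  }

  if (scenario == "lattice-contact-F-strand") {
    # membrane axis -> -y (parallel to the P2 two-fold), outer face -> -x
    R <- cbind(c(0, 0, -1), c(-1, 0, 0), c(0, 1, 0))
    atoms <- transform_atoms(cpx1$atoms, R, center = c(0, 0, 0))
    ca <- atoms[atoms$domain == "Ca", ]
    op <- parse_symop("-x,y,-z")
    span <- function(v) max(v) - min(v)
    ext <- c(span(atoms$x), span(atoms$y), span(atoms$z))
    cell_try <- function(d) c(6 * (ext[1] + d), 3 * ext[2] + 40,
                              3 * ext[3] + 40, 90, 90, 90)
    f <- function(d) {
      cad <- ca; cad$x <- cad$x + d
      cell <- cell_try(d)
      frac <- cart2frac(cbind(cad$x, cad$y, cad$z), cell)
      mate <- frac2cart(apply_symop(frac, op), cell)
      mated <- cad; mated$x <- mate[, 1]; mated$y <- mate[, 2]
      mated$z <- mate[, 3]
      min_set_distance(cad, mated) - contact_target
    }
    d0 <- stats::uniroot(f, c(0, 200), tol = 1e-9)$root
    atoms$x <- atoms$x + d0
    cell <- cell_try(d0)
    sg <- "P 1 2 1"
    truth$expected_symmetry <- list(angle = 180, screw = 0)
    truth$expected_orientation_class <- "upright-side-by-side"
    truth$expected_contacts <- list(ca_elements = "F")
    truth$model2_consistent <- TRUE
  } else {
    span <- function(v) max(v) - min(v)
    ext <- c(span(atoms$x), span(atoms$y), span(atoms$z))
    dia <- sqrt(sum(ext^2))
    cell <- c(3 * dia, 3 * dia, 3 * dia, 90, 90, 90)
  }

  paths <- list(structure = file.path(dir, paste0(entry_id, ".pdb")),
                manifest = file.path(dir, paste0(entry_id, "_manifest.tsv")),
                strand_map = file.path(dir, "toy_strandmap.tsv"),
                reference = file.path(dir, "toy_ca_reference.fasta"),
                truth = file.path(dir, paste0(entry_id, "_truth.json")))
  write_fixture_pdb(atoms, cell, sg, paths$structure)

  mrows <- cpx1$manifest
  mrows <- data.frame(entry_id = entry_id, complex_index = 1L, mrows,
                      species = "toy", stringsAsFactors = FALSE)
  if (two_complexes) {
    m2 <- mrows
    m2$complex_index <- 2L
    m2$chain_id <- c(A = "C", B = "D")[m2$chain_id]
    mrows <- rbind(mrows, m2)
  }
  utils::write.table(mrows, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sm <- cpx1$strand_map
  utils::write.table(data.frame(species = "toy", sm), paths$strand_map,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ref <- paste(rep("A", cpx1$n_res), collapse = "")
  writeLines(c(sprintf(">ca_toy author_start=%d", TOY_CA_AUTHOR_START), ref),
             paths$reference)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, null = "null",
                       digits = NA)

  list(entry_id = entry_id, paths = paths, manifest = mrows, truth = truth,
       cell = cell, sg_symbol = sg)
}

#' Generate sequences with planted N-X-S/T sequons
#'
#' Background residues are drawn uniformly from the 17 amino acids other
#' than N, S and T, so no sequon can arise by chance; planted triplets are
#' inserted verbatim.
#'
#' @param n_sequences number of sequences.
#' @param length length of each sequence.
#' @param planted data frame with columns `seq_index`, `position`, `sequon`
#'   (3-letter string). Planted positions on one sequence must be >= 3
#'   apart; overlaps are an error.
#' @param seed integer seed; the FASTA output is byte-identical given the
#'   same arguments and seed.
#' @param fasta optional path; when given, sequences are written as FASTA.
#' @return list with `sequences` (named character), `truth` (data frame of
#'   expected hits: seq_index, position, sequon, efficient) and `fasta`
#'   (path or NA).
#' @export
make_sequences <- function(n_sequences = 1, length = 100,
                           planted = NULL, seed = 1, fasta = NULL) {
  set.seed(as.integer(seed))
  background <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        c("N", "S", "T"))
  seqs <- vapply(seq_len(n_sequences), function(i) {
    paste(sample(background, length, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("synthetic_%03d", seq_len(n_sequences))

  if (!is.null(planted) && nrow(planted) > 0) {
    for (i in unique(planted$seq_index)) {
      pos <- sort(planted$position[planted$seq_index == i])
      if (any(diff(pos) < 3)) stop("planted sequon positions overlap")
    }
    for (r in seq_len(nrow(planted))) {
      i <- planted$seq_index[r]
      p <- planted$position[r]
      sq <- toupper(planted$sequon[r])
      if (nchar(sq) != 3L) stop("planted sequon must have 3 letters")
      if (p < 1 || p + 2 > length) stop("planted position out of range")
      substr(seqs[i], p, p + 2) <- sq
    }
  }

  truth <- do.call(rbind, lapply(seq_len(n_sequences), function(i) {
    m <- gregexpr("N(?=[^P][ST])", seqs[i], perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    sequon <- substr(rep(seqs[i], length(m)), m, m + 2)
    data.frame(seq_index = i, position = as.integer(m), sequon = sequon,
               efficient = sequon_efficient(substr(sequon, 2, 2),
                                            substr(sequon, 3, 3)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(seq_index = integer(), position = integer(),
                        sequon = character(), efficient = logical())
  }

  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
  }
  list(sequences = seqs, truth = truth,
       fasta = if (is.null(fasta)) NA_character_ else fasta)
}
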