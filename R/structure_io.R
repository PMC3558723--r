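# Reading crystal structures and generating symmetry-related neighbours.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a crystal structure
#'
#' Parses a PDB or mmCIF file into a `crystal_structure`: all heavy atoms of
#' model 1 (hydrogens and waters removed, highest-occupancy alternate
#' conformer kept), the unit cell, and the space-group operators resolved
#' from the Hermann-Mauguin symbol on the CRYST1 / `_symmetry` record.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"mmcif"`. `"auto"` decides from
#'   the file extension.
#' @param entry_id accession label; defaults to the file base name.
#' @param require_cell if `TRUE` (default) a missing or invalid unit cell
#'   raises an error of class `tcrlattice_no_crystal_context`. Set to `FALSE`
#'   for sequence-only work on coordinate files without crystal context.
#' @return object of class `crystal_structure`: a list with `entry_id`,
#'   `atoms` (data frame with columns elety, alt, resid, chain, resno,
#'   insert, x, y, z, o, type, elesy), `cell` (length-6 numeric or `NULL`),
#'   `sg_symbol`, `ops` (operator list, identity first) and `asu_chain_ids`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           entry_id = NULL, require_cell = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (is.null(entry_id)) {
    entry_id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                    ignore.case = TRUE)
  }
  if (format == "pdb") {
    parsed <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                              verbose = FALSE)
    header <- read_cryst1(path)
  } else {
    parsed <- withCallingHandlers(
      bio3d::read.cif(path, verbose = FALSE),
      warning = function(w) {
        # silence the parser's advisory notes; real problems still surface
        if (grepl("beta version|helix/sheet", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    header <- read_cif_cell(path)
  }
  atoms <- parsed$atom
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy)) ||
      all(atoms$elesy == "")) {
    atoms$elesy <- bio3d::atom2ele(atoms$elety)
  }
  blank <- is.na(atoms$elesy) | atoms$elesy == ""
  if (any(blank)) atoms$elesy[blank] <- bio3d::atom2ele(atoms$elety[blank])
  atoms$elesy <- toupper(atoms$elesy)
  keep <- !(atoms$elesy %in% c("H", "D")) &
    !(atoms$resid %in% WATER_RESIDUES)
  atoms <- atoms[keep, , drop = FALSE]
  atoms <- keep_best_altloc(atoms)
  atoms <- atoms[, c("elety", "alt", "resid", "chain", "resno", "insert",
                     "x", "y", "z", "o", "type", "elesy")]
  rownames(atoms) <- NULL

  cell <- header$cell
  ops <- NULL
  sg_symbol <- header$sg_symbol
  if (is.null(cell) || any(!is.finite(cell)) || any(cell[1:3] <= 0) ||
      any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
    if (require_cell) {
      stop(structure(class = c("tcrlattice_no_crystal_context",
                               "error", "condition"),
                     list(message = paste0("no crystal context in ", path,
                                           " (missing or invalid unit cell)"),
                          call = sys.call(-1))))
    }
    cell <- NULL
  } else {
    ops <- spacegroup_ops(sg_symbol)
  }

  out <- list(entry_id = entry_id, atoms = atoms, cell = cell,
              sg_symbol = sg_symbol, ops = ops,
              asu_chain_ids = sort(unique(atoms$chain)))
  class(out) <- "crystal_structure"
  out
}

# highest occupancy conformer per atom site; ties broken by altloc order
keep_best_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "|")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

read_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0L) return(list(cell = NULL, sg_symbol = NA_character_))
  cl <- cl[1]
  cell <- suppressWarnings(as.numeric(c(
    substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
    substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54))))
  sg <- trimws(substr(cl, 56, 66))
  list(cell = cell, sg_symbol = sg)
}

read_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(ln) == 0L) return(NA_character_)
    trimws(sub(paste0("^", tag, "\\s+"), "", ln[1]))
  }
  num <- function(tag) suppressWarnings(as.numeric(grab(tag)))
  cell <- c(num("_cell\\.length_a"), num("_cell\\.length_b"),
            num("_cell\\.length_c"), num("_cell\\.angle_alpha"),
            num("_cell\\.angle_beta"), num("_cell\\.angle_gamma"))
  sg <- grab("_symmetry\\.space_group_name_H-M")
  if (is.na(sg)) sg <- grab("_space_group\\.name_H-M_alt")
  if (!is.na(sg)) sg <- gsub("^['\"]|['\"]$", "", sg)
  if (any(is.na(cell))) cell <- NULL
  list(cell = cell, sg_symbol = sg)
}

atom_xyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Enumerate symmetry mates near the asymmetric unit
#'
#' Applies every space-group operator combined with integer lattice
#' translations and returns each copy ("symmetry mate") that approaches the
#' asymmetric unit within `contact_radius`. The identity operator with zero
#' shift (the ASU itself) is never returned. The lattice-shift search window
#' is derived per structure from the unit cell and the molecule's bounding
#' sphere, so large molecules in small cells are still fully covered.
#'
#' @param structure a `crystal_structure`.
#' @param contact_radius Angstrom; a mate is kept if any of its atoms lies
#'   within this distance of any ASU atom. Default 5.0, chosen strictly
#'   larger than the 4.5 A contact cutoff so no contact can be missed.
#' @return list of `symmetry_mate` objects, ordered by (op_index, u, v, w);
#'   each has `op_index`, `shift`, `label` (`"op{i}+({u},{v},{w})"`), `atoms`
#'   (transformed copy of the ASU atom table) and `min_distance`.
#' @export
expand_symmetry <- function(structure, contact_radius = 5.0) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (is.null(structure$cell) || is.null(structure$ops)) {
    stop("structure has no crystal context; cannot expand symmetry")
  }
  if (!is.numeric(contact_radius) || contact_radius <= 0) {
    stop("contact_radius must be > 0")
  }
  cell <- structure$cell
  M <- cell_orth_matrix(cell)
  xyz <- atom_xyz(structure$atoms)
  frac <- cart2frac(xyz, cell)
  center <- colMeans(xyz)
  rad <- sqrt(max(rowSums(sweep(xyz, 2, center)^2)))
  # interplanar spacings give the Cartesian thickness of one cell along each
  # fractional axis; window must cover 2*rad + contact_radius of separation
  Minv <- solve(M)
  d_axis <- 1 / sqrt(rowSums(Minv^2))
  n_axis <- ceiling((2 * rad + contact_radius) / d_axis) + 1L

  mates <- list()
  for (i in seq_along(structure$ops)) {
    op <- structure$ops[[i]]
    tfrac0 <- apply_symop(frac, op)
    tcenter0 <- colMeans(frac2cart(tfrac0, cell))
    base <- round(solve(M, center - tcenter0))
    for (u in (base[1] - n_axis[1]):(base[1] + n_axis[1])) {
      for (v in (base[2] - n_axis[2]):(base[2] + n_axis[2])) {
        for (w in (base[3] - n_axis[3]):(base[3] + n_axis[3])) {
          shift <- c(u, v, w)
          if (is_identity_op(op) && all(shift == 0)) next
          tcenter <- tcenter0 + as.vector(M %*% shift)
          cdist <- sqrt(sum((tcenter - center)^2))
          if (cdist > 2 * rad + contact_radius) next
          txyz <- sweep(frac2cart(tfrac0, cell), 2,
                        as.vector(M %*% shift), `+`)
          dmin <- min_cross_distance(xyz, txyz, contact_radius)
          if (!is.na(dmin) && dmin <= contact_radius) {
            m_atoms <- structure$atoms
            m_atoms$x <- txyz[, 1]; m_atoms$y <- txyz[, 2]
            m_atoms$z <- txyz[, 3]
            mate <- list(op_index = i, shift = as.integer(shift),
                         label = sprintf("op%d+(%d,%d,%d)", i, u, v, w),
                         atoms = m_atoms, min_distance = dmin)
            class(mate) <- "symmetry_mate"
            mates[[length(mates) + 1L]] <- mate
          }
        }
      }
    }
  }
  if (length(mates) == 0L) return(mates)
  ord <- order(vapply(mates, `[[`, 1L, "op_index"),
               vapply(mates, function(m) m$shift[1], 1L),
               vapply(mates, function(m) m$shift[2], 1L),
               vapply(mates, function(m) m$shift[3], 1L))
  mates[ord]
}

# minimum inter-set atom distance, or NA if certainly > cutoff.
# bounding-box prefilter, then chunked exact distances.
min_cross_distance <- function(A, B, cutoff) {
  lo <- pmax(apply(A, 2, min), apply(B, 2, min)) - cutoff
  hi <- pmin(apply(A, 2, max), apply(B, 2, max)) + cutoff
  if (any(lo > hi)) return(NA_real_)
  inbox <- function(X) {
    X[, 1] >= lo[1] - cutoff & X[, 1] <= hi[1] + cutoff &
      X[, 2] >= lo[2] - cutoff & X[, 2] <= hi[2] + cutoff &
      X[, 3] >= lo[3] - cutoff & X[, 3] <= hi[3] + cutoff
  }
  A <- A[inbox(A), , drop = FALSE]
  B <- B[inbox(B), , drop = FALSE]
  if (nrow(A) == 0L || nrow(B) == 0L) return(NA_real_)
  best <- Inf
  chunk <- max(1L, floor(4e6 / nrow(B)))
  for (s in seq(1L, nrow(A), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(A))
    d2 <- outer(rowSums(A[idx, , drop = FALSE]^2), rowSums(B^2), `+`) -
      2 * (A[idx, , drop = FALSE] %*% t(B))
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Write a symmetry mate as a PDB file (debugging aid)
#'
#' @param structure the parent `crystal_structure` (provides the cell).
#' @param mate a `symmetry_mate` from [expand_symmetry()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mate_pdb <- function(structure, mate, path) {
  stopifnot(inherits(mate, "symmetry_mate"))
  a <- mate$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(atom_xyz(a))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = a$insert, alt = a$alt,
                   o = a$o, b = rep(0, nrow(a)), elesy = a$elesy)
  body <- readLines(tmp, warn = FALSE)
  header <- c(sprintf("TITLE     SYMMETRY MATE %s OF %s", mate$label,
                      structure$entry_id),
              cryst1_line(structure$cell, structure$sg_symbol))
  writeLines(c(header, body), path)
  invisible(path)
}

cryst1_line <- function(cell, sg_symbol) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
          cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
          sg_symbol, 1L)
}
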