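# Geometric assessment of candidate Ca-Ca pairs: pseudo-two-fold symmetry,
# orientation relative to the membrane axis, and interface strand
# composition. These are the computations behind accepting or rejecting a
# crystal-packing pair as a physiologically plausible side-by-side dimer.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Least-squares superposition (Kabsch)
#'
#' Rigid transformation `y = R x + t` minimizing the RMSD between matched
#' coordinate sets, with proper rotation enforced.
#'
#' @param X,Y n x 3 matrices of matched coordinates.
#' @return list with `R` (3x3 rotation), `t` (translation), `rmsd`.
#' @export
kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3, nrow(X) >= 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(Xc %*% t(R), 2, cy, `+`)
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fit - Y)^2))))
}

rotation_angle_axis <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  if (ang < 1e-6) {
    return(list(angle = ang, axis = c(NA_real_, NA_real_, NA_real_)))
  }
  e <- eigen(R)
  k <- which.min(abs(e$values - 1))
  axis <- Re(e$vectors[, k])
  list(angle = ang, axis = axis / sqrt(sum(axis^2)))
}

# annotated atoms of one molecule-instance: complex cx of the ASU or of a
# symmetry mate
instance_atoms <- function(structure, annotation, complex_index,
                           mate = NULL) {
  atoms <- if (is.null(mate)) structure$atoms else mate$atoms
  atoms <- annotate_atoms(atoms, annotation)
  atoms[!is.na(atoms$complex_index) &
          atoms$complex_index == complex_index, , drop = FALSE]
}

segment_length <- function(annotation, complex_index, domains) {
  segs <- attr(annotation, "segments")
  segs <- segs[segs$complex_index == complex_index &
                 segs$domain_name %in% domains, , drop = FALSE]
  if (nrow(segs) == 0L) return(0L)
  sum(segs$end - segs$start + 1L)
}

resolved_fraction <- function(atoms, annotation, complex_index, domains) {
  n_seg <- segment_length(annotation, complex_index, domains)
  if (n_seg == 0L) return(0)
  sel <- atoms$domain %in% domains
  n_res <- nrow(unique(atoms[sel, c("chain", "resno", "insert")]))
  n_res / n_seg
}

#' Assess the symmetry of a candidate Ca-Ca pair
#'
#' Superposes the first Ca instance onto the second over matched backbone
#' atoms and decomposes the relating rigid transformation into its rotation
#' angle and screw translation (the component of the translation along the
#' rotation axis). A true two-fold dimer has an angle near 180 degrees and
#' a near-zero screw.
#'
#' @param atoms1,atoms2 annotated atom tables of the two Ca instances (see
#'   the internal pairing in [assess_dimers()]); matched by residue number,
#'   insertion code and backbone atom name.
#' @param annotation the entry's `domain_annotation` (for segment coverage).
#' @param cx1,cx2 complex indices of the two instances.
#' @param min_angle,max_screw symmetry thresholds (degrees, Angstrom);
#'   defaults 160 and 3 tolerate lattice distortion while excluding
#'   glancing asymmetric touches.
#' @param min_coverage minimum fraction of the manifest Ca segment that
#'   must be resolved on both sides (default 0.8).
#' @return list: `is_symmetric`, `rotation_angle`, `screw_translation`,
#'   `two_fold_axis`, `rmsd`.
#' @export
assess_symmetry <- function(atoms1, atoms2, annotation, cx1, cx2,
                            min_angle = 160, max_screw = 3,
                            min_coverage = 0.8) {
  ca1 <- atoms1[atoms1$domain == "Ca" & atoms1$elety %in% BACKBONE_ATOMS, ]
  ca2 <- atoms2[atoms2$domain == "Ca" & atoms2$elety %in% BACKBONE_ATOMS, ]
  f1 <- resolved_fraction(atoms1, annotation, cx1, "Ca")
  f2 <- resolved_fraction(atoms2, annotation, cx2, "Ca")
  if (f1 < min_coverage || f2 < min_coverage) {
    stop(structure(class = c("tcrlattice_insufficient_coordinates",
                             "error", "condition"),
                   list(message = sprintf(
                     "insufficient-coordinates: Ca instances %.0f%% / %.0f%% resolved",
                     100 * f1, 100 * f2), call = sys.call(-1))))
  }
  k1 <- paste(ca1$resno, ca1$insert, ca1$elety, sep = "|")
  k2 <- paste(ca2$resno, ca2$insert, ca2$elety, sep = "|")
  common <- intersect(k1, k2)
  X <- as.matrix(ca1[match(common, k1), c("x", "y", "z")])
  Y <- as.matrix(ca2[match(common, k2), c("x", "y", "z")])
  fit <- kabsch(X, Y)
  ra <- rotation_angle_axis(fit$R)
  screw <- if (any(is.na(ra$axis))) {
    sqrt(sum(fit$t^2))          # pure translation: all of it is screw
  } else {
    abs(sum(ra$axis * fit$t))
  }
  list(is_symmetric = ra$angle >= min_angle && screw <= max_screw,
       rotation_angle = ra$angle, screw_translation = screw,
       two_fold_axis = ra$axis, rmsd = fit$rmsd)
}

unit <- function(v) v / sqrt(sum(v^2))

angle_between <- function(a, b) {
  acos(max(-1, min(1, sum(unit(a) * unit(b))))) * 180 / pi
}

membrane_axis <- function(atoms, annotation, complex_index,
                          min_coverage = 0.5) {
  v_ok <- resolved_fraction(atoms, annotation, complex_index,
                            c("Va", "Vb")) >= min_coverage
  c_ok <- resolved_fraction(atoms, annotation, complex_index,
                            c("Ca", "Cb")) >= min_coverage
  if (!v_ok || !c_ok) return(NULL)
  bb <- atoms[atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  vc <- colMeans(bb[bb$domain %in% c("Va", "Vb"), c("x", "y", "z")])
  cc <- colMeans(bb[bb$domain %in% c("Ca", "Cb"), c("x", "y", "z")])
  unit(cc - vc)
}

#' Classify the membrane orientation of a candidate pair
#'
#' The membrane axis of each complex is the unit vector from its variable
#' module (Va+Vb) backbone centroid to its constant module (Ca+Cb)
#' centroid, pointing toward the cell membrane. For a symmetric pair the
#' two-fold axis tilt against the (sign-aligned) mean membrane axis decides
#' the class: upright side-by-side when the tilt is at most
#' `tilt_boundary`, flat-on-membrane beyond it. Non-symmetric pairs are
#' classified `asymmetric-touch`.
#'
#' @param atoms1,atoms2 annotated atom tables of the two full complexes.
#' @param annotation the entry's `domain_annotation`.
#' @param cx1,cx2 complex indices.
#' @param symmetry result of [assess_symmetry()].
#' @param tilt_boundary degrees, default 45 (midpoint between the ideal
#'   upright and flat geometries).
#' @return list: `orientation_class`, `membrane_axis_1`, `membrane_axis_2`,
#'   `axis_angle` (between the membrane axes), `two_fold_axis_tilt`.
#' @export
assess_orientation <- function(atoms1, atoms2, annotation, cx1, cx2,
                               symmetry, tilt_boundary = 45,
                               min_coverage = 0.5) {
  m1 <- membrane_axis(atoms1, annotation, cx1, min_coverage)
  m2 <- membrane_axis(atoms2, annotation, cx2, min_coverage)
  if (is.null(m1) || is.null(m2)) {
    return(list(orientation_class = "undetermined",
                membrane_axis_1 = rep(NA_real_, 3),
                membrane_axis_2 = rep(NA_real_, 3),
                axis_angle = NA_real_, two_fold_axis_tilt = NA_real_))
  }
  axis_angle <- angle_between(m1, m2)
  if (!isTRUE(symmetry$is_symmetric)) {
    return(list(orientation_class = "asymmetric-touch",
                membrane_axis_1 = m1, membrane_axis_2 = m2,
                axis_angle = axis_angle, two_fold_axis_tilt = NA_real_))
  }
  # sign-align the second axis so antiparallel pairs (flat dimers) keep a
  # well-defined mean direction
  m2s <- if (sum(m1 * m2) < 0) -m2 else m2
  mean_axis <- unit(m1 + m2s)
  tilt <- angle_between(symmetry$two_fold_axis, mean_axis)
  tilt <- min(tilt, 180 - tilt)   # axis direction is sign-ambiguous
  cls <- if (tilt <= tilt_boundary) "upright-side-by-side"
         else "flat-on-membrane"
  list(orientation_class = cls, membrane_axis_1 = m1, membrane_axis_2 = m2,
       axis_angle = axis_angle, two_fold_axis_tilt = tilt)
}

#' Interface composition by Ig element
#'
#' Counts unique Ca-side contact atoms per strand/loop element on each side
#' of a Ca-Ca pair (an atom contributes once however many pairs it joins),
#' averages the two sides, and normalizes.
#'
#' @param pair_records contact records of one Ca-Ca pair.
#' @param min_cf_fraction combined C-strand + F-strand fraction required
#'   for consistency with the C/F-strand dimerization model (default 0.5).
#' @param symmetric,upright logical context from the symmetry and
#'   orientation assessments.
#' @return list: `fractions` (named numeric over elements plus
#'   "unassigned"), `cf_fraction`, `model2_consistent`.
#' @export
interface_elements <- function(pair_records, min_cf_fraction = 0.5,
                               symmetric = FALSE, upright = FALSE) {
  stopifnot(nrow(pair_records) >= 1L)
  side1 <- unique(pair_records[, c("ca_chain", "ca_resno", "ca_insert",
                                   "ca_atom", "ca_element")])
  side2 <- unique(pair_records[, c("partner_chain", "partner_resno",
                                   "partner_insert", "partner_atom",
                                   "partner_element")])
  frac <- function(el) {
    tab <- table(el)
    as.numeric(tab) / sum(tab) -> f
    stats::setNames(f, names(tab))
  }
  f1 <- frac(side1$ca_element)
  f2 <- frac(side2$partner_element)
  els <- union(names(f1), names(f2))
  avg <- (ifelse(is.na(f1[els]), 0, f1[els]) +
            ifelse(is.na(f2[els]), 0, f2[els])) / 2
  avg <- stats::setNames(as.numeric(avg) / sum(avg), els)
  cf <- sum(avg[names(avg) %in% c("C", "F")])
  list(fractions = avg[order(-avg)], cf_fraction = cf,
       model2_consistent = isTRUE(symmetric) && isTRUE(upright) &&
         cf >= min_cf_fraction)
}

#' Assess every candidate Ca-Ca pair of an entry
#'
#' Identifies all molecule-instance pairs connected by at least one Ca-Ca
#' contact record and runs the symmetry, orientation and interface
#' assessments on each.
#'
#' @param structure a `crystal_structure`.
#' @param annotation its `domain_annotation` (after [map_strands()]).
#' @param records contact records from [find_ca_contacts()].
#' @param mates the symmetry mates used for contact detection.
#' @param config a [survey_config()] list of thresholds.
#' @return data frame, one row per candidate pair, with symmetry,
#'   orientation and interface fields; zero rows when no Ca-Ca contact
#'   exists.
#' @export
assess_dimers <- function(structure, annotation, records, mates,
                          config = survey_config()) {
  empty <- data.frame(entry_id = character(), pair_label = character(),
                      complex_index_1 = integer(),
                      complex_index_2 = integer(),
                      mate_label = character(), is_symmetric = logical(),
                      rotation_angle = numeric(),
                      screw_translation = numeric(),
                      axis_angle = numeric(), two_fold_axis_tilt = numeric(),
                      orientation_class = character(),
                      interface_elements = character(),
                      cf_fraction = numeric(),
                      model2_consistent = logical(), n_contact_atoms = integer(),
                      note = character(), stringsAsFactors = FALSE)
  caca <- records[records$partner_domain %in% "Ca", , drop = FALSE]
  if (nrow(caca) == 0L) return(empty)
  mate_by_label <- stats::setNames(mates, vapply(mates, `[[`, "", "label"))
  # within-ASU pairs appear in both directions; keep the canonical one
  mirrored <- caca$partner_label == "ASU" &
    caca$partner_complex_index < caca$ca_complex_index
  caca <- caca[!mirrored, , drop = FALSE]
  if (nrow(caca) == 0L) return(empty)
  pair_key <- paste(caca$ca_complex_index, caca$partner_label,
                    caca$partner_complex_index, sep = "||")
  rows <- lapply(unique(pair_key), function(pk) {
    rec <- caca[pair_key == pk, , drop = FALSE]
    cx1 <- rec$ca_complex_index[1]
    cx2 <- rec$partner_complex_index[1]
    lab <- rec$partner_label[1]
    mate <- if (lab == "ASU") NULL else mate_by_label[[lab]]
    atoms1 <- instance_atoms(structure, annotation, cx1)
    atoms2 <- instance_atoms(structure, annotation, cx2, mate)
    pair_label <- sprintf("cx%s|%s:cx%s", cx1, lab, cx2)
    sym <- tryCatch(
      assess_symmetry(atoms1, atoms2, annotation, cx1, cx2,
                      min_angle = config$symmetry_min_angle,
                      max_screw = config$symmetry_max_screw,
                      min_coverage = config$symmetry_min_coverage),
      tcrlattice_insufficient_coordinates = function(e) e)
    if (inherits(sym, "condition")) {
      out <- empty[0, ]
      out[1, c("entry_id", "pair_label", "mate_label", "note")] <-
        c(structure$entry_id, pair_label, lab, conditionMessage(sym))
      out$complex_index_1 <- cx1; out$complex_index_2 <- cx2
      return(out)
    }
    ori <- assess_orientation(atoms1, atoms2, annotation, cx1, cx2, sym,
                              tilt_boundary = config$orientation_tilt_boundary,
                              min_coverage = config$orientation_min_coverage)
    ifc <- interface_elements(
      rec, min_cf_fraction = config$model2_min_cf_fraction,
      symmetric = sym$is_symmetric,
      upright = ori$orientation_class == "upright-side-by-side")
    n_atoms <- nrow(unique(rec[, c("ca_chain", "ca_resno", "ca_insert",
                                   "ca_atom")]))
    data.frame(entry_id = structure$entry_id, pair_label = pair_label,
               complex_index_1 = cx1, complex_index_2 = cx2,
               mate_label = lab, is_symmetric = sym$is_symmetric,
               rotation_angle = round(sym$rotation_angle, 4),
               screw_translation = round(sym$screw_translation, 4),
               axis_angle = round(ori$axis_angle, 4),
               two_fold_axis_tilt = round(ori$two_fold_axis_tilt, 4),
               orientation_class = ori$orientation_class,
               interface_elements = paste(
                 sprintf("%s=%.3f", names(ifc$fractions), ifc$fractions),
                 collapse = ";"),
               cf_fraction = ifc$cf_fraction,
               model2_consistent = ifc$model2_consistent,
               n_contact_atoms = n_atoms, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
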