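# Inter-molecular heavy-atom contacts of the Ca domain, within the
# asymmetric unit and to symmetry mates, with Table-style partner
# classification.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE")

# instance key: a molecule copy is identified by its complex index (or its
# chain, for unassigned chains) plus the symmetry-mate label
instance_key <- function(complex_index, chain, mate_label) {
  cx <- ifelse(is.na(complex_index), paste0("chain:", chain),
               paste0("cx:", complex_index))
  paste(mate_label, cx, sep = "/")
}

annotate_atoms <- function(atoms, annotation) {
  key_a <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  key_r <- paste(annotation$chain, annotation$resno, annotation$insert,
                 sep = "|")
  idx <- match(key_a, key_r)
  atoms$complex_index <- annotation$complex_index[idx]
  atoms$molecule <- annotation$molecule[idx]
  atoms$domain <- annotation$domain[idx]
  atoms$element <- annotation$element[idx]
  atoms
}

# all cross pairs within cutoff between two atom tables
cross_pairs <- function(A, B, cutoff) {
  Ax <- cbind(A$x, A$y, A$z)
  Bx <- cbind(B$x, B$y, B$z)
  lo <- pmax(apply(Ax, 2, min), apply(Bx, 2, min)) - cutoff
  hi <- pmin(apply(Ax, 2, max), apply(Bx, 2, max)) + cutoff
  if (any(lo > hi)) return(NULL)
  ai <- which(Ax[, 1] >= lo[1] & Ax[, 1] <= hi[1] &
                Ax[, 2] >= lo[2] & Ax[, 2] <= hi[2] &
                Ax[, 3] >= lo[3] & Ax[, 3] <= hi[3])
  bi <- which(Bx[, 1] >= lo[1] & Bx[, 1] <= hi[1] &
                Bx[, 2] >= lo[2] & Bx[, 2] <= hi[2] &
                Bx[, 3] >= lo[3] & Bx[, 3] <= hi[3])
  if (length(ai) == 0L || length(bi) == 0L) return(NULL)
  d2 <- outer(rowSums(Ax[ai, , drop = FALSE]^2),
              rowSums(Bx[bi, , drop = FALSE]^2), `+`) -
    2 * (Ax[ai, , drop = FALSE] %*% t(Bx[bi, , drop = FALSE]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  data.frame(i = ai[hit[, 1]], j = bi[hit[, 2]],
             distance = sqrt(pmax(d2[hit], 0)))
}

#' Detect inter-molecular contacts of the Ca domain
#'
#' One record per qualifying heavy-atom pair between a Ca-domain atom and a
#' protein atom of a *different molecule instance*: a different complex in
#' the asymmetric unit, an unassigned chain, or any symmetry mate. A
#' molecule instance is identified by (complex_index, mate_label); atoms of
#' the Ca domain's own complex are never partners. Waters, ions, glycans
#' and other non-protein HETATM groups are excluded on the partner side.
#'
#' @param structure a `crystal_structure`.
#' @param annotation matching `domain_annotation` (ideally after
#'   [map_strands()], so records carry strand elements).
#' @param mates list of `symmetry_mate` from [expand_symmetry()]; their
#'   generation radius must exceed `contact_cutoff`.
#' @param contact_cutoff heavy-atom distance cutoff in Angstrom (default
#'   4.5, the standard crystal-contact criterion; a single qualifying atom
#'   pair registers, so marginal touches are kept).
#' @return data frame of contact records: entry_id, ca_complex_index,
#'   ca_chain, ca_resno, ca_insert, ca_element, ca_atom, partner_label,
#'   partner_chain, partner_resno, partner_insert, partner_complex_index,
#'   partner_molecule, partner_domain, partner_element, partner_atom,
#'   distance.
#' @export
find_ca_contacts <- function(structure, annotation, mates,
                             contact_cutoff = 4.5) {
  stopifnot(inherits(structure, "crystal_structure"),
            inherits(annotation, "domain_annotation"))
  atoms <- annotate_atoms(structure$atoms, annotation)
  prot <- atoms[atoms$resid %in% STANDARD_AA, , drop = FALSE]
  empty <- contact_record_frame()
  ca_all <- prot[prot$domain %in% "Ca", , drop = FALSE]
  if (nrow(ca_all) == 0L) return(empty)

  records <- list()
  add_records <- function(ca, partner, mate_label) {
    pr <- cross_pairs(ca, partner, contact_cutoff)
    if (is.null(pr)) return()
    records[[length(records) + 1L]] <<- data.frame(
      entry_id = structure$entry_id,
      ca_complex_index = ca$complex_index[pr$i],
      ca_chain = ca$chain[pr$i], ca_resno = ca$resno[pr$i],
      ca_insert = ca$insert[pr$i],
      ca_element = ifelse(is.na(ca$element[pr$i]) | ca$element[pr$i] == "",
                          "unassigned", ca$element[pr$i]),
      ca_atom = ca$elety[pr$i],
      partner_label = mate_label,
      partner_chain = partner$chain[pr$j],
      partner_resno = partner$resno[pr$j],
      partner_insert = partner$insert[pr$j],
      partner_complex_index = partner$complex_index[pr$j],
      partner_molecule = partner$molecule[pr$j],
      partner_domain = partner$domain[pr$j],
      partner_element = ifelse(is.na(partner$element[pr$j]) |
                                 partner$element[pr$j] == "",
                               "unassigned", partner$element[pr$j]),
      partner_atom = partner$elety[pr$j],
      distance = pr$distance,
      stringsAsFactors = FALSE)
  }

  mate_atoms <- lapply(mates, function(m) {
    matoms <- annotate_atoms(m$atoms, annotation)
    matoms[matoms$resid %in% STANDARD_AA, , drop = FALSE]
  })
  for (cx in unique(ca_all$complex_index)) {
    ca <- ca_all[ca_all$complex_index == cx, , drop = FALSE]
    own <- instance_key(cx, ca$chain[1], "ASU")
    asu_key <- instance_key(prot$complex_index, prot$chain, "ASU")
    partner <- prot[asu_key != own, , drop = FALSE]
    if (nrow(partner) > 0L) add_records(ca, partner, "ASU")
    for (k in seq_along(mates)) {
      if (nrow(mate_atoms[[k]]) > 0L) {
        add_records(ca, mate_atoms[[k]], mates[[k]]$label)
      }
    }
  }
  if (length(records) == 0L) return(empty)
  out <- do.call(rbind, records)
  out <- out[order(out$ca_complex_index, out$partner_label, out$ca_resno,
                   out$ca_atom, out$partner_chain, out$partner_resno,
                   out$partner_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

contact_record_frame <- function() {
  data.frame(entry_id = character(), ca_complex_index = integer(),
             ca_chain = character(), ca_resno = integer(),
             ca_insert = character(), ca_element = character(),
             ca_atom = character(), partner_label = character(),
             partner_chain = character(), partner_resno = integer(),
             partner_insert = character(),
             partner_complex_index = integer(),
             partner_molecule = character(), partner_domain = character(),
             partner_element = character(), partner_atom = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

# human-readable partner class in survey-table vocabulary
partner_class <- function(molecule, domain) {
  ifelse(molecule %in% c("TCRa", "TCRb"),
         paste("TCR", domain),
         ifelse(molecule == "CD4", paste("CD4", domain),
                ifelse(molecule %in% c("MHCI-heavy", "MHCII-a", "MHCII-b",
                                       "b2m"),
                       paste(ifelse(molecule == "b2m", "b2m",
                                    sub("-.*", "", molecule)), domain),
                       paste(molecule, domain))))
}

#' Summarise Ca contacts per complex
#'
#' Ranks partner domains by descending heavy-atom contact count and formats
#' a survey-table verdict per complex: `"no contact"`, `"Ca contacts
#' <partners>"`, or `"Ca forms dimer"` when the top partner is another Ca
#' domain whose pair was assessed as symmetric.
#'
#' @param records contact records from [find_ca_contacts()] (one entry).
#' @param annotation the entry's `domain_annotation`.
#' @param assessments optional dimer assessment table from
#'   [assess_dimers()]; used to upgrade top-ranked Ca-Ca contacts to
#'   "forms dimer".
#' @return data frame with one row per complex: entry_id, complex_index,
#'   partner_domains (";"-separated, ranked), contact_counts
#'   (";"-separated), verdict.
#' @export
summarize_ca_contacts <- function(records, annotation, assessments = NULL) {
  stopifnot(inherits(annotation, "domain_annotation"))
  entry <- attr(annotation, "entry_id")
  complexes <- sort(unique(stats::na.omit(annotation$complex_index)))
  rows <- lapply(complexes, function(cx) {
    rec <- records[records$ca_complex_index %in% cx, , drop = FALSE]
    if (nrow(rec) == 0L) {
      return(data.frame(entry_id = entry, complex_index = cx,
                        partner_domains = "", contact_counts = "",
                        verdict = "no contact", stringsAsFactors = FALSE))
    }
    cls <- partner_class(rec$partner_molecule, rec$partner_domain)
    counts <- sort(table(cls), decreasing = TRUE)
    top <- names(counts)[1]
    verdict <- if (top == "TCR Ca" && !is.null(assessments) &&
                   any(assessments$is_symmetric[
                     assessments$complex_index_1 == cx |
                       assessments$complex_index_2 == cx], na.rm = TRUE)) {
      "Ca forms dimer"
    } else {
      partners <- names(counts)
      joined <- if (length(partners) == 2L) {
        paste(partners, collapse = " and ")
      } else {
        paste(partners, collapse = ", ")
      }
      paste("Ca contacts", joined)
    }
    data.frame(entry_id = entry, complex_index = cx,
               partner_domains = paste(names(counts), collapse = ";"),
               contact_counts = paste(as.integer(counts), collapse = ";"),
               verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
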