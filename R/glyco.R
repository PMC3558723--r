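# N-linked glycosylation sequon scanning, the glycosylation-efficiency
# rule, and the occlusion test of the putative C/F-strand dimer interface.
#
# A sequon is the tripeptide N-X-S/T with X any residue except proline
# (the standard biochemical definition). The efficiency rule encodes the
# published observation that an N-X-S site is efficiently glycosylated as
# long as X is not Trp, Asp, Glu or Leu; the rule table is configurable so
# alternative published rules can be swapped in.

#' Default sequon efficiency rule
#'
#' @return list with `S_excluded` and `T_excluded`: X residues that make an
#'   N-X-S (resp. N-X-T) sequon inefficient. The stated rule concerns
#'   N-X-S only; N-X-T sites default to efficient.
#' @export
default_efficiency_rule <- function() {
  list(S_excluded = c("W", "D", "E", "L"), T_excluded = character(0))
}

#' Sequon efficiency flag
#'
#' @param x_residue one-letter X residue(s) of the sequon.
#' @param third_residue `"S"` or `"T"`.
#' @param rule rule table, see [default_efficiency_rule()].
#' @return logical vector.
#' @export
sequon_efficient <- function(x_residue, third_residue,
                             rule = default_efficiency_rule()) {
  ifelse(third_residue == "S",
         !(x_residue %in% rule$S_excluded),
         !(x_residue %in% rule$T_excluded))
}

#' Scan a sequence for N-X-S/T sequons
#'
#' Reports every position i with sequence\[i\] = N, sequence\[i+2\] in
#' \{S, T\} and sequence\[i+1\] != P, including overlapping sequons.
#' Ambiguity codes (X, B, Z) never match as N, S or T.
#'
#' @param sequence amino-acid string.
#' @param sequence_id identifier carried into the result.
#' @param rule efficiency rule table.
#' @return data frame of sequon hits: sequence_id, position (1-based index
#'   of the Asn), sequon, x_residue, third_residue, efficient, element
#'   (NA until mapped), author_resno (NA until mapped).
#' @export
find_sequons <- function(sequence, sequence_id = "seq",
                         rule = default_efficiency_rule()) {
  s <- toupper(as.character(sequence))
  empty <- data.frame(sequence_id = character(), position = integer(),
                      sequon = character(), x_residue = character(),
                      third_residue = character(), efficient = logical(),
                      element = character(), author_resno = integer(),
                      stringsAsFactors = FALSE)
  n <- nchar(s)
  if (n < 3L) return(empty)
  ch <- strsplit(s, "")[[1]]
  pos <- which(ch[1:(n - 2)] == "N" & ch[3:n] %in% c("S", "T") &
                 ch[2:(n - 1)] != "P")
  if (length(pos) == 0L) return(empty)
  x <- ch[pos + 1L]
  third <- ch[pos + 2L]
  data.frame(sequence_id = sequence_id, position = as.integer(pos),
             sequon = paste0("N", x, third), x_residue = x,
             third_residue = third,
             efficient = sequon_efficient(x, third, rule),
             element = NA_character_, author_resno = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Scan a reference Ca sequence and map hits to strand elements
#'
#' Convenience scanner for a strand-mapped reference: positions are
#' reference offsets, so elements and author residue numbers follow
#' directly from the strand map.
#'
#' @param strand_map a `strand_map` (see [read_strand_map()]).
#' @param rule efficiency rule table.
#' @return sequon hit data frame with `element` and `author_resno` filled.
#' @export
scan_reference_sequons <- function(strand_map,
                                   rule = default_efficiency_rule()) {
  hits <- find_sequons(strand_map$reference,
                       sequence_id = paste0("ca_", strand_map$species),
                       rule = rule)
  if (nrow(hits) > 0L) {
    hits$element <- element_at_offset(strand_map, hits$position)
    hits$author_resno <- hits$position + strand_map$author_start - 1L
  }
  hits
}

#' Scan the Ca domain of an annotated structure for sequons
#'
#' Extracts each complex's Ca sequence from the resolved residues, scans
#' it, and maps hits back to author residue numbers and (when
#' [map_strands()] has run) Ig elements.
#'
#' @param annotation a `domain_annotation`.
#' @param rule efficiency rule table.
#' @return sequon hit data frame with one extra column `complex_index`.
#' @export
scan_ca_sequons <- function(annotation, rule = default_efficiency_rule()) {
  out <- list()
  for (cx in unique(stats::na.omit(annotation$complex_index))) {
    cs <- ca_sequence(annotation, cx)
    if (nrow(cs$residues) == 0L) next
    hits <- find_sequons(cs$sequence,
                         sequence_id = sprintf("%s_cx%d_Ca",
                                               attr(annotation, "entry_id"),
                                               cx),
                         rule = rule)
    if (nrow(hits) > 0L) {
      hits$author_resno <- cs$residues$resno[hits$position]
      hits$element <- ifelse(cs$residues$element[hits$position] == "",
                             NA_character_,
                             cs$residues$element[hits$position])
    }
    hits$complex_index <- rep(cx, nrow(hits))
    out[[length(out) + 1L]] <- hits
  }
  if (length(out) == 0L) {
    hits <- find_sequons("")
    hits$complex_index <- integer(0)
    return(hits)
  }
  do.call(rbind, out)
}

#' Do glycan sites occlude the putative dimer interface?
#'
#' A hit occludes the putative C/F-strand interface when its Asn lies on an
#' interface element (by default the C and F strands; pass the observed
#' interface element set to test an actual interface) and is efficiently
#' glycosylated. Hits without a structural element mapping are flagged
#' `unmapped` and excluded from the verdict.
#'
#' @param hits sequon hit data frame with `element` filled where mapped.
#' @param interface_elements character vector of Ig elements forming the
#'   interface under test (default `c("C", "F")`).
#' @return list: `hits` (with `occludes` and `status` columns), `verdict`
#'   (`"dimer-interface-occluded"` or `"not-occluded"`).
#' @export
occlusion_check <- function(hits, interface_elements = c("C", "F")) {
  if (nrow(hits) == 0L) {
    hits$occludes <- logical(0)
    hits$status <- character(0)
    return(list(hits = hits, verdict = "not-occluded"))
  }
  mapped <- !is.na(hits$element)
  hits$occludes <- mapped & hits$efficient &
    hits$element %in% interface_elements
  hits$status <- ifelse(mapped, "mapped", "unmapped")
  verdict <- if (any(hits$occludes[mapped])) "dimer-interface-occluded"
             else "not-occluded"
  list(hits = hits, verdict = verdict)
}
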