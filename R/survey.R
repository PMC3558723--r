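# Survey orchestration: run every stage over all manifest entries and
# render the survey-table report with full provenance.

#' Survey configuration
#'
#' Every geometric threshold of the pipeline in one validated list.
#' Defaults: 4.5 A heavy-atom contact cutoff (standard crystal-contact
#' criterion); 5.0 A mate-generation radius (strictly larger, so no
#' contact can be missed); two-fold acceptance at rotation >= 160 degrees
#' and screw <= 3 A; upright/flat boundary at 45 degrees tilt; 30%
#' identity floor for strand transfer; 0.5 combined C+F interface fraction
#' for consistency with the C/F-strand dimer model.
#'
#' @param contact_cutoff,mate_radius Angstrom.
#' @param symmetry_min_angle degrees; `symmetry_max_screw` Angstrom;
#'   `symmetry_min_coverage` fraction of the Ca segment required resolved.
#' @param orientation_tilt_boundary degrees; `orientation_min_coverage`
#'   fraction of the V/C modules required resolved.
#' @param alignment_min_identity fraction for strand transfer.
#' @param model2_min_cf_fraction combined C+F interface fraction.
#' @return named list of class `survey_config`.
#' @export
survey_config <- function(contact_cutoff = 4.5, mate_radius = 5.0,
                          symmetry_min_angle = 160,
                          symmetry_max_screw = 3.0,
                          symmetry_min_coverage = 0.8,
                          orientation_tilt_boundary = 45,
                          orientation_min_coverage = 0.5,
                          alignment_min_identity = 0.30,
                          model2_min_cf_fraction = 0.5) {
  cfg <- list(contact_cutoff = contact_cutoff, mate_radius = mate_radius,
              symmetry_min_angle = symmetry_min_angle,
              symmetry_max_screw = symmetry_max_screw,
              symmetry_min_coverage = symmetry_min_coverage,
              orientation_tilt_boundary = orientation_tilt_boundary,
              orientation_min_coverage = orientation_min_coverage,
              alignment_min_identity = alignment_min_identity,
              model2_min_cf_fraction = model2_min_cf_fraction)
  for (k in names(cfg)) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L ||
        !is.finite(cfg[[k]])) {
      stop("malformed config value for key '", k, "'")
    }
  }
  if (cfg$mate_radius <= cfg$contact_cutoff) {
    stop("malformed config: mate_radius must exceed contact_cutoff")
  }
  structure(cfg, class = c("survey_config", "list"))
}

#' Read a key=value configuration file
#'
#' @param path text file with one `key = value` pair per line; `#` starts
#'   a comment. Unknown keys are an error naming the key.
#' @return a [survey_config()].
#' @export
read_survey_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
  known <- names(formals(survey_config))
  bad <- setdiff(keys, known)
  if (length(bad) > 0) {
    stop("malformed config: unknown key '", bad[1], "'")
  }
  if (any(is.na(vals))) {
    stop("malformed config value for key '", keys[which(is.na(vals))[1]], "'")
  }
  do.call(survey_config, as.list(stats::setNames(vals, keys)))
}

default_strand_maps <- function() {
  list(human = read_strand_map("human"), mouse = read_strand_map("mouse"))
}

find_structure_file <- function(structures_dir, entry_id) {
  for (ext in c(".pdb", ".ent", ".cif", ".mmcif")) {
    for (name in c(entry_id, tolower(entry_id), toupper(entry_id))) {
      p <- file.path(structures_dir, paste0(name, ext))
      if (file.exists(p)) return(p)
    }
  }
  NA_character_
}

#' Run the full Ca packing survey
#'
#' For each manifest entry: parse the structure, annotate domains, map Ca
#' strand elements, expand crystallographic symmetry, detect and classify
#' all Ca contacts, assess candidate Ca-Ca pairs, and scan the Ca sequence
#' for glycosylation sequons. Entries whose structure file is absent are
#' reported as `skipped`, never dropped. All outputs are deterministic
#' given identical inputs and configuration.
#'
#' @param manifest manifest data frame or TSV path.
#' @param structures_dir directory holding `<entry_id>.pdb` / `.cif` files.
#'   The pipeline performs no network access; see
#'   `inst/cli/fetch_structures.R` for a documented fetch helper.
#' @param config a [survey_config()].
#' @param out_dir optional output directory; when given, writes survey.tsv,
#'   contacts.tsv, assessments.tsv, sequons.tsv, a JSON provenance sidecar
#'   (config, thresholds, file checksums) and a log file.
#' @param strand_maps named list of `strand_map` objects by species;
#'   defaults to the bundled human and mouse maps. Supply a `toy` entry
#'   when surveying fixture scenarios.
#' @param metadata optional data frame (entry_id, mhc_class, species) to
#'   decorate the survey rows; defaults to the bundled survey-set table.
#' @return list with data frames `survey`, `contacts`, `assessments`,
#'   `sequons`, and `log` (character).
#' @export
run_survey <- function(manifest, structures_dir,
                       config = survey_config(), out_dir = NULL,
                       strand_maps = NULL, metadata = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  maps <- default_strand_maps()
  if (!is.null(strand_maps)) maps[names(strand_maps)] <- strand_maps
  if (is.null(metadata)) {
    meta_path <- system.file("extdata", "table1_entries.tsv",
                             package = "tcrlattice")
    metadata <- if (nzchar(meta_path)) {
      utils::read.delim(meta_path, stringsAsFactors = FALSE)
    } else {
      data.frame(entry_id = character(), mhc_class = character(),
                 species = character())
    }
  }

  entries <- sort(unique(manifest$entry_id))
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  survey_rows <- list(); all_contacts <- list()
  all_assessments <- list(); all_sequons <- list()
  checksums <- character(0)

  for (entry in entries) {
    rows <- manifest[manifest$entry_id == entry, , drop = FALSE]
    species <- rows$species[1]
    n_cx <- length(unique(rows$complex_index))
    path <- find_structure_file(structures_dir, entry)
    meta <- metadata[metadata$entry_id == entry, , drop = FALSE]
    mhc_class <- if (nrow(meta) > 0) meta$mhc_class[1] else NA_character_
    if (is.na(path)) {
      note("[%s] skipped: no structure file in %s", entry, structures_dir)
      survey_rows[[entry]] <- data.frame(
        entry_id = entry, mhc_class = mhc_class, species = species,
        n_complexes = n_cx, status = "skipped", verdict = "skipped",
        glyco_verdict = "skipped", stringsAsFactors = FALSE)
      next
    }
    checksums[basename(path)] <- unname(tools::md5sum(path))
    structure <- read_structure(path, entry_id = entry)
    note("[%s] read: %d atoms, %d chains, %s", entry,
         nrow(structure$atoms), length(structure$asu_chain_ids),
         structure$sg_symbol)
    ann <- annotate(structure, manifest)
    map <- maps[[species]]
    if (is.null(map)) {
      note("[%s] no strand map for species '%s'; elements left empty",
           entry, species)
    } else {
      ann <- withCallingHandlers(
        map_strands(ann, map, min_identity = config$alignment_min_identity),
        warning = function(w) {
          note("[%s] %s", entry, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
    mates <- expand_symmetry(structure, contact_radius = config$mate_radius)
    note("[%s] %d symmetry mates within %.1f A", entry, length(mates),
         config$mate_radius)
    records <- find_ca_contacts(structure, ann, mates,
                                contact_cutoff = config$contact_cutoff)
    note("[%s] %d Ca contact records", entry, nrow(records))
    assessments <- assess_dimers(structure, ann, records, mates, config)
    summary <- summarize_ca_contacts(records, ann, assessments)
    hits <- scan_ca_sequons(ann)
    occ <- occlusion_check(hits)
    verdict <- if (n_cx == 1L) {
      summary$verdict[1]
    } else if (length(unique(summary$verdict)) == 1L) {
      summary$verdict[1]
    } else {
      sprintf("%d molecules. %s", n_cx,
              paste(sprintf("cx%d: %s", summary$complex_index,
                            summary$verdict), collapse = "; "))
    }
    survey_rows[[entry]] <- data.frame(
      entry_id = entry, mhc_class = mhc_class, species = species,
      n_complexes = n_cx, status = "ok", verdict = verdict,
      glyco_verdict = occ$verdict, stringsAsFactors = FALSE)
    all_contacts[[entry]] <- records
    all_assessments[[entry]] <- assessments
    if (nrow(occ$hits) > 0) {
      occ$hits$entry_id <- entry
      all_sequons[[entry]] <- occ$hits
    }
  }

  bind <- function(lst, proto) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    if (length(lst) == 0L) return(proto)
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  result <- list(
    survey = bind(survey_rows, NULL),
    contacts = bind(all_contacts, contact_record_frame()),
    assessments = bind(all_assessments,
                       assess_dimers_frame()),
    sequons = bind(all_sequons, NULL),
    log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
      if (is.null(df)) df <- data.frame()
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(result$survey, "survey.tsv")
    wt(result$contacts, "contacts.tsv")
    wt(result$assessments, "assessments.tsv")
    wt(result$sequons, "sequons.tsv")
    jsonlite::write_json(
      list(config = unclass(config), structure_checksums = as.list(checksums),
           n_entries = length(entries)),
      file.path(out_dir, "run_provenance.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "survey.log"))
  }
  result
}

assess_dimers_frame <- function() {
  assess_dimers(
    structure = structure(list(entry_id = "none",
                               atoms = data.frame()),
                          class = "crystal_structure"),
    annotation = structure(data.frame(), class = c("domain_annotation",
                                                   "data.frame")),
    records = contact_record_frame(), mates = list())
}
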