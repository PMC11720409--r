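#' Build a reagent annotation table
#'
#' One row per reagent, with the UniProt accession set that defines
#' which protein (or protein complex) the reagent targets.  Multiple
#' accessions are pipe-separated; their order is irrelevant because all
#' matching goes through the canonical sorted set.
#'
#' @param reagent_id Character vector of reagent ids, unique within a
#'   platform run.
#' @param platform Platform tag (recycled), one of `"SOMA_A"`,
#'   `"SOMA_B"`, `"OLINK"`.
#' @param uniprot_ids Character vector of pipe-separated UniProt
#'   accessions, each entry non-empty.
#' @param gene_symbol,panel Optional character vectors.
#' @return A `data.frame` with class `reagent_annotation`.
#' @export
reagent_annotation <- function(reagent_id, platform, uniprot_ids,
                               gene_symbol = NA_character_,
                               panel = NA_character_) {
  reagent_id <- as.character(reagent_id)
  uniprot_ids <- as.character(uniprot_ids)
  if (anyNA(uniprot_ids) || any(uniprot_ids == "")) {
    stop("every reagent needs at least one UniProt accession")
  }
  platform <- as.character(platform)
  if (!all(platform %in% .platforms)) {
    stop("platform must be one of: ", paste(.platforms, collapse = ", "))
  }
  df <- data.frame(reagent_id = reagent_id,
                   platform = rep_len(platform, length(reagent_id)),
                   uniprot_ids = uniprot_ids,
                   gene_symbol = rep_len(as.character(gene_symbol),
                                         length(reagent_id)),
                   panel = rep_len(as.character(panel), length(reagent_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("reagent_id", "platform")])) {
    stop("(reagent_id, platform) must be unique within an annotation table")
  }
  class(df) <- c("reagent_annotation", "data.frame")
  df
}

#' Canonical key for a UniProt accession set
#'
#' Splits pipe-separated accessions, sorts them, and re-joins, so that
#' `"P01857|P01834"` and `"P01834|P01857"` map to the same key.
#'
#' @param x Character vector of pipe-separated accession strings.
#' @return Character vector of canonical keys.
#' @export
uniprot_key <- function(x) {
  vapply(strsplit(as.character(x), "|", fixed = TRUE), function(ids) {
    paste(sort(unique(ids)), collapse = "|")
  }, character(1))
}

#' Pair reagents across two panels by UniProt accession set
#'
#' A reagent from `a` is matched to a reagent from `b` when their
#' complete UniProt accession sets are equal (so multi-accession
#' complex annotations must agree in full, and a single-accession
#' reagent never matches a complex).  Several reagents may target the
#' same protein on either side; all combinations are returned
#' (many-to-many pairing).
#'
#' @param a,b `reagent_annotation` tables from two distinct panels or
#'   assay runs.
#' @return A `data.frame` with columns `reagent_a`, `reagent_b`,
#'   `uniprot_ids` (the shared canonical set).  Empty when nothing
#'   matches.
#' @export
pair_reagents <- function(a, b) {
  ka <- uniprot_key(a$uniprot_ids)
  kb <- uniprot_key(b$uniprot_ids)
  da <- data.frame(reagent_a = a$reagent_id, key = ka,
                   stringsAsFactors = FALSE)
  db <- data.frame(reagent_b = b$reagent_id, key = kb,
                   stringsAsFactors = FALSE)
  out <- merge(da, db, by = "key")
  out <- out[order(out$reagent_a, out$reagent_b), ]
  data.frame(reagent_a = out$reagent_a, reagent_b = out$reagent_b,
             uniprot_ids = out$key, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Collapse reagent-level identifiers to unique protein level
#'
#' Reagent counts and protein counts differ whenever several reagents
#' target one protein; summaries are reported at both levels.  This
#' maps reagent ids to their canonical UniProt set and returns the
#' unique sets.
#'
#' @param reagents Character vector of reagent ids.
#' @param annotation A `reagent_annotation` table covering them.
#' @return Character vector of unique canonical UniProt keys.
#' @export
collapse_to_proteins <- function(reagents, annotation) {
  idx <- match(reagents, annotation$reagent_id)
  if (anyNA(idx)) {
    stop("unannotated reagent ids: ",
         paste(utils::head(reagents[is.na(idx)], 5L), collapse = ", "))
  }
  unique(uniprot_key(annotation$uniprot_ids[idx]))
}

#' Read / write annotation, plate-map and phenotype tables
#'
#' Plain TSV round-trippable readers for the side tables the pipeline
#' consumes: reagent annotations (`reagent_id`, `platform`,
#' `uniprot_ids`, `gene_symbol`, `panel`), plate maps (`sample_id`,
#' `plate_id`, `role` with role `STUDY` or `CALIBRATOR`) and phenotype
#' tables (one row per sample).
#'
#' @param path Path to a tab-separated file with header.
#' @return A validated `data.frame`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reagent_id", "platform", "uniprot_ids")
  if (!all(need %in% names(df))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  reagent_annotation(df$reagent_id, df$platform, df$uniprot_ids,
                     if ("gene_symbol" %in% names(df)) df$gene_symbol else NA,
                     if ("panel" %in% names(df)) df$panel else NA)
}

#' @rdname read_annotation
#' @param x Table to write.
#' @export
write_annotation <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_annotation
#' @export
read_plate_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  plate_map(df$sample_id, df$plate_id, df$role)
}

#' Build a plate map
#'
#' @param sample_id,plate_id Character vectors.
#' @param role `"STUDY"` or `"CALIBRATOR"` per sample.
#' @return A `data.frame` with class `plate_map`.
#' @export
plate_map <- function(sample_id, plate_id, role) {
  role <- as.character(role)
  if (!all(role %in% c("STUDY", "CALIBRATOR"))) {
    stop("role must be STUDY or CALIBRATOR")
  }
  df <- data.frame(sample_id = as.character(sample_id),
                   plate_id = as.character(plate_id),
                   role = role, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("each sample belongs to exactly one plate: duplicate sample ids")
  }
  class(df) <- c("plate_map", "data.frame")
  df
}

#' @rdname read_annotation
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(df)
}

#' Validate a phenotype table
#'
#' Checks the clinical-table invariants: MMSE within 0-30, positive
#' ages, and an assay-technique entry wherever a CSF core biomarker
#' value is present.
#'
#' @param df Phenotype `data.frame`, one row per sample with a
#'   `sample_id` column.
#' @return `df`, invisibly validated.
#' @export
validate_phenotypes <- function(df) {
  if (!"sample_id" %in% names(df)) stop("phenotype table needs sample_id")
  if ("mmse" %in% names(df)) {
    ok <- is.na(df$mmse) | (df$mmse >= 0 & df$mmse <= 30)
    if (!all(ok)) stop("mmse values outside [0, 30]")
  }
  if ("age" %in% names(df) && any(df$age <= 0, na.rm = TRUE)) {
    stop("age must be positive")
  }
  has_marker <- rep(FALSE, nrow(df))
  for (v in c("csf_ab42", "csf_ptau")) {
    if (v %in% names(df)) has_marker <- has_marker | !is.na(df[[v]])
  }
  if (any(has_marker)) {
    if (!"technique" %in% names(df) || anyNA(df$technique[has_marker])) {
      stop("technique must be present whenever csf_ab42/csf_ptau is present")
    }
  }
  df
}
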