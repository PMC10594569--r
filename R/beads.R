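#' Read a bead-level fluorescence event table
#'
#' Bead events are the raw unit of a QMI experiment: one row per flow-cytometry
#' bead read, keyed by sample, well, batch and the ordered `IP_probe` pair it
#' reports on. The interaction identifier is always `"<ip>_<probe>"`; IP and
#' probe roles are not interchangeable (`AKT_mTOR` and `mTOR_AKT` are distinct
#' measurements, and `AKT_AKT` is an apparent-abundance proxy).
#'
#' @param path Path to a CSV file with header
#'   `sample_id,well_id,batch_id,ip,probe,fluorescence`.
#' @return A tibble with the six input columns plus `interaction`
#'   (`"<ip>_<probe>"`). Identifier columns are whitespace-trimmed; event
#'   order is preserved.
#' @seealso [write_bead_events()], [validate_bead_events()], [collapse_to_mfi()]
#' @export
read_bead_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("bead event file not found: ", path))
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_bead_events(x)
}

#' Validate (and normalize) a bead event table
#'
#' Checks the invariants every downstream stage relies on: required columns
#' present, all fluorescence values finite and strictly positive. Adds the
#' `interaction` column if absent.
#'
#' @param beads A data frame of bead events.
#' @return The validated tibble.
#' @export
validate_bead_events <- function(beads) {
  required <- c("sample_id", "well_id", "batch_id", "ip", "probe", "fluorescence")
  missing <- setdiff(required, names(beads))
  if (length(missing) > 0) {
    abort(paste0("bead event table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  beads <- tibble::as_tibble(beads)
  beads <- dplyr::mutate(beads, dplyr::across(
    c("sample_id", "well_id", "batch_id", "ip", "probe"),
    ~ stringr::str_trim(as.character(.x))
  ))
  bad <- which(!is.finite(beads$fluorescence) | beads$fluorescence <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive or non-finite fluorescence at row(s): ",
                 paste(head(bad, 5L), collapse = ", "),
                 if (length(bad) > 5L) " ..." else ""))
  }
  if (!"interaction" %in% names(beads)) {
    beads$interaction <- paste(beads$ip, beads$probe, sep = "_")
  }
  beads
}

#' @rdname read_bead_events
#' @param beads A validated bead event table.
#' @export
write_bead_events <- function(beads, path) {
  beads <- validate_bead_events(beads)
  cols <- c("sample_id", "well_id", "batch_id", "ip", "probe", "fluorescence")
  readr::write_csv(beads[cols], path, progress = FALSE)
  invisible(path)
}

#' Read or validate sample metadata
#'
#' One row per sample: biological replicate, condition, batch, technical
#' duplicate index (1 unless a sample is itself a re-preparation; duplicate
#' *wells* live in the bead table) and `pair_key`, which links the matched
#' samples of one biological replicate across conditions. The matched design
#' admits at most one sample per condition within a biological replicate.
#'
#' @param path CSV with header
#'   `sample_id,biological_replicate_id,condition,batch_id,technical_duplicate_index,pair_key`.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata file not found: ", path))
  validate_sample_metadata(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_sample_metadata
#' @param meta A data frame of sample metadata.
#' @export
validate_sample_metadata <- function(meta) {
  required <- c("sample_id", "biological_replicate_id", "condition", "batch_id",
                "technical_duplicate_index", "pair_key")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("sample metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  meta <- tibble::as_tibble(meta)
  meta <- dplyr::mutate(meta, dplyr::across(
    c("sample_id", "biological_replicate_id", "condition", "batch_id", "pair_key"),
    ~ stringr::str_trim(as.character(.x))
  ))
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in metadata")
  }
  if (any(meta$technical_duplicate_index < 1)) {
    abort("technical_duplicate_index must be >= 1")
  }
  dup <- meta |>
    dplyr::count(.data$biological_replicate_id, .data$condition,
                 .data$technical_duplicate_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("matched design violated: more than one sample per condition within a biological replicate")
  }
  meta
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(meta, path) {
  meta <- validate_sample_metadata(meta)
  readr::write_csv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read or validate a trait ("hypothesis") table
#'
#' Each row encodes one coded hypothesis over samples: a 0/1 contrast
#' (e.g. starved vs refed) or an ordinal/numeric coding (e.g. minutes since
#' refeeding). Rows must be non-constant, otherwise the module-trait
#' correlation is undefined.
#'
#' @param path CSV whose first column is the hypothesis name and remaining
#'   columns are one per sample.
#' @param sample_ids Optional character vector the trait sample set must equal.
#' @return A tibble with column `hypothesis` followed by one numeric column
#'   per sample.
#' @export
read_trait_table <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) abort(paste0("trait file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "hypothesis"
  validate_trait_table(x, sample_ids = sample_ids)
}

#' @rdname read_trait_table
#' @param traits A data frame with a `hypothesis` column plus sample columns.
#' @export
validate_trait_table <- function(traits, sample_ids = NULL) {
  traits <- tibble::as_tibble(traits)
  if (!"hypothesis" %in% names(traits)) {
    abort("trait table must have a 'hypothesis' column")
  }
  vals <- as.matrix(traits[setdiff(names(traits), "hypothesis")])
  if (!is.numeric(vals)) abort("trait codes must be numeric")
  if (anyDuplicated(traits$hypothesis)) abort("duplicate hypothesis names")
  const <- apply(vals, 1L, function(r) length(unique(r)) < 2L)
  if (any(const)) {
    abort(paste0("constant trait row(s): ",
                 paste(traits$hypothesis[const], collapse = ", ")))
  }
  if (!is.null(sample_ids) && !setequal(colnames(vals), sample_ids)) {
    abort("trait table sample set does not match the expected sample set")
  }
  traits
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(traits, path) {
  readr::write_csv(traits, path, progress = FALSE)
  invisible(path)
}
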