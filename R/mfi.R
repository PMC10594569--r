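#' MFI matrices as interaction-keyed tibbles
#'
#' The unit of the network analysis is the interactions x samples matrix of
#' median fluorescent intensities (MFI). `qminet` carries it as a tibble whose
#' first column is `interaction` and whose remaining columns are samples, with
#' a `scale` attribute recording whether values are linear-scale MFI or log2
#' units.
#'
#' @param values Numeric matrix, interactions in rows (rownames = interaction
#'   ids), samples in columns (colnames = sample ids).
#' @param scale `"linear"` or `"log2"`.
#' @return A `qmi_mfi` tibble.
#' @export
new_qmi_mfi <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyNA(values) || any(!is.finite(values))) abort("MFI matrix contains missing/non-finite values")
  if (scale == "linear" && any(values <= 0)) abort("linear-scale MFI values must be > 0")
  out <- tibble::as_tibble(values, rownames = "interaction")
  class(out) <- c("qmi_mfi", class(out))
  attr(out, "scale") <- scale
  out
}

#' @rdname new_qmi_mfi
#' @param mfi A `qmi_mfi` tibble.
#' @export
mfi_values <- function(mfi) {
  m <- as.matrix(mfi[setdiff(names(mfi), "interaction")])
  rownames(m) <- mfi$interaction
  m
}

#' @rdname new_qmi_mfi
#' @export
mfi_scale <- function(mfi) attr(mfi, "scale") %||% "linear"

#' @rdname new_qmi_mfi
#' @export
mfi_samples <- function(mfi) setdiff(names(mfi), "interaction")

#' @export
print.qmi_mfi <- function(x, ...) {
  cat(sprintf("# MFI matrix: %d interactions x %d samples (%s scale)\n",
              nrow(x), length(mfi_samples(x)), mfi_scale(x)))
  NextMethod()
}

#' Read/write an MFI matrix as TSV (interactions as rows, samples as columns)
#'
#' @param path TSV path; the first column is the interaction id.
#' @param scale Scale flag to attach on read.
#' @export
read_mfi_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "interaction"
  m <- as.matrix(x[-1])
  rownames(m) <- x$interaction
  new_qmi_mfi(m, scale = scale)
}

#' @rdname read_mfi_matrix
#' @param mfi A `qmi_mfi` tibble.
#' @export
write_mfi_matrix <- function(mfi, path) {
  readr::write_tsv(tibble::as_tibble(mfi), path, progress = FALSE)
  invisible(path)
}

#' Collapse bead distributions into an MFI matrix
#'
#' Per (interaction, well) the bead distribution is collapsed to its median —
#' the Luminex-standard MFI. Per (interaction, sample) the technical-duplicate
#' well medians are then combined by arithmetic mean on the linear scale.
#'
#' @param beads Bead event table (see [read_bead_events()]).
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param on_missing What to do when an interaction is absent from some sample:
#'   `"drop"` removes the interaction (default), `"error"` aborts.
#' @return A linear-scale `qmi_mfi` tibble covering every metadata sample.
#' @export
collapse_to_mfi <- function(beads, meta, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  beads <- validate_bead_events(beads)
  meta <- validate_sample_metadata(meta)
  extra <- setdiff(unique(beads$sample_id), meta$sample_id)
  if (length(extra) > 0) {
    abort(paste0("bead table contains samples absent from metadata: ",
                 paste(head(extra, 5L), collapse = ", ")))
  }
  well_medians <- beads |>
    dplyr::group_by(.data$interaction, .data$sample_id, .data$well_id) |>
    dplyr::summarise(mfi = median(.data$fluorescence), .groups = "drop")
  sample_mfi <- well_medians |>
    dplyr::group_by(.data$interaction, .data$sample_id) |>
    dplyr::summarise(mfi = mean(.data$mfi), .groups = "drop")

  samples <- sort(meta$sample_id)
  wide <- tidyr::pivot_wider(sample_mfi, names_from = "sample_id", values_from = "mfi")
  absent <- setdiff(samples, names(wide))
  for (s in absent) wide[[s]] <- NA_real_
  m <- as.matrix(wide[samples])
  rownames(m) <- wide$interaction
  incomplete <- rownames(m)[!complete.cases(m)]
  if (length(incomplete) > 0) {
    if (on_missing == "error") {
      abort(paste0("interaction(s) missing in some sample: ",
                   paste(head(incomplete, 5L), collapse = ", ")))
    }
    warn(paste0("dropping ", length(incomplete),
                " interaction(s) absent from some sample"))
    m <- m[setdiff(rownames(m), incomplete), , drop = FALSE]
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  new_qmi_mfi(m, scale = "linear")
}

#' Remove low-signal interactions
#'
#' Interactions whose median MFI across all samples falls below `threshold`
#' (default 100 fluorescence units) are removed as noise. The removed ids are
#' attached as the `removed_interactions` attribute.
#'
#' @param mfi Linear-scale `qmi_mfi`.
#' @param threshold Non-negative MFI cutoff; 0 keeps everything.
#' @return Filtered `qmi_mfi`; `attr(, "removed_interactions")` lists the drops.
#' @export
filter_low_mfi <- function(mfi, threshold = 100) {
  if (threshold < 0) abort("threshold must be >= 0")
  if (mfi_scale(mfi) != "linear") abort("filter_low_mfi expects linear-scale MFI")
  m <- mfi_values(mfi)
  med <- apply(m, 1L, median)
  keep <- med >= threshold
  out <- new_qmi_mfi(m[keep, , drop = FALSE], scale = "linear")
  attr(out, "removed_interactions") <- rownames(m)[!keep]
  out
}

#' Log2-transform an MFI matrix
#'
#' @param mfi Linear-scale `qmi_mfi` with strictly positive values.
#' @return `qmi_mfi` with `scale = "log2"`.
#' @export
log2_transform <- function(mfi) {
  if (mfi_scale(mfi) != "linear") abort("matrix is already on the log2 scale")
  m <- mfi_values(mfi)
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("non-positive MFI for interaction '%s', sample '%s'",
                  rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
  }
  new_qmi_mfi(log2(m), scale = "log2")
}

#' Undo a log2 transform
#' @rdname log2_transform
#' @export
linear_transform <- function(mfi) {
  if (mfi_scale(mfi) != "log2") abort("matrix is already on the linear scale")
  new_qmi_mfi(2^mfi_values(mfi), scale = "linear")
}
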