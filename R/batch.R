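#' Empirical-Bayes batch correction of a log2 MFI matrix
#'
#' Removes per-batch location/scale effects with the parametric empirical-Bayes
#' location-scale model (normal prior on batch offsets, inverse-gamma on batch
#' scale factors, moment-matched hyperparameters, iterative conditional
#' estimation) while protecting the condition effects named in `covariate`.
#' The adjustment is delegated to [sva::ComBat()].
#'
#' Correction operates on the log2 scale: a linear-scale input is
#' log-transformed internally and returned on its input scale.
#'
#' @param mfi A `qmi_mfi` tibble (linear or log2 scale).
#' @param meta Sample metadata supplying `batch_id` and the covariate column.
#' @param covariate Metadata column whose group structure must be preserved
#'   during standardization (default `"condition"`); `NULL` for no covariate.
#' @param mean_only If `TRUE`, adjust batch locations only (required when some
#'   batch has a single sample, where a batch scale is not estimable).
#' @param quiet Suppress ComBat progress messages (default `TRUE`).
#' @return A `qmi_mfi` on the same scale and with the same dimensions as the
#'   input.
#' @export
correct_batch_effects <- function(mfi, meta, covariate = "condition",
                                  mean_only = FALSE, quiet = TRUE) {
  meta <- validate_sample_metadata(meta)
  samples <- mfi_samples(mfi)
  meta <- meta[match(samples, meta$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata is missing some MFI samples")

  input_scale <- mfi_scale(mfi)
  m <- if (input_scale == "linear") log2(mfi_values(mfi)) else mfi_values(mfi)

  batch <- factor(meta$batch_id)
  if (nlevels(batch) < 2L) {
    inform("single batch: no correction applied")
    return(mfi)
  }
  sizes <- table(batch)
  if (any(sizes < 2L) && !mean_only) {
    abort(paste0("batch(es) with a single sample: ",
                 paste(names(sizes)[sizes < 2L], collapse = ", "),
                 "; scale not estimable (set mean_only = TRUE to shrink locations only)"))
  }

  mod <- NULL
  if (!is.null(covariate)) {
    if (!covariate %in% names(meta)) abort(paste0("covariate column not found: ", covariate))
    g <- factor(meta[[covariate]])
    if (nlevels(g) > 1L) {
      # condition effects inseparable from batch make the EB fit rank-deficient
      full <- cbind(model.matrix(~batch), model.matrix(~g)[, -1, drop = FALSE])
      if (qr(full)$rank < ncol(full)) {
        warn("condition confounded with batch: correction may absorb part of the condition effect; dropping the covariate")
      } else {
        mod <- model.matrix(~g)
      }
    }
  }

  run <- function() sva::ComBat(dat = m, batch = batch, mod = mod,
                                par.prior = TRUE, mean.only = mean_only)
  corrected <- if (quiet) suppressMessages(run()) else run()
  dimnames(corrected) <- dimnames(m)
  if (input_scale == "linear") corrected <- 2^corrected
  new_qmi_mfi(corrected, scale = input_scale)
}
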