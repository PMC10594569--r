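#' End-to-end QMI analysis pipeline
#'
#' Orchestrates the full analysis: load (or simulate) bead events, collapse
#' to MFI, remove low-signal interactions, run ANC on the bead distributions
#' and, in parallel, log2-transform + batch-correct the MFI matrix and run
#' CNA; intersect the two hit lists into the high-confidence set; attach
#' log2 fold changes, median-scaled values, module activity, PCA and sample
#' clustering; optionally write the whole artifact bundle to disk.
#'
#' @param config A list with elements:
#'   * `simulation`: a [simulation_config()] (or `inputs`: list with paths
#'     `beads`, `metadata`, `traits`);
#'   * `contrast`: `c(control, treated)` condition pair for ANC and log2FC;
#'   * `hypothesis`: trait row defining modules of interest (defaults to the
#'     treated condition's 0/1 trait);
#'   * optional `alpha` (0.05), `mfi_threshold` (100), `min_module_size` (5),
#'     `cut_height_fraction` (0.9), `power` (NULL = auto).
#' @param seed Integer seed for the simulation branch (defaults to the
#'   simulation config's seed).
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `mfi.tsv`, `anc.tsv`, `modules.tsv`, `module_trait.tsv`, `hits.tsv`,
#'   `edges.tsv`, `scaled.tsv`, `eigenvectors.tsv`, `pca.tsv`.
#' @return A `qmi_pipeline` list with every intermediate object plus a
#'   machine-readable `report` list. Identical config + seed give identical
#'   results and artifacts.
#' @export
run_qmi_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  alpha <- config$alpha %||% 0.05
  mfi_threshold <- config$mfi_threshold %||% 100
  min_size <- config$min_module_size %||% 5
  chf <- config$cut_height_fraction %||% 0.9

  sim_truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_qmi(config$simulation, seed = seed)
    beads <- sim$beads; meta <- sim$metadata; traits <- sim$traits
    sim_truth <- sim$truth
  } else if (!is.null(config$inputs)) {
    beads <- read_bead_events(config$inputs$beads)
    meta <- read_sample_metadata(config$inputs$metadata)
    traits <- read_trait_table(config$inputs$traits, sample_ids = meta$sample_id)
  } else {
    abort("config needs either 'simulation' or 'inputs'")
  }
  contrast <- config$contrast
  if (is.null(contrast) || length(contrast) != 2L) {
    abort("config$contrast must be c(control, treated)")
  }
  hypothesis <- config$hypothesis %||% contrast[2]

  mfi <- collapse_to_mfi(beads, meta)
  mfi_f <- filter_low_mfi(mfi, threshold = mfi_threshold)

  anc <- anc_test(beads, meta, contrast = contrast, base_alpha = alpha,
                  interactions = mfi_f$interaction)

  mfi_log <- log2_transform(mfi_f)
  mfi_bc <- correct_batch_effects(mfi_log, meta)
  cna <- run_cna(mfi_bc, traits = traits, power = config$power,
                 min_size = min_size, cut_height_fraction = chf)

  hits <- intersect_hits(anc, cna, hypothesis = hypothesis, alpha = alpha)
  stopifnot(all(hits$interaction %in% anc$results$interaction[anc$results$hit]))

  log2fc <- compute_log2fc(mfi_f, meta, contrast[1], contrast[2])
  scaled <- scale_by_row_median(mfi_f)
  pca <- pca_samples(mfi_bc)
  tree <- hierarchical_cluster_samples(mfi_bc)
  activity <- NULL
  moi <- attr(hits, "modules_of_interest")
  if (length(moi) > 0) {
    members <- cna$modules$interaction[cna$modules$module == moi[1]]
    activity <- module_activity(scaled, members, meta)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("qminet")),
    parameters = list(alpha = alpha, mfi_threshold = mfi_threshold,
                      min_module_size = min_size,
                      cut_height_fraction = chf,
                      contrast = contrast, hypothesis = hypothesis,
                      seed = if (!is.null(sim_truth)) sim_truth$seed else NULL),
    n_interactions_measured = nrow(mfi),
    n_interactions_after_filter = nrow(mfi_f),
    alpha_used = anc$alpha_used,
    soft_power = cna$power,
    module_sizes = as.list(table(cna$modules$module)),
    modules_of_interest = as.list(moi),
    n_anc_hits = attr(hits, "n_anc_hits"),
    n_cna_hits = attr(hits, "n_cna_hits"),
    n_high_confidence = nrow(hits),
    high_confidence = as.list(hits$interaction)
  )

  out <- structure(list(beads = beads, metadata = meta, traits = traits,
                        truth = sim_truth, mfi = mfi, mfi_filtered = mfi_f,
                        anc = anc, cna = cna, hits = hits, log2fc = log2fc,
                        scaled = scaled, pca = pca, sample_tree = tree,
                        activity = activity, report = report),
                   class = "qmi_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' @export
print.qmi_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("# QMI pipeline: %d interactions (%d after MFI filter), ",
           "alpha* = %.3g, power = %d\n# ANC hits: %d | CNA hits: %d | ",
           "high-confidence: %d\n"),
    r$n_interactions_measured, r$n_interactions_after_filter, r$alpha_used,
    r$soft_power, r$n_anc_hits, r$n_cna_hits, r$n_high_confidence))
  invisible(x)
}

#' @rdname run_qmi_pipeline
#' @param pipeline A `qmi_pipeline` object.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline_artifacts <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  jsonlite::write_json(pipeline$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  write_mfi_matrix(pipeline$mfi_filtered, p("mfi.tsv"))
  write_anc_results(pipeline$anc, p("anc.tsv"))
  readr::write_tsv(tidy(pipeline$cna), p("modules.tsv"), progress = FALSE)
  if (!is.null(pipeline$cna$module_trait)) {
    readr::write_tsv(pipeline$cna$module_trait, p("module_trait.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(tibble::as_tibble(pipeline$hits), p("hits.tsv"),
                   progress = FALSE)
  export_edge_list(pipeline$hits, p("edges.tsv"))
  write_mfi_matrix(pipeline$scaled, p("scaled.tsv"))
  readr::write_tsv(tibble::as_tibble(pipeline$cna$eigenvectors,
                                     rownames = "sample_id"),
                   p("eigenvectors.tsv"), progress = FALSE)
  readr::write_tsv(pipeline$pca$scores, p("pca.tsv"), progress = FALSE)
  invisible(dir)
}
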