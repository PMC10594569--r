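#' Two-sample Kolmogorov-Smirnov comparison of bead distributions
#'
#' The statistic is the supremum absolute difference between the two empirical
#' CDFs, evaluated over the pooled step points (ties handled exactly). The
#' p-value comes from the asymptotic Kolmogorov distribution at effective
#' sample size \eqn{n_e = n_a n_b / (n_a + n_b)}, appropriate at bead-array
#' sample sizes (>= 50 reads per well).
#'
#' @param a,b Numeric vectors of fluorescence values (length >= 2, finite).
#' @return A list with `statistic` (D in \[0,1\]) and `p.value` (clamped to
#'   \[0,1\]).
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) abort("both samples need >= 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("non-finite values in input")
  D <- ks_statistic(a, b)
  n_e <- length(a) * length(b) / (length(a) + length(b))
  list(statistic = D, p.value = kolmogorov_sf(sqrt(n_e) * D))
}

# sup |F_a - F_b| over pooled step points; exact under ties. Computed on
# integer cumulative counts with a single final division, so the result is
# exact in floating point.
ks_statistic <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  pts <- sort(unique(c(a, b)))
  ca <- findInterval(pts, sort(a))
  cb <- findInterval(pts, sort(b))
  max(abs(ca * n_b - cb * n_a)) / (n_a * n_b)
}

# survival function of the Kolmogorov distribution, Q(lambda) = 2*sum (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda, k_max = 100L) {
  if (lambda <= 0) return(1)
  k <- seq_len(k_max)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Empirically calibrated multiple-comparison alpha
#'
#' Starts from the Bonferroni level `base_alpha / n_interactions` and checks it
#' against p-values from known-null comparisons (in this pipeline: technical
#' duplicate wells of the same sample). If more than `base_alpha` of the null
#' comparisons fall below the Bonferroni level — i.e. the nominal test is
#' anti-conservative on real assay noise — the cutoff is lowered to the
#' largest level at which the null exceedance fraction is at most
#' `base_alpha`, stepping through the sorted null p-values.
#'
#' @param null_pvalues Numeric vector of p-values from null comparisons (may
#'   be empty: falls back to the Bonferroni level).
#' @param n_interactions Number of interactions tested (multiplicity).
#' @param base_alpha Experiment-wise significance level, in (0,1).
#' @return The calibrated alpha, in `(0, base_alpha]`.
#' @export
empirical_alpha <- function(null_pvalues, n_interactions, base_alpha = 0.05) {
  if (base_alpha <= 0 || base_alpha >= 1) abort("base_alpha must be in (0,1)")
  if (n_interactions < 1L) abort("n_interactions must be >= 1")
  alpha_b <- base_alpha / n_interactions
  null_pvalues <- null_pvalues[is.finite(null_pvalues)]
  if (length(null_pvalues) == 0L) return(alpha_b)
  if (mean(null_pvalues <= alpha_b) <= base_alpha) return(alpha_b)
  p_sorted <- sort(null_pvalues)
  k <- floor(base_alpha * length(p_sorted))
  if (k < 1L) {
    warn("empirical alpha degenerate (every candidate level exceeded); using Bonferroni level")
    return(alpha_b)
  }
  # largest level whose null exceedance fraction stays within base_alpha
  cand <- p_sorted[k]
  while (k >= 1L && mean(null_pvalues <= cand) > base_alpha) {
    k <- k - 1L
    if (k >= 1L) cand <- p_sorted[k]
  }
  if (k < 1L) {
    warn("empirical alpha degenerate (tied null p-values); using Bonferroni level")
    return(alpha_b)
  }
  min(cand, alpha_b)
}

#' Adaptive nonparametric comparison (ANC) of matched bead distributions
#'
#' For every interaction and every matched control/treated pair (samples of
#' one biological replicate linked by `pair_key`), the duplicate-well bead
#' reads of each sample are pooled and the two distributions compared by
#' [ks_two_sample()]; the shift direction is the sign of the median
#' difference. The significance cutoff is calibrated by [empirical_alpha()]
#' on within-sample duplicate-well comparisons — true nulls present in every
#' experiment. An interaction is a hit when strictly more than
#' `consistency_threshold` (default 70%) of its pairs are significant *and*
#' agree with the modal direction of the significant pairs.
#'
#' @param beads Bead event table.
#' @param meta Sample metadata.
#' @param contrast Length-2 character vector `c(control, treated)`.
#' @param base_alpha Experiment-wise alpha before calibration (default 0.05).
#' @param consistency_threshold Strict lower bound on the consistent
#'   significant fraction (default 0.7).
#' @param interactions Optional character vector restricting the tested panel
#'   (e.g. the survivors of [filter_low_mfi()]).
#' @return A `qmi_anc` object; [tidy()] gives the per-interaction table
#'   (`statistic`/`p_values` as list columns, `f_consistent`, `hit`,
#'   `median_log2fc`, `direction`), [glance()] the run summary.
#' @export
anc_test <- function(beads, meta, contrast, base_alpha = 0.05,
                     consistency_threshold = 0.7, interactions = NULL) {
  beads <- validate_bead_events(beads)
  meta <- validate_sample_metadata(meta)
  if (length(contrast) != 2L) abort("contrast must be c(control, treated)")
  if (!all(contrast %in% meta$condition)) {
    abort(paste0("contrast condition absent from metadata: ",
                 paste(setdiff(contrast, meta$condition), collapse = ", ")))
  }
  if (!is.null(interactions)) {
    beads <- dplyr::filter(beads, .data$interaction %in% interactions)
  }

  msub <- dplyr::filter(meta, .data$condition %in% contrast)
  pairs <- msub |>
    dplyr::select("sample_id", "condition", "pair_key") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "sample_id")
  incomplete <- !complete.cases(pairs[contrast])
  if (any(incomplete)) {
    warn(sprintf("%d pair(s) missing one side of the contrast; skipped",
                 sum(incomplete)))
    pairs <- pairs[!incomplete, ]
  }
  if (nrow(pairs) < 2L) abort("need at least 2 complete matched pairs")
  control_ids <- pairs[[contrast[1]]]
  treated_ids <- pairs[[contrast[2]]]

  bsub <- dplyr::filter(beads, .data$sample_id %in% msub$sample_id)
  ids <- sort(unique(bsub$interaction))
  # pooled per (interaction, sample) and per-well bead vectors, built once
  by_sample <- split(bsub$fluorescence,
                     list(factor(bsub$interaction, ids),
                          factor(bsub$sample_id, msub$sample_id)), sep = "\r")
  by_well <- split(bsub$fluorescence,
                   paste(bsub$interaction, bsub$sample_id, bsub$well_id, sep = "\r"))
  well_key <- strsplit(names(by_well), "\r", fixed = TRUE)
  well_is <- vapply(well_key, function(k) paste(k[1], k[2], sep = "\r"), "")

  # null calibration: duplicate well vs duplicate well within each sample
  null_groups <- split(by_well, well_is)
  null_p <- vapply(null_groups, function(ws) {
    if (length(ws) < 2L) return(NA_real_)
    ks_two_sample(ws[[1]], ws[[2]])$p.value
  }, 0)
  null_p <- null_p[!is.na(null_p)]
  alpha_used <- empirical_alpha(null_p, n_interactions = length(ids),
                                base_alpha = base_alpha)

  # per-sample MFI (mean of duplicate-well medians) for the log2FC report
  well_medians <- vapply(by_well, median, 0)
  sample_mfi <- tapply(well_medians, well_is, mean)

  n_pairs <- length(control_ids)
  res <- purrr::map_dfr(ids, function(g) {
    p_vec <- d_vec <- lfc_vec <- numeric(n_pairs)
    dir_vec <- integer(n_pairs)
    for (j in seq_len(n_pairs)) {
      a <- by_sample[[paste(g, control_ids[j], sep = "\r")]]
      b <- by_sample[[paste(g, treated_ids[j], sep = "\r")]]
      ks <- ks_two_sample(a, b)
      d_vec[j] <- ks$statistic
      p_vec[j] <- ks$p.value
      dir_vec[j] <- sign(median(b) - median(a))
      lfc_vec[j] <- log2(sample_mfi[[paste(g, treated_ids[j], sep = "\r")]] /
                           sample_mfi[[paste(g, control_ids[j], sep = "\r")]])
    }
    sig <- p_vec <= alpha_used
    if (any(sig)) {
      tab <- table(dir_vec[sig])
      modal <- as.integer(names(tab)[which.max(tab)])
      f <- sum(sig & dir_vec == modal) / n_pairs
    } else {
      modal <- 0L
      f <- 0
    }
    tibble::tibble(
      interaction = g,
      n_pairs = n_pairs,
      statistic = list(d_vec),
      p_values = list(p_vec),
      directions = list(dir_vec),
      f_consistent = f,
      hit = f > consistency_threshold,
      direction = if (any(sig)) modal else sign(median(lfc_vec)),
      median_log2fc = median(lfc_vec)
    )
  })

  structure(list(results = res,
                 alpha_used = alpha_used,
                 base_alpha = base_alpha,
                 consistency_threshold = consistency_threshold,
                 n_comparisons = n_pairs,
                 n_interactions_tested = length(ids),
                 n_null_comparisons = length(null_p),
                 contrast = contrast),
            class = "qmi_anc")
}

#' @export
print.qmi_anc <- function(x, ...) {
  cat(sprintf(
    "# ANC: %s -> %s | %d interactions, %d matched pairs, alpha* = %.3g, %d hit(s)\n",
    x$contrast[1], x$contrast[2], x$n_interactions_tested, x$n_comparisons,
    x$alpha_used, sum(x$results$hit)))
  invisible(x)
}

#' @rdname anc_test
#' @param x A `qmi_anc` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qmi_anc <- function(x, ...) x$results

#' @rdname anc_test
#' @exportS3Method generics::glance
glance.qmi_anc <- function(x, ...) {
  tibble::tibble(alpha_used = x$alpha_used,
                 base_alpha = x$base_alpha,
                 n_comparisons = x$n_comparisons,
                 n_interactions_tested = x$n_interactions_tested,
                 n_null_comparisons = x$n_null_comparisons,
                 n_hits = sum(x$results$hit))
}

#' Write an ANC result table as TSV
#'
#' @param anc A `qmi_anc` object.
#' @param path Output path.
#' @export
write_anc_results <- function(anc, path) {
  out <- anc$results |>
    dplyr::mutate(alpha_used = anc$alpha_used,
                  p_values = vapply(.data$p_values,
                                    function(p) paste(signif(p, 6), collapse = ";"), ""),
                  statistic = vapply(.data$statistic,
                                     function(d) paste(signif(d, 6), collapse = ";"), ""),
                  directions = vapply(.data$directions,
                                      function(d) paste(d, collapse = ";"), "")) |>
    dplyr::select("interaction", "n_pairs", "f_consistent", "alpha_used",
                  "hit", "direction", "median_log2fc", "p_values",
                  "statistic", "directions")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
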