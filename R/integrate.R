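#' Intersect ANC and CNA hits into the high-confidence set
#'
#' Modules of interest are those whose eigenvector correlates with the chosen
#' hypothesis at `p < alpha`; CNA hits are interactions with membership
#' `p < alpha` (and positive kME) in a module of interest. Interactions called
#' by both ANC and CNA are the high-confidence set, reported with their
#' direction, median log2 fold change and module label.
#'
#' @param anc A `qmi_anc` object for the matching contrast.
#' @param cna A `qmi_cna` object fit with traits.
#' @param hypothesis Trait row name to define modules of interest.
#' @param alpha Significance level for both CNA gates (default 0.05).
#' @return A `qmi_hits` tibble: `interaction, ip, probe, module, direction,
#'   log2fc, anc_hit, cna_hit, self_interaction` (one row per high-confidence
#'   interaction; the evidence flags are all `TRUE` by construction).
#' @export
intersect_hits <- function(anc, cna, hypothesis, alpha = 0.05) {
  if (is.null(cna$module_trait)) abort("CNA fit has no module-trait table; run run_cna() with traits")
  if (nrow(cna$module_trait) > 0 &&
      !hypothesis %in% cna$module_trait$hypothesis) {
    abort(paste0("hypothesis not found in module-trait table: ", hypothesis))
  }
  moi <- cna$module_trait |>
    dplyr::filter(.data$hypothesis == !!hypothesis, .data$p < alpha) |>
    dplyr::pull("module")
  cna_hits <- cna$membership |>
    dplyr::filter(.data$module %in% moi, .data$p < alpha, .data$kME > 0) |>
    dplyr::group_by(.data$interaction) |>
    dplyr::slice_max(.data$kME, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  anc_tab <- dplyr::filter(anc$results, .data$hit)
  out <- dplyr::inner_join(
    dplyr::select(anc_tab, "interaction", "direction",
                  log2fc = "median_log2fc"),
    dplyr::select(cna_hits, "interaction", "module", kME_p = "p"),
    by = "interaction") |>
    dplyr::mutate(ip = sub("_.*$", "", .data$interaction),
                  probe = sub("^.*_", "", .data$interaction),
                  self_interaction = .data$ip == .data$probe,
                  anc_hit = TRUE, cna_hit = TRUE) |>
    dplyr::select("interaction", "ip", "probe", "module", "direction",
                  "log2fc", "kME_p", "self_interaction", "anc_hit", "cna_hit")
  class(out) <- c("qmi_hits", class(out))
  attr(out, "hypothesis") <- hypothesis
  attr(out, "modules_of_interest") <- moi
  attr(out, "n_anc_hits") <- nrow(anc_tab)
  attr(out, "n_cna_hits") <- length(unique(cna_hits$interaction))
  out
}

#' Log2 fold change between two conditions
#'
#' `log2(mean MFI in condition_b / mean MFI in condition_a)` per interaction,
#' on group means of per-sample linear-scale MFI.
#'
#' @param mfi Linear-scale `qmi_mfi`.
#' @param meta Sample metadata.
#' @param condition_a Reference condition (denominator).
#' @param condition_b Comparison condition (numerator).
#' @return Tibble `(interaction, log2fc)`.
#' @export
compute_log2fc <- function(mfi, meta, condition_a, condition_b) {
  if (mfi_scale(mfi) != "linear") abort("compute_log2fc expects linear-scale MFI")
  meta <- validate_sample_metadata(meta)
  v <- mfi_values(mfi)
  sa <- meta$sample_id[meta$condition == condition_a]
  sb <- meta$sample_id[meta$condition == condition_b]
  if (length(sa) == 0L || length(sb) == 0L) abort("both conditions must have samples")
  ma <- rowMeans(v[, sa, drop = FALSE])
  mb <- rowMeans(v[, sb, drop = FALSE])
  if (any(ma <= 0) || any(mb <= 0)) abort("non-positive group mean MFI")
  tibble::tibble(interaction = rownames(v), log2fc = unname(log2(mb / ma)))
}

#' Median-scale an MFI matrix by row
#'
#' Divides each interaction row by its across-sample median, yielding the
#' "median scaled values" used for heatmaps and module-activity summaries:
#' every row has median exactly 1 and rows become comparable regardless of
#' baseline MFI.
#'
#' @param mfi Linear-scale `qmi_mfi` with positive values.
#' @return A `qmi_mfi`-like scaled tibble; the row medians are attached as
#'   attribute `row_medians` so scaling is invertible.
#' @export
scale_by_row_median <- function(mfi) {
  if (mfi_scale(mfi) != "linear") abort("scale_by_row_median expects linear-scale MFI")
  v <- mfi_values(mfi)
  med <- apply(v, 1L, median)
  if (any(med <= 0)) abort("zero or negative row median")
  out <- new_qmi_mfi(v / med, scale = "linear")
  attr(out, "row_medians") <- setNames(med, rownames(v))
  out
}

#' Module activity summary with ANOVA and Bonferroni post hoc tests
#'
#' Per-sample activity is the mean scaled value of the module's member
#' interactions. Differences across condition groups are tested by one-way
#' ANOVA followed by pairwise Welch t tests with Bonferroni correction over
#' the tested pairs.
#'
#' @param scaled Output of [scale_by_row_median()].
#' @param members Character vector of member interaction ids.
#' @param meta Sample metadata.
#' @param group Metadata column defining the groups (default `"condition"`).
#' @return A `qmi_activity` object; [tidy()] returns the post hoc table,
#'   [glance()] the ANOVA row; `$activity` holds the per-sample scores.
#' @export
module_activity <- function(scaled, members, meta, group = "condition") {
  meta <- validate_sample_metadata(meta)
  v <- mfi_values(scaled)
  missing <- setdiff(members, rownames(v))
  if (length(missing) > 0) abort(paste0("unknown member(s): ", paste(missing, collapse = ", ")))
  act <- colMeans(v[members, , drop = FALSE])
  tab <- tibble::tibble(sample_id = names(act), activity = unname(act)) |>
    dplyr::left_join(meta[c("sample_id", group)], by = "sample_id") |>
    dplyr::rename(group = dplyr::all_of(group))
  if (dplyr::n_distinct(tab$group) < 2L) abort("need >= 2 groups")

  fit <- aov(activity ~ group, data = tab)
  an <- summary(fit)[[1]]
  anova_row <- tibble::tibble(statistic = an[["F value"]][1],
                              p.value = an[["Pr(>F)"]][1],
                              df_between = an[["Df"]][1],
                              df_within = an[["Df"]][2])

  sizes <- table(tab$group)
  usable <- names(sizes)[sizes >= 2L]
  if (length(usable) < length(sizes)) {
    warn(paste0("group(s) with < 2 samples excluded from post hoc tests: ",
                paste(setdiff(names(sizes), usable), collapse = ", ")))
  }
  posthoc <- NULL
  if (length(usable) >= 2L) {
    pairs_m <- combn(sort(usable), 2L)
    posthoc <- purrr::map_dfr(seq_len(ncol(pairs_m)), function(j) {
      g1 <- pairs_m[1, j]; g2 <- pairs_m[2, j]
      tt <- t.test(tab$activity[tab$group == g1], tab$activity[tab$group == g2])
      tibble::tibble(group1 = g1, group2 = g2,
                     estimate = mean(tab$activity[tab$group == g2]) -
                       mean(tab$activity[tab$group == g1]),
                     statistic = unname(tt$statistic), p.value = tt$p.value)
    })
    posthoc$p.adjusted <- pmin(1, posthoc$p.value * nrow(posthoc))
  }
  structure(list(activity = tab, anova = anova_row, posthoc = posthoc,
                 members = members),
            class = "qmi_activity")
}

#' @export
print.qmi_activity <- function(x, ...) {
  cat(sprintf("# module activity: %d member(s), ANOVA F = %.3g, p = %.3g\n",
              length(x$members), x$anova$statistic, x$anova$p.value))
  invisible(x)
}

#' @rdname module_activity
#' @param x A `qmi_activity` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qmi_activity <- function(x, ...) {
  if (is.null(x$posthoc)) return(tibble::tibble())
  x$posthoc
}

#' @rdname module_activity
#' @exportS3Method generics::glance
glance.qmi_activity <- function(x, ...) x$anova

#' PCA of samples from a log2 MFI matrix
#'
#' Rows (interactions) are centered and sample scores are taken from the
#' singular value decomposition of the centered matrix (via [stats::prcomp()]
#' on the transposed matrix).
#'
#' @param mfi A `qmi_mfi`, normally log2 scale.
#' @return A `qmi_pca` object: `scores` tibble (sample, PC columns),
#'   `var_explained` (fractions summing to 1), and the `prcomp` fit.
#' @export
pca_samples <- function(mfi) {
  v <- mfi_values(mfi)
  if (ncol(v) < 3L) abort("need >= 3 samples")
  pr <- prcomp(t(v), center = TRUE, scale. = FALSE)
  var_explained <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- tibble::as_tibble(pr$x, rownames = "sample_id")
  structure(list(scores = scores, var_explained = var_explained, fit = pr),
            class = "qmi_pca")
}

#' @export
print.qmi_pca <- function(x, ...) {
  cat(sprintf("# sample PCA: %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * (x$var_explained[2] %||% 0)))
  invisible(x)
}

#' @rdname pca_samples
#' @param x A `qmi_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qmi_pca <- function(x, ...) x$scores

#' @rdname pca_samples
#' @exportS3Method generics::glance
glance.qmi_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_explained),
                 var_explained = x$var_explained)
}

#' Average-linkage clustering of samples on correlation distance
#'
#' Distance between samples is `1 - Pearson` over interaction profiles;
#' agglomeration is average linkage. Samples are ordered lexicographically
#' before clustering so ties resolve deterministically.
#'
#' @param mfi A `qmi_mfi`, normally log2 scale.
#' @return An `hclust` object.
#' @export
hierarchical_cluster_samples <- function(mfi) {
  v <- mfi_values(mfi)
  if (ncol(v) < 3L) abort("need >= 3 samples")
  v <- v[, order(colnames(v)), drop = FALSE]
  const <- apply(v, 2L, sd) == 0
  if (any(const)) {
    abort(paste0("constant sample profile(s): ",
                 paste(colnames(v)[const], collapse = ", ")))
  }
  d <- as.dist(1 - cor(v))
  hclust(d, method = "average")
}

#' Export a high-confidence set as a Cytoscape-compatible edge list
#'
#' TSV with columns `source` (IP), `target` (probe), `log2fc`, `direction`,
#' `module`, `self_interaction`. Self-edges (IP = probe) are apparent
#' abundance proxies; they are retained and flagged.
#'
#' @param hits A `qmi_hits` tibble from [intersect_hits()].
#' @param path Output TSV path.
#' @export
export_edge_list <- function(hits, path) {
  out <- tibble::tibble(source = hits$ip, target = hits$probe,
                        log2fc = hits$log2fc, direction = hits$direction,
                        module = hits$module,
                        self_interaction = hits$self_interaction)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname export_edge_list
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
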