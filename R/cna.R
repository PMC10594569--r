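#' Standard module color sequence
#'
#' Modules are labeled by arbitrary color names in decreasing size order, the
#' convention of weighted correlation network analysis; `"grey"` is reserved
#' for unassigned interactions.
#'
#' @param n Number of labels needed.
#' @return Character vector of length `n`.
#' @export
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "skyblue", "saddlebrown",
            "steelblue", "paleturquoise", "violet", "darkolivegreen",
            "darkmagenta")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("module%d", seq_len(n - length(base))))
}

# interaction-by-interaction |Pearson| with constant profiles mapped to 0
abs_cor_matrix <- function(values) {
  const <- apply(values, 1L, sd) == 0
  if (any(const)) {
    warn(paste0("constant interaction profile(s), correlations set to 0: ",
                paste(head(rownames(values)[const], 5L), collapse = ", ")))
  }
  r <- suppressWarnings(abs(cor(t(values))))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency \eqn{a_{ij} = |cor(x_i,
#' x_j)|^\beta} is formed and the connectivity distribution \eqn{k_i =
#' \sum_{j \ne i} a_{ij}} is tested for approximate scale-freeness: k is
#' binned (10 equal-width bins over its range), and the mean log10 frequency
#' is regressed on the mean log10 connectivity per bin. The signed fit index
#' is \eqn{-sign(slope) \cdot R^2}. The chosen power is the smallest one whose
#' signed fit reaches `rsq_cut`, falling back to the maximizing power.
#'
#' @param mfi A `qmi_mfi` (log2, batch-corrected recommended).
#' @param powers Candidate integer powers (default 1:20).
#' @param rsq_cut Signed-R^2 threshold (default 0.8).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return A `qmi_sft` list with `power` and the `fit_table` tibble
#'   (`power`, `fit_signed_r2`, `slope`, `mean_k`, `max_k`).
#' @export
pick_soft_threshold <- function(mfi, powers = 1:20, rsq_cut = 0.8, n_bins = 10) {
  v <- mfi_values(mfi)
  if (ncol(v) < 8L) abort("need >= 8 samples to estimate scale-free fit")
  if (nrow(v) < 10L) abort("need >= 10 interactions")
  r <- abs_cor_matrix(v)
  fit <- purrr::map_dfr(powers, function(b) {
    a <- r^b
    k <- colSums(a) - 1  # exclude the diagonal
    sf <- scale_free_fit(k, n_bins = n_bins)
    tibble::tibble(power = b, fit_signed_r2 = sf$signed_r2, slope = sf$slope,
                   mean_k = mean(k), max_k = max(k))
  })
  if (all(is.na(fit$fit_signed_r2))) {
    warn("scale-free fit undefined (degenerate connectivity); using default power 6")
    power <- 6L
  } else {
    ok <- which(!is.na(fit$fit_signed_r2) & fit$fit_signed_r2 >= rsq_cut)
    power <- if (length(ok) > 0) fit$power[ok[1]] else
      fit$power[which.max(fit$fit_signed_r2)]
  }
  structure(list(power = as.integer(power), fit_table = fit, rsq_cut = rsq_cut),
            class = "qmi_sft")
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins || diff(range(k)) == 0) {
    return(list(signed_r2 = NA_real_, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  p_k <- tabulate(bin, nbins = n_bins) / length(k)
  keep <- !is.na(dk) & p_k > 0 & dk > 0
  if (sum(keep) < 3L) return(list(signed_r2 = NA_real_, slope = NA_real_))
  f <- lm(log10(p_k[keep]) ~ log10(dk[keep]))
  r2 <- summary(f)$r.squared
  slope <- coef(f)[[2]]
  list(signed_r2 = -sign(slope) * r2, slope = slope)
}

#' @export
print.qmi_sft <- function(x, ...) {
  cat(sprintf("# soft threshold: power = %d (signed R^2 cut %.2f)\n",
              x$power, x$rsq_cut))
  print(x$fit_table)
  invisible(x)
}

#' Unsigned power adjacency of interaction profiles
#'
#' @param mfi A `qmi_mfi`.
#' @param power Soft-threshold power (>= 1).
#' @return A `qmi_network` list: `adjacency` (symmetric, \[0,1\], zero
#'   diagonal), `connectivity` \eqn{k_i}, and `power`.
#' @export
compute_adjacency <- function(mfi, power) {
  if (power < 1) abort("power must be >= 1")
  v <- mfi_values(mfi)
  a <- abs_cor_matrix(v)^power
  diag(a) <- 0  # the diagonal never contributes to connectivity or overlap
  structure(list(adjacency = a, connectivity = colSums(a),
                 power = as.integer(power)),
            class = "qmi_network")
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
#' \quad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},}
#' with unit diagonal. Two interactions overlap strongly when they share the
#' same network neighbours even if their direct correlation is modest.
#'
#' @param network A `qmi_network` from [compute_adjacency()], or a plain
#'   symmetric adjacency matrix in \[0,1\] (zero or unit diagonal).
#' @return Symmetric matrix in \[0,1\] with unit diagonal.
#' @export
compute_tom <- function(network) {
  a <- if (inherits(network, "qmi_network")) network$adjacency else as.matrix(network)
  if (!isSymmetric(unname(a))) abort("adjacency must be symmetric")
  diag(a) <- 0
  if (any(a < 0 | a > 1)) abort("adjacency entries must lie in [0,1]")
  k <- colSums(a)
  l <- a %*% a            # with zero diagonal this is exactly sum over u != i,j
  min_k <- outer(k, k, pmin)
  tom <- (l + a) / pmax(min_k + 1 - a, 1e-12)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by average-linkage clustering of topological overlap
#'
#' Interactions are clustered on the dissimilarity `1 - TOM` with
#' average-linkage agglomeration; the tree is cut statically at
#' `cut_height_fraction` of the maximum merge height. Clusters smaller than
#' `min_size` become `"grey"` (unassigned); the rest are labeled by
#' decreasing size with the standard color sequence.
#'
#' @param tom TOM matrix from [compute_tom()].
#' @param min_size Minimum module size (>= 2).
#' @param cut_height_fraction Static cut height as a fraction of the tallest
#'   merge (default 0.9).
#' @return A tibble `(interaction, module)` with the `hclust` tree attached
#'   as attribute `tree`.
#' @export
detect_modules <- function(tom, min_size = 5, cut_height_fraction = 0.9) {
  if (min_size < 2) abort("min_size must be >= 2")
  ids <- rownames(tom) %||% sprintf("i%d", seq_len(nrow(tom)))
  tree <- hclust(as.dist(1 - tom), method = "average")
  # merge heights at floating-point noise mean "everything identical"
  cl <- if (max(tree$height) > 1e-10) {
    cutree(tree, h = cut_height_fraction * max(tree$height))
  } else rep(1L, nrow(tom))
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  # decreasing size; ties broken by cluster index for determinism
  big <- big[order(-sizes[big], as.integer(big))]
  labels <- setNames(rep("grey", length(sizes)), names(sizes))
  labels[big] <- module_colors(length(big))
  out <- tibble::tibble(interaction = ids, module = unname(labels[as.character(cl)]))
  attr(out, "tree") <- tree
  out
}

#' Module eigenvector (eigengene)
#'
#' The first right singular vector of the z-scored member-by-sample matrix:
#' the unit-norm per-sample score that captures the maximal variance of the
#' standardized member profiles. The sign is oriented so the mean Pearson
#' correlation with member profiles is positive (ties: positive first
#' coordinate).
#'
#' @param mfi A `qmi_mfi`.
#' @param members Character vector of member interaction ids.
#' @return Named numeric vector of per-sample scores, unit norm.
#' @export
module_eigenvector <- function(mfi, members) {
  v <- mfi_values(mfi)
  missing <- setdiff(members, rownames(v))
  if (length(missing) > 0) abort(paste0("unknown member(s): ", paste(missing, collapse = ", ")))
  x <- v[members, , drop = FALSE]
  if (ncol(x) < 3L) abort("need >= 3 samples")
  const <- apply(x, 1L, sd) == 0
  if (any(const)) {
    warn(paste0("dropping constant member profile(s): ",
                paste(rownames(x)[const], collapse = ", ")))
    x <- x[!const, , drop = FALSE]
    if (nrow(x) == 0L) abort("no non-constant member profiles")
  }
  z <- t(scale(t(x)))
  sv <- svd(z)
  e <- sv$v[, 1]
  mc <- mean(suppressWarnings(cor(e, t(x))), na.rm = TRUE)
  if (isTRUE(mc < 0) || (isTRUE(abs(mc) < 1e-12) && e[1] < 0)) e <- -e
  setNames(e, colnames(v))
}

# two-sided p for a Pearson correlation via the t transform
cor_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t_stat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(t_stat), df = n - 2)
  p
}

#' Module-trait correlation table
#'
#' Pearson correlation of each module eigenvector with each coded hypothesis,
#' with the two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom.
#'
#' @param eigenvectors Samples-by-modules matrix (or the `eigenvectors`
#'   element of a [run_cna()] fit).
#' @param traits Trait table (see [read_trait_table()]).
#' @return Tibble `(module, hypothesis, r, p)`.
#' @export
module_trait_correlation <- function(eigenvectors, traits) {
  traits <- validate_trait_table(traits)
  e <- as.matrix(eigenvectors)
  n <- nrow(e)
  if (n < 4L) abort("need >= 4 samples")
  tv <- as.matrix(traits[setdiff(names(traits), "hypothesis")])
  rownames(tv) <- traits$hypothesis
  tv <- tv[, rownames(e), drop = FALSE]
  r <- cor(e, t(tv))  # modules x hypotheses
  tidyr::expand_grid(module = colnames(e), hypothesis = traits$hypothesis) |>
    dplyr::mutate(r = as.vector(t(r)),
                  p = cor_pvalue(.data$r, n))
}

#' Module membership (kME) table
#'
#' kME is the Pearson correlation between an interaction profile and a module
#' eigenvector; its p-value uses the same t transform as
#' [module_trait_correlation()]. The CNA hit set for a module are the
#' interactions with `p < alpha` and `kME > 0`.
#'
#' @param mfi A `qmi_mfi`.
#' @param eigenvectors Samples-by-modules matrix.
#' @return Tibble `(interaction, module, kME, p)` over all pairs.
#' @export
module_membership <- function(mfi, eigenvectors) {
  v <- mfi_values(mfi)
  e <- as.matrix(eigenvectors)
  n <- ncol(v)
  r <- suppressWarnings(cor(t(v), e[colnames(v), , drop = FALSE]))
  r[!is.finite(r)] <- 0
  tidyr::expand_grid(interaction = rownames(v), module = colnames(e)) |>
    dplyr::mutate(kME = as.vector(t(r)),
                  p = cor_pvalue(.data$kME, n))
}

#' Weighted correlation network analysis of an MFI matrix
#'
#' Runs the full CNA chain: soft-threshold selection ([pick_soft_threshold()]),
#' power adjacency, topological overlap, module detection, module
#' eigenvectors, module membership, and (when `traits` is given) module-trait
#' correlation.
#'
#' @param mfi A `qmi_mfi`, normally log2-scale and batch-corrected.
#' @param traits Optional trait table.
#' @param power Soft power; `NULL` (default) selects it by scale-free fit.
#' @param min_size,cut_height_fraction Module detection parameters, see
#'   [detect_modules()].
#' @param powers,rsq_cut Passed to [pick_soft_threshold()].
#' @return A `qmi_cna` object with elements `modules`, `eigenvectors`
#'   (samples x modules), `membership`, `module_trait`, `power`, `fit_table`,
#'   `tree`. [tidy()] returns the per-interaction module/kME table,
#'   [glance()] a one-row summary.
#' @export
run_cna <- function(mfi, traits = NULL, power = NULL, min_size = 5,
                    cut_height_fraction = 0.9, powers = 1:20, rsq_cut = 0.8) {
  if (mfi_scale(mfi) == "linear") {
    inform("run_cna received linear-scale MFI; proceeding (log2 batch-corrected input is the default pipeline)")
  }
  fit_table <- NULL
  if (is.null(power)) {
    sft <- pick_soft_threshold(mfi, powers = powers, rsq_cut = rsq_cut)
    power <- sft$power
    fit_table <- sft$fit_table
  }
  net <- compute_adjacency(mfi, power)
  tom <- compute_tom(net)
  modules <- detect_modules(tom, min_size = min_size,
                            cut_height_fraction = cut_height_fraction)
  mods <- setdiff(unique(modules$module), "grey")
  mods <- mods[order(match(mods, module_colors(length(mods) + 5L)))]
  if (length(mods) > 0) {
    eig <- vapply(mods, function(m) {
      module_eigenvector(mfi, modules$interaction[modules$module == m])
    }, numeric(length(mfi_samples(mfi))))
    eig <- matrix(eig, ncol = length(mods),
                  dimnames = list(mfi_samples(mfi), mods))
  } else {
    eig <- matrix(numeric(0), nrow = length(mfi_samples(mfi)), ncol = 0,
                  dimnames = list(mfi_samples(mfi), NULL))
  }
  membership <- if (length(mods) > 0) module_membership(mfi, eig) else
    tibble::tibble(interaction = character(), module = character(),
                   kME = numeric(), p = numeric())
  module_trait <- if (is.null(traits)) NULL else if (length(mods) > 0) {
    module_trait_correlation(eig, traits)
  } else {
    tibble::tibble(module = character(), hypothesis = character(),
                   r = numeric(), p = numeric())
  }

  structure(list(modules = modules, eigenvectors = eig,
                 membership = membership, module_trait = module_trait,
                 power = power, fit_table = fit_table,
                 tree = attr(modules, "tree")),
            class = "qmi_cna")
}

#' @export
print.qmi_cna <- function(x, ...) {
  sz <- table(x$modules$module)
  cat(sprintf("# CNA: power %d, %d module(s): %s\n", x$power,
              sum(names(sz) != "grey"),
              paste(sprintf("%s(%d)", names(sz), sz), collapse = ", ")))
  invisible(x)
}

#' @rdname run_cna
#' @param x A `qmi_cna` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qmi_cna <- function(x, ...) {
  own <- dplyr::filter(x$membership,
                       .data$module == x$modules$module[
                         match(.data$interaction, x$modules$interaction)])
  dplyr::left_join(x$modules, own, by = c("interaction", "module"))
}

#' @rdname run_cna
#' @exportS3Method generics::glance
glance.qmi_cna <- function(x, ...) {
  sz <- table(x$modules$module)
  tibble::tibble(power = x$power,
                 n_modules = sum(names(sz) != "grey"),
                 n_grey = sum(x$modules$module == "grey"),
                 n_interactions = nrow(x$modules))
}
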