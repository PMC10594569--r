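# deterministic multi-module expression fixture: block-correlated profiles
block_mfi <- function(n_blocks = 2, block_size = 10, n_samples = 12,
                      noise = 0, seed = 1) {
  set.seed(seed)
  signals <- matrix(rnorm(n_blocks * n_samples), n_blocks, n_samples)
  rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    matrix(rep(signals[b, ], each = block_size), block_size, n_samples) +
      if (noise > 0) matrix(rnorm(block_size * n_samples, 0, noise),
                            block_size, n_samples) else 0
  }))
  dimnames(rows) <- list(sprintf("B%d_I%02d", rep(seq_len(n_blocks), each = block_size),
                                 rep(seq_len(block_size), n_blocks)),
                         sprintf("s%02d", seq_len(n_samples)))
  new_qmi_mfi(rows + 15, scale = "log2")
}

test_that("power-1 adjacency is |correlation| and the hand-computed case holds", {
  m <- rbind(x = c(1, 2, 3), y = c(1, 2, 4), z = c(3, 2, 1))
  dimnames(m) <- list(c("x", "y", "z"), c("s1", "s2", "s3"))
  mfi <- new_qmi_mfi(m, scale = "log2")
  net1 <- compute_adjacency(mfi, 1)
  expect_equal(net1$adjacency["x", "y"], abs(cor(c(1, 2, 3), c(1, 2, 4))))
  expect_equal(net1$adjacency["x", "z"], 1)  # perfect anticorrelation, unsigned
  net6 <- compute_adjacency(mfi, 6)
  expect_equal(net6$adjacency["x", "y"], 0.897, tolerance = 5e-4)
  expect_equal(net6$adjacency["x", "z"], 1)
  # symmetry and range
  expect_true(isSymmetric(net6$adjacency))
  expect_true(all(net6$adjacency >= 0 & net6$adjacency <= 1))
})

test_that("constant profiles get zero correlations with a warning", {
  m <- rbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2), b = c(4, 1, 3, 2))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(net <- compute_adjacency(new_qmi_mfi(m, scale = "log2"), 2),
                 "constant")
  expect_equal(net$adjacency["flat", "a"], 0)
  expect_equal(net$adjacency["flat", "b"], 0)
})

test_that("TOM matches its closed forms on complete and empty graphs", {
  for (n in 3:6) {
    ones <- matrix(1, n, n)
    tom <- compute_tom(ones)
    expect_equal(tom, matrix(1, n, n))
  }
  zeros <- matrix(0, 5, 5)
  tom0 <- compute_tom(zeros)
  expect_equal(tom0, diag(5))
})

test_that("TOM equals the triple-loop oracle on random networks", {
  set.seed(2)
  for (i in 1:50) {
    a <- matrix(runif(64), 8, 8)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- compute_tom(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1))
  }
})

test_that("module detection separates correlation blocks and labels by size", {
  mfi <- block_mfi(n_blocks = 2, block_size = 10)
  tom <- compute_tom(compute_adjacency(mfi, 6))
  mods <- detect_modules(tom)
  expect_setequal(unique(mods$module), c("turquoise", "blue"))
  split_by_block <- split(mods$module, sub("_.*", "", mods$interaction))
  expect_true(all(vapply(split_by_block, function(x) length(unique(x)) == 1L,
                         TRUE)))
  # three blocks of different sizes: colors follow decreasing size
  m3 <- rbind(mfi_values(block_mfi(1, 14, seed = 3)),
              mfi_values(block_mfi(1, 9, seed = 4)) + 5,
              mfi_values(block_mfi(1, 6, seed = 5)) - 5)
  rownames(m3) <- sprintf("i%02d", 1:29)
  tom3 <- compute_tom(compute_adjacency(new_qmi_mfi(m3, scale = "log2"), 6))
  mods3 <- detect_modules(tom3)
  expect_equal(as.integer(table(mods3$module)[c("turquoise", "blue", "brown")]),
               c(14L, 9L, 6L))
})

test_that("identical profiles give one module; min_size > n gives all grey", {
  one <- matrix(rep(rnorm(10), each = 8), 8, 10,
                dimnames = list(paste0("i", 1:8), paste0("s", 1:10)))
  mfi <- new_qmi_mfi(one + 20, scale = "log2")
  tom <- compute_tom(compute_adjacency(mfi, 6))
  mods <- detect_modules(tom, min_size = 5)
  expect_equal(unique(mods$module), "turquoise")
  mods2 <- detect_modules(tom, min_size = 9)
  expect_equal(unique(mods2$module), "grey")
  expect_error(detect_modules(tom, min_size = 1), "min_size")
})

test_that("module eigenvector matches the SVD oracle and its invariants", {
  set.seed(11)
  m <- matrix(rnorm(6 * 12), 6, 12,
              dimnames = list(paste0("i", 1:6), paste0("s", 1:12)))
  mfi <- new_qmi_mfi(m, scale = "log2")
  e <- module_eigenvector(mfi, paste0("i", 1:6))
  z <- t(scale(t(m)))
  sv <- svd(z)
  ref <- sv$v[, 1]
  if (mean(cor(ref, t(m))) < 0) ref <- -ref
  expect_equal(unname(e), ref, tolerance = 1e-10)
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
  # maximal-variance property among random unit vectors
  var_e <- sum((z %*% e)^2)
  for (k in 1:25) {
    u <- rnorm(12); u <- u / sqrt(sum(u^2))
    expect_lte(sum((z %*% u)^2), var_e + 1e-8)
  }
  # shared profile: eigenvector proportional to it
  shared <- matrix(rep(rnorm(12), each = 4), 4, 12,
                   dimnames = list(paste0("j", 1:4), paste0("s", 1:12)))
  es <- module_eigenvector(new_qmi_mfi(shared + 9, scale = "log2"),
                           paste0("j", 1:4))
  zprof <- as.vector(scale(shared[1, ]))
  expect_equal(unname(es), zprof / sqrt(sum(zprof^2)), tolerance = 1e-10)
  # single member: z-scored normalized profile; orientation positive
  e1 <- module_eigenvector(mfi, "i3")
  expect_gt(cor(e1, m[3, ]), 0.999)
})

test_that("correlation p-values follow the t transform and its monotonicity", {
  ns <- c(10, 28, 50)
  rs <- seq(0.05, 0.95, by = 0.1)
  for (n in ns) {
    p <- qminet:::cor_pvalue(rs, n)
    expect_true(all(diff(p) < 0))            # decreasing in |r|
    t_ref <- rs * sqrt((n - 2) / (1 - rs^2))
    expect_equal(p, 2 * pt(-t_ref, n - 2), tolerance = 1e-12)
  }
  for (r in c(0.3, 0.6, 0.9)) {
    p_by_n <- vapply(ns, function(n) qminet:::cor_pvalue(r, n), 0)
    expect_true(all(diff(p_by_n) < 0))       # decreasing in n
  }
  expect_equal(qminet:::cor_pvalue(1, 10), 0)
  expect_equal(qminet:::cor_pvalue(-1, 10), 0)
})

test_that("module-trait correlation reproduces exact and boundary cases", {
  n <- 28
  set.seed(21)
  z1 <- as.vector(scale(rnorm(n)))
  raw <- rnorm(n)
  e2 <- as.vector(scale(residuals(lm(raw ~ z1))))
  r_target <- 0.83
  eig <- matrix(r_target * z1 + sqrt(1 - r_target^2) * e2, ncol = 1,
                dimnames = list(sprintf("s%02d", 1:n), "red"))
  # e3 is orthogonal to span(z1, e2), hence exactly uncorrelated with eig
  e3 <- as.vector(scale(residuals(lm(rnorm(n) ~ z1 + e2))))
  traits <- dplyr::bind_cols(
    tibble::tibble(hypothesis = c("time_since_refeeding", "orthogonal", "identical")),
    tibble::as_tibble(rbind(z1, e3, as.vector(eig)) |>
                        `colnames<-`(rownames(eig))))
  mt <- module_trait_correlation(eig, traits)
  r_time <- mt$r[mt$hypothesis == "time_since_refeeding"]
  p_time <- mt$p[mt$hypothesis == "time_since_refeeding"]
  expect_equal(r_time, 0.83, tolerance = 1e-12)
  expect_gt(p_time, 2e-8)
  expect_lt(p_time, 1e-7)
  expect_equal(mt$r[mt$hypothesis == "orthogonal"], 0, tolerance = 1e-12)
  expect_equal(mt$p[mt$hypothesis == "orthogonal"], 1, tolerance = 1e-12)
  expect_equal(mt$r[mt$hypothesis == "identical"], 1, tolerance = 1e-12)
  expect_equal(mt$p[mt$hypothesis == "identical"], 0)
})

test_that("module membership equals the direct correlation oracle", {
  mfi <- block_mfi(n_blocks = 1, block_size = 5, noise = 0.5, seed = 31)
  e <- module_eigenvector(mfi, mfi$interaction)
  memb <- module_membership(mfi, matrix(e, ncol = 1,
                                        dimnames = list(names(e), "turquoise")))
  v <- mfi_values(mfi)
  for (k in seq_len(nrow(memb))) {
    expect_equal(memb$kME[k], cor(v[memb$interaction[k], ], e),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(memb$kME) <= 1))
  # profile equal to the eigenvector: kME = 1, p = 0
  v2 <- rbind(v, exact = e)
  memb2 <- module_membership(new_qmi_mfi(v2, scale = "log2"),
                             matrix(e, ncol = 1,
                                    dimnames = list(names(e), "turquoise")))
  expect_equal(memb2$kME[memb2$interaction == "exact"], 1, tolerance = 1e-12)
  expect_equal(memb2$p[memb2$interaction == "exact"], 0)
})

test_that("soft-threshold selection matches an independent fit recomputation", {
  sim <- simulate_qmi(recovery_config(1))
  mfi <- collapse_to_mfi(sim$beads, sim$metadata) |>
    filter_low_mfi() |> log2_transform()
  bc <- correct_batch_effects(mfi, sim$metadata)
  sft <- pick_soft_threshold(bc, powers = 1:12)
  # independent recomputation of the signed scale-free fit per power
  v <- mfi_values(bc)
  r <- abs(cor(t(v)))
  refit <- vapply(1:12, function(b) {
    a <- r^b
    k <- colSums(a) - 1
    breaks <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, breaks, include.lowest = TRUE)
    dk <- tapply(k, bin, mean)
    pk <- as.vector(table(bin)) / length(k)
    keep <- !is.na(dk) & pk > 0 & dk > 0
    f <- lm(log10(pk[keep]) ~ log10(dk[keep]))
    -sign(coef(f)[[2]]) * summary(f)$r.squared
  }, 0)
  expect_equal(sft$fit_table$fit_signed_r2, unname(refit), tolerance = 1e-10)
  chosen_ref <- if (any(refit >= 0.8)) which(refit >= 0.8)[1] else which.max(refit)
  expect_equal(sft$power, chosen_ref)
  # beta = 1 adjacency is |cor|
  expect_equal(compute_adjacency(bc, 1)$adjacency[2, 5], r[2, 5])
})

test_that("degenerate inputs fall back to the default power with a warning", {
  one <- matrix(rep(rnorm(10), each = 12), 12, 10,
                dimnames = list(paste0("i", 1:12), paste0("s", 1:10)))
  mfi <- new_qmi_mfi(one + 20, scale = "log2")
  expect_warning(sft <- pick_soft_threshold(mfi), "default power")
  expect_equal(sft$power, 6L)
})

test_that("run_cna assembles a coherent fit and planted modules are recovered", {
  sim <- simulate_qmi(recovery_config(5))
  bc <- collapse_to_mfi(sim$beads, sim$metadata) |>
    filter_low_mfi() |> log2_transform() |>
    correct_batch_effects(sim$metadata)
  cna <- suppressWarnings(run_cna(bc, traits = sim$traits, power = 6))
  truth <- ifelse(is.na(sim$truth$module$module), "none",
                  sim$truth$module$module)
  det <- cna$modules$module[match(sim$truth$module$interaction,
                                  cna$modules$interaction)]
  expect_gte(mclust::adjustedRandIndex(truth, det), 0.8)
  # eigenvectors unit-norm, membership of own module positive
  expect_equal(colSums(cna$eigenvectors^2), rep(1, ncol(cna$eigenvectors)),
               tolerance = 1e-10, ignore_attr = TRUE)
  own <- tidy(cna) |> dplyr::filter(module != "grey")
  expect_true(all(own$kME > 0))
  # each planted module's trait row is significant for its condition
  mt <- cna$module_trait
  for (cond in c("c2", "c3", "c4")) {
    expect_true(any(mt$p[mt$hypothesis == cond] < 0.05))
  }
  g <- glance(cna)
  expect_equal(g$n_modules, 3L)
})
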