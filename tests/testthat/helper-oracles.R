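# Independent brute-force oracles used across tests. These deliberately use
# different code paths (ecdf(), triple loops, naive agglomeration) than the
# package implementation.

# sup |F_a - F_b| over all pooled ECDF step points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
}

# topological overlap by direct triple-loop summation
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- colSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# naive O(n^3) average-linkage agglomeration; returns sorted merge heights
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_h)
  }
  sort(heights)
}

# all multisets of size k over values 0:3, as count vectors (c0,c1,c2,c3)
all_multisets_0to3 <- function(k) {
  g <- expand.grid(c0 = 0:k, c1 = 0:k, c2 = 0:k, c3 = 0:k)
  as.matrix(g[rowSums(g) == k, , drop = FALSE])
}

counts_to_values <- function(counts) rep(0:3, times = counts)

# small bead table with explicit per-well values for constructed ANC cases
make_bead_table <- function(well_values) {
  # well_values: named list  "<sample>|<well>" -> numeric vector, one interaction
  rows <- lapply(names(well_values), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    tibble::tibble(sample_id = parts[1], well_id = paste0(parts[1], "_", parts[2]),
                   batch_id = "b1", ip = "A", probe = "B",
                   fluorescence = well_values[[key]])
  })
  dplyr::bind_rows(rows)
}

make_meta <- function(sample_ids, conditions, replicates = NULL, batches = "b1") {
  n <- length(sample_ids)
  if (is.null(replicates)) replicates <- paste0("r", seq_len(n))
  tibble::tibble(sample_id = sample_ids,
                 biological_replicate_id = replicates,
                 condition = conditions,
                 batch_id = rep_len(batches, n),
                 technical_duplicate_index = 1L,
                 pair_key = replicates)
}

# metadata + matrix fixture for batch-correction tests
make_batch_fixture <- function(G = 100, n_per_batch = 32, noise_sd = 0.08,
                               batch_offset = 0.5, batch_scale = 1.5,
                               cond_effect = 0.5, n_affected = 30, seed = 42) {
  n_affected <- min(n_affected, G)
  set.seed(seed)
  n <- 2 * n_per_batch
  batch <- rep(c("b1", "b2"), each = n_per_batch)
  cond <- rep(rep_len(c("ctl", "trt"), n_per_batch), 2)
  base <- runif(G, 8, 12)
  noise <- matrix(rnorm(G * n, 0, noise_sd), G, n)
  noise[, batch == "b2"] <- noise[, batch == "b2"] * batch_scale
  m <- base + noise
  if (n_affected > 0) {
    m[seq_len(n_affected), cond == "trt"] <-
      m[seq_len(n_affected), cond == "trt"] + cond_effect
  }
  m[, batch == "b2"] <- m[, batch == "b2"] + batch_offset
  dimnames(m) <- list(sprintf("I%03d", seq_len(G)), sprintf("s%02d", seq_len(n)))
  meta <- make_meta(colnames(m), cond, batches = batch)
  list(log2_mfi = new_qmi_mfi(2^m, scale = "linear") |> log2_transform(),
       meta = meta, batch = batch, cond = cond,
       n_affected = n_affected, cond_effect = cond_effect)
}

# standard planted-module recovery fixture: 3 modules with distinct
# condition-response patterns among background noise
recovery_config <- function(seed) {
  mods <- list(list(members = 1:10, effects = c(c2 = 0.5), label = "m1"),
               list(members = 11:19, effects = c(c3 = 0.5), label = "m2"),
               list(members = 20:31, effects = c(c4 = 0.5), label = "m3"))
  simulation_config(n_interactions = 60, conditions = c("c1", "c2", "c3", "c4"),
                    n_replicates = 10, planted_modules = mods, seed = seed)
}

# two trait-linked modules for end-to-end recovery
e2e_config <- function(seed, null = FALSE) {
  mods <- if (null) list() else
    list(list(members = 1:10, effects = c(refed = 0.5), label = "m1"),
         list(members = 11:20, effects = c(refed = 0.5), label = "m2"))
  simulation_config(n_interactions = 120, n_replicates = 8,
                    planted_modules = mods, seed = seed)
}

run_e2e <- function(seed, null = FALSE) {
  cfg <- e2e_config(seed, null = null)
  suppressWarnings(suppressMessages(
    run_qmi_pipeline(list(simulation = cfg, contrast = c("starved", "refed")))))
}
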