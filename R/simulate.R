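#' Configure a synthetic QMI experiment
#'
#' Defines the generative model for bead-level data with known ground truth.
#' Per interaction g a baseline MFI \eqn{\mu_g} is drawn log-uniformly over
#' `baseline_mfi_range`. The expected level of interaction g in sample s
#' (condition c, biological replicate r, batch b) is
#' \deqn{m = \mu_g \cdot 2^{e_{g,c}} \cdot \rho_{g,r} \cdot \beta_{g,b},}
#' with replicate multiplier \eqn{\rho \sim} LogNormal(0, sd from
#' `replicate_cv`) and batch multiplier \eqn{\beta \sim} LogNormal(0,
#' `batch_sigma` \eqn{\cdot \ln 2}). Every sample is measured in two
#' technical-duplicate wells carrying a shared per-well pipetting multiplier
#' (LogNormal, `duplicate_cv`); each well draws a uniform-integer number of
#' beads in `beads_per_well`, and each bead fluorescence is LogNormal with
#' arithmetic mean m and coefficient of variation `bead_cv`. Matched design:
#' each biological replicate contributes exactly one sample per condition,
#' linked by `pair_key`, and is assigned whole to one batch (replicates split
#' evenly across batches so batch never confounds condition).
#'
#' Defaults mirror the assay this generator emulates: a panel of 384
#' `IP_probe` interactions read 50-150 beads per well in duplicate, baselines
#' spanning 150-20,000 fluorescence units, and planted per-condition log2
#' effects in the 0.1-0.5 range typical of acute signaling rewiring.
#'
#' @param n_interactions Panel size (default 384).
#' @param conditions Ordered condition labels; the first is the reference
#'   (zero planted effect).
#' @param n_replicates Biological replicates per condition (default 8).
#' @param beads_per_well Integer range, beads per interaction per well.
#' @param baseline_mfi_range Range of baseline MFI, sampled log-uniformly.
#' @param bead_cv,replicate_cv,duplicate_cv Coefficients of variation of
#'   bead-level, replicate-level and duplicate-well noise.
#' @param n_batches Number of batches replicates are split across.
#' @param batch_sigma Log2 standard deviation of per-interaction batch
#'   multipliers.
#' @param planted_modules List of `list(members =, effects =)` entries:
#'   `members` are interaction indices, `effects` a named numeric vector of
#'   per-condition log2 effects (conditions not named get 0).
#' @param trait_codes Optional named list of extra hypotheses: each a named
#'   numeric vector keyed by condition (e.g. minutes since refeeding).
#' @param seed Default RNG seed used by [simulate_qmi()] when none is given.
#' @return A `qmi_sim_config` list.
#' @export
simulation_config <- function(n_interactions = 384,
                              conditions = c("starved", "refed"),
                              n_replicates = 8,
                              beads_per_well = c(50, 150),
                              baseline_mfi_range = c(150, 20000),
                              bead_cv = 0.30,
                              replicate_cv = 0.10,
                              duplicate_cv = 0.05,
                              n_batches = 2,
                              batch_sigma = 0.25,
                              planted_modules = list(),
                              trait_codes = NULL,
                              seed = 1L) {
  cfg <- list(n_interactions = as.integer(n_interactions),
              conditions = as.character(conditions),
              n_replicates = as.integer(n_replicates),
              beads_per_well = as.integer(beads_per_well),
              baseline_mfi_range = as.numeric(baseline_mfi_range),
              bead_cv = bead_cv, replicate_cv = replicate_cv,
              duplicate_cv = duplicate_cv,
              n_batches = as.integer(n_batches),
              batch_sigma = batch_sigma,
              planted_modules = planted_modules,
              trait_codes = trait_codes,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_interactions < 1L) abort("n_interactions must be >= 1")
  if (length(cfg$conditions) < 2L) abort("need at least two conditions")
  if (anyDuplicated(cfg$conditions)) abort("duplicate condition labels")
  if (cfg$n_replicates < 1L) abort("n_replicates must be >= 1")
  if (length(cfg$beads_per_well) != 2L || any(cfg$beads_per_well < 1L) ||
      cfg$beads_per_well[1] > cfg$beads_per_well[2]) {
    abort("beads_per_well must be an increasing positive integer pair")
  }
  if (any(cfg$baseline_mfi_range <= 0) ||
      cfg$baseline_mfi_range[1] > cfg$baseline_mfi_range[2]) {
    abort("baseline_mfi_range must be positive and increasing")
  }
  if (any(c(cfg$bead_cv, cfg$replicate_cv, cfg$duplicate_cv, cfg$batch_sigma) < 0)) {
    abort("all CVs and batch_sigma must be >= 0")
  }
  if (cfg$n_batches < 1L) abort("n_batches must be >= 1")
  seen <- integer(0)
  for (pm in cfg$planted_modules) {
    if (!all(c("members", "effects") %in% names(pm))) {
      abort("each planted module needs 'members' and 'effects'")
    }
    if (any(pm$members < 1L | pm$members > cfg$n_interactions)) {
      abort("planted module member index out of range")
    }
    if (any(pm$members %in% seen)) abort("planted modules must be disjoint")
    if (!all(is.finite(pm$effects))) abort("planted effects must be finite")
    if (!all(names(pm$effects) %in% cfg$conditions)) {
      abort("planted effect names must be conditions")
    }
    seen <- c(seen, pm$members)
  }
  structure(cfg, class = "qmi_sim_config")
}

# lognormal sdlog giving coefficient of variation cv
cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

#' Simulate a QMI experiment with known ground truth
#'
#' Draws a full bead-level experiment from the generative model described in
#' [simulation_config()]. The same config and seed always give bit-identical
#' output. The trait table carries one 0/1 hypothesis per non-reference
#' condition plus any `trait_codes` hypotheses from the config.
#'
#' @param config A `qmi_sim_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `qmi_simulation` list with elements `beads`, `metadata`,
#'   `traits` and `truth`. `truth` records the planted module of every
#'   interaction, the expected per-condition log2 effects, and all nuisance
#'   multipliers actually drawn.
#' @export
simulate_qmi <- function(config, seed = NULL) {
  cfg <- validate_sim_config(config)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  G <- cfg$n_interactions
  conds <- cfg$conditions
  R <- cfg$n_replicates
  interactions <- sprintf("P%03d_Q%03d", seq_len(G), seq_len(G))

  effects <- matrix(0, G, length(conds), dimnames = list(interactions, conds))
  module_of <- rep(NA_character_, G)
  for (i in seq_along(cfg$planted_modules)) {
    pm <- cfg$planted_modules[[i]]
    lab <- pm$label %||% paste0("planted", i)
    module_of[pm$members] <- lab
    for (cn in names(pm$effects)) effects[pm$members, cn] <- pm$effects[[cn]]
  }

  mu <- exp(runif(G, log(cfg$baseline_mfi_range[1]), log(cfg$baseline_mfi_range[2])))
  rho <- matrix(rlnorm(G * R, 0, cv_to_sdlog(cfg$replicate_cv)), G, R)
  beta <- matrix(rlnorm(G * cfg$n_batches, 0, cfg$batch_sigma * log(2)),
                 G, cfg$n_batches)

  meta <- tidyr::expand_grid(replicate = seq_len(R), condition = conds) |>
    dplyr::mutate(
      sample_id = sprintf("r%02d_%s", .data$replicate, .data$condition),
      biological_replicate_id = sprintf("r%02d", .data$replicate),
      batch_id = sprintf("b%d", (.data$replicate - 1L) %% cfg$n_batches + 1L),
      technical_duplicate_index = 1L,
      pair_key = .data$biological_replicate_id
    )
  S <- nrow(meta)

  # per (sample, well) pipetting multiplier shared across the panel
  dup <- matrix(rlnorm(S * 2L, 0, cv_to_sdlog(cfg$duplicate_cv)), S, 2L)

  wells <- tidyr::expand_grid(s = seq_len(S), w = 1:2, g = seq_len(G))
  n_beads <- if (cfg$beads_per_well[1] == cfg$beads_per_well[2]) {
    rep(cfg$beads_per_well[1], nrow(wells))
  } else {
    sample(cfg$beads_per_well[1]:cfg$beads_per_well[2], nrow(wells), replace = TRUE)
  }
  cond_idx <- match(meta$condition, conds)
  rep_idx <- meta$replicate
  batch_idx <- as.integer(sub("^b", "", meta$batch_id))
  m_expected <- mu[wells$g] *
    2^effects[cbind(wells$g, cond_idx[wells$s])] *
    rho[cbind(wells$g, rep_idx[wells$s])] *
    beta[cbind(wells$g, batch_idx[wells$s])] *
    dup[cbind(wells$s, wells$w)]

  sdlog <- cv_to_sdlog(cfg$bead_cv)
  meanlog <- log(m_expected) - sdlog^2 / 2
  fl <- rlnorm(sum(n_beads), rep(meanlog, n_beads), sdlog)

  idx <- rep(seq_len(nrow(wells)), n_beads)
  beads <- tibble::tibble(
    sample_id = meta$sample_id[wells$s][idx],
    well_id = sprintf("%s_w%d", meta$sample_id[wells$s], wells$w)[idx],
    batch_id = meta$batch_id[wells$s][idx],
    ip = sub("_.*$", "", interactions[wells$g])[idx],
    probe = sub("^.*_", "", interactions[wells$g])[idx],
    fluorescence = fl,
    interaction = interactions[wells$g][idx]
  )

  traits <- build_traits(meta, conds, cfg$trait_codes)

  truth <- list(
    seed = seed,
    interactions = interactions,
    module = tibble::tibble(interaction = interactions, module = module_of),
    effects = tibble::as_tibble(effects, rownames = "interaction"),
    baseline_mfi = tibble::tibble(interaction = interactions, mu = mu),
    replicate_multipliers = tibble::as_tibble(
      `dimnames<-`(rho, list(interactions, sprintf("r%02d", seq_len(R)))),
      rownames = "interaction"),
    batch_multipliers = tibble::as_tibble(
      `dimnames<-`(beta, list(interactions, sprintf("b%d", seq_len(cfg$n_batches)))),
      rownames = "interaction"),
    duplicate_multipliers = tibble::tibble(
      sample_id = rep(meta$sample_id, 2L),
      well = rep(1:2, each = S),
      multiplier = as.vector(dup))
  )

  structure(list(beads = beads,
                 metadata = validate_sample_metadata(
                   meta[c("sample_id", "biological_replicate_id", "condition",
                          "batch_id", "technical_duplicate_index", "pair_key")]),
                 traits = traits,
                 truth = truth,
                 config = cfg),
            class = "qmi_simulation")
}

build_traits <- function(meta, conds, trait_codes) {
  rows <- lapply(conds[-1], function(cn) as.numeric(meta$condition == cn))
  names(rows) <- conds[-1]
  if (!is.null(trait_codes)) {
    for (hn in names(trait_codes)) {
      code <- trait_codes[[hn]]
      rows[[hn]] <- as.numeric(code[meta$condition])
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- meta$sample_id
  traits <- dplyr::bind_cols(tibble::tibble(hypothesis = names(rows)),
                             tibble::as_tibble(m))
  validate_trait_table(traits, sample_ids = meta$sample_id)
}

#' @rdname simulate_qmi
#' @details `simulate_null()` strips all planted effects from the config, so
#'   the truth records zero expected log2 effect everywhere.
#' @export
simulate_null <- function(config, seed = NULL) {
  cfg <- validate_sim_config(config)
  cfg$planted_modules <- list()
  simulate_qmi(cfg, seed = seed)
}

#' @export
print.qmi_simulation <- function(x, ...) {
  cat(sprintf(
    "# simulated QMI experiment: %d interactions, %d samples (%s), %d bead reads\n",
    x$config$n_interactions, nrow(x$metadata),
    paste(x$config$conditions, collapse = "/"), nrow(x$beads)))
  invisible(x)
}

#' Serialize / restore simulation ground truth
#'
#' @param truth The `truth` element of a [simulate_qmi()] result.
#' @param path JSON file path.
#' @export
write_simulation_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_simulation_truth
#' @export
read_simulation_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("module", "effects", "baseline_mfi", "replicate_multipliers",
               "batch_multipliers", "duplicate_multipliers")) {
    x[[nm]] <- tibble::as_tibble(x[[nm]])
  }
  x$seed <- as.integer(x$seed)
  x
}
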