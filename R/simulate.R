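#' Configuration for a synthetic decay-array experiment
#'
#' Describes the generative model behind the synthetic serum experiments:
#' each sample `j` of group `g` in batch `i` yields, for compound `c`, a
#' true half-lifetime
#'
#' `T = t_half[g] * effect(c, g) * exp(eps) + group_delta[g] + batch_offsets[i]`
#'
#' with `eps ~ Normal(0, sigma_log^2)` drawn per well. Compound effects are
#' multiplicative on the half-life (additive in log space); batch offsets
#' are additive minutes on the feature, matching the additive baseline model
#' the correction stage assumes. Decay traces are emitted from the one-phase
#' model `amplitude * exp(-ln(2) t / T) + plateau` with multiplicative
#' Gaussian intensity noise.
#'
#' @param n_per_group Named integer vector of samples per group
#'   (default `c(AD = 31, HC = 37)`).
#' @param n_batches Number of batches; samples are assigned round-robin
#'   within each group so every batch contains every group.
#' @param n_compounds Library size (default 96, up to 1024).
#' @param t_half Named per-group baseline half-lifetimes in minutes
#'   (default `c(HC = 13.15, AD = 11.18)`: healthy serum kinetics, with the
#'   case group decaying faster).
#' @param flag_compounds Planted flag compounds: either a count (the first
#'   so many compound ids) or a character vector of ids. Default 12.
#' @param flag_effect Multiplicative half-life effect of a flag compound in
#'   the `flag_group` (default 2).
#' @param flag_group Group carrying the flag effect (default `"AD"`).
#' @param balanced_flags If `TRUE`, split each flag effect symmetrically in
#'   log space (`sqrt(effect)` in `flag_group`, `1/sqrt(effect)` elsewhere)
#'   so the planted log effects sum to zero.
#' @param group_delta Named additive per-group offsets in minutes
#'   (default all 0); the zero-sum additive mode used by the exactness
#'   checks of the batch correction.
#' @param batch_offsets Additive per-batch baseline offsets in minutes
#'   (default evenly spaced on `[-1, 1]`; 0 for a single batch).
#' @param sigma_log SD of the per-well log-half-life perturbation
#'   (default 0.05).
#' @param trace_noise SD of the multiplicative intensity noise as a fraction
#'   of the signal (default 0.02).
#' @param t_grid Acquisition times in minutes
#'   (default `seq(5, 180, by = 5)`).
#' @param amplitude_range,plateau_range Uniform ranges for per-well
#'   amplitude and plateau (arbitrary units).
#' @param n_replicates Wells per (sample, compound), default 3.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = c(AD = 31L, HC = 37L),
                              n_batches = 2L,
                              n_compounds = 96L,
                              t_half = c(HC = 13.15, AD = 11.18),
                              flag_compounds = 12L,
                              flag_effect = 2,
                              flag_group = "AD",
                              balanced_flags = FALSE,
                              group_delta = NULL,
                              batch_offsets = NULL,
                              sigma_log = 0.05,
                              trace_noise = 0.02,
                              t_grid = seq(5, 180, by = 5),
                              amplitude_range = c(800, 1200),
                              plateau_range = c(20, 60),
                              n_replicates = 3L) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups)))
    stop("n_per_group must be named by group label")
  if (!all(groups %in% names(t_half)))
    stop("t_half must name every group in n_per_group")
  if (any(t_half[groups] <= 0)) stop("baseline half-lives must be positive")
  if (n_compounds < 1L || n_compounds > 1024L)
    stop("n_compounds must lie in [1, 1024]")
  compound_ids <- sprintf("C%04d", seq_len(n_compounds))
  if (is.numeric(flag_compounds) && length(flag_compounds) == 1L) {
    if (flag_compounds > n_compounds)
      stop("more flag compounds than compounds")
    flag_compounds <- compound_ids[seq_len(flag_compounds)]
  } else {
    flag_compounds <- as.character(flag_compounds)
    if (!all(flag_compounds %in% compound_ids))
      stop("unknown flag compound id(s)")
  }
  if (flag_effect <= 0) stop("flag_effect must be positive")
  if (!flag_group %in% groups) stop("flag_group must be one of the groups")
  if (is.null(group_delta)) group_delta <- stats::setNames(rep(0, length(groups)), groups)
  if (!all(groups %in% names(group_delta)))
    stop("group_delta must name every group")
  if (is.null(batch_offsets))
    batch_offsets <- if (n_batches == 1L) 0 else seq(-1, 1, length.out = n_batches)
  if (length(batch_offsets) != n_batches)
    stop("batch_offsets must have one entry per batch")
  if (sigma_log < 0 || trace_noise < 0) stop("noise SDs must be >= 0")
  if (length(t_grid) < 4L || any(diff(t_grid) <= 0) || any(t_grid < 0))
    stop("t_grid must be >= 4 strictly increasing non-negative times")
  structure(list(n_per_group = n_per_group, groups = groups,
                 n_batches = as.integer(n_batches),
                 n_compounds = as.integer(n_compounds),
                 compound_ids = compound_ids,
                 t_half = t_half[groups],
                 flag_compounds = flag_compounds,
                 flag_effect = flag_effect, flag_group = flag_group,
                 balanced_flags = isTRUE(balanced_flags),
                 group_delta = group_delta[groups],
                 batch_offsets = as.numeric(batch_offsets),
                 sigma_log = sigma_log, trace_noise = trace_noise,
                 t_grid = as.numeric(t_grid),
                 amplitude_range = amplitude_range,
                 plateau_range = plateau_range,
                 n_replicates = as.integer(n_replicates)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic decay-array configuration\n")
  cat("  samples:", paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                          collapse = ", "),
      " batches:", x$n_batches, " compounds:", x$n_compounds, "\n")
  cat(sprintf("  flags: %d at effect %.3g in %s%s; sigma_log %.3g, trace noise %.3g\n",
              length(x$flag_compounds), x$flag_effect, x$flag_group,
              if (x$balanced_flags) " (balanced)" else "",
              x$sigma_log, x$trace_noise))
  invisible(x)
}

# Per-group multiplicative effect of a compound on the half-life.
.compound_effect <- function(config, compound, group) {
  if (!compound %in% config$flag_compounds) return(1)
  f <- config$flag_effect
  if (config$balanced_flags) {
    if (group == config$flag_group) sqrt(f) else 1 / sqrt(f)
  } else {
    if (group == config$flag_group) f else 1
  }
}

.sample_table <- function(config) {
  rows <- list()
  for (g in config$groups) {
    n <- config$n_per_group[[g]]
    ids <- sprintf("%s%03d", g, seq_len(n))
    batch <- sprintf("b%02d", rep_len(seq_len(config$n_batches), n))
    rows[[g]] <- data.frame(sample_id = ids, group = g, batch_id = batch)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sample_metadata", "data.frame")
  out
}

.true_half_life <- function(config, group, compound, eps) {
  batchless <- config$t_half[[group]] *
    .compound_effect(config, compound, group) * exp(eps) +
    config$group_delta[[group]]
  batchless
}

#' Simulate a complete plate-level experiment
#'
#' Generates decay traces well by well from the configured ground truth:
#' every (sample, compound) cell gets `n_replicates` wells plus baseline
#' (no-compound) wells per sample, each with its own log-normal half-life
#' perturbation, uniform amplitude and plateau, and multiplicative intensity
#' noise. All randomness derives from `seed`; the same seed reproduces the
#' experiment byte for byte when written to disk.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, `plate.csv`,
#'   `metadata.csv` and `truth.json` are written there.
#' @return A list of class `synthetic_experiment`: `records`
#'   (a `well_records` plate), `metadata` (a `sample_metadata` table) and
#'   `truth` (per-well true half-lives plus the planted flag set, batch
#'   offsets and group parameters).
#' @export
simulate_experiment <- function(config, seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  meta <- .sample_table(config)
  compounds <- c(config$compound_ids, BASELINE_COMPOUND)
  n_wells <- nrow(meta) * length(compounds) * config$n_replicates
  records <- vector("list", n_wells)
  tw_well <- tw_sample <- tw_compound <- character(n_wells)
  tw_rep <- integer(n_wells)
  tw_half <- numeric(n_wells)
  idx <- 0L
  for (s in seq_len(nrow(meta))) {
    g <- meta$group[[s]]
    off <- config$batch_offsets[[match(meta$batch_id[[s]],
                                       sprintf("b%02d", seq_len(config$n_batches)))]]
    for (cmp in compounds) {
      for (r in seq_len(config$n_replicates)) {
        eps <- if (config$sigma_log > 0) stats::rnorm(1, 0, config$sigma_log) else 0
        T_true <- .true_half_life(config, g, cmp, eps) + off
        if (!is.finite(T_true) || T_true <= 0)
          stop("configuration yields a non-positive half-life (",
               format(T_true), " min) for sample ", meta$sample_id[[s]],
               ", compound ", cmp)
        A <- stats::runif(1, config$amplitude_range[[1L]],
                          config$amplitude_range[[2L]])
        p <- stats::runif(1, config$plateau_range[[1L]],
                          config$plateau_range[[2L]])
        I <- A * exp(-log(2) * config$t_grid / T_true) + p
        if (config$trace_noise > 0)
          I <- I * (1 + stats::rnorm(length(I), 0, config$trace_noise))
        idx <- idx + 1L
        plate <- (idx - 1L) %/% 96L + 1L
        pos <- (idx - 1L) %% 96L
        well <- sprintf("P%04d-%s%02d", plate, LETTERS[pos %/% 12L + 1L],
                        pos %% 12L + 1L)
        records[[idx]] <- new_well_record(well, meta$sample_id[[s]], cmp, r,
                                          config$t_grid, I)
        tw_well[idx] <- well; tw_sample[idx] <- meta$sample_id[[s]]
        tw_compound[idx] <- cmp; tw_rep[idx] <- r; tw_half[idx] <- T_true
      }
    }
  }
  records <- structure(records, class = "well_records")
  truth <- list(wells = data.frame(well_id = tw_well, sample_id = tw_sample,
                                   compound_id = tw_compound,
                                   replicate = tw_rep,
                                   true_half_life = tw_half),
                flag_compounds = config$flag_compounds,
                batch_offsets = stats::setNames(
                  config$batch_offsets,
                  sprintf("b%02d", seq_len(config$n_batches))),
                t_half = config$t_half,
                group_delta = config$group_delta,
                flag_effect = config$flag_effect,
                flag_group = config$flag_group,
                seed = seed)
  out <- structure(list(records = records, metadata = meta, truth = truth),
                   class = "synthetic_experiment")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_plate(records, file.path(dir, "plate.csv"))
    write_metadata(meta, file.path(dir, "metadata.csv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic decay-array experiment\n")
  print(x$records)
  cat("Planted flags:", length(x$truth$flag_compounds),
      " batches:", length(x$truth$batch_offsets), "\n")
  invisible(x)
}

#' Simulate a half-life feature matrix directly
#'
#' Emits the samples x compounds half-life matrix straight from the
#' generative model, skipping trace synthesis and curve fitting — the fast
#' path for statistical tests of the correction and classification stages.
#' In the zero-trace-noise limit the result is distributionally identical to
#' fitting the simulated plates. One log-perturbation is drawn per
#' (sample, compound) cell.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_features`: `features`
#'   (a `feature_matrix`), `metadata`, and `truth` (cell-level expected
#'   half-lives and planted parameters).
#' @export
simulate_feature_matrix <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  meta <- .sample_table(config)
  x <- matrix(NA_real_, nrow(meta), config$n_compounds,
              dimnames = list(meta$sample_id, config$compound_ids))
  expected <- x
  for (s in seq_len(nrow(meta))) {
    g <- meta$group[[s]]
    off <- config$batch_offsets[[match(meta$batch_id[[s]],
                                       sprintf("b%02d", seq_len(config$n_batches)))]]
    for (ci in seq_len(config$n_compounds)) {
      cmp <- config$compound_ids[[ci]]
      eps <- if (config$sigma_log > 0) stats::rnorm(1, 0, config$sigma_log) else 0
      v <- .true_half_life(config, g, cmp, eps) + off
      if (!is.finite(v) || v <= 0)
        stop("configuration yields a non-positive half-life for sample ",
             meta$sample_id[[s]], ", compound ", cmp)
      x[s, ci] <- v
      expected[s, ci] <- .true_half_life(config, g, cmp, 0) + off
    }
  }
  structure(list(features = feature_matrix(x, meta$group, meta$batch_id),
                 metadata = meta,
                 truth = list(expected = expected,
                              flag_compounds = config$flag_compounds,
                              batch_offsets = stats::setNames(
                                config$batch_offsets,
                                sprintf("b%02d", seq_len(config$n_batches))),
                              t_half = config$t_half,
                              group_delta = config$group_delta,
                              seed = seed)),
            class = "synthetic_features")
}

#' @export
print.synthetic_features <- function(x, ...) {
  cat("Synthetic half-life feature matrix\n")
  print(x$features)
  invisible(x)
}
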