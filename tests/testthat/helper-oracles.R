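# Shared fixtures and independent oracles for the test suite.

default_grid <- seq(5, 180, by = 5)

# Noiseless (or multiplicatively noisy) one-phase decay trace.
make_trace <- function(half_life, amplitude = 1000, plateau = 0,
                       times = default_grid, noise_frac = 0) {
  I <- amplitude * exp(-log(2) * times / half_life) + plateau
  if (noise_frac > 0) I <- I * (1 + rnorm(length(I), 0, noise_frac))
  list(times = times, intensities = I)
}

# Brute-force decay oracle: grid search over the rate; for each candidate k
# the amplitude and plateau solve a linear least-squares problem, so the
# oracle only scans one dimension. Independent of the package's optimizer.
oracle_decay_fit <- function(times, intensities, k_min = 1e-4, k_max = 1,
                             k_step = 1e-4) {
  ks <- seq(k_min, k_max, by = k_step)
  best <- list(sse = Inf)
  for (k in ks) {
    e <- exp(-k * times)
    fit <- stats::lm.fit(cbind(e, 1), intensities)
    sse <- sum(fit$residuals^2)
    if (sse < best$sse)
      best <- list(k = k, amplitude = fit$coefficients[[1L]],
                   plateau = fit$coefficients[[2L]], sse = sse)
  }
  best
}

# Brute-force AUC: average over all positive-negative pairs, ties counted
# as one half.
oracle_auc <- function(truth_pos, scores) {
  pos <- scores[truth_pos]; neg <- scores[!truth_pos]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Long-format plate data frame for IO tests.
plate_df <- function(n_wells = 4, times = default_grid, half_life = 20) {
  do.call(rbind, lapply(seq_len(n_wells), function(i) {
    tr <- make_trace(half_life, times = times)
    data.frame(well_id = sprintf("%s%d", LETTERS[(i - 1) %/% 12 + 1],
                                 (i - 1) %% 12 + 1),
               sample_id = sprintf("s%02d", (i - 1) %/% 2 + 1),
               compound_id = sprintf("C%02d", i),
               replicate = 1L,
               time_min = tr$times, intensity = tr$intensities)
  }))
}
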