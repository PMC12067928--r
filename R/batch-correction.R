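#' Construct a half-life feature matrix
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   compounds in columns (colnames = compound ids); half-lifetimes in
#'   minutes (or batch-corrected differences).
#' @param group Character vector of group labels, one per sample.
#' @param batch Character vector of batch ids, one per sample.
#' @return A list of class `feature_matrix` with `values`, `group`, `batch`.
#' @export
feature_matrix <- function(values, group, batch) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  if (length(group) != nrow(values) || length(batch) != nrow(values))
    stop("group and batch must have one entry per sample (row)")
  if (anyNA(values))
    stop("feature matrix must not contain missing values")
  structure(list(values = values,
                 group = stats::setNames(as.character(group), rownames(values)),
                 batch = stats::setNames(as.character(batch), rownames(values))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Half-life feature matrix: %d samples x %d compounds\n",
              nrow(x$values), ncol(x$values)))
  cat("Groups:", paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                       collapse = ", "), "\n")
  cat("Batches:", paste(unique(x$batch), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a feature matrix from plate fits and metadata
#'
#' Builds the samples x compounds matrix of replicate-averaged
#' half-lifetimes. Samples with a failed or missing fit in any requested
#' compound are excluded and reported via a warning and the `excluded`
#' attribute, so the matrix is complete.
#'
#' @param fits Fit table from [fit_plate()].
#' @param metadata A `sample_metadata` table covering every sample.
#' @param compounds Compound ids to keep (default: all non-baseline
#'   compounds present).
#' @return A `feature_matrix`.
#' @export
assemble_features <- function(fits, metadata, compounds = NULL) {
  agg <- .mean_half_lives(fits)
  agg <- agg[agg$compound_id != BASELINE_COMPOUND, , drop = FALSE]
  if (is.null(compounds)) compounds <- sort(unique(agg$compound_id))
  agg <- agg[agg$compound_id %in% compounds, , drop = FALSE]
  samples <- sort(unique(agg$sample_id))
  m <- matrix(NA_real_, length(samples), length(compounds),
              dimnames = list(samples, compounds))
  m[cbind(agg$sample_id, agg$compound_id)] <- agg$half_life
  complete <- !apply(m, 1L, anyNA)
  if (!all(complete))
    warning("excluding sample(s) with failed fits in panel compounds: ",
            paste(samples[!complete], collapse = ", "))
  m <- m[complete, , drop = FALSE]
  unknown <- setdiff(rownames(m), metadata$sample_id)
  if (length(unknown))
    stop("sample(s) missing from metadata: ", paste(unknown, collapse = ", "))
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  out <- feature_matrix(m, meta$group, meta$batch_id)
  attr(out, "excluded") <- samples[!complete]
  out
}

#' Estimate per-batch baselines from anchor groups
#'
#' Under the additive model `x_ij = mu_i + Delta_g + eps_ij`, with the
#' convention `Delta_HC + Delta_AD = 0` and zero-mean noise, the batch
#' baseline is identified as half the sum of the control-group and
#' case-group means within the batch, computed per compound. Every batch
#' must therefore contain at least one sample of each anchor group;
#' otherwise the estimator is undefined and the batch is rejected.
#'
#' @param X A `feature_matrix`.
#' @param case,control Anchor group labels (defaults `"AD"`, `"HC"`).
#' @return An object of class `batch_model`: list with `mu` (batches x
#'   compounds matrix of baselines, minutes), `case`, `control` and the
#'   recorded zero-sum group-effect convention.
#' @export
estimate_batch_baselines <- function(X, case = "AD", control = "HC") {
  stopifnot(inherits(X, "feature_matrix"))
  batches <- unique(X$batch)
  mu <- matrix(NA_real_, length(batches), ncol(X$values),
               dimnames = list(batches, colnames(X$values)))
  for (b in batches) {
    in_b <- X$batch == b
    hc <- in_b & X$group == control
    ad <- in_b & X$group == case
    if (!any(hc) || !any(ad))
      stop("batch '", b, "' lacks ", if (!any(hc)) control else case,
           " samples; its baseline is undefined")
    mu[b, ] <- (colMeans(X$values[hc, , drop = FALSE]) +
                colMeans(X$values[ad, , drop = FALSE])) / 2
  }
  structure(list(mu = mu, case = case, control = control,
                 convention = "Delta_control + Delta_case = 0"),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, digits = 4, ...) {
  cat(sprintf("Batch-baseline model (%s anchors: %s/%s; convention %s)\n",
              "additive", x$control, x$case, x$convention))
  cat(sprintf("%d batch(es) x %d compound(s); baseline summary (min):\n",
              nrow(x$mu), ncol(x$mu)))
  print(round(stats::setNames(rowMeans(x$mu), rownames(x$mu)), digits))
  invisible(x)
}

#' Subtract batch baselines from a feature matrix
#'
#' Produces the corrected feature `z_ij = x_ij - mu_i` per compound.
#' Annotations are preserved; within-batch differences between samples are
#' untouched by construction. Samples from non-anchor groups (e.g. MS, DB,
#' RA, AD-MCI) are corrected with the baselines estimated from the anchor
#' groups of their batch.
#'
#' @param X A `feature_matrix`.
#' @param model A `batch_model` covering every batch and compound in `X`.
#' @return A `feature_matrix` of corrected values.
#' @export
correct_batches <- function(X, model) {
  stopifnot(inherits(X, "feature_matrix"), inherits(model, "batch_model"))
  unknown <- setdiff(unique(X$batch), rownames(model$mu))
  if (length(unknown))
    stop("batch(es) not covered by the model: ",
         paste(unknown, collapse = ", "))
  missing_c <- setdiff(colnames(X$values), colnames(model$mu))
  if (length(missing_c))
    stop("compound(s) not covered by the model: ",
         paste(missing_c, collapse = ", "))
  z <- X$values - model$mu[X$batch, colnames(X$values), drop = FALSE]
  feature_matrix(z, X$group, X$batch)
}
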