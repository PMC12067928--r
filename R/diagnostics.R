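#' Standardize a feature matrix
#'
#' Centers every feature to mean 0 and scales it to sample SD 1, retaining
#' the scaling parameters so the identical transform can be applied to
#' held-out samples. Zero-variance features carry no information at this
#' stage and are dropped with a warning rather than aborting.
#'
#' @param x Numeric matrix (samples x features) or a `feature_matrix`.
#' @return A list of class `standardization`: `values` (standardized
#'   matrix), `center`, `scale` (per kept feature), `dropped` (ids of
#'   zero-variance features).
#' @export
standardize_features <- function(x) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 samples are required")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  keep <- scl > 0
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
  x <- x[, keep, drop = FALSE]
  ctr <- ctr[keep]; scl <- scl[keep]
  structure(list(values = sweep(sweep(x, 2L, ctr), 2L, scl, "/"),
                 center = ctr, scale = scl, dropped = dropped),
            class = "standardization")
}

#' Apply a stored standardization to new samples
#'
#' @param object A `standardization` from [standardize_features()].
#' @param newdata Matrix of new samples over (at least) the kept features.
#' @return Standardized matrix over the kept features.
#' @export
standardize_apply <- function(object, newdata) {
  newdata <- as.matrix(newdata)[, names(object$center), drop = FALSE]
  sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
}

#' Principal component reduction
#'
#' Projects a standardized matrix onto its top right singular directions.
#' Explained-variance fractions are non-increasing across components and sum
#' to at most 1 over the retained set.
#'
#' @param s Standardized numeric matrix (samples x features).
#' @param npc Number of components to retain, between 1 and
#'   `min(nrow(s) - 1, ncol(s))`.
#' @return A list of class `pca_reduction`: `scores` (samples x npc),
#'   `loadings` (features x npc), `explained` (variance fractions for all
#'   components), `npc`.
#' @export
pca_reduce <- function(s, npc) {
  s <- as.matrix(s)
  limit <- min(nrow(s) - 1L, ncol(s))
  if (length(npc) != 1L || npc < 1L || npc > limit)
    stop("npc must lie in [1, ", limit, "]")
  pr <- stats::prcomp(s, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x[, seq_len(npc), drop = FALSE],
                 loadings = pr$rotation[, seq_len(npc), drop = FALSE],
                 explained = ev, npc = as.integer(npc)),
            class = "pca_reduction")
}

#' Project new samples onto stored principal components
#'
#' @param object A `pca_reduction`.
#' @param newdata Standardized matrix over the same features.
#' @return Scores matrix (samples x npc).
#' @export
pca_apply <- function(object, newdata) {
  as.matrix(newdata) %*% object$loadings
}

.model_families <- c("logistic", "lda", "qda", "svm", "knn", "tree", "rf")

.default_hyperparameters <- function(family) {
  switch(family,
         logistic = list(),
         lda = list(),
         qda = list(),
         svm = list(kernel = "radial", cost = 1),
         knn = list(k = 5L),
         tree = list(cp = 0.01, minsplit = 20L),
         rf = list(ntree = 500L))
}

#' Specify a classifier
#'
#' Fixes the model family (one of logistic regression, LDA, QDA, SVM, KNN,
#' decision tree, random forest), the number of principal components
#' retained before fitting, the family-specific hyperparameters (all
#' defaulted and recorded in every report) and the seed.
#'
#' @param family One of `"logistic"`, `"lda"`, `"qda"`, `"svm"`, `"knn"`,
#'   `"tree"`, `"rf"`.
#' @param npc Number of principal components retained.
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer seed controlling fold shuffling and any stochastic
#'   fitting.
#' @return A list of class `model_spec`.
#' @export
classifier_spec <- function(family, npc = 2L, hyperparameters = list(),
                            seed = 1L) {
  family <- match.arg(family, .model_families)
  if (length(npc) != 1L || npc < 1L) stop("npc must be a positive integer")
  hp <- utils::modifyList(.default_hyperparameters(family), hyperparameters)
  structure(list(family = family, npc = as.integer(npc),
                 hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("Classifier spec: %s, nPC=%d, seed=%d (%s)\n",
              x$family, x$npc, x$seed, hp))
  invisible(x)
}

# Fit one family on training PC scores and predict labels + positive-class
# scores on the test scores. Column names are kept identical between the
# two matrices so formula interfaces line up.
.fit_predict <- function(family, xtr, ytr, xte, hp, positive) {
  lev <- levels(ytr)
  xtr_df <- as.data.frame(xtr)
  xte_df <- as.data.frame(xte)
  names(xte_df) <- names(xtr_df)
  switch(family,
    logistic = {
      dat <- cbind(xtr_df, .y = as.integer(ytr == positive))
      m <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                       family = stats::binomial()))
      p <- suppressWarnings(stats::predict(m, xte_df, type = "response"))
      list(labels = factor(ifelse(p > 0.5, positive,
                                  setdiff(lev, positive)[1L]), levels = lev),
           scores = as.numeric(p))
    },
    lda = {
      m <- MASS::lda(xtr, grouping = ytr)
      p <- stats::predict(m, xte)
      list(labels = p$class, scores = as.numeric(p$posterior[, positive]))
    },
    qda = {
      m <- MASS::qda(xtr, grouping = ytr)
      p <- stats::predict(m, xte)
      list(labels = p$class, scores = as.numeric(p$posterior[, positive]))
    },
    svm = {
      m <- e1071::svm(xtr, ytr, kernel = hp$kernel, cost = hp$cost)
      pr <- stats::predict(m, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      pair <- strsplit(colnames(dv)[[1L]], "/", fixed = TRUE)[[1L]]
      sc <- if (pair[[1L]] == positive) dv[, 1L] else -dv[, 1L]
      list(labels = factor(as.character(pr), levels = lev),
           scores = as.numeric(sc))
    },
    knn = {
      pr <- class::knn(xtr, xte, cl = ytr, k = hp$k, prob = TRUE)
      win <- attr(pr, "prob")
      sc <- ifelse(pr == positive, win, 1 - win)
      list(labels = factor(as.character(pr), levels = lev),
           scores = as.numeric(sc))
    },
    tree = {
      dat <- cbind(xtr_df, .y = ytr)
      m <- rpart::rpart(.y ~ ., data = dat, method = "class",
                        control = rpart::rpart.control(cp = hp$cp,
                                                       minsplit = hp$minsplit))
      list(labels = factor(as.character(
             stats::predict(m, xte_df, type = "class")), levels = lev),
           scores = as.numeric(stats::predict(m, xte_df)[, positive]))
    },
    rf = {
      m <- randomForest::randomForest(xtr, ytr, ntree = hp$ntree)
      list(labels = factor(as.character(stats::predict(m, xte)), levels = lev),
           scores = as.numeric(stats::predict(m, xte, type = "prob")[, positive]))
    })
}

# Stratified fold assignment: per-class seeded shuffle, folds filled
# cyclically, so per-fold class counts differ from balance by at most one.
.stratified_folds <- function(labels, k, seed) {
  if (k < 2L) stop("k must be at least 2")
  if (k > min(table(labels)))
    stop("k (", k, ") exceeds the size of the smallest class (",
         min(table(labels)), ") under stratification")
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(factor(labels))) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.rank_auc <- function(truth_pos, scores) {
  n1 <- sum(truth_pos); n0 <- sum(!truth_pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.confusion_metrics <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos); fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos); tn <- sum(!truth_pos & !pred_pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = precision, recall = recall, f1 = f1)
}

#' Classification metrics from scores
#'
#' Accuracy, precision, recall and F1 from the confusion matrix obtained by
#' thresholding the scores, plus the area under the ROC curve computed by
#' the rank (Mann-Whitney) statistic with ties averaged — equivalent to the
#' trapezoidal ROC area. Precision, recall and F1 treat the case class as
#' positive. With a single class in `truth`, AUC is undefined: it is
#' returned as `NA` with a warning while the threshold metrics are still
#' reported.
#'
#' @param truth True labels: logical, 0/1, or factels matched against
#'   `positive`.
#' @param scores Real-valued classifier scores, larger for the positive
#'   class.
#' @param threshold Decision cutoff applied to `scores` (default 0.5).
#' @param positive Label counted as positive when `truth` is not logical
#'   (default `"AD"`; ignored for logical/0-1 truth).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`, all in `[0, 1]`.
#' @export
compute_metrics <- function(truth, scores, threshold = 0.5,
                            positive = "AD") {
  if (length(truth) != length(scores))
    stop("truth and scores must have the same length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  truth_pos <- if (is.logical(truth)) truth
               else if (is.numeric(truth)) truth == 1
               else as.character(truth) == positive
  out <- .confusion_metrics(truth_pos, scores > threshold)
  if (length(unique(truth_pos)) < 2L) {
    warning("AUC undefined: only one class present in truth")
    auc <- NA_real_
  } else auc <- .rank_auc(truth_pos, scores)
  c(out, auc = auc)
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation (default 3-fold) with seeded
#' shuffling. Within each iteration the standardization and PCA are fitted
#' on the k-1 training folds and applied to the held-out fold, the model is
#' fitted on the training PC scores, and accuracy, precision, recall, F1
#' (from the model's native label predictions, case class positive) and
#' rank-based AUC (from its scores) are measured on the held-out fold. The
#' reported averages are the arithmetic means of the per-fold metrics.
#'
#' `preprocess = "full"` instead fits standardization and PCA once on the
#' complete matrix before splitting; it mirrors a preprocessing-first
#' workflow but lets information from held-out samples into the projection,
#' so the fold-wise default is preferred.
#'
#' @param features Numeric matrix (samples x features) or `feature_matrix`
#'   (typically batch-corrected half-lives).
#' @param labels Group labels, one per sample; exactly two classes. Defaults
#'   to the `feature_matrix` group annotation.
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 3).
#' @param positive Label treated as positive (default `"AD"`).
#' @param preprocess `"within"` (fit scaling/PCA on training folds; default)
#'   or `"full"`.
#' @param repeats Number of repeated cross-validation rounds averaged into
#'   the report (default 1; each repeat reshuffles the folds).
#' @return An object of class `classifier_report`: per-fold metric matrix,
#'   averaged metrics, fold assignments, the spec, and the seed.
#' @export
cross_validate <- function(features, labels = NULL, spec, k = 3L,
                           positive = "AD",
                           preprocess = c("within", "full"), repeats = 1L) {
  preprocess <- match.arg(preprocess)
  if (inherits(features, "feature_matrix")) {
    if (is.null(labels)) labels <- features$group
    features <- features$values
  }
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required (got ",
         paste(levels(labels), collapse = ", "), ")")
  if (!positive %in% levels(labels))
    stop("positive class '", positive, "' not present in labels")
  labels <- stats::relevel(labels, ref = setdiff(levels(labels), positive))
  limit <- min(nrow(features) - 1L, ncol(features))
  if (spec$npc > limit)
    stop("npc (", spec$npc, ") exceeds min(samples - 1, features) = ", limit)

  fold_rows <- list(); assignments <- list()
  for (rep_i in seq_len(repeats)) {
    folds <- .stratified_folds(labels, k, spec$seed + 1000L * (rep_i - 1L))
    assignments[[rep_i]] <- folds
    if (preprocess == "full") {
      std <- standardize_features(features)
      red <- pca_reduce(std$values, min(spec$npc, ncol(std$values),
                                        nrow(std$values) - 1L))
      all_scores <- red$scores
    }
    for (f in seq_len(k)) {
      tr <- folds != f; te <- !tr
      if (preprocess == "within") {
        std <- standardize_features(features[tr, , drop = FALSE])
        npc_eff <- min(spec$npc, ncol(std$values), sum(tr) - 1L)
        red <- pca_reduce(std$values, npc_eff)
        xtr <- red$scores
        xte <- pca_apply(red, standardize_apply(std, features[te, , drop = FALSE]))
      } else {
        xtr <- all_scores[tr, , drop = FALSE]
        xte <- all_scores[te, , drop = FALSE]
      }
      set.seed(spec$seed + 7L * f + 100000L * (rep_i - 1L))
      pred <- .fit_predict(spec$family, xtr, droplevels(labels[tr]), xte,
                           spec$hyperparameters, positive)
      truth_pos <- labels[te] == positive
      m <- c(.confusion_metrics(truth_pos, pred$labels == positive),
             auc = .rank_auc(truth_pos, pred$scores))
      fold_rows[[length(fold_rows) + 1L]] <- m
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)
  rownames(fold_metrics) <- paste0("fold", seq_len(nrow(fold_metrics)))
  structure(list(spec = spec, k = as.integer(k), repeats = as.integer(repeats),
                 positive = positive, preprocess = preprocess,
                 fold_metrics = fold_metrics,
                 averages = colMeans(fold_metrics),
                 folds = assignments[[1L]], seed = spec$seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated %s (nPC=%d, seed=%d, positive=%s)\n",
              x$k, x$spec$family, x$spec$npc, x$seed, x$positive))
  avg <- x$averages
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%  AUC %.2f%%\n",
              100 * avg[["accuracy"]], 100 * avg[["precision"]],
              100 * avg[["recall"]], 100 * avg[["f1"]], 100 * avg[["auc"]]))
  invisible(x)
}

#' Compare classifier families over a grid of PCA dimensions
#'
#' Runs [cross_validate()] for every (family, nPC) combination, selects for
#' each family the nPC maximizing the mean AUC (smallest nPC on ties), and
#' ranks the families by that AUC. The full grid is retained.
#'
#' @param features,labels,k,positive,preprocess As in [cross_validate()].
#' @param families Character vector of model families (default: all seven).
#' @param npc_grid Integer vector of candidate nPC values.
#' @param seed Integer seed shared by all runs.
#' @return An object of class `model_sweep`: `grid` (data frame of averaged
#'   metrics per family and nPC), `best` (per-family winning row, ranked by
#'   AUC), and `reports` (all `classifier_report` objects).
#' @export
sweep_models <- function(features, labels = NULL,
                         families = .model_families, npc_grid = 1:5,
                         seed = 1L, k = 3L, positive = "AD",
                         preprocess = "within") {
  if (length(families) == 0L || length(npc_grid) == 0L)
    stop("families and npc_grid must be non-empty")
  rows <- list(); reports <- list()
  for (fam in families) for (npc in npc_grid) {
    rep_ <- cross_validate(features, labels,
                           classifier_spec(fam, npc, seed = seed),
                           k = k, positive = positive,
                           preprocess = preprocess)
    key <- sprintf("%s_npc%d", fam, npc)
    reports[[key]] <- rep_
    rows[[key]] <- data.frame(family = fam, npc = npc,
                              t(rep_$averages))
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  best <- do.call(rbind, lapply(split(grid, grid$family), function(g) {
    g[order(-g$auc, g$npc), ][1L, ]
  }))
  best <- best[order(-best$auc, best$family), ]
  rownames(best) <- NULL
  structure(list(grid = grid, best = best, reports = reports,
                 seed = as.integer(seed), k = as.integer(k)),
            class = "model_sweep")
}

#' @export
print.model_sweep <- function(x, digits = 3, ...) {
  cat(sprintf("Model sweep (%d-fold CV, seed %d); families ranked by best AUC:\n",
              x$k, x$seed))
  b <- x$best
  b[, -(1:2)] <- round(b[, -(1:2)], digits)
  print(b, row.names = FALSE)
  invisible(x)
}

#' Two-dimensional discriminant projection for multi-group comparison
#'
#' Projects samples into a plane for visual comparison of two or more
#' groups. `"lda"` projects onto the top two linear discriminant axes (with
#' a zero second axis when only two groups leave a single discriminant);
#' `"qda"` uses the first two class log-posterior contrasts against the
#' first group as coordinates. These views are descriptive and are not
#' optimized for classification performance.
#'
#' @param features Numeric matrix or `feature_matrix`.
#' @param labels Group labels (>= 2 groups). Defaults to the
#'   `feature_matrix` annotation.
#' @param method `"lda"` or `"qda"`.
#' @return An object of class `projection_2d`: `coords` (samples x 2),
#'   `labels`, `method`.
#' @export
project_2d <- function(features, labels = NULL, method = c("lda", "qda")) {
  method <- match.arg(method)
  if (inherits(features, "feature_matrix")) {
    if (is.null(labels)) labels <- features$group
    features <- features$values
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("at least 2 groups are required")
  std <- standardize_features(as.matrix(features))
  x <- std$values
  if (method == "lda") {
    m <- MASS::lda(x, grouping = labels)
    sc <- stats::predict(m, x)$x
    coords <- if (ncol(sc) >= 2L) sc[, 1:2] else cbind(sc[, 1L], 0)
  } else {
    m <- tryCatch(MASS::qda(x, grouping = labels), error = function(e)
      stop("QDA failed (", conditionMessage(e),
           "); a group is likely too small for a full covariance - ",
           "consider method = \"lda\""))
    post <- pmax(stats::predict(m, x)$posterior, 1e-300)
    lp <- log(post)
    coords <- cbind(lp[, 2L] - lp[, 1L],
                    if (ncol(lp) >= 3L) lp[, 3L] - lp[, 1L] else 0)
  }
  dimnames(coords) <- list(rownames(features), c("axis1", "axis2"))
  structure(list(coords = coords, labels = labels, method = method),
            class = "projection_2d")
}

#' @export
print.projection_2d <- function(x, ...) {
  cat(sprintf("2-D %s projection of %d samples in %d groups\n",
              toupper(x$method), nrow(x$coords), nlevels(x$labels)))
  invisible(x)
}

#' @export
plot.projection_2d <- function(x, ...) {
  graphics::plot(x$coords, col = as.integer(x$labels),
                 pch = as.integer(x$labels),
                 xlab = "axis 1", ylab = "axis 2", ...)
  graphics::legend("topright", legend = levels(x$labels),
                   col = seq_len(nlevels(x$labels)),
                   pch = seq_len(nlevels(x$labels)), bty = "n")
}

#' Unpaired two-tailed Student t test between two groups
#'
#' Classical equal-variance t test, with group means and standard errors of
#' the mean reported and significance annotated at P <= 0.05.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return A list of class `group_diff`: `statistic`, `df`, `p.value`,
#'   `significant`, and per-group `mean` and `sem`.
#' @export
group_difference_test <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value, significant = ht$p.value <= 0.05,
                 mean = c(a = mean(values_a), b = mean(values_b)),
                 sem = c(a = sem(values_a), b = sem(values_b))),
            class = "group_diff")
}

#' @export
print.group_diff <- function(x, ...) {
  star <- if (!x$significant) "n.s."
          else if (x$p.value < 0.001) "***"
          else if (x$p.value < 0.01) "**" else "*"
  cat(sprintf("Unpaired two-tailed t test: t = %.4g (df = %g), P = %.4g [%s]\n",
              x$statistic, x$df, x$p.value, star))
  cat(sprintf("  group a: %.4g +/- %.4g (mean +/- SEM); group b: %.4g +/- %.4g\n",
              x$mean[["a"]], x$sem[["a"]], x$mean[["b"]], x$sem[["b"]]))
  invisible(x)
}
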