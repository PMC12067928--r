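test_that("standardization centers, scales, and is idempotent", {
  m <- cbind(a = c(8, 10, 12), b = c(1, 5, 3))
  std <- standardize_features(m)
  expect_equal(unname(std$values[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(std$values), c(a = 0, b = 0))
  expect_equal(apply(std$values, 2, sd), c(a = 1, b = 1))
  again <- standardize_features(std$values)
  expect_equal(again$values, std$values, tolerance = 1e-12)
  # held-out application reuses the stored parameters
  expect_equal(standardize_apply(std, m), std$values)
})

test_that("zero-variance features are dropped with a warning, not an abort", {
  m <- cbind(a = c(8, 10, 12), flat = c(2, 2, 2))
  expect_warning(std <- standardize_features(m), "flat")
  expect_identical(colnames(std$values), "a")
  expect_identical(std$dropped, "flat")
})

test_that("PCA reconstructs an exact-rank matrix and orders variance", {
  set.seed(10)
  basis <- matrix(rnorm(8), 4, 2)
  m <- matrix(rnorm(12), 6, 2) %*% t(basis)      # rank 2, 6 x 4
  m <- scale(m, scale = FALSE)
  red <- pca_reduce(m, 2)
  expect_equal(red$scores %*% t(red$loadings), m, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(red$explained) <= 1e-12))
  expect_lte(sum(red$explained), 1 + 1e-12)
  expect_error(pca_reduce(m, 7), "npc")
})

test_that("PCA scores match an independent eigendecomposition", {
  set.seed(77)
  s <- scale(matrix(rnorm(24), 6, 4))
  red <- pca_reduce(s, 3)
  eig <- eigen(cov(s))
  for (j in 1:3) {
    ours <- red$scores[, j]
    ref <- as.numeric(s %*% eig$vectors[, j])
    if (sum(ours * ref) < 0) ref <- -ref   # sign alignment
    expect_equal(ours, ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("threshold metrics follow the confusion matrix", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  scores <- c(rep(0.9, 8), rep(0.1, 2),   # 8 TP, 2 FN
              rep(0.9, 2), rep(0.1, 8))   # 2 FP, 8 TN
  m <- compute_metrics(truth, scores)
  expect_equal(m[["accuracy"]], 0.8)
  expect_equal(m[["precision"]], 0.8)
  expect_equal(m[["recall"]], 0.8)
  expect_equal(m[["f1"]], 0.8)
})

test_that("rank AUC equals brute-force pair counting and is rank-invariant", {
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3))
  expect_equal(m[["auc"]], 0.75)
  expect_equal(m[["auc"]], oracle_auc(c(TRUE, FALSE, TRUE, FALSE),
                                      c(0.9, 0.8, 0.4, 0.3)))
  set.seed(123)
  for (i in 1:20) {
    truth <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(.4, .6))
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(20), 1)          # induce ties
    a <- compute_metrics(truth, scores)[["auc"]]
    expect_equal(a, oracle_auc(truth, scores))
    # strictly increasing transform leaves AUC unchanged
    expect_equal(compute_metrics(truth, exp(3 * scores))[["auc"]], a)
  }
  expect_equal(compute_metrics(c(1, 0, 1), c(1, 0, 1))[["auc"]], 1)
})

test_that("one-class truth yields NA AUC with the other metrics intact", {
  expect_warning(m <- compute_metrics(c(1, 1, 1), c(0.9, 0.8, 0.2)),
                 "AUC undefined")
  expect_true(is.na(m[["auc"]]))
  expect_equal(m[["recall"]], 2 / 3)
})

sep_data <- function(n = 30, gap = 10, p = 4, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = gap), n, p))
  colnames(x) <- sprintf("C%02d", seq_len(p))
  list(x = x, y = rep(c("HC", "AD"), each = n))
}

test_that("well-separated classes are classified perfectly under 3-fold CV", {
  d <- sep_data()
  rep_ <- cross_validate(d$x, d$y, classifier_spec("lda", npc = 2, seed = 1))
  expect_equal(rep_$averages[["auc"]], 1)
  expect_equal(rep_$averages[["accuracy"]], 1)
  expect_equal(rep_$averages, colMeans(rep_$fold_metrics))
})

test_that("every model family runs through cross-validation", {
  d <- sep_data(n = 15)
  for (fam in c("logistic", "lda", "qda", "svm", "knn", "tree", "rf")) {
    rep_ <- cross_validate(d$x, d$y, classifier_spec(fam, npc = 2, seed = 1))
    expect_true(all(rep_$fold_metrics >= 0 & rep_$fold_metrics <= 1),
                info = fam)
    expect_gte(rep_$averages[["auc"]], 0.9)
  }
})

test_that("permuted labels drive LDA to chance AUC", {
  d <- sep_data(n = 15, gap = 10)
  aucs <- vapply(1:101, function(s) {
    set.seed(1000 + s)
    y <- sample(d$y)
    cross_validate(d$x, y, classifier_spec("lda", npc = 2, seed = s)
                   )$averages[["auc"]]
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("infeasible folds and degenerate labels are errors", {
  d <- sep_data(n = 5)
  expect_error(cross_validate(d$x, d$y,
                              classifier_spec("lda", 2, seed = 1), k = 20),
               "smallest class")
  expect_error(cross_validate(d$x, rep("AD", 10),
                              classifier_spec("lda", 2, seed = 1)),
               "two classes")
  expect_error(cross_validate(d$x, d$y,
                              classifier_spec("lda", npc = 50, seed = 1)),
               "npc")
})

test_that("stratified folds are balanced to within one sample per class", {
  set.seed(2)
  y <- factor(rep(c("AD", "HC"), times = c(31, 37)))
  folds <- lumisense:::.stratified_folds(y, 3, seed = 9)
  for (cl in levels(y)) {
    counts <- table(folds[y == cl])
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("the sweep is deterministic and degenerates to one CV call", {
  d <- sep_data(n = 12, gap = 3, seed = 5)
  s1 <- sweep_models(d$x, d$y, families = "lda", npc_grid = 3, seed = 7)
  s2 <- sweep_models(d$x, d$y, families = "lda", npc_grid = 3, seed = 7)
  expect_identical(s1$grid, s2$grid)
  single <- cross_validate(d$x, d$y, classifier_spec("lda", 3, seed = 7))
  expect_equal(unlist(s1$grid[1, c("accuracy", "precision", "recall",
                                   "f1", "auc")]),
               single$averages, ignore_attr = TRUE)
})

test_that("the sweep concentrates on few PCs when only two carry signal", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 20
    y <- rep(c("HC", "AD"), each = n)
    latent <- matrix(rnorm(2 * n * 2), 2 * n, 2)
    latent[y == "AD", ] <- latent[y == "AD", ] + 6
    # two correlated blocks of features carry the latent factors (hence the
    # top two PCs); the last two features are idiosyncratic noise
    x <- cbind(latent[, c(1, 1, 1, 2, 2, 2)] +
                 matrix(rnorm(2 * n * 6, sd = 0.3), 2 * n, 6),
               matrix(rnorm(2 * n * 2), 2 * n, 2))
    colnames(x) <- sprintf("C%02d", seq_len(8))
    sw <- sweep_models(x, y, families = "lda", npc_grid = 1:6, seed = s)
    sw$best$npc[[1L]]
  }, numeric(1))
  expect_true(all(wins <= 3))
})

test_that("LDA projection pads the second axis for two groups", {
  d <- sep_data(n = 10)
  prj <- project_2d(d$x, d$y, method = "lda")
  expect_equal(dim(prj$coords), c(20L, 2L))
  expect_true(all(prj$coords[, 2L] == 0))
})

test_that("collinear group means leave no variance for the second axis", {
  set.seed(4)
  n <- 15
  x <- rbind(matrix(rnorm(n * 3, 0), n, 3),
             matrix(rnorm(n * 3, 5), n, 3),
             matrix(rnorm(n * 3, 10), n, 3))
  colnames(x) <- c("a", "b", "c")
  y <- rep(c("g1", "g2", "g3"), each = n)
  prj <- project_2d(x, y, method = "lda")
  between_var <- function(col) var(tapply(col, y, mean))
  expect_lt(between_var(prj$coords[, 2L]) / between_var(prj$coords[, 1L]),
            0.05)
})

test_that("separated groups stay separated in both 2-D projections", {
  set.seed(12)
  n <- 20
  centers <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0), c(0, 0, 6))
  x <- do.call(rbind, lapply(1:4, function(g)
    sweep(matrix(rnorm(n * 3), n, 3), 2, centers[g, ], "+")))
  colnames(x) <- c("a", "b", "c")
  y <- rep(paste0("g", 1:4), each = n)
  for (meth in c("lda", "qda")) {
    prj <- project_2d(x, y, method = meth)
    d <- as.matrix(dist(prj$coords))
    same <- outer(y, y, "==") & upper.tri(d)
    diff_ <- outer(y, y, "!=") & upper.tri(d)
    expect_lt(mean(d[same]), mean(d[diff_]))
  }
})

test_that("QDA projection fails helpfully for undersized groups", {
  set.seed(6)
  x <- matrix(rnorm(40), 8, 5)
  colnames(x) <- sprintf("C%02d", 1:5)
  y <- rep(c("g1", "g2"), each = 4)   # 4 samples < 5 features per group
  expect_error(project_2d(x, y, method = "qda"), "lda")
})

test_that("the unpaired t test matches the textbook formula", {
  same <- group_difference_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_false(same$significant)

  far <- group_difference_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(far$p.value, 0.001)
  expect_true(far$significant)

  a <- c(10, 12, 14); b <- c(11, 13, 15)
  got <- group_difference_test(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4          # pooled variance, n1=n2=3
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$statistic, t_ref)
  expect_equal(got$p.value, 2 * pt(-abs(t_ref), df = 4))
  expect_error(group_difference_test(1, c(1, 2)), "at least 2")
})

test_that("cross-validated AUC grows with the planted effect size", {
  effect_auc <- function(mult, seeds = 1:12) {
    mean(vapply(seeds, function(s) {
      cfg <- simulation_config(n_per_group = c(AD = 15L, HC = 15L),
                               n_batches = 1L, n_compounds = 24L,
                               flag_compounds = 6L,
                               flag_effect = exp(mult * 0.05),
                               t_half = c(HC = 13.15, AD = 13.15),
                               sigma_log = 0.05)
      sim <- simulate_feature_matrix(cfg, seed = 3000 + s)
      cross_validate(sim$features,
                     spec = classifier_spec("lda", npc = 5, seed = s)
                     )$averages[["auc"]]
    }, numeric(1)))
  }
  aucs <- vapply(c(0, 2, 6), effect_auc, numeric(1))
  expect_gt(aucs[[1L]], 0.35)
  expect_lt(aucs[[1L]], 0.65)
  expect_true(all(diff(aucs) > 0))
  expect_gt(aucs[[3L]], 0.8)
})
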