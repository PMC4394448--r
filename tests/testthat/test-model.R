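test_that("RBF kernel values match closed forms", {
  u <- c(1, 0)
  v <- c(0, 1)
  expect_equal(rbf_kernel(u, u, gamma = 3), 1.0)
  expect_equal(rbf_kernel(u, v, gamma = 0.5), exp(-1))
  expect_equal(rbf_kernel(u, v, gamma = 1e-12), 1.0, tolerance = 1e-9)
  # unsquared (printed) form uses the plain Euclidean distance
  expect_equal(rbf_kernel(u, v, gamma = 0.5, squared = FALSE),
               exp(-0.5 * sqrt(2)))
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), gamma = 1), "dimension")
})

test_that("RBF kernel matrices are symmetric positive semidefinite", {
  withr::with_seed(51, {
    for (i in 1:5) {
      n <- sample(3:12, 1)
      x <- matrix(stats::rnorm(n * 4), n, 4)
      g <- stats::runif(1, 0.01, 4)
      K <- outer(seq_len(n), seq_len(n),
                 Vectorize(function(a, b) rbf_kernel(x[a, ], x[b, ], g)))
      expect_equal(K, t(K), tolerance = 1e-12)
      expect_true(all(eigen(K, symmetric = TRUE,
                            only.values = TRUE)$values > -1e-10))
    }
  })
})

test_that("metrics follow their defining ratios", {
  m <- compute_metrics(confusion_counts(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(1, 1, 1))

  m <- compute_metrics(confusion_counts(tp = 64, fp = 6, tn = 62, fn = 5))
  expect_equal(m$sensitivity, 64 / 69)
  expect_equal(m$specificity, 62 / 68)
  expect_equal(m$accuracy, 126 / 137)

  m <- compute_metrics(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(0, 1, 0.5))

  expect_error(compute_metrics(confusion_counts(1, 0, 0, 1)),
               "no actual negatives")
  expect_error(compute_metrics(confusion_counts(0, 3, 3, 0)),
               "no actual positives")
})

test_that("accuracy is the prevalence-weighted mean of sensitivity and specificity", {
  withr::with_seed(61, {
    for (i in 1:20) {
      cc <- confusion_counts(tp = sample(1:50, 1), fp = sample(0:50, 1),
                             tn = sample(1:50, 1), fn = sample(0:50, 1))
      m <- compute_metrics(cc)
      P <- cc$tp + cc$fn
      N <- cc$tn + cc$fp
      expect_equal(m$accuracy,
                   (m$sensitivity * P + m$specificity * N) / (P + N),
                   tolerance = 1e-12)
      expect_gte(m$accuracy, min(m$sensitivity, m$specificity))
      expect_lte(m$accuracy, max(m$sensitivity, m$specificity))
    }
  })
})

test_that("ROC curve endpoints, monotonicity and AUC match examples", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  r <- roc_auc(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)
  r <- roc_auc(c(0.5, 0.5), c(1, 0))
  expect_equal(r$auc, 0.5)

  withr::with_seed(71, {
    s <- stats::rnorm(60)
    y <- rep(c(1L, 0L), 30)
    r <- roc_auc(s, y)
  })
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals the all-pairs statistic and the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(81, {
    for (i in 1:10) {
      n <- sample(10:200, 1)
      y <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
      s <- round(stats::rnorm(n), sample(0:2, 1)) # induce ties
      r <- roc_auc(s, y)
      expect_equal(r$auc, oracle_auc(s, y), tolerance = 1e-12)
      expect_equal(r$auc,
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    }
  })
})

test_that("stratified folds respect sizes, classes, seeds and groups", {
  withr::with_seed(5, {
    x <- matrix(stats::rnorm(137 * 3), 137, 3)
  })
  ds <- labeled_dataset(x, rep(c(1L, 0L), c(69, 68)))
  folds <- stratified_kfold(ds, k = 5, seed = 2)
  expect_equal(sort(lengths(folds), decreasing = TRUE), c(28, 28, 27, 27, 27))
  expect_setequal(unlist(folds), 1:137)

  small <- labeled_dataset(x[1:10, ], rep(c(1L, 0L), 5))
  f <- stratified_kfold(small, k = 5, seed = 3)
  for (fi in f) expect_setequal(small$y[fi], c(0L, 1L))

  expect_identical(stratified_kfold(ds, k = 5, seed = 9),
                   stratified_kfold(ds, k = 5, seed = 9))
  expect_error(stratified_kfold(small, k = 6), "fewer")
  # leave-one-out is allowed as the degenerate k = n case
  loo <- stratified_kfold(small, k = 10, seed = 1)
  expect_equal(lengths(loo), rep(1L, 10))

  # replicates of one source protein stay together unless leakage is requested
  pos <- proteome(sprintf("P%02d", 1:10),
                  withr::with_seed(6, vapply(rep(30, 10), random_sequence,
                                             character(1))))
  neg <- proteome(sprintf("N%02d", 1:30),
                  withr::with_seed(7, vapply(rep(30, 30), random_sequence,
                                             character(1))))
  ds_up <- assemble_dataset(upsample_positives(pos, 3), neg)
  safe <- stratified_kfold(ds_up, k = 5, seed = 4)
  fold_of <- integer(length(ds_up$y))
  for (i in seq_along(safe)) fold_of[safe[[i]]] <- i
  split_groups <- tapply(fold_of, ds_up$group, function(v) length(unique(v)))
  expect_true(all(split_groups == 1))
  leaky <- stratified_kfold(ds_up, k = 5, seed = 4, leaky_upsampling = TRUE)
  fold_of <- integer(length(ds_up$y))
  for (i in seq_along(leaky)) fold_of[leaky[[i]]] <- i
  split_groups <- tapply(fold_of, ds_up$group, function(v) length(unique(v)))
  expect_true(any(split_groups > 1))
})

test_that("training separates a separable toy problem and is label-symmetric", {
  ds <- separable_dataset()
  m <- train_svm(ds, model_config(C = 10, gamma = 1), calibrate = FALSE)
  expect_equal(predict(m, ds$x, type = "class"),
               stats::setNames(ds$y, ds$accession))

  flipped <- labeled_dataset(ds$x, 1L - ds$y, ds$accession)
  mf <- train_svm(flipped, model_config(C = 10, gamma = 1), calibrate = FALSE)
  expect_equal(unname(predict(mf, ds$x, type = "class")),
               1L - unname(predict(m, ds$x, type = "class")))

  # exact duplication of a separable dataset leaves the boundary unchanged
  dup <- labeled_dataset(rbind(ds$x, ds$x), c(ds$y, ds$y))
  md <- train_svm(dup, model_config(C = 10, gamma = 1), calibrate = FALSE)
  grid <- as.matrix(expand.grid(f1 = seq(-3, 3, 0.5), f2 = seq(-3, 3, 0.5)))
  expect_equal(unname(predict(md, grid, type = "decision")),
               unname(predict(m, grid, type = "decision")), tolerance = 1e-3)
})

test_that("calibrated probabilities are monotone in the decision value", {
  ds <- preset_dataset("strong", seed = 33)$dataset
  m <- train_svm(ds, model_config(C = 2, gamma = 0.5), seed = 7)
  dv <- predict(m, ds$x, type = "decision")
  p <- predict(m, ds$x, type = "probability")
  ord <- order(dv)
  expect_true(all(diff(p[ord]) >= -1e-12))
  expect_true(all(p >= 0 & p <= 1))
  # calibration separates the classes on recoverable signal
  expect_gt(mean(p[ds$y == 1]), mean(p[ds$y == 0]))
})

test_that("cross validation recovers strong signal and stays at chance on noise", {
  ds <- separable_dataset(n_per_class = 25)
  cv <- cross_validate(ds, model_config(C = 10, gamma = 1), k = 5, seed = 1)
  expect_gte(cv$accuracy, 0.95)
  expect_equal(sum(unlist(cv$metrics$confusion)), length(ds$y))

  withr::with_seed(91, {
    x <- matrix(stats::rnorm(100 * 10), 100, 10)
    y <- sample(rep(c(1L, 0L), 50))
  })
  null_cv <- cross_validate(labeled_dataset(x, y), model_config(C = 2, gamma = 0.5),
                            k = 5, seed = 2)
  expect_gte(null_cv$accuracy, 0.35)
  expect_lte(null_cv$accuracy, 0.65)

  # leave-one-out pools n single-sample evaluations
  small <- separable_dataset(n_per_class = 5)
  loo <- cross_validate(small, model_config(C = 10, gamma = 1), k = 10, seed = 3)
  expect_equal(sum(unlist(loo$metrics$confusion)), 10)

  # bit-reproducible for a fixed seed
  a <- cross_validate(ds, model_config(C = 1, gamma = 0.5), k = 5, seed = 17)
  b <- cross_validate(ds, model_config(C = 1, gamma = 0.5), k = 5, seed = 17)
  expect_identical(a$scores, b$scores)
  expect_identical(a$metrics, b$metrics)
})

test_that("grid search maximizes accuracy with deterministic tie-breaking", {
  g1 <- grid_spec(C_values = 2, gamma_values = 0.5, feature_counts = 0L)
  ds <- separable_dataset(n_per_class = 10)
  gs <- grid_search(ds, g1, k = 5, seed = 1)
  expect_equal(gs$best$C, 2)
  expect_equal(gs$best$gamma, 0.5)
  expect_equal(nrow(gs$surface), 1L)

  # a separable problem is solved by every cell: ties resolve to fewer
  # features, then smaller C, then smaller gamma
  g2 <- grid_spec(C_values = c(1, 2), gamma_values = c(0.5, 1),
                  feature_counts = c(2L, 1L))
  gs2 <- grid_search(ds, g2, k = 5, seed = 1)
  expect_equal(max(gs2$surface$accuracy), gs2$best_accuracy)
  ties <- gs2$surface[gs2$surface$accuracy == gs2$best_accuracy, ]
  expect_equal(gs2$best$n_features, min(ties$n_features))
  best_nf <- ties[ties$n_features == min(ties$n_features), ]
  expect_equal(gs2$best$C, min(best_nf$C))

  # default ladders enumerate 9 x 21 (C, gamma) cells per feature count
  expect_equal(nrow(expand.grid(2^(-4:4), 2^(-10:10))), 189L)
  expect_equal(default_feature_ladder(433L), c(433L, 216L, 108L, 54L, 27L, 16L))
})

test_that("trained models persist and restore through the archive format", {
  ds <- separable_dataset()
  m <- train_svm(ds, model_config(C = 2, gamma = 1), seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, ds$x, type = "probability"),
               predict(m, ds$x, type = "probability"))
  saveRDS(list(a = 1), f)
  expect_error(load_model(f), "not a protint model")
})
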