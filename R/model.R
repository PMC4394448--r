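#' Model configuration
#'
#' @param C soft-margin regularization parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param n_features number of top-ranked features (by F-score) to use;
#'   0 means all features.
#' @return object of class `model_config`.
#' @export
model_config <- function(C = 2, gamma = 0.5, n_features = 0L) {
  if (!is.finite(C) || C <= 0) stop("`C` must be > 0", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  n_features <- as.integer(n_features)
  if (n_features < 0) stop("`n_features` must be >= 0", call. = FALSE)
  structure(list(C = C, gamma = gamma, n_features = n_features),
            class = "model_config")
}

#' Hyperparameter grid specification
#'
#' Defaults follow the usual geometric ladders: `C` over `2^-4 .. 2^4` and
#' `gamma` over `2^-10 .. 2^10`. Feature-count candidates default to a halving
#' ladder from the full dimension down to 16 (resolved against the dataset at
#' search time).
#'
#' @param C_values,gamma_values positive numeric ladders.
#' @param feature_counts integer candidates for the number of selected
#'   features (`NULL` = halving ladder, `0` = all features only).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(C_values = 2^(-4:4), gamma_values = 2^(-10:10),
                      feature_counts = NULL) {
  if (length(C_values) == 0 || length(gamma_values) == 0) {
    stop("grid ladders must be non-empty", call. = FALSE)
  }
  if (any(C_values <= 0) || any(gamma_values <= 0)) {
    stop("grid values must be positive", call. = FALSE)
  }
  structure(list(C_values = C_values, gamma_values = gamma_values,
                 feature_counts = feature_counts),
            class = "grid_spec")
}

#' Default feature-count candidate ladder
#'
#' Halving ladder `d, d/2, d/4, ..., 16` (plus 16 itself), the customary
#' schedule for F-score selection sweeps.
#'
#' @param d full feature dimension.
#' @return integer vector of candidates, decreasing.
#' @export
default_feature_ladder <- function(d) {
  d <- as.integer(d)
  if (d <= 16L) return(d)
  out <- integer(0)
  v <- d
  while (v > 16L) {
    out <- c(out, v)
    v <- v %/% 2L
  }
  unique(c(out, 16L))
}

#' Radial-basis-function kernel
#'
#' `k(u, v) = exp(-gamma * ||u - v||^2)` by default (the squared-distance form
#' used by libsvm-style SVM implementations). `squared = FALSE` gives the
#' Laplacian-like unsquared form `exp(-gamma * ||u - v||)`.
#'
#' @param u,v numeric vectors of equal length.
#' @param gamma kernel width (> 0).
#' @param squared use the squared Euclidean distance (default).
#' @return kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(u, v, gamma, squared = TRUE) {
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v), call. = FALSE)
  }
  d2 <- sum((u - v)^2)
  exp(-gamma * if (squared) d2 else sqrt(d2))
}

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`. Both classes must be
#' represented among the evaluated samples; an empty class is an error rather
#' than a silent zero.
#'
#' @param confusion a [confusion_counts()].
#' @return object of class `metrics_report` with fields `sensitivity`,
#'   `specificity`, `accuracy` and `confusion`.
#' @export
compute_metrics <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_counts"))
  p <- confusion$tp + confusion$fn
  n <- confusion$tn + confusion$fp
  if (p < 1) stop("no actual positives: sensitivity undefined", call. = FALSE)
  if (n < 1) stop("no actual negatives: specificity undefined", call. = FALSE)
  structure(list(
    sensitivity = confusion$tp / p,
    specificity = confusion$tn / n,
    accuracy = (confusion$tp + confusion$tn) / (p + n),
    confusion = confusion
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("sensitivity %.4f  specificity %.4f  accuracy %.4f  (TP %d FP %d TN %d FN %d)\n",
              x$sensitivity, x$specificity, x$accuracy,
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn))
  invisible(x)
}

#' ROC curve and AUC from scores
#'
#' Sweeps a decision threshold over all distinct scores; the curve runs from
#' (0, 0) to (1, 1) and the AUC is computed by the trapezoid rule, which
#' equals the tie-corrected probability that a random positive outscores a
#' random negative.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (1 = positive).
#' @return object of class `roc_curve` with `points` (data frame `fpr`,
#'   `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0 || nn == 0) stop("both classes required", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # collapse tied scores into single sweep points
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == 0L)[last]
  pts <- data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np),
                    threshold = c(Inf, s[last]))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Stratified k-fold partition
#'
#' Partitions a dataset into `k` folds with per-fold class ratios as close to
#' the overall ratio as integer arithmetic allows and total fold sizes
#' differing by at most one. Replicates of a common source protein (from
#' [upsample_positives()]) are kept in the same fold unless
#' `leaky_upsampling = TRUE`, which lets duplicates straddle folds.
#' Deterministic for a fixed seed.
#'
#' @param dataset a [labeled_dataset()].
#' @param k number of folds (`k = n` gives leave-one-out).
#' @param seed RNG seed for the shuffle.
#' @param leaky_upsampling ignore replicate grouping.
#' @return list of `k` integer vectors of row indices.
#' @export
stratified_kfold <- function(dataset, k = 5, seed = 1,
                             leaky_upsampling = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- length(dataset$y)
  k <- as.integer(k)
  if (k < 2 || k > n) stop("`k` must be in [2, n]", call. = FALSE)
  groups <- if (leaky_upsampling) dataset$accession else dataset$group
  if (k < n) {
    for (cls in c(1L, 0L)) {
      if (length(unique(groups[dataset$y == cls])) < k) {
        stop("a class has fewer (groups of) samples than k", call. = FALSE)
      }
    }
  }
  fold_of <- integer(n)
  load <- integer(k)
  with_rng(seed, {
    for (cls in c(1L, 0L)) {
      idx <- which(dataset$y == cls)
      gs <- unique(groups[idx])
      gs <- gs[sample.int(length(gs))]
      for (g in gs) {
        members <- idx[groups[idx] == g]
        f <- which.min(load) # ties -> smallest fold index
        fold_of[members] <- f
        load[f] <- load[f] + length(members)
      }
    }
  })
  lapply(seq_len(k), function(f) which(fold_of == f))
}

# --- internal SVM plumbing -------------------------------------------------

# Fit a C-classification RBF SVM (libsvm via e1071) on a feature matrix and
# 0/1 labels, recording the decision-value orientation so positive decision
# values always favor class 1.
svm_fit <- function(x, y, C, gamma) {
  yf <- factor(y, levels = c(1L, 0L))
  fit <- e1071::svm(x = x, y = yf, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE, probability = FALSE)
  dv <- attr(predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- if (colnames(dv)[1] == "1/0") 1 else -1
  list(fit = fit, flip = flip)
}

svm_decision <- function(model, x) {
  p <- predict(model$fit, x, decision.values = TRUE)
  as.numeric(attr(p, "decision.values")[, 1]) * model$flip
}

# Platt sigmoid fit: p(y=1 | f) = 1 / (1 + exp(A f + B)), fitted by Newton
# iterations with backtracking on the prior-corrected negative log likelihood
# (the standard libsvm procedure). Deterministic.
fit_platt <- function(decision, y, maxit = 100, minstep = 1e-10,
                      sigma = 1e-12) {
  y <- as.integer(y)
  np <- sum(y == 1L)
  nn <- sum(y == 0L)
  t <- ifelse(y == 1L, (np + 1) / (np + 2), 1 / (nn + 2))
  A <- 0
  B <- log((nn + 1) / (np + 1))
  fval <- function(A, B) {
    fApB <- decision * A + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(A, B)
  for (it in seq_len(maxit)) {
    fApB <- decision * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(decision * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(decision^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(decision * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= minstep) {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- fval(newA, newB)
      if (newf < fv + 1e-4 * step * gd) {
        A <- newA; B <- newB; fv <- newf
        break
      }
      step <- step / 2
    }
    if (step < minstep) break
  }
  c(A = A, B = B)
}

platt_prob <- function(decision, platt) {
  fApB <- decision * platt[["A"]] + platt[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# Top-n feature indices by F-score on (x, y); n = 0 keeps everything.
select_features <- function(x, y, n) {
  d <- ncol(x)
  if (n <= 0 || n >= d) return(seq_len(d))
  f <- f_score_values(x, y)
  head(order(-f, seq_along(f)), n)
}

#' Train the RBF-SVM interaction classifier
#'
#' Optionally restricts the dataset to its `n_features` top-ranked features
#' (F-score on this dataset), fits a soft-margin RBF SVM, and calibrates class
#' probabilities by fitting a Platt sigmoid to out-of-fold decision values
#' from a seeded stratified cross validation inside the training set.
#'
#' @param dataset a [labeled_dataset()] with both classes present.
#' @param config a [model_config()].
#' @param seed seed for the calibration folds.
#' @param calibrate fit the probability sigmoid (needed for probability
#'   output and threshold derivation).
#' @param calibration_folds folds for the internal calibration CV.
#' @return object of class `ppi_svm`.
#' @export
train_svm <- function(dataset, config = model_config(), seed = 1,
                      calibrate = TRUE, calibration_folds = 5) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "model_config"))
  sel <- select_features(dataset$x, dataset$y, config$n_features)
  xs <- dataset$x[, sel, drop = FALSE]
  model <- svm_fit(xs, dataset$y, config$C, config$gamma)
  platt <- NULL
  if (calibrate) {
    k <- min(calibration_folds, sum(dataset$y == 1L), sum(dataset$y == 0L))
    if (k < 2) stop("too few samples per class to calibrate", call. = FALSE)
    folds <- stratified_kfold(dataset, k = k, seed = derive_seed(seed, 1))
    dv <- numeric(length(dataset$y))
    for (f in folds) {
      train_idx <- setdiff(seq_along(dataset$y), f)
      m <- svm_fit(xs[train_idx, , drop = FALSE], dataset$y[train_idx],
                   config$C, config$gamma)
      dv[f] <- svm_decision(m, xs[f, , drop = FALSE])
    }
    platt <- fit_platt(dv, dataset$y)
  }
  structure(list(
    model = model,
    config = config,
    space = dataset$space,
    selected = sel,
    feature_names = colnames(dataset$x)[sel],
    platt = platt,
    training_accessions = unique(source_accession(dataset$accession)),
    seed = seed
  ), class = "ppi_svm")
}

#' @export
print.ppi_svm <- function(x, ...) {
  cat(sprintf("RBF-SVM interaction classifier: C = %g, gamma = %g, %d feature(s)%s\n",
              x$config$C, x$config$gamma, length(x$selected),
              if (is.null(x$platt)) " (uncalibrated)" else ""))
  invisible(x)
}

#' Predict with a trained interaction classifier
#'
#' @param object a [train_svm()] model.
#' @param newdata a [proteome()] (encoded in the model's frozen feature
#'   space) or a numeric matrix in full feature-space dimension.
#' @param type `"probability"` (calibrated probability of the interacting
#'   class), `"decision"` (raw decision value, positive favors interaction) or
#'   `"class"` (0/1 call).
#' @param ... unused.
#' @return numeric (or integer for `"class"`) vector named by accession when
#'   available.
#' @export
predict.ppi_svm <- function(object, newdata,
                            type = c("probability", "decision", "class"),
                            ...) {
  type <- match.arg(type)
  if (inherits(newdata, "proteome")) {
    if (is.null(object$space)) stop("model has no feature space", call. = FALSE)
    newdata <- encode_proteome(newdata, object$space)
  }
  newdata <- as.matrix(newdata)
  x <- newdata[, object$selected, drop = FALSE]
  dv <- svm_decision(object$model, x)
  names(dv) <- rownames(newdata)
  if (type == "decision") return(dv)
  if (is.null(object$platt)) {
    if (type == "class") return(stats::setNames(as.integer(dv > 0), names(dv)))
    stop("model was trained with calibrate = FALSE; no probabilities",
         call. = FALSE)
  }
  p <- stats::setNames(platt_prob(dv, object$platt), names(dv))
  if (type == "class") return(stats::setNames(as.integer(p >= 0.5), names(p)))
  p
}

# Shared fold-level CV engine. `orders` is a list (one per fold) of feature
# indices ordered by decreasing training-fold F-score; `global_order` replaces
# them when selection is done once on the full dataset.
cv_engine <- function(dataset, folds, config, orders = NULL,
                      global_order = NULL) {
  n <- length(dataset$y)
  pred <- integer(n)
  score <- numeric(n)
  for (i in seq_along(folds)) {
    test <- folds[[i]]
    train <- setdiff(seq_len(n), test)
    ord <- if (!is.null(global_order)) global_order else orders[[i]]
    sel <- if (config$n_features <= 0 || config$n_features >= ncol(dataset$x)) {
      seq_len(ncol(dataset$x))
    } else {
      head(ord, config$n_features)
    }
    m <- svm_fit(dataset$x[train, sel, drop = FALSE], dataset$y[train],
                 config$C, config$gamma)
    dv <- svm_decision(m, dataset$x[test, sel, drop = FALSE])
    score[test] <- dv
    pred[test] <- as.integer(dv > 0)
  }
  cc <- confusion_counts(tp = sum(pred == 1L & dataset$y == 1L),
                         fp = sum(pred == 1L & dataset$y == 0L),
                         tn = sum(pred == 0L & dataset$y == 0L),
                         fn = sum(pred == 0L & dataset$y == 1L))
  list(confusion = cc, scores = score)
}

# Per-fold feature orderings (decreasing F-score on the training folds only).
fold_orders <- function(dataset, folds) {
  lapply(folds, function(test) {
    train <- setdiff(seq_along(dataset$y), test)
    f <- f_score_values(dataset$x[train, , drop = FALSE], dataset$y[train])
    order(-f, seq_along(f))
  })
}

global_order <- function(dataset) {
  f <- f_score_values(dataset$x, dataset$y)
  order(-f, seq_along(f))
}

#' Stratified k-fold cross validation
#'
#' Trains on `k - 1` folds and predicts the held-out fold, pooling all
#' held-out confusion counts into a single estimate. By default the F-score
#' feature ranking is recomputed inside each set of training folds, so feature
#' selection never sees held-out data; `global_selection = TRUE` ranks once on
#' the full dataset (the optimistic protocol some published pipelines use).
#'
#' @param dataset a [labeled_dataset()].
#' @param config a [model_config()].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param global_selection rank features on the full dataset instead of
#'   nested inside the training folds.
#' @param leaky_upsampling let replicates of one source protein straddle
#'   folds (see [stratified_kfold()]).
#' @return object of class `cv_result`: `metrics` (a `metrics_report`),
#'   `roc` (a `roc_curve` over pooled held-out decision values), `accuracy`,
#'   and the pooled `scores`.
#' @export
cross_validate <- function(dataset, config = model_config(), k = 5, seed = 1,
                           global_selection = FALSE,
                           leaky_upsampling = FALSE) {
  folds <- stratified_kfold(dataset, k = k, seed = seed,
                            leaky_upsampling = leaky_upsampling)
  need_sel <- config$n_features > 0 && config$n_features < ncol(dataset$x)
  res <- cv_engine(
    dataset, folds, config,
    orders = if (need_sel && !global_selection) fold_orders(dataset, folds),
    global_order = if (need_sel && global_selection) global_order(dataset)
  )
  metrics <- compute_metrics(res$confusion)
  structure(list(metrics = metrics,
                 roc = roc_auc(res$scores, dataset$y),
                 accuracy = metrics$accuracy,
                 scores = res$scores,
                 k = k, seed = seed, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: ", x$k))
  print(x$metrics)
  cat(sprintf("AUC = %.4f\n", x$roc$auc))
  invisible(x)
}

#' Grid search over C, gamma and selected-feature count
#'
#' Evaluates [cross_validate()] for every `(C, gamma, n_features)` triple on
#' shared folds (and shared per-fold feature rankings) and returns the
#' accuracy-maximizing configuration. Ties break toward fewer features, then
#' smaller `C`, then smaller `gamma`, making the winner deterministic.
#'
#' @param dataset a [labeled_dataset()].
#' @param grid a [grid_spec()].
#' @param k folds.
#' @param seed fold-assignment seed.
#' @param global_selection,leaky_upsampling see [cross_validate()].
#' @param verbose print progress per feature-count candidate.
#' @return object of class `grid_search`: `best` (a `model_config`),
#'   `best_accuracy`, and the full accuracy `surface` (data frame `C`,
#'   `gamma`, `n_features`, `accuracy`).
#' @export
grid_search <- function(dataset, grid = grid_spec(), k = 5, seed = 1,
                        global_selection = FALSE, leaky_upsampling = FALSE,
                        verbose = FALSE) {
  d <- ncol(dataset$x)
  counts <- grid$feature_counts
  if (is.null(counts)) counts <- default_feature_ladder(d)
  counts <- as.integer(counts)
  folds <- stratified_kfold(dataset, k = k, seed = seed,
                            leaky_upsampling = leaky_upsampling)
  need_sel <- any(counts > 0 & counts < d)
  orders <- NULL
  gorder <- NULL
  if (need_sel) {
    if (global_selection) gorder <- global_order(dataset)
    else orders <- fold_orders(dataset, folds)
  }
  cells <- expand.grid(gamma = grid$gamma_values, C = grid$C_values,
                       n_features = counts, KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- model_config(C = cells$C[i], gamma = cells$gamma[i],
                        n_features = cells$n_features[i])
    res <- cv_engine(dataset, folds, cfg, orders = orders,
                     global_order = gorder)
    acc[i] <- compute_metrics(res$confusion)$accuracy
    if (verbose && i %% length(grid$gamma_values) == 0) {
      message(sprintf("grid search: %d / %d cells", i, nrow(cells)))
    }
  }
  surface <- data.frame(C = cells$C, gamma = cells$gamma,
                        n_features = cells$n_features, accuracy = acc)
  nf_eff <- ifelse(surface$n_features <= 0 | surface$n_features > d,
                   d, surface$n_features)
  best_i <- order(-surface$accuracy, nf_eff, surface$C, surface$gamma)[1]
  best <- model_config(C = surface$C[best_i], gamma = surface$gamma[best_i],
                       n_features = surface$n_features[best_i])
  structure(list(best = best, best_accuracy = surface$accuracy[best_i],
                 surface = surface, k = k, seed = seed),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("grid search over %d cells: best accuracy %.4f at C = %g, gamma = %g, %d feature(s)\n",
              nrow(x$surface), x$best_accuracy, x$best$C, x$best$gamma,
              x$best$n_features))
  invisible(x)
}

#' Persist / restore a trained model
#'
#' @param model a `ppi_svm`.
#' @param path archive path.
#' @return `path` (save) or the restored `ppi_svm` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ppi_svm"))
  saveRDS(list(format = "protint-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "protint-model")) {
    stop("not a protint model archive: ", path, call. = FALSE)
  }
  obj$model
}
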