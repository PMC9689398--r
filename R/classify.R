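#' Confusion-matrix metrics for a binary acidosis classifier
#'
#' Computes accuracy, sensitivity (recall on the acidotic class),
#' specificity and precision as percentages, from predictions and reference
#' labels. Ratios with a zero denominator are reported as `NA` and flagged,
#' never silently zero-filled.
#'
#' @param preds predicted classes (0/1).
#' @param labels reference classes (0/1).
#' @param positive the positive (acidotic) class, default 1.
#' @return Object of class `ctg_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `precision` (percent) and `confusion`
#'   (named counts TP, FP, TN, FN).
#' @export
evaluate_predictions <- function(preds, labels, positive = 1) {
  if (length(preds) != length(labels) || !length(preds))
    stop("evaluate_predictions: preds and labels must be nonempty and of ",
         "equal length", call. = FALSE)
  preds <- as.integer(as.character(preds))
  labels <- as.integer(as.character(labels))
  tp <- sum(preds == positive & labels == positive)
  tn <- sum(preds != positive & labels != positive)
  fp <- sum(preds == positive & labels != positive)
  fn <- sum(preds != positive & labels == positive)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(
    accuracy = pct(tp + tn, tp + tn + fp + fn),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    precision = pct(tp, tp + fp),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
    class = "ctg_metrics")
}

#' @export
print.ctg_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  cat(sprintf("accuracy %s  sensitivity %s  specificity %s  precision %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$precision)))
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  invisible(x)
}

default_grid <- function(kind) {
  switch(kind,
    svm = {
      g <- list()
      for (cost in c(0.1, 1, 10)) {
        g[[length(g) + 1L]] <- list(kernel = "linear", cost = cost)
        for (gamma in c(0.01, 0.1, 1)) {
          g[[length(g) + 1L]] <- list(kernel = "rbf", gamma = gamma,
                                      cost = cost)
          for (degree in c(2, 3))
            g[[length(g) + 1L]] <- list(kernel = "polynomial", gamma = gamma,
                                        coef0 = 1, degree = degree,
                                        cost = cost)
        }
      }
      g
    },
    random_forest = {
      g <- list()
      for (ntree in c(50, 100, 200))
        for (maxnodes in c(NA, 8, 32))
          g[[length(g) + 1L]] <- list(ntree = ntree, maxnodes = maxnodes)
      g
    },
    neural_net = {
      g <- list()
      for (size in c(4, 8, 16))
        for (decay in c(1e-4, 1e-2))
          g[[length(g) + 1L]] <- list(size = size, decay = decay)
      g
    },
    kmeans = list(list(k = 2)),
    stop("default_grid: unknown learner kind '", kind, "'", call. = FALSE))
}

# Model-complexity score used for tie-breaking in grid search: among grid
# points with equal CV accuracy, prefer the simpler model, then the first
# listed.
grid_complexity <- function(kind, pt) {
  switch(kind,
    svm = {
      k_rank <- match(pt$kernel, c("linear", "rbf", "polynomial"))
      gamma <- if (is.null(pt$gamma)) 0 else pt$gamma
      k_rank * 1e6 + gamma * pt$cost
    },
    random_forest = pt$ntree + if (is.na(pt$maxnodes)) 1e4 else pt$maxnodes,
    neural_net = pt$size,
    kmeans = 0)
}

scale_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}
scale_apply <- function(x, sc) {
  scale(as.matrix(x), center = sc$center, scale = sc$scale)
}

# Convert the radial-kernel width from the exp(-||x-y||^2 / (2 gamma^2))
# parameterisation to e1071's exp(-g ||x-y||^2).
rbf_gamma_to_e1071 <- function(gamma) 1 / (2 * gamma^2)

fit_one <- function(kind, pt, x, y, seed) {
  yf <- factor(y, levels = c(0, 1))
  set.seed(seed)
  switch(kind,
    svm = {
      args <- list(x = x, y = yf, cost = pt$cost, scale = FALSE)
      args$kernel <- if (pt$kernel == "rbf") "radial" else pt$kernel
      if (pt$kernel == "rbf") args$gamma <- rbf_gamma_to_e1071(pt$gamma)
      if (pt$kernel == "polynomial") {
        args$gamma <- pt$gamma; args$coef0 <- pt$coef0; args$degree <- pt$degree
      }
      do.call(e1071::svm, args)
    },
    random_forest = {
      if (is.na(pt$maxnodes))
        randomForest::randomForest(x, yf, ntree = pt$ntree)
      else
        randomForest::randomForest(x, yf, ntree = pt$ntree,
                                   maxnodes = min(pt$maxnodes, nrow(x)))
    },
    neural_net = nnet::nnet(x, nnet::class.ind(yf), size = pt$size,
                            decay = pt$decay, maxit = 300, trace = FALSE,
                            softmax = TRUE),
    stop("fit_one: unsupported kind ", kind))
}

predict_one <- function(kind, model, x) {
  switch(kind,
    svm = as.integer(as.character(predict(model, x))),
    random_forest = as.integer(as.character(predict(model, x))),
    neural_net = {
      pr <- predict(model, x)
      as.integer(colnames(pr)[max.col(pr, ties.method = "first")])
    })
}

#' Train a base learner with grid search and 5-fold cross-validation
#'
#' Features are z-scored with statistics learned on the training folds only.
#' The grid point with the highest mean cross-validated accuracy is chosen
#' (ties broken toward the simpler model, then grid order), the model is
#' refit on the full training data, and the pooled out-of-fold predictions
#' of the winning configuration are summarised as a [evaluate_predictions()]
#' report.
#'
#' @param kind `"svm"`, `"random_forest"`, `"neural_net"` or `"kmeans"`
#'   (the latter delegates to [fit_kmeans_classifier()]).
#' @param table data frame or matrix of numeric features (>= 10 rows).
#' @param labels 0/1 vector; both classes must be present.
#' @param grid list of hyperparameter sets; `NULL` uses the package default.
#' @param folds number of CV folds.
#' @param seed RNG seed controlling folds and stochastic fits.
#' @return Object of class `ctg_learner` with the fitted model, the chosen
#'   hyperparameters, the full CV table and `cv_metrics`.
#' @export
train_learner <- function(kind = c("svm", "random_forest", "neural_net",
                                   "kmeans"),
                          table, labels, grid = NULL, folds = 5L,
                          seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(table[vapply(as.data.frame(table), is.numeric, TRUE)])
  labels <- as.integer(as.character(labels))
  if (nrow(x) < 10L)
    stop("train_learner: need at least 10 rows", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("train_learner: both classes must be present", call. = FALSE)
  if (kind == "kmeans")
    return(fit_kmeans_classifier(x, labels, seed = seed))
  if (is.null(grid)) grid <- default_grid(kind)
  if (!length(grid)) stop("train_learner: empty grid", call. = FALSE)

  fold_id <- with_seed(seed, make_folds(labels, folds))
  cv_acc <- numeric(length(grid))
  oof <- matrix(NA_integer_, length(labels), length(grid))
  for (gi in seq_along(grid)) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      sc <- scale_fit(x[tr, , drop = FALSE])
      xtr <- scale_apply(x[tr, , drop = FALSE], sc)
      xte <- scale_apply(x[!tr, , drop = FALSE], sc)
      m <- with_seed(seed + 1000L * gi + f,
                     fit_one(kind, grid[[gi]], xtr, labels[tr],
                             seed + 1000L * gi + f))
      oof[!tr, gi] <- predict_one(kind, m, xte)
    }
    cv_acc[gi] <- mean(oof[, gi] == labels)
  }
  best_acc <- max(cv_acc)
  cand <- which(cv_acc >= best_acc - 1e-12)
  cx <- vapply(cand, function(i) grid_complexity(kind, grid[[i]]), 1.0)
  best <- cand[order(cx, cand)][1L]
  sc <- scale_fit(x)
  model <- with_seed(seed, fit_one(kind, grid[[best]], scale_apply(x, sc),
                                   labels, seed))
  structure(list(
    kind = kind, model = model, scaling = sc, best = grid[[best]],
    cv_accuracy = cv_acc, grid = grid,
    cv_metrics = evaluate_predictions(oof[, best], labels)),
    class = "ctg_learner")
}

make_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' @export
print.ctg_learner <- function(x, ...) {
  cat("CTG learner:", x$kind, "\n")
  cat("  chosen hyperparameters:",
      paste(names(x$best), vapply(x$best, format, ""), sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$cv_metrics)) {
    cat("  5-fold CV (out-of-fold): ")
    print(x$cv_metrics)
  }
  invisible(x)
}

#' @export
predict.ctg_learner <- function(object, newdata, ...) {
  if (object$kind == "fixed")
    return(rep_len(object$model$preds, nrow(as.data.frame(newdata))))
  x <- as.matrix(as.data.frame(newdata)[names(object$scaling$center)])
  xs <- scale_apply(x, object$scaling)
  if (object$kind == "kmeans") {
    d <- as.matrix(dist(rbind(object$model$centers, xs)))
    k <- nrow(object$model$centers)
    nearest <- apply(d[-(1:k), 1:k, drop = FALSE], 1, which.min)
    unname(object$model$map[nearest])
  } else {
    predict_one(object$kind, object$model, xs)
  }
}

#' K-means classifier over the feature space
#'
#' Fits k-means (features only, labels withheld) with several seeded
#' restarts keeping the best inertia, then maps each cluster to the majority
#' training label among its members; prediction assigns the mapped label of
#' the nearest centroid. Ties in the majority vote break toward the acidotic
#' class (a false alarm is safer than a miss).
#'
#' @param table numeric feature matrix or data frame.
#' @param labels 0/1 vector.
#' @param k number of clusters (default 2).
#' @param nstart restarts.
#' @param seed RNG seed.
#' @return A `ctg_learner` of kind `"kmeans"`.
#' @export
fit_kmeans_classifier <- function(table, labels, k = 2L, nstart = 10L,
                                  seed = 1L) {
  x <- as.matrix(as.data.frame(table)[vapply(as.data.frame(table),
                                             is.numeric, TRUE)])
  labels <- as.integer(as.character(labels))
  if (nrow(x) < k)
    stop("fit_kmeans_classifier: fewer rows than clusters", call. = FALSE)
  if (nrow(unique(x)) < k)
    stop("fit_kmeans_classifier: fewer than k distinct feature rows",
         call. = FALSE)
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  km <- with_seed(seed, kmeans(xs, centers = k, nstart = nstart))
  map <- vapply(seq_len(k), function(ci) {
    members <- labels[km$cluster == ci]
    if (!length(members)) return(1L)
    n1 <- sum(members == 1L)
    n0 <- sum(members == 0L)
    if (n1 >= n0) 1L else 0L          # tie -> acidotic
  }, 1L)
  structure(list(kind = "kmeans",
                 model = list(centers = km$centers, map = map,
                              inertia = km$tot.withinss),
                 scaling = sc, best = list(k = k),
                 cv_metrics = NULL),
            class = "ctg_learner")
}

#' Degenerate learner with fixed predictions
#'
#' A stand-in learner that always emits the supplied votes (recycled to the
#' number of rows it is asked about). Useful for worked examples of the
#' ensemble logic and for testing combination behaviour independently of
#' any fitted model.
#'
#' @param preds vector of 0/1 votes.
#' @return A `ctg_learner` of kind `"fixed"`.
#' @export
fixed_learner <- function(preds) {
  structure(list(kind = "fixed", model = list(preds = as.integer(preds)),
                 scaling = NULL, best = list(), cv_metrics = NULL),
            class = "ctg_learner")
}

#' Abstaining unanimous-vote ensemble
#'
#' Combines two or more fitted learners. For each observation every learner
#' votes 0 or 1; the ensemble outputs that class only if the votes are
#' unanimous and abstains with `"unsure"` otherwise. Abstention is a
#' first-class outcome: downstream accuracy is always computed over the
#' classified observations only.
#'
#' @param models named list of `ctg_learner` objects (>= 2).
#' @return Object of class `ctg_ensemble`.
#' @export
ctg_ensemble <- function(models) {
  if (!length(models))
    stop("ctg_ensemble: empty model set", call. = FALSE)
  if (length(models) < 2L)
    stop("ctg_ensemble: need at least 2 models", call. = FALSE)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("m", seq_along(models))
  stopifnot(all(vapply(models, inherits, TRUE, "ctg_learner")))
  structure(list(models = models), class = "ctg_ensemble")
}

#' @export
print.ctg_ensemble <- function(x, ...) {
  cat("Abstaining unanimous-vote ensemble of",
      paste(names(x$models), collapse = "/"), "\n")
  invisible(x)
}

#' @export
predict.ctg_ensemble <- function(object, newdata, ...) {
  per <- lapply(object$models, predict, newdata = newdata)
  per <- as.data.frame(per)
  consensus_from_votes(per)
}

# Shared consensus rule: unanimous vote -> that class, else "unsure".
consensus_from_votes <- function(per_learner) {
  votes <- as.matrix(per_learner)
  consensus <- apply(votes, 1, function(v) {
    if (all(v == v[1L])) as.character(v[1L]) else "unsure"
  })
  out <- cbind(per_learner,
               data.frame(consensus = consensus, stringsAsFactors = FALSE))
  class(out) <- c("ensemble_decision", class(out))
  out
}

#' Ensemble consensus from already-computed per-learner votes
#'
#' The pure combination rule, usable with externally supplied predictions
#' (e.g. a published worked example): unanimity gives the shared class,
#' anything else abstains.
#'
#' @param per_learner data frame or named list of 0/1 votes, one column per
#'   learner, one row per observation.
#' @return Data frame of the votes plus a `consensus` column with values
#'   `"0"`, `"1"` or `"unsure"`.
#' @export
ensemble_consensus <- function(per_learner) {
  per_learner <- as.data.frame(per_learner)
  if (ncol(per_learner) < 2L)
    stop("ensemble_consensus: need votes from at least 2 learners",
         call. = FALSE)
  consensus_from_votes(per_learner)
}

#' Evaluate learner combinations under the abstaining rule
#'
#' For each combination (subset of named learners of size two or more) the
#' unanimous-vote ensemble is applied to the test features; the number of
#' classified (non-abstained) samples and the accuracy over those samples
#' are reported. With no combinations given, all subsets of size >= 2 are
#' evaluated.
#'
#' @param models named list of `ctg_learner`s.
#' @param newdata test feature table.
#' @param labels test labels (0/1).
#' @param combos list of character vectors of model names; `NULL` = all.
#' @return Data frame with `combo`, `n_classified`, `accuracy` (`NA` when
#'   nothing was classified).
#' @export
evaluate_combinations <- function(models, newdata, labels, combos = NULL) {
  if (is.null(combos)) {
    nm <- names(models)
    combos <- unlist(lapply(2:length(nm), function(k)
      combn(nm, k, simplify = FALSE)), recursive = FALSE)
  }
  labels <- as.integer(as.character(labels))
  preds <- lapply(models, predict, newdata = newdata)
  rows <- lapply(combos, function(cb) {
    if (!all(cb %in% names(models)))
      stop("evaluate_combinations: unknown model in combo: ",
           paste(cb, collapse = "/"), call. = FALSE)
    dec <- consensus_from_votes(as.data.frame(preds[cb]))
    keep <- dec$consensus != "unsure"
    acc <- if (any(keep))
      100 * mean(as.integer(dec$consensus[keep]) == labels[keep]) else
      NA_real_
    data.frame(combo = paste(cb, collapse = "/"),
               n_classified = sum(keep), accuracy = acc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pareto front of coverage versus accuracy
#'
#' A combination is non-dominated when no other point is at least as good in
#' both the number of samples classified and the accuracy, and strictly
#' better in at least one. The front is returned ordered by coverage
#' (descending), then accuracy.
#'
#' @param points data frame with columns `n_classified` and `accuracy`
#'   (rows with `NA` accuracy are never on the front).
#' @return The non-dominated subset of `points`.
#' @export
pareto_front <- function(points) {
  stopifnot(nrow(points) >= 1L)
  n <- points$n_classified
  a <- points$accuracy
  keep <- vapply(seq_len(nrow(points)), function(i) {
    if (is.na(a[i])) return(FALSE)
    !any(n >= n[i] & !is.na(a) & a >= a[i] &
           (n > n[i] | a > a[i]))
  }, TRUE)
  out <- points[keep, , drop = FALSE]
  out[order(-out$n_classified, -out$accuracy), , drop = FALSE]
}

#' Gaussian-noise oversampling of a feature table
#'
#' Augments a small cohort by adding, for each original row,
#' `factor - 1` synthetic copies perturbed with zero-mean Gaussian noise of
#' sd `sigma_frac` times the column sd; labels are copied, count-valued
#' columns are re-rounded to nonnegative integers. Original rows come
#' first, so class balance is preserved exactly.
#'
#' @param table numeric feature data frame.
#' @param labels 0/1 vector.
#' @param factor integer >= 1; total size becomes `factor * nrow(table)`.
#' @param sigma_frac noise scale as a fraction of each column's sd.
#' @param seed RNG seed.
#' @param count_cols columns re-rounded to counts (default `n_*`).
#' @return List with `table` and `labels`, augmented.
#' @export
oversample_gaussian <- function(table, labels, factor = 2, sigma_frac = 0.1,
                                seed = 1L,
                                count_cols = grep("^n_", names(table),
                                                  value = TRUE)) {
  if (factor < 1) stop("oversample_gaussian: factor must be >= 1",
                       call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(list(table = table, labels = labels))
  sds <- vapply(table, function(col) sd(col), 1.0)
  sds[is.na(sds)] <- 0
  with_seed(seed, {
    extra <- list()
    for (r in seq_len(factor - 1L)) {
      noisy <- table
      for (j in seq_along(table))
        noisy[[j]] <- table[[j]] + rnorm(nrow(table), 0, sigma_frac * sds[j])
      for (cn in count_cols)
        noisy[[cn]] <- pmax(round(noisy[[cn]]), 0)
      extra[[r]] <- noisy
    }
    list(table = rbind(table, do.call(rbind, extra)),
         labels = c(labels, rep(labels, factor - 1L)))
  })
}

#' Stratified train/test split
#'
#' Draws a label-stratified test set of `test_size` records (per-class
#' counts proportional, rounded), leaving the remainder for training. Errors
#' if the split would leave a class empty on either side.
#'
#' @param table feature data frame.
#' @param labels 0/1 vector.
#' @param test_size number of test rows.
#' @param seed RNG seed.
#' @return List with `train_idx` and `test_idx` (integer row indices).
#' @export
split_train_test <- function(table, labels, test_size = 24L, seed = 1L) {
  n <- nrow(table)
  labels <- as.integer(as.character(labels))
  if (test_size >= n)
    stop("split_train_test: test_size must be smaller than the cohort",
         call. = FALSE)
  test_idx <- with_seed(seed, {
    idx <- integer(0)
    for (cl in sort(unique(labels))) {
      pool <- which(labels == cl)
      k <- round(test_size * length(pool) / n)
      idx <- c(idx, sample(pool, k))
    }
    sort(idx)
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  for (cl in unique(labels)) {
    if (!any(labels[train_idx] == cl))
      stop("split_train_test: a class would be empty in training",
           call. = FALSE)
    if (!any(labels[test_idx] == cl))
      stop("split_train_test: a class would be empty in the test set",
           call. = FALSE)
  }
  list(train_idx = train_idx, test_idx = test_idx)
}

#' Published benchmark of ensemble combinations
#'
#' A worked example from a published intrapartum acidosis study: ten
#' unanimous-vote combinations of a neural network (NN), support vector
#' machine (SVM), random forest (RF) and k-means clusterer (Clu), each
#' evaluated on a 24-sample test set, reported as the number of samples the
#' combination agreed on and the accuracy over those samples. Used as input
#' to [pareto_front()] in examples and tests.
#'
#' @return Data frame with `combo`, `n_classified`, `accuracy`.
#' @export
reference_combos <- function() {
  data.frame(
    combo = c("NN/SVM", "NN/Clu", "RF/NN", "RF/Clu", "SVM/Clu",
              "NN/RF/SVM", "NN/RF/Clu", "RF/SVM/Clu", "NN/Clu/SVM",
              "NN/RF/Clu/SVM"),
    n_classified = c(18, 21, 20, 22, 17, 15, 14, 16, 17, 13),
    accuracy = c(71.42, 80.95, 85.12, 81.81, 82.35, 86.67, 85.71, 87.50,
                 88.24, 92.30),
    stringsAsFactors = FALSE)
}

#' Published worked example of future-state ensemble votes
#'
#' Per-learner future-state predictions (random forest and neural network)
#' for a non-acidotic and an acidotic tracing at the 2-min (480-step) and
#' 4-min (960-step) horizons, from the same published study. Feeding the
#' votes to [ensemble_consensus()] reproduces the published ensemble row
#' (0, 0, 1, Unsure).
#'
#' @return Data frame with `scenario`, `horizon_steps`, `RF`, `NN`.
#' @export
reference_future_states <- function() {
  data.frame(
    scenario = c("non_acidosis", "non_acidosis", "acidosis", "acidosis"),
    horizon_steps = c(480, 960, 480, 960),
    RF = c(0L, 0L, 1L, 1L),
    NN = c(0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
}
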