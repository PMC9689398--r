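test_that("confusion metrics match hand arithmetic", {
  m <- evaluate_predictions(c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1),
                            c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  ## TP=3 FN=1 TN=4 FP=2
  expect_equal(m$confusion, c(TP = 3, FP = 2, TN = 4, FN = 1))
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 400 / 6)
  expect_equal(m$accuracy, 70)
  expect_equal(m$precision, 60)
  perfect <- evaluate_predictions(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity,
                 perfect$precision), rep(100, 4))
  wrong <- evaluate_predictions(c(1, 0), c(0, 1))
  expect_equal(c(wrong$accuracy, wrong$sensitivity, wrong$specificity), rep(0, 3))
  ## undefined ratios flagged, not zeroed
  nopos <- evaluate_predictions(c(0, 0), c(0, 0))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$precision))
  expect_error(evaluate_predictions(1, c(1, 0)), "equal length")
})

test_that("sensitivity and specificity swap under class complementation", {
  set.seed(4)
  for (i in 1:20) {
    preds <- sample(0:1, 30, replace = TRUE)
    labs <- sample(0:1, 30, replace = TRUE)
    a <- evaluate_predictions(preds, labs)
    b <- evaluate_predictions(1 - preds, 1 - labs)
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
    expect_equal(a$accuracy, b$accuracy)
  }
})

test_that("grid-searched learners separate constructed blobs", {
  blobs <- make_blobs(n = 40, sep = 8, seed = 2)
  svm <- train_learner("svm", blobs$x, blobs$labels, seed = 3)
  expect_equal(max(svm$cv_accuracy), 1)
  expect_equal(svm$cv_metrics$accuracy, 100)
  expect_equal(predict(svm, blobs$x), blobs$labels)
  ## determinism of the selection
  svm2 <- train_learner("svm", blobs$x, blobs$labels, seed = 3)
  expect_identical(svm$best, svm2$best)
  expect_identical(predict(svm, blobs$x), predict(svm2, blobs$x))
  rf <- train_learner("random_forest", blobs$x, blobs$labels, seed = 3)
  expect_equal(predict(rf, blobs$x), blobs$labels)
  nn <- train_learner("neural_net", blobs$x, blobs$labels, seed = 3)
  expect_equal(predict(nn, blobs$x), blobs$labels)
  expect_error(train_learner("svm", blobs$x, rep(1, 40)), "both classes")
  expect_error(train_learner("svm", blobs$x[1:5, ], blobs$labels[1:5]),
               "10 rows")
  expect_error(train_learner("svm", blobs$x, blobs$labels, grid = list()),
               "empty grid")
})

test_that("k-means classifier maps clusters to majority labels", {
  blobs <- make_blobs(n = 30, sep = 10, seed = 5)
  km <- fit_kmeans_classifier(blobs$x, blobs$labels, seed = 1)
  expect_equal(predict(km, blobs$x), blobs$labels)
  ## tied cluster votes break toward acidotic
  x <- data.frame(f1 = c(0, 0.1, 10, 10.1), f2 = c(0, 0.1, 10, 10.1))
  km2 <- fit_kmeans_classifier(x, c(0, 1, 0, 0), seed = 1)
  pr <- predict(km2, data.frame(f1 = c(0.05, 10), f2 = c(0.05, 10)))
  expect_equal(pr, c(1L, 0L))
  expect_error(fit_kmeans_classifier(x[1, , drop = FALSE], 1), "fewer rows")
  expect_error(fit_kmeans_classifier(x[c(1, 1), ], c(0, 1)), "distinct")
})

test_that("the unanimous-vote rule outputs a class only on agreement", {
  dec <- ensemble_consensus(data.frame(RF = c(1, 1, 0), NN = c(1, 0, 0)))
  expect_equal(dec$consensus, c("1", "unsure", "0"))
  expect_error(ensemble_consensus(data.frame(RF = 1)), "at least 2")
  expect_error(ctg_ensemble(list()), "empty")
  expect_error(ctg_ensemble(list(a = fixed_learner(1))), "at least 2")
})

test_that("combination evaluation counts abstentions honestly", {
  labs <- rep(c(0, 1), each = 12)
  newdata <- data.frame(x = seq_len(24))
  agree <- list(a = fixed_learner(labs), b = fixed_learner(labs))
  res <- evaluate_combinations(agree, newdata, labs)
  expect_equal(res$n_classified, 24)
  expect_equal(res$accuracy, 100)
  disagree <- list(a = fixed_learner(rep(0, 24)), b = fixed_learner(rep(1, 24)))
  res2 <- evaluate_combinations(disagree, newdata, labs)
  expect_equal(res2$n_classified, 0)
  expect_true(is.na(res2$accuracy))
  ## one dissent on 4 of 24 in a triple
  v <- labs
  dissent <- v; dissent[1:4] <- 1 - dissent[1:4]
  triple <- list(a = fixed_learner(v), b = fixed_learner(v),
                 c = fixed_learner(dissent))
  res3 <- evaluate_combinations(triple, newdata, labs,
                                combos = list(c("a", "b", "c")))
  expect_equal(res3$n_classified, 20)
  expect_equal(res3$accuracy, 100)
  expect_error(evaluate_combinations(triple, newdata, labs,
                                     combos = list(c("a", "zz"))), "unknown")
})

test_that("adding a learner never increases the number classified", {
  set.seed(7)
  labs <- sample(0:1, 24, replace = TRUE)
  newdata <- data.frame(x = seq_len(24))
  for (rep_i in 1:50) {
    votes <- lapply(1:4, function(i)
      fixed_learner(sample(0:1, 24, replace = TRUE)))
    names(votes) <- c("a", "b", "c", "d")
    res <- evaluate_combinations(votes, newdata, labs)
    sets <- strsplit(res$combo, "/", fixed = TRUE)
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i == j) next
      if (all(sets[[i]] %in% sets[[j]]))
        expect_lte(res$n_classified[j], res$n_classified[i])
    }
  }
})

test_that("pareto front equals the brute-force dominance oracle", {
  ref <- reference_combos()
  front <- pareto_front(ref)
  expect_setequal(front$combo, oracle_pareto(ref)$combo)
  ## the published highest-coverage/accuracy corners are on the front
  expect_true(all(c("NN/RF/Clu/SVM", "NN/Clu/SVM", "RF/NN") %in% front$combo))
  expect_equal(front$combo[1], "RF/Clu")       # ordered by coverage
  set.seed(11)
  for (i in 1:200) {
    pts <- data.frame(n_classified = sample(0:24, 8, replace = TRUE),
                      accuracy = round(runif(8, 50, 100), 2))
    expect_setequal(
      do.call(paste, pareto_front(pts)),
      do.call(paste, oracle_pareto(pts)))
  }
  single <- data.frame(n_classified = 5, accuracy = 80)
  expect_equal(pareto_front(single), single)
  dup <- data.frame(n_classified = c(10, 5, 5), accuracy = c(90, 70, 70))
  expect_equal(nrow(pareto_front(dup)), 1L)
})

test_that("gaussian oversampling preserves originals and balance", {
  set.seed(2)
  tab <- data.frame(baseline_bpm = rnorm(94, 140, 5),
                    n_late_decel = rpois(94, 2))
  labs <- rep(c(0, 1), each = 47)
  out <- oversample_gaussian(tab, labs, factor = 2, sigma_frac = 0.1,
                             seed = 9)
  expect_equal(nrow(out$table), 188)
  expect_equal(out$table[1:94, ], tab)
  expect_equal(table(out$labels), table(c(labs, labs)))
  expect_true(all(out$table$n_late_decel == round(out$table$n_late_decel)))
  expect_true(all(out$table$n_late_decel >= 0))
  ## identity cases
  expect_identical(oversample_gaussian(tab, labs, factor = 1)$table, tab)
  tiny <- oversample_gaussian(tab, labs, factor = 2, sigma_frac = 1e-12,
                              seed = 9)
  expect_equal(tiny$table[95:188, ]$baseline_bpm, tab$baseline_bpm,
               tolerance = 1e-6)
  expect_error(oversample_gaussian(tab, labs, factor = 0.5), ">= 1")
})

test_that("the stratified split is balanced, disjoint and reproducible", {
  tab <- data.frame(x = rnorm(94))
  labs <- rep(c(0, 1), each = 47)
  sp <- split_train_test(tab, labs, 24, seed = 4)
  expect_length(sp$test_idx, 24)
  expect_length(sp$train_idx, 70)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_equal(sum(labs[sp$test_idx] == 1), 12)
  expect_identical(sp, split_train_test(tab, labs, 24, seed = 4))
  expect_error(split_train_test(tab, labs, 94), "smaller")
})
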