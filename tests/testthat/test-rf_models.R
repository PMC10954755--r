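# Small-n model tests use a reduced tree count and a single-value mtry
# grid to stay fast; the full study-scale settings are exercised by the
# acceptance suite.

fast_spec <- function(task, seed = 1L) {
  model_spec(task, n_trees = 50L, cv_folds = 5L, mtry_grid = c(2L, 5L),
             seed = seed)
}

make_training_set <- function(n, seed, sigma = 0.4) {
  set.seed(seed)
  f <- data.frame(
    transcript_id = sprintf("T%04d", seq_len(n)),
    stop_codon = sample(c("UAA", "UAG", "UGA"), n, TRUE),
    nt_p4 = sample(c("A", "C", "G", "U"), n, TRUE),
    utr3_len = round(exp(rnorm(n, 6, 1))),
    nc_letter = sample(c("A", "C", "G", "U"), n, TRUE),
    nc_number = sample(1:100, n, TRUE),
    stringsAsFactors = FALSE)
  y <- 0.8 * (f$stop_codon == "UGA") + 0.5 * (f$nt_p4 == "C") +
    0.4 * log10(f$utr3_len) + rnorm(n, 0, sigma)
  list(features = f, y = y)
}

test_that("nrmse matches closed forms and an independent oracle", {
  expect_equal(nrmse(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(nrmse(c(0, 1), c(0.5, 0.5)), 0.5)
  set.seed(2)
  y <- rnorm(40)
  yhat <- rnorm(40)
  oracle <- sqrt(sum((y - yhat)^2) / 40) / (max(y) - min(y))
  expect_equal(nrmse(y, yhat), oracle, tolerance = 1e-12)
  expect_error(nrmse(rep(1, 5), rnorm(5)), "range")
})

test_that("auroc handles separation, ties, and both-class checks", {
  expect_equal(auroc(c(1, 2, 3, 4), c("low", "low", "high", "high")), 1)
  expect_equal(auroc(rep(1, 6), rep(c("low", "high"), 3)), 0.5)
  expect_error(auroc(1:3, rep("high", 3)), "both classes")
})

test_that("the default mtry grid spans both split heuristics", {
  g <- default_mtry_grid(77)
  expect_true(all(g >= 1 & g <= 77))
  expect_true(ceiling(sqrt(77)) %in% g)
  expect_true(ceiling(77 / 3) %in% g)
  expect_equal(default_mtry_grid(1), 1L)
})

test_that("training is reproducible and predictions are pure", {
  d <- make_training_set(150, seed = 5)
  m1 <- train_regressor(d$features, d$y, fast_spec("regression", 3))
  m2 <- train_regressor(d$features, d$y, fast_spec("regression", 3))
  expect_equal(m1$mtry, m2$mtry)
  p1 <- predict_readthrough(m1, d$features)
  p2 <- predict_readthrough(m2, d$features)
  expect_identical(p1, p2)
  # duplicated rows give duplicated predictions
  dup <- d$features[c(1, 1, 2, 2), ]
  pd <- predict_readthrough(m1, dup)
  expect_equal(pd[1], pd[2])
  expect_equal(pd[3], pd[4])
})

test_that("planted signal beats a controls-only model and noise matches baseline", {
  d <- make_training_set(600, seed = 8)
  full <- train_regressor(d$features, d$y, fast_spec("regression", 1))
  nc_only <- train_regressor(d$features[, c("transcript_id", "nc_letter",
                                            "nc_number")],
                             d$y, model_spec("regression", n_trees = 50L,
                                             mtry_grid = 1L, seed = 1))
  expect_lt(full$cv_metric, nc_only$cv_metric - 0.05)

  # target independent of all features: CV NRMSE near the mean-predictor
  set.seed(9)
  y_noise <- rnorm(400)
  f_noise <- make_training_set(400, seed = 10)$features
  m_noise <- train_regressor(f_noise, y_noise, fast_spec("regression", 2))
  baseline <- sd(y_noise) / diff(range(y_noise))
  expect_lt(abs(m_noise$cv_metric - baseline), 0.03)
})

test_that("classifier recovers planted separation and rejects bad folds", {
  d <- make_training_set(400, seed = 12, sigma = 0.25)
  lab <- ifelse(d$y > quantile(d$y, 0.85), "high",
                ifelse(d$y < quantile(d$y, 0.15), "low", "none"))
  keep <- lab != "none"
  m <- train_classifier(d$features[keep, ], lab[keep],
                        fast_spec("classification", 4))
  expect_gt(m$cv_metric, 0.8)
  scores <- predict_readthrough(m, d$features[keep, ])
  expect_true(all(scores >= 0 & scores <= 1))

  # shuffled labels: no signal left
  set.seed(13)
  m0 <- train_classifier(d$features[keep, ], sample(lab[keep]),
                         fast_spec("classification", 4))
  expect_lt(abs(m0$cv_metric - 0.5), 0.12)

  expect_error(
    train_classifier(d$features[1:4, ], c("high", "high", "low", "low"),
                     model_spec("classification", cv_folds = 5L)),
    "class count")
  expect_error(
    train_classifier(d$features[keep, ], rep("high", sum(keep)),
                     fast_spec("classification", 1)),
    "both classes")
})

test_that("a perfect predictor dominates permutation importance", {
  d <- make_training_set(200, seed = 15)
  f <- d$features
  f$leak <- d$y
  m <- train_regressor(f, d$y, model_spec("regression", n_trees = 50L,
                                          mtry_grid = 3L, seed = 2))
  imp <- permutation_importance(m)
  expect_equal(imp$feature[imp$rank == 1], "leak")
  unscaled <- permutation_importance(m, scaled = FALSE)
  expect_equal(unscaled$feature[unscaled$rank == 1], "leak")
  expect_false(identical(imp$score, unscaled$score))
})

test_that("constant features get zero-ish importance and unseen levels warn", {
  d <- make_training_set(150, seed = 17)
  f <- d$features
  f$constant <- "X"
  m <- train_regressor(f, d$y, model_spec("regression", n_trees = 50L,
                                          mtry_grid = 2L, seed = 2))
  imp <- permutation_importance(m)
  expect_equal(imp$score[imp$feature == "constant"], 0)

  newdata <- f[1:3, ]
  newdata$stop_codon[1] <- "XXX"
  expect_warning(predict_readthrough(m, newdata), "unseen")
})

test_that("CV folds partition the data", {
  ids <- readthroughr:::cv_fold_ids(103, 5, seed = 42)
  expect_equal(length(ids), 103L)
  expect_setequal(unique(ids), 1:5)
  expect_true(max(table(ids)) - min(table(ids)) <= 1)
  strat <- rep(c("a", "b"), c(60, 43))
  ids2 <- readthroughr:::cv_fold_ids(103, 5, seed = 42, strata = strat)
  expect_true(max(table(ids2[strat == "b"])) -
                min(table(ids2[strat == "b"])) <= 1)
})
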