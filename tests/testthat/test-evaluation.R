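test_that("confusion counts tally each outcome and partition the sample", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 0, tn = 2, fn = 0))
  cc2 <- confusion(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                   c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(unlist(cc2[c("tp", "fn", "tn", "fp")]),
               c(tp = 3, fn = 2, tn = 4, fp = 1))
  cc3 <- confusion(c(1, 1, 1), c(0, 0, 0))
  expect_equal(unlist(cc3[c("tp", "fn", "tn", "fp")]),
               c(tp = 0, fn = 3, tn = 0, fp = 0))
  expect_error(confusion(c(1, 0), c(1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics reproduce the printed formulas, including edge conventions", {
  perfect <- metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unlist(perfect[c("se", "sp", "acc", "mcc", "f1")]),
               c(se = 1, sp = 1, acc = 1, mcc = 1, f1 = 1))

  r <- metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(r$se, 0.6)
  expect_equal(r$sp, 0.8)
  expect_equal(r$acc, 0.7)
  expect_equal(r$f1, 2 * (0.75 * 0.6) / (0.75 + 0.6))
  expect_equal(r$mcc, 10 / sqrt(4 * 5 * 5 * 6))

  # all-negative predictor: zero-denominator metrics are 0 and flagged
  z <- metrics(list(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(unlist(z[c("se", "sp", "acc", "mcc", "f1")]),
               c(se = 0, sp = 1, acc = 0.5, mcc = 0, f1 = 0))
  expect_true(all(c("mcc", "f1") %in% z$zero_denominator))
  expect_error(metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)), "no evaluated")
})

test_that("metrics agree with hand formulas on random confusion matrices", {
  withr::with_seed(41, {
    for (i in 1:200) {
      cc <- as.list(stats::setNames(rpois(4, 6), c("tp", "fp", "tn", "fn")))
      if (Reduce(`+`, cc) == 0) next
      r <- metrics(cc)
      with(cc, {
        expect_equal(r$acc, (tp + tn) / (tp + fp + tn + fn))
        if (tp + fn > 0) expect_equal(r$se, tp / (tp + fn))
        if (tn + fp > 0) expect_equal(r$sp, tn / (tn + fp))
        den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
        if (den > 0) expect_equal(r$mcc, (tp * tn - fn * fp) / den)
      })
    }
  })
})

test_that("MCC is invariant under a simultaneous class swap", {
  withr::with_seed(43, {
    for (i in 1:20) {
      y <- rbinom(40, 1, 0.5); p <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) next
      m1 <- metrics(confusion(y, p))
      m2 <- metrics(confusion(1 - y, 1 - p))
      expect_equal(m1$mcc, m2$mcc)
    }
  })
})

test_that("ROC/AUC equals the Mann-Whitney pair count and is well-formed", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 3 / 4)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  withr::with_seed(47, {
    for (i in 1:40) {
      n <- sample(6:25, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
      ra <- roc_auc(y, s)
      expect_equal(ra$auc, oracle_auc(y, s))
      # curve anchored at (0,0) and (1,1), monotone in both coordinates
      expect_equal(ra$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
      expect_equal(as.numeric(ra$roc_points[nrow(ra$roc_points), ]), c(1, 1))
      expect_true(all(diff(ra$roc_points$fpr) >= 0))
      expect_true(all(diff(ra$roc_points$tpr) >= 0))
      # invariance under a strictly monotone score transform
      expect_equal(roc_auc(y, exp(3 * s))$auc, ra$auc)
    }
  })
})

test_that("ROC/AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(53, {
    for (i in 1:10) {
      y <- rbinom(30, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- rnorm(30)
      expect_equal(roc_auc(y, s)$auc,
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))))
    }
  })
})

test_that("Yule's Q follows its closed forms", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  a <- c(1, 1, 0, 0, 0, 0, 1, 1)  # right on 4, wrong on 4
  expect_equal(yule_q(a, a, y), 1)  # identical classifiers
  # N11=4, N00=4, N01=1, N10=1 -> 15/17
  y2 <- rep(1, 10)
  a2 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)  # correct on 1-5
  b2 <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0)  # correct on 1-4 and 6
  expect_equal(yule_q(a2, b2, y2), 15 / 17)
  # independence: N11*N00 == N01*N10 -> 0
  y3 <- rep(1, 4)
  a3 <- c(1, 1, 0, 0)
  b3 <- c(1, 0, 1, 0)  # N11=1, N00=1, N10=1, N01=1
  expect_equal(yule_q(a3, b3, y3), 0)
  # symmetry in the two classifiers
  withr::with_seed(59, {
    for (i in 1:20) {
      yy <- rbinom(20, 1, 0.5); aa <- rbinom(20, 1, 0.5); bb <- rbinom(20, 1, 0.5)
      expect_equal(yule_q(aa, bb, yy), yule_q(bb, aa, yy))
    }
  })
  expect_error(yule_q(c(1, 0), c(1), c(1, 0)), "length")
})

test_that("forest tree diversity matches an exhaustive pair loop", {
  noisy <- generate_table(synthetic_spec(n_molecules = 120, n_features = 4,
                                         flip_noise = 0.2, seed = 61,
                                         add_constant = FALSE,
                                         add_zero = FALSE))
  cfg <- ensemble_config(n_estimators = 5, min_samples_leaf = 2, seed = 7)
  m <- train_ensemble(noisy$X, noisy$labels, cfg)
  member <- m$members[[1]]
  rep <- forest_tree_diversity(member, noisy$X, noisy$labels)
  expect_equal(nrow(rep$pairwise_q), choose(5, 2))
  # independent recomputation from the per-tree votes
  ind <- predict(member, noisy$X, predict.all = TRUE)$individual
  votes <- matrix(as.integer(ind == "1"), nrow = nrow(ind))
  k <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    k <- k + 1
    expect_equal(rep$pairwise_q$q[k],
                 yule_q(votes[, i], votes[, j], noisy$labels))
  }
  expect_equal(rep$average_q, mean(rep$pairwise_q$q))
  expect_true(all(abs(rep$pairwise_q$q) <= 1))
})

test_that("a forest of effectively identical imperfect trees has Q = 1", {
  # one binary feature fully determines the fit, so every tree predicts the
  # same way; judging against partially flipped labels makes them err
  # together (N01 = N10 = 0, N00 > 0), hence Q = 1 for every pair
  withr::with_seed(67, {
    x1 <- rep(c(0, 1), each = 30)
    X <- cbind(d001 = x1, d002 = 0.01 * rnorm(60))
    y_fit <- as.integer(x1 == 1)
    m <- randomForest::randomForest(
      x = X, y = factor(y_fit, levels = c(0, 1)), ntree = 2, nodesize = 1,
      mtry = 2)
    y_eval <- y_fit
    y_eval[c(1, 31)] <- 1L - y_eval[c(1, 31)]
    rep <- forest_tree_diversity(m, X, y_eval)
    expect_equal(rep$average_q, 1)
  })
  expect_error(
    forest_tree_diversity(
      randomForest::randomForest(x = cbind(a = rnorm(30), b = rnorm(30)),
                                 y = factor(rbinom(30, 1, 0.5)), ntree = 1),
      cbind(a = rnorm(5), b = rnorm(5)), rbinom(5, 1, 0.5)),
    "fewer than 2")
})

test_that("identity predictions give perfect accuracy for any labeling", {
  withr::with_seed(71, {
    for (i in 1:10) {
      y <- rbinom(25, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(metrics(confusion(y, y))$acc, 1)
    }
  })
})
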