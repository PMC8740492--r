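# a hand-built attribution_matrix for tests that need controlled phi values
fake_attribution <- function(phi, base = 0.5) {
  structure(list(phi = phi, base_value = base,
                 molecule_ids = rownames(phi), feature_names = colnames(phi)),
            class = "attribution_matrix")
}

test_that("hand-built trees: stumps and constant models attribute exactly", {
  # constant model (single leaf): no feature can move the output
  const_tree <- list(left = -1L, right = -1L, feature = -1L,
                     threshold = 0, value = 0.7)
  bg <- matrix(rnorm(20 * 3), 20, 3)
  x <- matrix(rnorm(2 * 3), 2, 3)
  res <- hobclass:::cpp_forest_shap(list(const_tree), x, bg)
  expect_equal(res$phi, matrix(0, 2, 3))
  expect_equal(res$base_value, 0.7)

  # single-split stump on feature 2: all mass on that feature, and the
  # one-feature Shapley value is f(x) - E[f] exactly
  stump <- list(left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
                feature = c(1L, -1L, -1L), threshold = c(0, 0, 0),
                value = c(0, 0, 1))
  res2 <- hobclass:::cpp_forest_shap(list(stump), x, bg)
  expect_equal(res2$phi[, c(1, 3)], matrix(0, 2, 2))
  p_right <- mean(bg[, 2] > 0)  # E[f] under the background
  for (r in 1:2) {
    fx <- as.numeric(x[r, 2] > 0)
    expect_equal(res2$phi[r, 2], fx - p_right)
    expect_equal(res2$base_value + sum(res2$phi[r, ]), fx)
  }
})

test_that("forest attributions equal the exhaustive-subset Shapley oracle", {
  noisy <- generate_table(synthetic_spec(n_molecules = 60, n_features = 4,
                                         flip_noise = 0.15, seed = 73,
                                         add_constant = FALSE,
                                         add_zero = FALSE))
  member <- withr::with_seed(74, randomForest::randomForest(
    x = noisy$X, y = factor(noisy$labels, levels = c(0, 1)),
    ntree = 3, nodesize = 10))
  bg <- noisy$X[1:30, ]
  xq <- noisy$X[31:33, ]
  am <- attributions(member, xq, background = bg)
  trees <- hobclass:::rf_tree_list(member)
  for (r in 1:3) {
    brute <- Reduce(`+`, lapply(trees, function(tr)
      oracle_tree_shap(tr, bg, xq[r, ]))) / length(trees)
    expect_equal(unname(am$phi[r, ]), brute, tolerance = 1e-10)
  }
})

test_that("attributions are locally accurate for every ensemble member", {
  tab <- generate_table(synthetic_spec(n_molecules = 200, n_features = 8,
                                       flip_noise = 0.1, seed = 79))
  X <- filter_descriptors(tab$X)$matrix
  cfg <- ensemble_config(n_estimators = 15, min_samples_leaf = 4, seed = 5)
  model <- train_ensemble(X, tab$labels, cfg)
  atts <- ensemble_attributions(model)
  for (i in seq_along(model$members)) {
    prob <- predict(model$members[[i]], X, type = "prob")[, "1"]
    recon <- atts[[i]]$base_value + rowSums(atts[[i]]$phi)
    expect_lt(max(abs(recon - unname(prob))), 1e-6)
  }
  # determinism for a fixed model and X
  atts2 <- attributions(model$members[[1]], X,
                        background = model$X[model$fold_assignments != 1, ])
  expect_identical(atts2$phi, atts[[1]]$phi)
  # schema mismatch is an error
  Xs <- X[, rev(colnames(X))]
  expect_error(attributions(model$members[[1]], Xs), "order|missing")
})

test_that("consensus importance averages members and counts occurrences", {
  phiA <- matrix(c(0.2, -0.2, 0.05, 0.0, 0.01, 0.02), 2, 3,
                 dimnames = list(c("m1", "m2"), c("fx", "fy", "fz")))
  phiB <- matrix(c(0.1, 0.1, 0.3, -0.3, 0.0, 0.0), 2, 3,
                 dimnames = list(c("m1", "m2"), c("fx", "fy", "fz")))
  a <- fake_attribution(phiA); b <- fake_attribution(phiB)

  # a single member: consensus equals that member's mean |phi|
  one <- consensus_importance(list(a), k = 3)
  expect_equal(one$consensus_importance[c("fx", "fy", "fz")],
               c(fx = 0.2, fy = 0.025, fz = 0.015))

  # five identical members: every consensus top-k feature occurs 5 times
  five <- consensus_importance(list(a, a, a, a, a), k = 2)
  expect_equal(unname(five$occurrence_counts[five$top_k]), c(5L, 5L))

  # member order does not matter
  ab <- consensus_importance(list(a, b), k = 2)
  ba <- consensus_importance(list(b, a), k = 2)
  expect_equal(ab$consensus_importance, ba$consensus_importance)
  expect_equal(ab$occurrence_counts, ba$occurrence_counts)
  expect_equal(unname(ab$consensus_importance[c("fx", "fy")]),
               c((0.2 + 0.1) / 2, (0.025 + 0.3) / 2))
  # sorted non-increasing, non-negative
  expect_true(all(diff(ab$consensus_importance) <= 0))
  expect_true(all(ab$consensus_importance >= 0))

  phiC <- phiA; colnames(phiC) <- c("fx", "fy", "OTHER")
  expect_error(consensus_importance(list(a, fake_attribution(phiC))),
               "schemas")
})

test_that("the signal feature dominates consensus importance on synthetic data", {
  tab <- generate_table(synthetic_spec(n_molecules = 300, n_features = 10,
                                       flip_noise = 0.1, seed = 83,
                                       add_constant = FALSE, add_zero = FALSE))
  cfg <- ensemble_config(n_estimators = 20, min_samples_leaf = 4, seed = 11)
  model <- train_ensemble(tab$X, tab$labels, cfg)
  imp <- consensus_importance(ensemble_attributions(model), k = 5)
  expect_equal(names(imp$consensus_importance)[1], "d001")
  expect_equal(unname(imp$occurrence_counts["d001"]), 5L)
})

test_that("dependence data reports direction and shape correctly", {
  # all-zero attributions: no association
  phi0 <- matrix(0, 10, 2, dimnames = list(NULL, c("fa", "fb")))
  X0 <- cbind(fa = rnorm(10), fb = rnorm(10))
  d0 <- dependence_data("fa", list(fake_attribution(phi0)), X0)
  expect_equal(d0$sign, "indeterminate")
  expect_equal(nrow(d0$data), 10)
  expect_error(dependence_data("nope", list(fake_attribution(phi0)), X0),
               "unknown feature")

  # a polar-surface-area-like feature: larger values push the negative
  # class, so the mean attribution trends downward with the feature value
  tab <- generate_table(synthetic_spec(n_molecules = 300, n_features = 6,
                                       signal_features = 1L,
                                       coefficients = -1,
                                       flip_noise = 0.05, seed = 89,
                                       add_constant = FALSE,
                                       add_zero = FALSE))
  cfg <- ensemble_config(n_estimators = 20, min_samples_leaf = 4, seed = 13)
  model <- train_ensemble(tab$X, tab$labels, cfg)
  atts <- ensemble_attributions(model)
  dep <- dependence_data("d001", atts, model$X)
  expect_equal(dep$sign, "negative")
  expect_lt(dep$rho, -0.5)
  expect_equal(nrow(dep$data), nrow(model$X))
})
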