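#' Configuration for the consensus random-forest ensemble
#'
#' The two tuned hyperparameters are the number of trees per forest
#' (`n_estimators`) and the minimum number of samples at a leaf
#' (`min_samples_leaf`); all other forest settings stay at the learner's
#' defaults. The default grid spans both optima conventionally reported for
#' this problem (31 trees / leaf size 6 at the 50% cutoff, 10 trees / leaf
#' size 6 at the 20% cutoff).
#'
#' @param n_estimators trees per forest member.
#' @param min_samples_leaf minimum samples at a leaf node.
#' @param n_folds number of cross-validation folds (= ensemble members).
#' @param seed integer seed controlling fold assignment and forest fitting.
#' @param grid named list with candidate `n_estimators` and
#'   `min_samples_leaf` values for [tune_hyperparameters()].
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(n_estimators = 31, min_samples_leaf = 6,
                            n_folds = 5, seed = 1,
                            grid = list(n_estimators = c(10, 31, 50, 100, 200),
                                        min_samples_leaf = c(1, 2, 4, 6, 8))) {
  stopifnot(n_estimators >= 1, min_samples_leaf >= 1, n_folds >= 2,
            length(grid$n_estimators) >= 1, length(grid$min_samples_leaf) >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 grid = grid),
            class = "ensemble_config")
}

#' Deterministic stratified fold assignment
#'
#' Permutes each class separately under the given seed and deals indices
#' round-robin, so every fold carries both classes whenever each class has
#' at least `n_folds` members.
#'
#' @param y integer 0/1 labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer fold index (1..n_folds) per observation.
#' @export
stratified_folds <- function(y, n_folds, seed) {
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("labels contain a single class; stratified folds are undefined",
         call. = FALSE)
  if (min(table(y)) < n_folds)
    stop("stratification error: a class has fewer members (",
         min(table(y)), ") than folds (", n_folds,
         "); reduce n_folds or rebalance the data", call. = FALSE)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Fit one seeded forest member on a 0/1 outcome.
rf_fit <- function(X, y, ntree, nodesize, seed) {
  yf <- factor(y, levels = c(0, 1))
  with_seed(seed, randomForest::randomForest(
    x = as.matrix(X), y = yf, ntree = ntree, nodesize = nodesize))
}

# Positive-class vote fraction of a fitted member.
rf_prob <- function(member, X) {
  unname(predict(member, as.matrix(X), type = "prob")[, "1"])
}

# Deterministic member vote: positive iff more than half the trees agree.
rf_vote <- function(member, X) as.integer(rf_prob(member, X) > 0.5)

#' Grid search for forest hyperparameters by cross-validated accuracy
#'
#' Evaluates every grid point by mean accuracy over the configuration's
#' stratified folds and returns the best point. Ties are broken toward the
#' smaller `n_estimators`, then the smaller `min_samples_leaf`. The full
#' search log (one mean CV accuracy per grid point) is returned alongside.
#'
#' @param X descriptor matrix (rows = molecules).
#' @param y integer 0/1 labels.
#' @param config an [ensemble_config()].
#' @return list with `n_estimators`, `min_samples_leaf`, and `log` (a data
#'   frame of every grid point with its mean CV accuracy).
#' @export
tune_hyperparameters <- function(X, y, config = ensemble_config()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("labels contain a single class; tuning is undefined", call. = FALSE)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2 * config$n_folds)
  fold <- stratified_folds(y, config$n_folds, config$seed)
  grid <- expand.grid(n_estimators = sort(config$grid$n_estimators),
                      min_samples_leaf = sort(config$grid$min_samples_leaf))
  grid <- grid[order(grid$n_estimators, grid$min_samples_leaf), , drop = FALSE]
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fold_acc <- numeric(config$n_folds)
    for (i in seq_len(config$n_folds)) {
      tr <- fold != i
      m <- rf_fit(X[tr, , drop = FALSE], y[tr],
                  grid$n_estimators[g], grid$min_samples_leaf[g],
                  seed = config$seed + 1009L * g + i)
      fold_acc[i] <- mean(rf_vote(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    acc[g] <- mean(fold_acc)
  }
  best <- which.max(acc)  # grid is sorted, so the first maximum wins ties
  list(n_estimators = grid$n_estimators[best],
       min_samples_leaf = grid$min_samples_leaf[best],
       log = cbind(grid, mean_cv_accuracy = acc))
}

#' Train the cross-validated forest ensemble
#'
#' Splits the data into `n_folds` stratified folds and fits one forest per
#' fold on the complementary folds, yielding exactly `n_folds` members (five
#' by default). Each member's held-out-fold predictions are retained so
#' training-set performance can be reported without leakage.
#'
#' @param X descriptor matrix (rows = molecules; column names are the
#'   feature schema shared by all members).
#' @param y integer 0/1 labels.
#' @param config an [ensemble_config()] with the tuned hyperparameters.
#' @return a `hob_ensemble` object: `members`, `feature_names`, `config`,
#'   `fold_assignments`, the training data (`X`, `y`) for attribution
#'   backgrounds, and `oof` (held-out fold predictions per molecule).
#' @export
train_ensemble <- function(X, y, config = ensemble_config()) {
  y <- as.integer(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  fold <- stratified_folds(y, config$n_folds, config$seed)
  members <- vector("list", config$n_folds)
  oof_prob <- numeric(length(y))
  for (i in seq_len(config$n_folds)) {
    tr <- fold != i
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
      stop("stratification error: fold ", i, " has a single class; ",
           "use more data or fewer folds", call. = FALSE)
    members[[i]] <- rf_fit(X[tr, , drop = FALSE], y[tr],
                           config$n_estimators, config$min_samples_leaf,
                           seed = config$seed + 7919L * i)
    oof_prob[!tr] <- rf_prob(members[[i]], X[!tr, , drop = FALSE])
  }
  oof <- data.frame(fold = fold, prob = oof_prob,
                    vote = as.integer(oof_prob > 0.5), y = y)
  structure(list(members = members, feature_names = colnames(X),
                 config = config, fold_assignments = fold,
                 X = X, y = y, oof = oof),
            class = "hob_ensemble")
}

#' @export
print.hob_ensemble <- function(x, ...) {
  cat("Consensus forest ensemble:", length(x$members), "members,",
      x$config$n_estimators, "trees each, min leaf",
      x$config$min_samples_leaf, "\n")
  held <- vapply(seq_along(x$members), function(i) {
    sel <- x$fold_assignments == i
    mean(x$oof$vote[sel] == x$y[sel])
  }, numeric(1))
  cat("  held-out fold accuracy per member:",
      paste(sprintf("%.3f", held), collapse = " "), "\n")
  invisible(x)
}

# Check a prediction matrix against the ensemble feature schema.
check_schema <- function(feature_names, X) {
  if (is.null(colnames(X)) || !identical(colnames(X), feature_names)) {
    missing <- setdiff(feature_names, colnames(X))
    extra <- setdiff(colnames(X), feature_names)
    if (length(missing) || length(extra))
      stop("feature schema mismatch; missing: [",
           paste(missing, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]", call. = FALSE)
    stop("feature columns are not in the training order; reorder columns to ",
         "match feature_names", call. = FALSE)
  }
  invisible(TRUE)
}

#' Consensus prediction by equal-weight voting
#'
#' Each member votes a class; the consensus label is the majority over the
#' members (an odd member count cannot tie). The consensus score - used for
#' ROC/AUC of the voting model - is the unweighted mean of the members'
#' positive-class probabilities, the only continuous score consistent with
#' equal voting weights.
#'
#' @param model a `hob_ensemble` from [train_ensemble()].
#' @param X descriptor matrix whose columns match the training schema
#'   exactly (names and order).
#' @return data frame with one row per molecule: `vote_1..vote_k`,
#'   `consensus_score` in `[0, 1]`, and `consensus_label` (0/1).
#' @export
predict_consensus <- function(model, X) {
  X <- as.matrix(X)
  check_schema(model$feature_names, X)
  k <- length(model$members)
  votes <- vapply(model$members, function(mm) rf_vote(mm, X), integer(nrow(X)))
  probs <- vapply(model$members, function(mm) rf_prob(mm, X), numeric(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  probs <- matrix(probs, nrow = nrow(X))
  out <- as.data.frame(votes)
  names(out) <- paste0("vote_", seq_len(k))
  out$consensus_score <- rowMeans(probs)
  out$consensus_label <- as.integer(rowSums(votes) > k / 2)
  if (!is.null(rownames(X))) out <- cbind(id = rownames(X), out)
  out
}

#' Stability of the consensus under repeated re-splitting and retraining
#'
#' Merges the training pool with an extra labeled set, then repeatedly
#' re-splits the merged data into new stratified folds, retrains the full
#' ensemble, and records the consensus accuracy on a fixed evaluation set.
#' Reports the mean and standard deviation over the repeats (the evaluation
#' set must be disjoint from the merged training pool).
#'
#' @param X_train,y_train training pool.
#' @param X_extra,y_extra extra labeled molecules merged into the pool
#'   (pass `NULL` / zero-row inputs to retrain on the pool alone).
#' @param X_eval,y_eval fixed evaluation set.
#' @param config an [ensemble_config()].
#' @param repeats number of retrain rounds (>= 2 so the sd is defined).
#' @param base_seed seed offset; round `r` uses `base_seed + r`.
#' @param seeds optional explicit per-round seeds overriding `base_seed`.
#' @return list with `mean`, `sd`, and the per-round `accuracies`.
#' @export
repeated_retrain_evaluation <- function(X_train, y_train, X_extra, y_extra,
                                        X_eval, y_eval,
                                        config = ensemble_config(),
                                        repeats = 50, base_seed = config$seed,
                                        seeds = NULL) {
  if (repeats < 2)
    stop("repeats must be >= 2 for the standard deviation to be defined",
         call. = FALSE)
  if (is.null(seeds)) seeds <- base_seed + seq_len(repeats)
  stopifnot(length(seeds) == repeats)
  if (!is.null(X_extra) && nrow(X_extra) > 0) {
    X_pool <- rbind(as.matrix(X_train), as.matrix(X_extra))
    y_pool <- c(as.integer(y_train), as.integer(y_extra))
  } else {
    X_pool <- as.matrix(X_train); y_pool <- as.integer(y_train)
  }
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[r])
    model <- train_ensemble(X_pool, y_pool, cfg)
    pred <- predict_consensus(model, as.matrix(X_eval))
    acc[r] <- mean(pred$consensus_label == as.integer(y_eval))
  }
  list(mean = mean(acc), sd = sd(acc), accuracies = acc)
}

#' Persist an ensemble to a directory
#'
#' Writes one serialized forest per member (`member_<i>.rds`), the training
#' data (`train.rds`, needed as the attribution background), and a JSON
#' metadata file (feature schema, configuration, seed, fold map).
#'
#' @param model a `hob_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(model$members))
    saveRDS(model$members[[i]], file.path(dir, sprintf("member_%d.rds", i)))
  saveRDS(list(X = model$X, y = model$y, oof = model$oof),
          file.path(dir, "train.rds"))
  meta <- list(n_members = length(model$members),
               feature_names = model$feature_names,
               config = model$config[c("n_estimators", "min_samples_leaf",
                                       "n_folds", "seed")],
               fold_assignments = model$fold_assignments)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an ensemble saved by [save_ensemble()]
#'
#' @param dir directory written by [save_ensemble()].
#' @return a `hob_ensemble`.
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  members <- lapply(seq_len(meta$n_members), function(i)
    readRDS(file.path(dir, sprintf("member_%d.rds", i))))
  train <- readRDS(file.path(dir, "train.rds"))
  cfg <- ensemble_config(n_estimators = meta$config$n_estimators,
                         min_samples_leaf = meta$config$min_samples_leaf,
                         n_folds = meta$config$n_folds,
                         seed = meta$config$seed)
  structure(list(members = members, feature_names = meta$feature_names,
                 config = cfg, fold_assignments = meta$fold_assignments,
                 X = train$X, y = train$y, oof = train$oof),
            class = "hob_ensemble")
}
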