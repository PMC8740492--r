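# Flatten a randomForest classifier into the flat-array tree representation
# consumed by the C++ attribution code. A leaf's value is its 0/1 vote for
# the positive class (second factor level), so the tree mean equals the
# forest's positive-class vote fraction.
rf_tree_list <- function(member) {
  pos_index <- 2L
  lapply(seq_len(member$ntree), function(k) {
    tr <- randomForest::getTree(member, k, labelVar = FALSE)
    leaf <- tr[, "status"] == -1
    list(left = as.integer(tr[, "left daughter"]) - 1L,
         right = as.integer(tr[, "right daughter"]) - 1L,
         feature = ifelse(leaf, -1L, as.integer(tr[, "split var"]) - 1L),
         threshold = as.numeric(tr[, "split point"]),
         value = ifelse(leaf, as.numeric(tr[, "prediction"] == pos_index), 0))
  })
}

rf_feature_names <- function(member) rownames(member$importance)

#' Tree-path Shapley attributions for one forest member
#'
#' Computes exact per-molecule, per-feature Shapley values of the member's
#' positive-class probability, using the path-dependent tree algorithm with
#' node covers taken from a background matrix (normally the member's
#' training data). The attributions are locally accurate: for every
#' molecule, `base_value + sum(phi)` reproduces the member's predicted
#' positive-class probability.
#'
#' @param member a fitted `randomForest` classifier.
#' @param X matrix of molecules to explain; columns must match the member's
#'   feature schema exactly.
#' @param background matrix supplying the cover distribution (defaults to
#'   `X`; use the member's training data for the standard construction).
#' @return an `attribution_matrix`: `phi` (molecules x features),
#'   `base_value`, `molecule_ids`, `feature_names`.
#' @export
attributions <- function(member, X, background = X) {
  X <- as.matrix(X); background <- as.matrix(background)
  fn <- rf_feature_names(member)
  check_schema(fn, X)
  check_schema(fn, background)
  res <- cpp_forest_shap(rf_tree_list(member), X, background)
  dimnames(res$phi) <- list(rownames(X), fn)
  structure(list(phi = res$phi, base_value = res$base_value,
                 molecule_ids = rownames(X), feature_names = fn),
            class = "attribution_matrix")
}

#' Attributions for every ensemble member
#'
#' Runs [attributions()] for each member, with each member's background set
#' to its own training rows (the folds it was fitted on).
#'
#' @param model a `hob_ensemble` from [train_ensemble()].
#' @param X molecules to explain (defaults to the full training matrix).
#' @return list of `attribution_matrix`, one per member.
#' @export
ensemble_attributions <- function(model, X = model$X) {
  lapply(seq_along(model$members), function(i) {
    bg <- model$X[model$fold_assignments != i, , drop = FALSE]
    attributions(model$members[[i]], X, background = bg)
  })
}

#' Consensus feature importance across ensemble members
#'
#' Per-member importance is the mean absolute attribution of each feature
#' over the explained molecules; the consensus importance is the unweighted
#' mean of the per-member vectors. Additionally counts, for every feature,
#' in how many members' own top-`k` lists it appears (the occurrence
#' statistic).
#'
#' @param per_model list of `attribution_matrix` objects with identical
#'   feature schemas (one per member), e.g. from [ensemble_attributions()].
#' @param k size of each member's top list (default 20).
#' @return an `importance_report`: `per_model_importance` (features x
#'   members), `consensus_importance` (named, sorted non-increasing),
#'   `top_k`, and `occurrence_counts`.
#' @export
consensus_importance <- function(per_model, k = 20) {
  stopifnot(length(per_model) >= 1)
  fn <- per_model[[1]]$feature_names
  for (am in per_model)
    if (!identical(am$feature_names, fn))
      stop("attribution matrices have different feature schemas",
           call. = FALSE)
  imp <- vapply(per_model, function(am) colMeans(abs(am$phi)),
                numeric(length(fn)))
  imp <- matrix(imp, nrow = length(fn),
                dimnames = list(fn, paste0("member_", seq_along(per_model))))
  consensus <- sort(rowMeans(imp), decreasing = TRUE)
  k <- min(k, length(fn))
  top_k <- names(consensus)[seq_len(k)]
  occur <- stats::setNames(integer(length(fn)), fn)
  for (m in seq_along(per_model)) {
    top_m <- names(sort(imp[, m], decreasing = TRUE))[seq_len(k)]
    occur[top_m] <- occur[top_m] + 1L
  }
  structure(list(per_model_importance = imp,
                 consensus_importance = consensus,
                 top_k = top_k, occurrence_counts = occur, k = k),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Consensus feature importance (mean |phi| averaged over",
      ncol(x$per_model_importance), "members), top", x$k, ":\n")
  top <- x$consensus_importance[seq_len(min(x$k, 10))]
  for (nm in names(top))
    cat(sprintf("  %-16s %.4f  (in %d member top-%d lists)\n",
                nm, top[nm], x$occurrence_counts[nm], x$k))
  invisible(x)
}

#' Dependence data for one feature
#'
#' Pairs every molecule's feature value with its mean attribution across
#' members (the data behind a dependence plot) and summarizes the
#' association by the Spearman rank correlation. The direction is reported
#' as `positive` or `negative` when `|rho| >= 0.1`, otherwise
#' `indeterminate`; a positive direction means larger feature values push
#' the predicted bioavailability class up.
#'
#' @param feature feature name.
#' @param per_model list of `attribution_matrix` objects (one per member).
#' @param X matrix the attributions were computed on.
#' @return list with `data` (data frame of `molecule_id`, `feature_value`,
#'   `mean_phi`), `rho`, and `sign`.
#' @export
dependence_data <- function(feature, per_model, X) {
  X <- as.matrix(X)
  fn <- per_model[[1]]$feature_names
  if (!feature %in% fn)
    stop("unknown feature: ", feature, call. = FALSE)
  phi <- rowMeans(vapply(per_model, function(am) am$phi[, feature],
                         numeric(nrow(X))))
  fv <- X[, feature]
  rho <- if (sd(phi) == 0 || sd(fv) == 0) NA_real_ else
    suppressWarnings(cor(fv, phi, method = "spearman"))
  sign <- if (is.na(rho) || abs(rho) < 0.1) "indeterminate"
          else if (rho > 0) "positive" else "negative"
  list(data = data.frame(molecule_id = if (is.null(rownames(X)))
                           seq_len(nrow(X)) else rownames(X),
                         feature_value = fv, mean_phi = phi,
                         row.names = NULL),
       rho = rho, sign = sign)
}
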