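# Independent oracles used across tests. These never call the code paths
# they check: cover routing, conditional expectation and Shapley values are
# recomputed from first principles on the flat tree representation.

# number of background rows reaching each node (1-based)
oracle_route_covers <- function(tree, bg) {
  cov <- numeric(length(tree$left))
  for (i in seq_len(nrow(bg))) {
    node <- 1L
    cov[node] <- cov[node] + 1
    while (tree$feature[node] >= 0L) {
      node <- if (bg[i, tree$feature[node] + 1L] <= tree$threshold[node])
        tree$left[node] + 1L else tree$right[node] + 1L
      cov[node] <- cov[node] + 1
    }
  }
  cov
}

# cover-weighted conditional expectation of a tree given the features in S
# (1-based indices) fixed at x
oracle_cond_exp <- function(tree, covers, x, S, node = 1L) {
  f <- tree$feature[node] + 1L
  if (f == 0L) return(tree$value[node])
  l <- tree$left[node] + 1L
  r <- tree$right[node] + 1L
  if (f %in% S) {
    if (x[f] <= tree$threshold[node])
      oracle_cond_exp(tree, covers, x, S, l)
    else oracle_cond_exp(tree, covers, x, S, r)
  } else {
    # zero-cover branches have probability zero under the background
    el <- if (covers[l] > 0) covers[l] * oracle_cond_exp(tree, covers, x, S, l) else 0
    er <- if (covers[r] > 0) covers[r] * oracle_cond_exp(tree, covers, x, S, r) else 0
    (el + er) / covers[node]
  }
}

# exhaustive-subset Shapley values of one tree (exponential in p; tiny p only)
oracle_tree_shap <- function(tree, bg, x) {
  covers <- oracle_route_covers(tree, bg)
  p <- length(x)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (k in 0:length(others)) {
      combs <- if (k == 0) list(integer(0)) else asplit(combn(others, k), 2)
      for (S in combs) {
        S <- as.integer(S)
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        phi[i] <- phi[i] +
          w * (oracle_cond_exp(tree, covers, x, c(S, i)) -
                 oracle_cond_exp(tree, covers, x, S))
      }
    }
  }
  phi
}

# Mann-Whitney pair-count AUC oracle with ties counted 1/2
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# linearly separable descriptor table: label = 1 iff first column positive
make_separable <- function(n, p, seed) {
  tab <- generate_table(synthetic_spec(
    n_molecules = n, n_features = p, signal_features = 1L,
    flip_noise = 0, seed = seed, add_constant = FALSE, add_zero = FALSE))
  list(X = tab$X, y = tab$labels)
}
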