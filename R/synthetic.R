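#' Specification for a synthetic descriptor-table dataset
#'
#' Describes a dataset whose labels follow a known threshold rule on a
#' linear combination of designated signal features, with independent label
#' flips as noise. Such tables exercise the modeling, evaluation and
#' attribution stages without any chemistry engine, and their known
#' generating rule serves as the accuracy/importance oracle in recovery
#' tests.
#'
#' @param n_molecules number of rows.
#' @param n_features number of informative-or-noise feature columns (all
#'   i.i.d. standard normal).
#' @param signal_features indices of the features entering the label rule.
#' @param coefficients linear coefficients of the signal features.
#' @param threshold rule threshold: label 1 when the combination exceeds it.
#' @param flip_noise probability in `[0, 0.5)` of flipping each label.
#' @param seed integer seed; the whole table is reproducible from it.
#' @param add_constant,add_zero append a constant-one and an all-zero column
#'   (degenerate columns that [filter_descriptors()] must remove).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 1000, n_features = 50,
                           signal_features = 1L,
                           coefficients = rep(1, length(signal_features)),
                           threshold = 0, flip_noise = 0.1, seed = 1,
                           add_constant = TRUE, add_zero = TRUE) {
  stopifnot(n_molecules >= 1, n_features >= 1,
            length(signal_features) >= 1,
            all(signal_features %in% seq_len(n_features)),
            length(coefficients) == length(signal_features))
  if (flip_noise < 0 || flip_noise >= 0.5)
    stop("flip_noise must lie in [0, 0.5) so the label signal is preserved",
         call. = FALSE)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_features = as.integer(n_features),
                 signal_features = as.integer(signal_features),
                 coefficients = as.numeric(coefficients),
                 threshold = threshold, flip_noise = flip_noise,
                 seed = as.integer(seed),
                 add_constant = add_constant, add_zero = add_zero),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor table with known label rule
#'
#' @param spec a [synthetic_spec()].
#' @return list with `X` (a `descriptor_matrix`, including the degenerate
#'   columns when requested), `labels` (integer 0/1 after noise),
#'   `oracle_rule` (function mapping a compatible matrix to noise-free
#'   labels), and `spec`.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_molecules; p <- spec$n_features
  feat_names <- sprintf("d%03d", seq_len(p))
  signal_names <- feat_names[spec$signal_features]
  res <- with_seed(spec$seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("m%05d", seq_len(n)), feat_names))
    score <- X[, spec$signal_features, drop = FALSE] %*% spec$coefficients
    y0 <- as.integer(score > spec$threshold)
    flip <- runif(n) < spec$flip_noise
    list(X = X, y = ifelse(flip, 1L - y0, y0))
  })
  X <- res$X
  if (spec$add_constant) X <- cbind(X, const_one = 1)
  if (spec$add_zero) X <- cbind(X, all_zero = 0)
  coefs <- spec$coefficients
  thr <- spec$threshold
  oracle_rule <- function(M)
    as.integer(as.matrix(M)[, signal_names, drop = FALSE] %*% coefs > thr)
  list(X = new_descriptor_matrix(X, provenance = "synthetic-threshold-rule"),
       labels = res$y, oracle_rule = oracle_rule, spec = spec)
}

#' Fixed SMILES fixture set
#'
#' A stable, hand-curated set of 20 simple drug-like molecules with
#' fabricated %F values chosen to span both conventional cutoffs (20% and
#' 50%), including a point value exactly at 20 and two interval
#' measurements. The %F values are synthetic test data, not literature
#' measurements; the set exists so the chemistry-facing code paths can be
#' exercised deterministically offline.
#'
#' @return a [molecule_records()] data frame of 20 molecules.
#' @export
fixture_smiles <- function() {
  tbl <- list(
    list("ethanol",      "CCO",                                   95, 95),
    list("benzene",      "c1ccccc1",                              80, 80),
    list("aspirin",      "CC(=O)Oc1ccccc1C(=O)O",                 68, 68),
    list("caffeine",     "Cn1cnc2c1c(=O)n(C)c(=O)n2C",            99, 99),
    list("paracetamol",  "CC(=O)Nc1ccc(O)cc1",                    88, 88),
    list("ibuprofen",    "CC(C)Cc1ccc(C(C)C(=O)O)cc1",            92, 92),
    list("naproxen",     "COc1ccc2cc(C(C)C(=O)O)ccc2c1",          95, 95),
    list("atenolol",     "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",        50, 50),
    list("propranolol",  "CC(C)NCC(O)COc1cccc2ccccc12",           26, 26),
    list("diazepam",     "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21",   98, 98),
    list("metformin",    "CN(C)C(=N)NC(=N)N",                     55, 55),
    list("glucose",      "OCC1OC(O)C(O)C(O)C1O",                   2,  2),
    list("acyclovir",    "Nc1nc2c(ncn2COCCO)c(=O)[nH]1",          20, 20),
    list("toluene",      "Cc1ccccc1",                             15, 15),
    list("phenol",       "Oc1ccccc1",                             10, 10),
    list("acetic_acid",  "CC(=O)O",                               45, 45),
    list("urea",         "NC(N)=O",                              100, 100),
    list("nicotine",     "CN1CCCC1c1cccnc1",                      30, 30),
    list("salbutamol",   "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",         10, 30),
    list("levodopa",     "NC(Cc1ccc(O)c(O)c1)C(=O)O",             30, 50)
  )
  molecule_records(id = vapply(tbl, `[[`, character(1), 1),
                   smiles = vapply(tbl, `[[`, character(1), 2),
                   f_lo = vapply(tbl, function(x) as.numeric(x[[3]]), numeric(1)),
                   f_hi = vapply(tbl, function(x) as.numeric(x[[4]]), numeric(1)),
                   validate = FALSE)
}
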