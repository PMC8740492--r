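#' Default 2D descriptor provider (OpenBabel property set)
#'
#' Computes a small set of interpretable 2D descriptors for one molecule:
#' molecular weight (`MW`), octanol/water partition estimate (`logP`),
#' topological polar surface area (`TPSA`), molar refractivity (`MR`),
#' hydrogen-bond acceptor counts (`HBA1`, `HBA2`), donor count (`HBD`),
#' fluorine count (`nF`), and heavy-atom/bond counts (`n_atoms`, `n_bonds`).
#' Any function mapping one SMILES string to a named numeric vector can be
#' used in its place, so a larger descriptor engine can be injected without
#' changing the pipeline.
#'
#' @param smiles a single SMILES string.
#' @return named numeric vector of descriptor values.
#' @export
ob_descriptor_provider <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))
  pr <- ChemmineR::propOB(sdf)
  num <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
  vals <- vapply(num, function(nm) as.numeric(pr[[nm]][1]), numeric(1))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  c(vals, n_atoms = nrow(ab), n_bonds = nrow(bb))
}

#' Compute a molecules-by-descriptors matrix
#'
#' Applies a descriptor provider to every record. Molecules the provider
#' fails on yield an all-`NA` row (reported with a warning) so the failure is
#' visible to [filter_descriptors()] rather than silently dropped; the
#' computation only aborts if the provider fails on every molecule.
#'
#' @param records a [molecule_records()] data frame.
#' @param provider function taking one SMILES string and returning a named
#'   numeric vector; defaults to [ob_descriptor_provider()].
#' @param provenance descriptor-set name stored with the matrix.
#' @return numeric matrix (class `descriptor_matrix`) with molecule ids as
#'   row names and a `"provenance"` attribute.
#' @export
compute_descriptors <- function(records, provider = ob_descriptor_provider,
                                provenance = "openbabel-properties") {
  n <- nrow(records)
  vals <- vector("list", n)
  for (i in seq_len(n))
    vals[[i]] <- tryCatch(provider(records$smiles[i]), error = function(e) NULL)
  if (n > 0 && all(vapply(vals, is.null, logical(1))))
    stop("descriptor provider failed on every molecule", call. = FALSE)
  schema <- character(0)
  for (v in vals) if (!is.null(v)) schema <- union(schema, names(v))
  if (n == 0 || length(schema) == 0) {
    m <- matrix(numeric(0), nrow = n, ncol = length(schema),
                dimnames = list(records$id, schema))
    return(new_descriptor_matrix(m, provenance))
  }
  m <- matrix(NA_real_, n, length(schema),
              dimnames = list(records$id, schema))
  n_failed <- 0L
  for (i in seq_len(n)) {
    if (is.null(vals[[i]])) { n_failed <- n_failed + 1L; next }
    m[i, names(vals[[i]])] <- as.numeric(vals[[i]])
  }
  if (n_failed > 0)
    warning(n_failed, " molecule(s) failed descriptor computation; ",
            "their rows are non-finite")
  new_descriptor_matrix(m, provenance)
}

new_descriptor_matrix <- function(m, provenance = "unspecified") {
  if (anyDuplicated(colnames(m)))
    stop("duplicated descriptor names", call. = FALSE)
  attr(m, "provenance") <- provenance
  class(m) <- c("descriptor_matrix", class(m))
  m
}

#' Remove degenerate descriptor columns
#'
#' Drops columns that are zero for all molecules, constant across molecules
#' (zero variance), or non-finite for any molecule, and reports each removal
#' with its reason. Filtering is idempotent: the surviving columns all have
#' at least two distinct finite values, so a second pass removes nothing.
#'
#' @param m a `descriptor_matrix` (any numeric matrix with column names
#'   works).
#' @return list with `matrix` (filtered) and `report` (a `filter_report`
#'   with a `removed` data frame of `name`/`reason` and `kept_count`).
#' @export
filter_descriptors <- function(m) {
  if (is.null(dim(m)) || ncol(m) == 0) stop("empty descriptor matrix", call. = FALSE)
  reasons <- rep(NA_character_, ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(!is.finite(col))) reasons[j] <- "non_finite"
    else if (all(col == 0)) reasons[j] <- "all_zero"
    else if (length(unique(col)) < 2) reasons[j] <- "zero_variance"
  }
  keep <- is.na(reasons)
  if (!any(keep)) stop("no usable features after filtering", call. = FALSE)
  removed <- data.frame(name = colnames(m)[!keep], reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  kept <- m[, keep, drop = FALSE]
  kept <- new_descriptor_matrix(unclass_matrix(kept),
                                provenance = attr(m, "provenance"))
  report <- structure(list(removed = removed, kept_count = ncol(kept),
                           original_count = ncol(m)),
                      class = "filter_report")
  list(matrix = kept, report = report)
}

unclass_matrix <- function(m) {
  attr(m, "provenance") <- NULL
  class(m) <- NULL
  m
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Descriptor filter:", x$original_count, "->", x$kept_count,
      "columns kept\n")
  if (nrow(x$removed))
    print(table(x$removed$reason))
  invisible(x)
}

#' Topological path fingerprints
#'
#' Hashed linear-path (topological) fingerprints of each molecule, as used
#' for Tanimoto similarity audits and fingerprint-stage deduplication. The
#' backend's path fingerprint is 1024 bits. Identical molecules always give
#' identical bit vectors.
#'
#' @param records a [molecule_records()] data frame.
#' @return 0/1 integer matrix (class `fingerprint_set`), one row per
#'   molecule, with attributes `kind = "topological_path"` and `nbits`.
#' @export
compute_fingerprints <- function(records) {
  if (nrow(records) == 0) {
    m <- matrix(integer(0), 0, 0)
  } else {
    sdf <- smiles_to_sdf(records$smiles, records$id)
    fp <- ChemmineR::fingerprintOB(sdf, "FP2")
    m <- fp@fpma
    storage.mode(m) <- "integer"
    rownames(m) <- records$id
  }
  structure(m, kind = "topological_path", nbits = ncol(m),
            class = c("fingerprint_set", class(m)))
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a & b| / |a | b|` over the set bits. When both fingerprints are empty
#' (all zero) the similarity is defined as 1, which keeps deduplication
#' conservative; a message notes when this convention fires.
#'
#' @param a,b fingerprint bit vectors of equal length (0/1 or logical).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint lengths differ", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) {
    message("both fingerprints empty; Tanimoto defined as 1")
    return(1)
  }
  sum(a & b) / u
}

#' Maximum Tanimoto similarity of each query molecule to a reference set
#'
#' For each query fingerprint, the maximum Tanimoto similarity over all
#' reference fingerprints, plus the arithmetic mean of those maxima - the
#' standard audit of how close a test set sits to the training chemistry.
#'
#' @param query,reference `fingerprint_set` matrices (or any 0/1 matrices
#'   with equal column counts).
#' @return list with `max_sim` (per-query maxima) and `mean_max_sim`.
#' @export
max_similarity_to_reference <- function(query, reference) {
  query <- unclass(query); reference <- unclass(reference)
  if (is.null(dim(reference)) || nrow(reference) == 0)
    stop("reference fingerprint set is empty", call. = FALSE)
  if (ncol(query) != ncol(reference))
    stop("fingerprint lengths differ", call. = FALSE)
  q <- matrix(as.numeric(query > 0), nrow(query), ncol(query))
  r <- matrix(as.numeric(reference > 0), nrow(reference), ncol(reference))
  inter <- tcrossprod(q, r)
  un <- outer(rowSums(q), rowSums(r), "+") - inter
  sims <- ifelse(un == 0, 1, inter / un)
  mx <- apply(sims, 1, max)
  names(mx) <- rownames(query)
  list(max_sim = mx, mean_max_sim = mean(mx))
}
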