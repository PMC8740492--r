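#' Construct a set of molecule records
#'
#' A molecule record holds an identifier, a SMILES string, and a measured
#' human oral bioavailability (%F) value. Imprecise measurements are stored
#' as intervals `[f_lo, f_hi]`; a point value has `f_lo == f_hi`. Records
#' whose SMILES the chemistry backend cannot parse, or whose %F values fall
#' outside `[0, 100]` or have `f_lo > f_hi`, are rejected.
#'
#' @param id character identifiers.
#' @param smiles SMILES strings.
#' @param f_lo,f_hi lower/upper %F in `[0, 100]`; `f_hi` defaults to `f_lo`.
#' @param validate check SMILES parseability (set `FALSE` only for inputs
#'   already validated).
#' @return a `molecule_records` data frame with columns `id`, `smiles`,
#'   `f_lo`, `f_hi`.
#' @export
molecule_records <- function(id, smiles, f_lo, f_hi = f_lo, validate = TRUE) {
  df <- data.frame(id = as.character(id), smiles = as.character(smiles),
                   f_lo = as.numeric(f_lo), f_hi = as.numeric(f_hi),
                   stringsAsFactors = FALSE)
  bad_f <- is.na(df$f_lo) | is.na(df$f_hi) | df$f_lo > df$f_hi |
    df$f_lo < 0 | df$f_hi > 100
  if (any(bad_f))
    stop("invalid %F value(s) for record(s): ",
         paste(df$id[bad_f], collapse = ", "), call. = FALSE)
  if (validate) {
    ok <- is_valid_smiles(df$smiles)
    if (any(!ok))
      stop("unparseable SMILES for record(s): ",
           paste(df$id[!ok], collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("molecule_records", "data.frame"))
}

# Parse a %F cell: a plain number or an interval "lo-hi" (separator
# configurable, en dash accepted by default). An optional "%F =" prefix is
# tolerated. Returns a two-column data frame; NA rows mark unparseable cells.
parse_f_values <- function(x, interval_sep = "[-–]") {
  x <- trimws(as.character(x))
  x <- sub("^%?\\s*F\\s*=\\s*", "", x, ignore.case = TRUE)
  num <- "([0-9]+\\.?[0-9]*)"
  point_re <- paste0("^", num, "$")
  int_re <- paste0("^", num, "\\s*", interval_sep, "\\s*", num, "$")
  lo <- hi <- rep(NA_real_, length(x))
  is_pt <- grepl(point_re, x)
  lo[is_pt] <- hi[is_pt] <- as.numeric(x[is_pt])
  is_int <- !is_pt & grepl(int_re, x)
  lo[is_int] <- as.numeric(sub(int_re, "\\1", x[is_int]))
  hi[is_int] <- as.numeric(sub(int_re, "\\2", x[is_int]))
  data.frame(f_lo = lo, f_hi = hi)
}

#' Read a molecule dataset from CSV or SDF
#'
#' CSV files need a header with identifier, SMILES and %F columns (names
#' configurable). %F cells may be point values (`"85"`) or intervals
#' (`"10-30"`, separator configurable; an optional `"%F ="` prefix is
#' tolerated). SDF files (V2000/V3000) carry the %F value in a named data
#' field. Rows with unparseable SMILES or invalid %F are skipped with a
#' warning; the number of skipped rows is recorded in the `"n_skipped"`
#' attribute of the result.
#'
#' @param path file path.
#' @param format `"csv"` or `"sdf"`.
#' @param id_col,smiles_col,f_col CSV column names.
#' @param f_tag SDF data-field name holding %F.
#' @param interval_sep regular expression matching the interval separator.
#' @return a [molecule_records()] data frame; attribute `n_skipped` counts
#'   rejected rows.
#' @export
read_dataset <- function(path, format = c("csv", "sdf"),
                         id_col = "id", smiles_col = "smiles", f_col = "f",
                         f_tag = "F", interval_sep = "[-–]") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) == 0) {
      warning("empty dataset: ", path)
      out <- molecule_records(character(0), character(0), numeric(0))
      attr(out, "n_skipped") <- 0L
      return(out)
    }
    missing_cols <- setdiff(c(id_col, smiles_col, f_col), names(df))
    if (length(missing_cols))
      stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
           " (configure id_col/smiles_col/f_col)", call. = FALSE)
    id <- as.character(df[[id_col]])
    smiles <- as.character(df[[smiles_col]])
    fv <- parse_f_values(df[[f_col]], interval_sep)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    id <- ChemmineR::sdfid(sdf)
    blocks <- ChemmineR::datablock(sdf)
    fraw <- vapply(blocks, function(b) {
      v <- b[f_tag]
      if (is.na(v)) NA_character_ else as.character(v)
    }, character(1))
    smiles <- unlist(ChemmineR::sdf2smiles(sdf)@smilist, use.names = FALSE)
    fv <- parse_f_values(fraw, interval_sep)
  }
  ok_f <- !is.na(fv$f_lo) & !is.na(fv$f_hi) & fv$f_lo <= fv$f_hi &
    fv$f_lo >= 0 & fv$f_hi <= 100
  ok_s <- is_valid_smiles(smiles)
  keep <- ok_f & ok_s
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    warning(n_skipped, " row(s) skipped (unparseable SMILES or invalid %F)")
  out <- molecule_records(id[keep], smiles[keep], fv$f_lo[keep], fv$f_hi[keep],
                          validate = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Label molecules as positive/negative at a %F cutoff
#'
#' A molecule is positive when its whole measured %F interval lies at or
#' above the cutoff (`f_lo >= cutoff`), negative when it lies strictly below
#' (`f_hi < cutoff`), and discarded when the interval straddles the cutoff so
#' the class cannot be determined. A point value equal to the cutoff is
#' positive. Discarded molecules are flagged, never dropped, so dataset
#' accounting stays reproducible.
#'
#' @param records a [molecule_records()] data frame (a previously labeled
#'   dataset is accepted; relabeling at the same cutoff is a no-op).
#' @param cutoff %F cutoff in (0, 100); 20 and 50 are the conventional values.
#' @return a `labeled_dataset`: the records plus a `label` factor
#'   (`positive`/`negative`/`discarded`) and a `"cutoff"` attribute.
#' @export
assign_labels <- function(records, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1)
  if (cutoff <= 0 || cutoff >= 100)
    stop("cutoff must lie strictly between 0 and 100", call. = FALSE)
  label <- ifelse(records$f_lo >= cutoff, "positive",
                  ifelse(records$f_hi < cutoff, "negative", "discarded"))
  out <- records
  out$label <- factor(label, levels = c("positive", "negative", "discarded"))
  attr(out, "cutoff") <- cutoff
  class(out) <- unique(c("labeled_dataset", class(records)))
  out
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cnt <- label_counts(x)
  cat("Labeled dataset:", nrow(x), "molecules at %F cutoff",
      attr(x, "cutoff"), "\n")
  cat("  positive:", cnt["positive"], " negative:", cnt["negative"],
      " discarded:", cnt["discarded"], "\n")
  invisible(x)
}

#' Per-class counts of a labeled dataset
#'
#' @param labeled a labeled dataset from [assign_labels()].
#' @return named integer vector (`positive`, `negative`, `discarded`).
#' @export
label_counts <- function(labeled) {
  stopifnot(!is.null(labeled$label))
  table(labeled$label)[c("positive", "negative", "discarded")]
}

#' Binary training labels from a labeled dataset
#'
#' Drops discarded molecules and encodes positive as 1, negative as 0.
#'
#' @param labeled a labeled dataset from [assign_labels()].
#' @return list with `y` (integer 0/1), `id`, and `index` (row positions of
#'   the retained molecules in `labeled`).
#' @export
binary_labels <- function(labeled) {
  keep <- which(labeled$label != "discarded")
  list(y = as.integer(labeled$label[keep] == "positive"),
       id = labeled$id[keep], index = keep)
}

#' Remove query molecules already present in a reference set
#'
#' Two-stage deduplication: (1) canonical 2D structure equality (canonical
#' SMILES of the largest fragment, salts stripped); (2) topological path
#' fingerprint identity (Tanimoto similarity exactly 1 against any reference
#' molecule). Stage 2 also removes distinct structures whose hashed
#' fingerprints collide, which keeps the curation conservative.
#'
#' @param query,reference [molecule_records()] data frames.
#' @return list with `kept` and `removed` record subsets (both in query
#'   order); `removed` gains a `stage` column (`"structure"` or
#'   `"fingerprint"`).
#' @export
deduplicate_against <- function(query, reference) {
  if (nrow(reference) == 0) {
    removed <- query[integer(0), , drop = FALSE]
    removed$stage <- character(0)
    return(list(kept = query, removed = removed))
  }
  q_can <- canonical_smiles(query$smiles, strip_salts = TRUE)
  r_can <- canonical_smiles(reference$smiles, strip_salts = TRUE)
  stage <- rep(NA_character_, nrow(query))
  stage[q_can %in% r_can] <- "structure"

  open <- which(is.na(stage))
  if (length(open)) {
    q_fp <- compute_fingerprints(query[open, , drop = FALSE])
    r_fp <- compute_fingerprints(reference)
    sims <- max_similarity_to_reference(q_fp, r_fp)
    stage[open[sims$max_sim >= 1]] <- "fingerprint"
  }
  removed <- query[!is.na(stage), , drop = FALSE]
  removed$stage <- stage[!is.na(stage)]
  list(kept = query[is.na(stage), , drop = FALSE], removed = removed)
}

#' Write a labeled dataset to CSV
#'
#' Columns: `id`, `smiles`, `f_lo`, `f_hi`, `cutoff`, `label`.
#'
#' @param labeled a labeled dataset from [assign_labels()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labeled <- function(labeled, path) {
  df <- data.frame(id = labeled$id, smiles = labeled$smiles,
                   f_lo = labeled$f_lo, f_hi = labeled$f_hi,
                   cutoff = attr(labeled, "cutoff"),
                   label = as.character(labeled$label))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Read back a labeled CSV written by write_labeled().
read_labeled <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  rec <- molecule_records(df$id, df$smiles, df$f_lo, df$f_hi, validate = FALSE)
  assign_labels(rec, df$cutoff[1])
}
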