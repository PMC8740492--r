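#' Canonical SMILES via the OpenBabel backend
#'
#' Converts SMILES strings to canonical SMILES. With `strip_salts = TRUE`
#' only the largest contiguous fragment is kept (standard QSAR curation for
#' salts and mixtures), so e.g. an ethanol sodium salt and plain ethanol map
#' to the same canonical form. Strings the backend cannot parse return `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @param strip_salts keep only the largest fragment before canonicalization.
#' @return character vector of canonical SMILES, `NA` where unparseable.
#' @examples
#' \donttest{
#' canonical_smiles(c("CCO", "OCC"))  # both "CCO"
#' }
#' @export
canonical_smiles <- function(smiles, strip_salts = TRUE) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  todo <- which(!is.na(smiles) & nzchar(smiles))
  if (!length(todo)) return(out)
  # batch conversion with index titles so unparseable lines can be matched back
  src <- paste0(smiles[todo], " x", seq_along(todo), collapse = "\n")
  opts <- if (strip_salts) data.frame(names = "r", args = "") else
    data.frame(names = character(0), args = character(0))
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = src, options = opts),
    error = function(e) ""
  )
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[\t ]+")[[1]]
    if (length(parts) < 2) next
    idx <- suppressWarnings(as.integer(sub("^x", "", parts[length(parts)])))
    if (!is.na(idx) && idx >= 1 && idx <= length(todo))
      out[todo[idx]] <- parts[1]
  }
  out
}

# SMILES that survive a plain (no salt stripping) canonicalization round trip.
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles, strip_salts = FALSE))
}

# One SDFset for a vector of valid SMILES; errors name the offending id.
smiles_to_sdf <- function(smiles, ids) {
  ok <- is_valid_smiles(smiles)
  if (any(!ok))
    stop("unparseable SMILES for record(s): ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  ChemmineR::smiles2sdf(stats::setNames(smiles, ids))
}
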