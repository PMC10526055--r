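#' Build molecule records from SMILES strings
#'
#' Parses and canonicalizes a character vector of SMILES. Invalid entries are
#' retained with `is_valid = FALSE` and an empty canonical form, so that
#' uniqueness/quality denominators over generated sets remain computable.
#'
#' @param smiles character vector, one SMILES per element. An optional
#'   tab-separated name column is ignored.
#' @param source_line integer vector of originating line numbers (1-based).
#' @return A `data.frame` with columns `raw_smiles`, `canonical_smiles`,
#'   `is_valid` and `source_line`.
#' @export
molecule_records <- function(smiles, source_line = seq_along(smiles)) {
  stopifnot(is.character(smiles), length(source_line) == length(smiles))
  canon <- vapply(smiles, chem_canonical, character(1), USE.NAMES = FALSE)
  data.frame(
    raw_smiles = smiles,
    canonical_smiles = canon,
    is_valid = nzchar(canon),
    source_line = as.integer(source_line),
    stringsAsFactors = FALSE
  )
}

#' Read a SMILES file into molecule records
#'
#' One molecule per line; blank lines are skipped. Invalid SMILES are flagged,
#' not dropped, and their count is reported via [message()].
#'
#' @param path path to a plain-text SMILES file.
#' @return A molecule record `data.frame` (see [molecule_records()]).
#' @export
parse_smiles_file <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("zero valid molecules in file: ", path)
  recs <- molecule_records(lines[keep], source_line = which(keep))
  n_bad <- sum(!recs$is_valid)
  if (n_bad > 0) message(n_bad, " invalid SMILES line(s) in ", path)
  if (!any(recs$is_valid)) stop("zero valid molecules in file: ", path)
  recs
}

#' Write canonical SMILES, one per line
#'
#' @param records molecule record data.frame.
#' @param path output file path.
#' @param valid_only drop invalid records before writing (default `TRUE`).
#' @export
write_smiles_file <- function(records, path, valid_only = TRUE) {
  recs <- if (valid_only) records[records$is_valid, , drop = FALSE] else records
  writeLines(recs$canonical_smiles, path)
  invisible(path)
}

#' Canonicalize a single SMILES string
#'
#' Idempotent: canonicalizing a canonical SMILES returns it unchanged.
#'
#' @param smiles a single SMILES string.
#' @return The canonical SMILES.
#' @export
canonicalize <- function(smiles) {
  out <- chem_canonical(smiles)
  if (!nzchar(out)) stop("unparsable SMILES: ", smiles)
  out
}

.assert_valid <- function(records) {
  stopifnot(is.data.frame(records), "canonical_smiles" %in% names(records))
  if (!all(records$is_valid)) {
    stop("operation requires valid molecules; invalid records at source line(s): ",
         paste(records$source_line[!records$is_valid], collapse = ", "))
  }
  invisible(records)
}

#' Count aromatic (or total) rings per molecule
#'
#' Ring perception is smallest-set-of-smallest-rings style: a minimal cycle
#' basis chosen smallest-first from the exhaustive ring enumeration.
#'
#' @param records molecule record data.frame; all records must be valid.
#' @param mode `"aromatic"` (default) counts aromatic basis rings only;
#'   `"total"` counts all basis rings.
#' @return integer vector of ring counts.
#' @export
count_aromatic_rings <- function(records, mode = c("aromatic", "total")) {
  mode <- match.arg(mode)
  .assert_valid(records)
  chem_warm(records$canonical_smiles)
  f <- if (mode == "aromatic") chem_aromatic_rings else chem_total_rings
  vapply(records$canonical_smiles, f, numeric(1), USE.NAMES = FALSE) |>
    as.integer()
}

#' Test for halogen atoms (F, Cl, Br, I)
#'
#' @param records molecule record data.frame; all records must be valid.
#' @return logical vector.
#' @export
has_halogen <- function(records) {
  .assert_valid(records)
  chem_warm(records$canonical_smiles)
  vapply(records$canonical_smiles,
         function(s) chem_halogen_count(s) > 0, logical(1), USE.NAMES = FALSE)
}

#' Extended-connectivity fingerprint
#'
#' Circular (ECFP) bit vector of a valid molecule, folded to `n_bits`.
#' Deterministic and a function of the canonical structure only.
#'
#' @param record a single-row molecule record data.frame (or a record set of
#'   one molecule).
#' @param radius circular neighbourhood radius (1, 2 or 3; default 2,
#'   i.e. ECFP4).
#' @param n_bits fingerprint length, a power of two between 64 and 4096.
#' @return An object of class `"fingerprint"`: logical bit vector with
#'   `radius`/`n_bits` attributes.
#' @export
fingerprint <- function(record, radius = 2L, n_bits = 2048L) {
  stopifnot(nrow(record) == 1L)
  .assert_valid(record)
  if (n_bits < 64 || n_bits > 4096 || bitwAnd(n_bits, n_bits - 1L) != 0)
    stop("n_bits must be a power of two in [64, 4096]")
  bits <- chem_ecfp(record$canonical_smiles, radius = as.integer(radius),
                    n_bits = as.integer(n_bits))
  structure(bits, radius = as.integer(radius), n_bits = as.integer(n_bits),
            class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both vectors are all-zero.
#'
#' @param a,b `"fingerprint"` objects (or logical vectors) of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Fingerprint bit matrix (rows = molecules) for a set of canonical SMILES.
fingerprint_matrix <- function(canons, radius = 2L, n_bits = 2048L) {
  chem_warm(canons)
  t(vapply(canons, chem_ecfp, logical(n_bits),
           radius = radius, n_bits = n_bits))
}
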