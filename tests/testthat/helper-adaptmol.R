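# Shared fixtures, built once per test run (chemistry results are memoised
# inside the package, so repeated metric calls are cheap).

.fixture_env <- new.env()

test_library <- function(n = 48L) {
  key <- paste0("lib", n)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- toy_molecule_library(n)
  .fixture_env[[key]]
}

test_sa_model <- function() {
  if (is.null(.fixture_env$sa))
    .fixture_env$sa <- fit_sa_model(test_library(96))
  .fixture_env$sa
}

recs <- function(...) molecule_records(c(...))

# Independent brute-force diversity oracle: double loop over all unordered
# pairs, one fingerprint per molecule.
oracle_diversity <- function(records, radius = 2L, n_bits = 2048L) {
  valid <- records[records$is_valid, , drop = FALSE]
  fps <- lapply(seq_len(nrow(valid)), function(i)
    fingerprint(valid[i, , drop = FALSE], radius, n_bits))
  n <- length(fps)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + tanimoto(fps[[i]], fps[[j]])
  }
  1 - tot / (n * (n - 1) / 2)
}

oracle_uniqueness <- function(records) {
  v <- records$canonical_smiles[records$is_valid]
  length(unique(v)) / length(v)
}

oracle_quality <- function(records, pred) {
  v <- records[records$is_valid, , drop = FALSE]
  u <- v[!duplicated(v$canonical_smiles), , drop = FALSE]
  sum(pred(u)) / nrow(records)
}

# Deterministic hash of network parameters, for freeze-contract checks.
param_hash <- function(net, layers = seq_along(net$W)) {
  digestible <- lapply(layers, function(i) list(net$W[[i]], net$b[[i]]))
  paste(vapply(digestible, function(x)
    paste(format(unlist(x), digits = 17), collapse = ","), character(1)),
    collapse = ";")
}
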