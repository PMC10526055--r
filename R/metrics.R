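# Evaluation metrics for generated molecule sets: diversity (one minus mean
# pairwise Tanimoto similarity of extended-connectivity fingerprints),
# uniqueness (distinct / valid after canonicalization), and quality
# (deduplicated molecules satisfying a structural predicate over the full
# generated count).

# Tanimoto similarity matrix between two sets of fingerprint rows.
tanimoto_matrix <- function(Fa, Fb) {
  inter <- (Fa * 1) %*% t(Fb * 1)
  pa <- rowSums(Fa)
  pb <- rowSums(Fb)
  un <- outer(pa, pb, "+") - inter
  s <- inter / un
  s[un == 0] <- 1          # both all-zero: degenerate, defined as 1
  s
}

#' Diversity of a molecule set
#'
#' `1 - mean pairwise Tanimoto similarity` over all pairs of distinct
#' elements of the generated multiset (duplicated structures contribute
#' similarity-1 pairs). Computed exactly via the multiset of distinct
#' structures and their multiplicities. Sets larger than `max_n` valid
#' molecules are reduced to a seeded random subsample, recorded in the
#' `"subsampled_to"` attribute.
#'
#' @param records molecule record data.frame (>= 2 valid molecules).
#' @param radius,n_bits fingerprint parameters.
#' @param max_n pairwise computation cap (default 5000).
#' @param seed seed for the subsample, used only above `max_n`.
#' @return diversity in `[0, 1]`.
#' @export
diversity <- function(records, radius = 2L, n_bits = 2048L,
                      max_n = 5000L, seed = 1L) {
  valid <- records[records$is_valid, , drop = FALSE]
  if (nrow(valid) < 2) stop("diversity undefined for fewer than 2 molecules")
  sub <- NULL
  if (nrow(valid) > max_n) {
    valid <- with_seed(seed, valid[sample.int(nrow(valid), max_n), ,
                                   drop = FALSE])
    sub <- max_n
  }
  tab <- table(valid$canonical_smiles)
  canons <- names(tab)
  counts <- as.numeric(tab)
  fpm <- fingerprint_matrix(canons, radius = radius, n_bits = n_bits)
  S <- tanimoto_matrix(fpm, fpm)
  Wt <- outer(counts, counts)
  diag(Wt) <- counts * (counts - 1)
  n <- sum(counts)
  d <- 1 - sum(S * Wt) / (n * (n - 1))
  if (!is.null(sub)) attr(d, "subsampled_to") <- sub
  d
}

#' Uniqueness of a molecule set
#'
#' Number of distinct canonical structures among valid molecules divided by
#' the number of valid molecules.
#'
#' @param records molecule record data.frame (>= 1 valid molecule).
#' @return uniqueness in `(0, 1]`.
#' @export
uniqueness <- function(records) {
  valid <- records[records$is_valid, , drop = FALSE]
  if (nrow(valid) == 0) stop("uniqueness undefined: zero valid molecules")
  length(unique(valid$canonical_smiles)) / nrow(valid)
}

#' Structural predicates for quality evaluation
#'
#' @param task one of `"ring_1"`, `"ring_2"`, `"ring_3"`, `"halogen"`, or
#'   `"ring_k"` with `k` supplied.
#' @param k exact aromatic-ring count for `"ring_k"`.
#' @param ring_mode passed to [count_aromatic_rings()].
#' @return predicate function: records -> logical vector.
#' @export
structure_predicate <- function(task = c("ring_1", "ring_2", "ring_3",
                                         "halogen", "ring_k"),
                                k = NULL,
                                ring_mode = c("aromatic", "total")) {
  task <- match.arg(task)
  ring_mode <- match.arg(ring_mode)
  if (task == "halogen") return(function(records) has_halogen(records))
  k <- if (task == "ring_k") as.integer(k) else
    as.integer(sub("ring_", "", task))
  if (is.na(k)) stop("ring_k predicate needs k")
  function(records) count_aromatic_rings(records, mode = ring_mode) == k
}

#' Quality of a generated molecule set
#'
#' Fraction of generated molecules with the desired structure. In the
#' defining ratio the numerator is the desired set *without duplicated
#' molecules* while the denominator is the full generated count (including
#' duplicates and invalid entries) — the literal reading, used by default.
#' With a small finite decoding library the deduplicated numerator
#' saturates at the library size; `dedup_numerator = FALSE` then gives the
#' informative per-sample reading (fraction of generated molecules
#' satisfying the predicate).
#'
#' @param records molecule record data.frame (nonempty).
#' @param predicate a predicate function (see [structure_predicate()]).
#' @param dedup_numerator deduplicate the numerator (default `TRUE`).
#' @return quality in `[0, 1]`.
#' @export
quality <- function(records, predicate, dedup_numerator = TRUE) {
  if (nrow(records) == 0) stop("quality undefined on an empty set")
  valid <- records[records$is_valid, , drop = FALSE]
  if (nrow(valid) == 0) return(0)
  num <- if (dedup_numerator)
    valid[!duplicated(valid$canonical_smiles), , drop = FALSE] else valid
  sum(predicate(num)) / nrow(records)
}

#' Evaluate a generated molecule set
#'
#' Aggregates diversity, uniqueness, optional predicate quality, and mean
#' property scores (computed over valid molecules only) into a metric report.
#'
#' @param records molecule record data.frame (nonempty).
#' @param predicate optional structural predicate for quality.
#' @param sa_model optional `"sa_model"` enabling penalized-logP scoring.
#' @param plogp_normalizer optional `"score_normalizer"` for normalized
#'   penalized logP.
#' @param with_qed include mean QED (default `TRUE`).
#' @param radius,n_bits fingerprint parameters for diversity.
#' @return An object of class `"metric_report"`.
#' @export
evaluate_molecules <- function(records, predicate = NULL, sa_model = NULL,
                               plogp_normalizer = NULL, with_qed = TRUE,
                               radius = 2L, n_bits = 2048L) {
  if (nrow(records) == 0) stop("cannot evaluate an empty generated set")
  valid <- records[records$is_valid, , drop = FALSE]
  mean_scores <- list()
  if (with_qed && nrow(valid) > 0)
    mean_scores$qed <- mean(qed(valid))
  if (!is.null(sa_model) && nrow(valid) > 0) {
    plogp <- penalized_logp_raw(valid, sa_model)
    mean_scores$plogp_raw <- mean(plogp)
    if (!is.null(plogp_normalizer))
      mean_scores$plogp_norm <- mean(normalize_score(plogp, plogp_normalizer))
    mean_scores$sa_norm <- mean(sa_normalized(valid, sa_model))
  }
  report <- list(
    n_generated = nrow(records),
    n_valid = nrow(valid),
    n_unique = length(unique(valid$canonical_smiles)),
    diversity = if (nrow(valid) >= 2)
      as.numeric(diversity(records, radius = radius, n_bits = n_bits))
      else NA_real_,
    uniqueness = if (nrow(valid) >= 1) uniqueness(records) else NA_real_,
    quality = if (!is.null(predicate)) quality(records, predicate)
      else NA_real_,
    mean_scores = mean_scores
  )
  structure(report, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Molecule set evaluation\n")
  cat(sprintf("  generated: %d   valid: %d   unique: %d\n",
              x$n_generated, x$n_valid, x$n_unique))
  cat(sprintf("  diversity:  %s\n", format(round(x$diversity, 4))))
  cat(sprintf("  uniqueness: %s\n", format(round(x$uniqueness, 4))))
  if (!is.na(x$quality))
    cat(sprintf("  quality:    %s\n", format(round(x$quality, 4))))
  for (nm in names(x$mean_scores))
    cat(sprintf("  mean %-10s %s\n", paste0(nm, ":"),
                format(round(x$mean_scores[[nm]], 4))))
  invisible(x)
}

#' Write a metric report as key-value text
#'
#' One `metric<TAB>value` pair per line, plus a human-readable header block.
#'
#' @param report a `"metric_report"`.
#' @param path output file.
#' @export
write_metric_report <- function(report, path) {
  kv <- c(n_generated = report$n_generated, n_valid = report$n_valid,
          n_unique = report$n_unique, diversity = report$diversity,
          uniqueness = report$uniqueness, quality = report$quality,
          unlist(report$mean_scores))
  kv <- kv[!is.na(kv)]
  writeLines(c(paste0("# ", utils::capture.output(print(report))),
               paste(names(kv), format(kv, digits = 10), sep = "\t")),
             path)
  invisible(path)
}
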