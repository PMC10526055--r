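# Few-shot reference dataset construction: structure-filtered subsets (exact
# aromatic-ring counts, halogenation), top-k property subsets (QED, penalized
# logP), nested 100/50/10/5 subsampling, and per-dataset statistics rows.

.structure_tasks <- c("ring_1", "ring_2", "ring_3", "halogen")
.property_tasks <- c("qed_top", "plogp_top")

#' Filter a molecule pool by structural task
#'
#' Ring tasks keep molecules with exactly 1, 2 or 3 aromatic rings (or total
#' rings with `ring_mode = "total"`); `"halogen"` keeps halogenated
#' molecules. Order is preserved.
#'
#' @param pool molecule record data.frame (valid molecules).
#' @param task one of `"ring_1"`, `"ring_2"`, `"ring_3"`, `"halogen"`.
#' @param ring_mode `"aromatic"` (default) or `"total"`.
#' @return filtered molecule record data.frame.
#' @export
filter_structure <- function(pool, task, ring_mode = c("aromatic", "total")) {
  task <- match.arg(task, .structure_tasks)
  ring_mode <- match.arg(ring_mode)
  pred <- structure_predicate(task, ring_mode = ring_mode)
  out <- pool[pred(pool), , drop = FALSE]
  if (nrow(out) == 0) stop("no molecules match task '", task, "'")
  rownames(out) <- NULL
  out
}

#' Select the top-k molecules by property score
#'
#' Scores are sorted descending; ties are broken by lexicographic canonical
#' SMILES so that top-5, top-10, ... are nested by construction.
#'
#' @param pool molecule record data.frame.
#' @param property `"qed"` or `"plogp"`.
#' @param k number of molecules (k <= pool size).
#' @param sa_model `"sa_model"`, required for `"plogp"`.
#' @return molecule record data.frame of the k top scorers, descending.
#' @export
top_k_by_property <- function(pool, property = c("qed", "plogp"), k,
                              sa_model = NULL) {
  property <- match.arg(property)
  if (k > nrow(pool)) stop("k (", k, ") exceeds pool size (", nrow(pool), ")")
  scores <- switch(property,
                   qed = qed(pool),
                   plogp = {
                     if (is.null(sa_model))
                       stop("penalized logP ranking needs an sa_model")
                     penalized_logp_raw(pool, sa_model)
                   })
  ord <- order(-scores, pool$canonical_smiles)
  out <- pool[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scores") <- scores[ord[seq_len(k)]]
  out
}

new_few_shot_dataset <- function(task, shots, records, seed,
                                 parent_shots = NA_integer_) {
  structure(list(task = task, shots = as.integer(shots), records = records,
                 seed = as.integer(seed),
                 parent_shots = as.integer(parent_shots)),
            class = "few_shot_dataset")
}

#' Nested few-shot subsampling
#'
#' Draws `sizes[1]` molecules without replacement from the (already filtered)
#' pool, then each subsequent size from the previous subset, so the k-shot
#' sets are nested: 5-shot is a subset of 10-shot is a subset of 50-shot is a
#' subset of 100-shot.
#'
#' @param filtered_pool molecule record data.frame (>= `max(sizes)` rows).
#' @param sizes decreasing subset sizes (default `c(100, 50, 10, 5)`).
#' @param seed RNG seed.
#' @param task task label stored with the datasets.
#' @return list of `"few_shot_dataset"` objects, largest first.
#' @export
nested_subsample <- function(filtered_pool, sizes = c(100L, 50L, 10L, 5L),
                             seed = 1L, task = "custom") {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) >= 0)) stop("sizes must be strictly decreasing")
  if (nrow(filtered_pool) < sizes[1])
    stop("pool of ", nrow(filtered_pool), " molecules cannot supply ",
         sizes[1], "; need at least ", sizes[1])
  out <- vector("list", length(sizes))
  with_seed(seed, {
    current <- filtered_pool[sample.int(nrow(filtered_pool), sizes[1]), ,
                             drop = FALSE]
    rownames(current) <- NULL
    out[[1]] <- new_few_shot_dataset(task, sizes[1], current, seed)
    for (i in seq_along(sizes)[-1]) {
      current <- current[sample.int(nrow(current), sizes[i]), , drop = FALSE]
      rownames(current) <- NULL
      out[[i]] <- new_few_shot_dataset(task, sizes[i], current, seed,
                                       parent_shots = sizes[i - 1])
    }
  })
  names(out) <- paste0(task, "_", sizes, "shot")
  out
}

#' Statistics row for a few-shot dataset
#'
#' Reports count, diversity, mean normalized penalized logP, mean QED, ring
#' membership counts (0, 1, 2, 3-or-more aromatic rings) and halogen count —
#' the usual dataset-summary column set. Diversity of a single-molecule
#' dataset is reported as `NA`.
#'
#' @param ds a `"few_shot_dataset"` (or plain molecule record data.frame).
#' @param sa_model optional `"sa_model"` for penalized logP.
#' @param plogp_normalizer optional `"score_normalizer"` fitted on the pool.
#' @return one-row `data.frame`.
#' @export
dataset_stats <- function(ds, sa_model = NULL, plogp_normalizer = NULL) {
  recs <- if (inherits(ds, "few_shot_dataset")) ds$records else ds
  if (nrow(recs) == 0) stop("empty dataset")
  rings <- count_aromatic_rings(recs)
  plogp <- if (!is.null(sa_model)) {
    raw <- penalized_logp_raw(recs, sa_model)
    if (!is.null(plogp_normalizer))
      mean(normalize_score(raw, plogp_normalizer)) else mean(raw)
  } else NA_real_
  data.frame(
    task = if (inherits(ds, "few_shot_dataset")) ds$task else NA_character_,
    shots = nrow(recs),
    diversity = if (nrow(recs) >= 2) as.numeric(diversity(recs)) else
      NA_real_,
    plogp = plogp,
    qed = mean(qed(recs)),
    ring0 = sum(rings == 0), ring1 = sum(rings == 1),
    ring2 = sum(rings == 2), ring3plus = sum(rings >= 3),
    halogen = sum(has_halogen(recs)),
    stringsAsFactors = FALSE)
}

#' Build every few-shot dataset family from a pool
#'
#' Structure tasks are filtered then nested-subsampled; property tasks take
#' the top-k scorers (nested by construction). A deposited reference file can
#' be passed through unchanged via [parse_smiles_file()] +
#' [nested_subsample()] when reproducing externally published subsets.
#'
#' @param pool molecule record data.frame.
#' @param sizes subset sizes (default `c(100, 50, 10, 5)`), truncated to what
#'   the filtered pools can supply.
#' @param seed RNG seed.
#' @param sa_model optional `"sa_model"` enabling the penalized-logP task.
#' @return named list of `"few_shot_dataset"` lists per task.
#' @export
build_few_shot_datasets <- function(pool, sizes = c(100L, 50L, 10L, 5L),
                                    seed = 1L, sa_model = NULL) {
  out <- list()
  for (task in .structure_tasks) {
    filtered <- tryCatch(filter_structure(pool, task),
                         error = function(e) NULL)
    if (is.null(filtered)) next
    sz <- sizes[sizes <= nrow(filtered)]
    if (length(sz) == 0) next
    out[[task]] <- nested_subsample(filtered, sz, seed = seed, task = task)
  }
  for (task in .property_tasks) {
    prop <- if (task == "qed_top") "qed" else "plogp"
    if (prop == "plogp" && is.null(sa_model)) next
    sz <- sizes[sizes <= nrow(pool)]
    out[[task]] <- lapply(sz, function(k) {
      new_few_shot_dataset(task, k,
                           top_k_by_property(pool, prop, k,
                                             sa_model = sa_model),
                           seed,
                           parent_shots = if (k == max(sz)) NA_integer_
                             else sz[match(k, sz) - 1L])
    })
    names(out[[task]]) <- paste0(task, "_", sz, "shot")
  }
  out
}

#' Write a few-shot dataset with its manifest
#'
#' Emits `<task>_<shots>shot.smi` plus a tab-delimited manifest row file
#' recording task, shots, seed, parent and the statistics columns.
#'
#' @param ds a `"few_shot_dataset"`.
#' @param dir output directory.
#' @param ... passed to [dataset_stats()].
#' @export
write_few_shot_dataset <- function(ds, dir, ...) {
  stopifnot(inherits(ds, "few_shot_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- paste0(ds$task, "_", ds$shots, "shot")
  write_smiles_file(ds$records, file.path(dir, paste0(stem, ".smi")))
  stats <- cbind(dataset_stats(ds, ...),
                 seed = ds$seed, parent_shots = ds$parent_shots)
  utils::write.table(stats, file.path(dir, paste0(stem, "_manifest.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, paste0(stem, ".smi")))
}
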