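test_that("structure filtering matches per-molecule perception", {
  lib <- test_library(48)
  for (task in c("ring_1", "ring_2", "ring_3", "halogen")) {
    sub <- filter_structure(lib, task)
    expect_gt(nrow(sub), 0)
    pred <- structure_predicate(task)
    expect_true(all(pred(sub)))
    # nothing satisfying the predicate was dropped
    expect_equal(nrow(sub), sum(pred(lib)))
  }
  benzene <- recs("c1ccccc1")
  expect_true(canonicalize("c1ccccc1") %in%
                filter_structure(lib, "ring_1")$canonical_smiles)
  expect_error(filter_structure(recs("CCO"), "halogen"), "no molecules")
})

test_that("top-k property selection matches a full-sort oracle and nests", {
  lib <- test_library(48)
  scores <- qed(lib)
  ord <- order(-scores, lib$canonical_smiles)
  for (k in c(1L, 5L, 10L, 48L)) {
    got <- top_k_by_property(lib, "qed", k)
    expect_identical(got$canonical_smiles, lib$canonical_smiles[ord[1:k]])
  }
  top5 <- top_k_by_property(lib, "qed", 5)$canonical_smiles
  top10 <- top_k_by_property(lib, "qed", 10)$canonical_smiles
  expect_true(all(top5 %in% top10))
  expect_error(top_k_by_property(lib, "qed", 100), "exceeds")
  # appending strictly-lower scorers never changes the top-k set
  low <- lib[order(scores)[1:5], , drop = FALSE]
  expect_identical(top_k_by_property(rbind(lib, low), "qed", 5)$canonical_smiles,
                   top5)
})

test_that("nested subsampling produces seeded nested chains", {
  lib <- test_library(96)
  halo <- filter_structure(lib, "halogen")
  sizes <- c(20L, 10L, 5L, 2L)
  ds <- nested_subsample(halo, sizes, seed = 42, task = "halogen")
  expect_length(ds, 4)
  for (i in seq_along(ds)) {
    expect_s3_class(ds[[i]], "few_shot_dataset")
    expect_equal(nrow(ds[[i]]$records), sizes[i])
    if (i > 1) {
      expect_true(all(ds[[i]]$records$canonical_smiles %in%
                        ds[[i - 1]]$records$canonical_smiles))
      expect_equal(ds[[i]]$parent_shots, sizes[i - 1])
    }
  }
  ds2 <- nested_subsample(halo, sizes, seed = 42, task = "halogen")
  expect_identical(lapply(ds, function(d) d$records$canonical_smiles),
                   lapply(ds2, function(d) d$records$canonical_smiles))
  # boundary: pool of exactly max(sizes)
  exact <- halo[seq_len(20), , drop = FALSE]
  ds3 <- nested_subsample(exact, sizes, seed = 1, task = "halogen")
  expect_setequal(ds3[[1]]$records$canonical_smiles, exact$canonical_smiles)
  expect_error(nested_subsample(halo[1:3, ], sizes), "at least")
})

test_that("structure datasets have quality 1 under their own predicate", {
  lib <- test_library(96)
  for (task in c("ring_1", "ring_2", "halogen")) {
    filtered <- filter_structure(lib, task)
    sizes <- c(min(10L, nrow(filtered)), 5L, 2L)
    sizes <- sizes[!duplicated(sizes) & sizes <= nrow(filtered)]
    ds <- nested_subsample(filtered, sizes, seed = 3, task = task)
    for (d in ds) {
      expect_equal(quality(d$records, structure_predicate(task)), 1)
    }
  }
})

test_that("dataset statistics rows equal standalone recomputation", {
  lib <- test_library(48)
  sa <- test_sa_model()
  nz <- fit_normalizer(penalized_logp_raw(lib, sa))
  ds <- nested_subsample(filter_structure(lib, "halogen"), c(6L, 3L),
                         seed = 2, task = "halogen")[[1]]
  row <- dataset_stats(ds, sa_model = sa, plogp_normalizer = nz)
  m <- ds$records
  expect_equal(row$shots, 6)
  expect_equal(row$diversity, as.numeric(diversity(m)))
  expect_equal(row$qed, mean(qed(m)))
  expect_equal(row$plogp, mean(normalize_score(penalized_logp_raw(m, sa), nz)))
  rings <- count_aromatic_rings(m)
  expect_equal(row$ring1, sum(rings == 1))
  expect_equal(row$halogen, 6)   # every member halogenated by construction
  # single-molecule dataset: diversity undefined
  one <- dataset_stats(m[1, , drop = FALSE])
  expect_true(is.na(one$diversity))
  ident <- dataset_stats(molecule_records(rep("CCCl", 5)))
  expect_equal(ident$diversity, 0)
  expect_equal(ident$shots, 5)
})

test_that("the full dataset family builds, writes, and reloads", {
  lib <- test_library(96)
  fam <- build_few_shot_datasets(lib, sizes = c(10L, 5L, 2L), seed = 7,
                                 sa_model = test_sa_model())
  expect_true(all(c("ring_1", "halogen", "qed_top", "plogp_top") %in%
                    names(fam)))
  d <- withr::local_tempdir()
  p <- write_few_shot_dataset(fam$halogen[[1]], d)
  back <- parse_smiles_file(p)
  expect_identical(back$canonical_smiles,
                   fam$halogen[[1]]$records$canonical_smiles)
  manifest <- file.path(d, "halogen_10shot_manifest.tsv")
  expect_true(file.exists(manifest))
})
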