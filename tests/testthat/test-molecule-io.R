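test_that("SMILES files parse with invalid lines flagged, not dropped", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "", "C(C", "c1ccccc1"), f)
  suppressMessages(out <- parse_smiles_file(f))
  expect_equal(nrow(out), 3)            # blank line skipped
  expect_equal(out$is_valid, c(TRUE, FALSE, TRUE))
  expect_equal(out$source_line, c(1L, 3L, 4L))
  expect_equal(out$canonical_smiles[2], "")

  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("", "  "), empty)
  expect_error(parse_smiles_file(empty), "zero valid molecules")
  expect_error(parse_smiles_file("no/such/file.smi"), "not found")
})

test_that("canonicalization merges equivalent writings and is idempotent", {
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  expect_identical(canonicalize("C1=CC=CC=C1"), canonicalize("c1ccccc1"))
  expect_error(canonicalize("C(C"), "unparsable")
  lib <- test_library()
  recanon <- vapply(lib$canonical_smiles, canonicalize, character(1),
                    USE.NAMES = FALSE)
  expect_identical(recanon, lib$canonical_smiles)
})

test_that("aromatic ring counts match known structures", {
  m <- recs("CCO", "c1ccccc1", "c1ccc2ccccc2c1",
            "c1ccc2cc3ccccc3cc2c1",            # anthracene
            "c1ccc(-c2ccccc2)cc1",             # biphenyl
            "c1ccc2ncccc2c1",                  # quinoline
            "C1CCCCC1")                        # cyclohexane
  expect_equal(count_aromatic_rings(m), c(0L, 1L, 2L, 3L, 2L, 2L, 0L))
  expect_equal(count_aromatic_rings(m, mode = "total"),
               c(0L, 1L, 2L, 3L, 2L, 2L, 1L))
  bad <- recs("C(C")
  expect_error(count_aromatic_rings(bad), "valid")
})

test_that("ring and halogen perception agree with an independent toolkit
           oracle on the full fixture library", {
  lib <- test_library(96)
  tmp_in <- withr::local_tempfile(fileext = ".smi")
  tmp_out <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lib$canonical_smiles, tmp_in)
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for line in open(sys.argv[1]):",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    ri = m.GetRingInfo()",
    "    ar = sum(1 for ring in ri.BondRings()",
    "             if all(m.GetBondWithIdx(b).GetIsAromatic() for b in ring))",
    "    hal = int(any(a.GetSymbol() in ('F','Cl','Br','I')",
    "              for a in m.GetAtoms()))",
    "    print(f'{ar}\\t{hal}')",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2("python", c(sf, tmp_in), stdout = tmp_out)
  expect_equal(res, 0L)
  oracle <- utils::read.table(tmp_out, sep = "\t")
  expect_equal(count_aromatic_rings(lib), oracle$V1)
  expect_equal(has_halogen(lib), oracle$V2 == 1)
})

test_that("halogen detection covers F, Cl, Br and I", {
  m <- recs("CCCl", "CCO", "FC(F)(F)c1ccccc1", "CCBr", "ICCC")
  expect_equal(has_halogen(m), c(TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("fingerprints are deterministic functions of structure", {
  a <- fingerprint(recs("OCC"))
  b <- fingerprint(recs("CCO"))
  expect_identical(c(unclass(a)), c(unclass(b)))
  expect_identical(c(unclass(a)), c(unclass(fingerprint(recs("OCC")))))
  expect_gt(sum(fingerprint(recs("c1ccccc1"))), 0)
  expect_equal(attr(a, "n_bits"), 2048L)
  expect_error(fingerprint(recs("CCO"), n_bits = 100), "power of two")
})

test_that("tanimoto similarity has the closed set-overlap form", {
  mk <- function(idx, n = 64) {
    v <- rep(FALSE, n); v[idx] <- TRUE
    structure(v, class = "fingerprint")
  }
  expect_equal(tanimoto(mk(1:3), mk(2:4)), 0.5)   # |∩|/|∪| = 2/4
  expect_equal(tanimoto(mk(1:5), mk(1:5)), 1)
  expect_equal(tanimoto(mk(1:3), mk(10:12)), 0)
  expect_equal(tanimoto(mk(integer(0)), mk(integer(0))), 1)  # degenerate
  expect_error(tanimoto(mk(1, 64), mk(1, 128)), "mismatch")
  # symmetry + range over fixture pairs
  lib <- test_library(24)
  fps <- lapply(seq_len(10), function(i)
    fingerprint(lib[i, , drop = FALSE]))
  for (i in 1:5) {
    for (j in 6:10) {
      t1 <- tanimoto(fps[[i]], fps[[j]])
      expect_identical(t1, tanimoto(fps[[j]], fps[[i]]))
      expect_true(t1 >= 0 && t1 <= 1)
    }
  }
})

test_that("round-trip SMILES writing preserves canonical forms", {
  lib <- test_library(24)
  f <- withr::local_tempfile(fileext = ".smi")
  write_smiles_file(lib, f)
  back <- parse_smiles_file(f)
  expect_identical(back$canonical_smiles, lib$canonical_smiles)
})
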