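# Synthetic test inputs: a deterministic toy molecule library covering every
# (aromatic-ring count 0-3) x (halogenated yes/no) cell, and Gaussian /
# affine-shifted latent distributions with known moments for recovery tests.

# Enumeration pools per (rings, halogen) cell. Small drug-like fragments:
# alkanes/alcohols/amines and their halides (0 rings), substituted benzenes
# (1), naphthalenes/biphenyls/quinolines (2), anthracene/phenanthrene/
# terphenyl scaffolds (3).
.library_cells <- list(
  r0_plain = c("CC", "CCC", "CCCC", "CCO", "CCCO", "CCN", "CCCN", "CC(C)C",
               "CCCCC", "CC(C)O", "CCOC", "CCCCCC"),
  r0_halo  = c("CCCl", "CCBr", "CCF", "CCCCl", "CCCBr", "CC(C)Cl", "CCCCF",
               "ClCCCl", "CCCCBr", "FCCF", "CC(C)Br", "CCCCCl"),
  r1_plain = c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
               "CCc1ccccc1", "COc1ccccc1", "Cc1ccccc1C", "c1ccncc1",
               "Cc1ccncc1", "CCCc1ccccc1", "Cc1cccc(C)c1", "OCc1ccccc1"),
  r1_halo  = c("Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1", "Cc1ccc(Cl)cc1",
               "Oc1ccc(Cl)cc1", "Fc1ccc(F)cc1", "Clc1ccccc1Cl",
               "Nc1ccc(Cl)cc1", "Cc1ccc(F)cc1", "Clc1cccnc1",
               "Brc1ccc(C)cc1", "COc1ccc(Cl)cc1"),
  r2_plain = c("c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1", "c1ccc(-c2ccccc2)cc1",
               "Oc1ccc2ccccc2c1", "c1ccc2ncccc2c1", "Cc1ccc(-c2ccccc2)cc1",
               "Nc1ccc2ccccc2c1", "CCc1ccc2ccccc2c1", "Oc1ccc(-c2ccccc2)cc1",
               "Cc1cccc2ccccc12", "COc1ccc2ccccc2c1", "Nc1ccc(-c2ccccc2)cc1"),
  r2_halo  = c("Clc1ccc2ccccc2c1", "Fc1ccc2ccccc2c1",
               "Clc1ccc(-c2ccccc2)cc1", "Brc1ccc2ccccc2c1",
               "Fc1ccc(-c2ccccc2)cc1", "Cc1ccc2cc(Cl)ccc2c1",
               "Brc1ccc(-c2ccccc2)cc1", "Clc1cccc2ccccc12",
               "Oc1ccc2cc(Cl)ccc2c1", "Fc1cccc2ccccc12",
               "Clc1ccc2cccnc2c1", "Cc1ccc(-c2ccc(F)cc2)cc1"),
  r3_plain = c("c1ccc2cc3ccccc3cc2c1", "c1ccc2c(c1)ccc1ccccc12",
               "c1ccc2nc3ccccc3cc2c1", "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1",
               "Cc1ccc2cc3ccccc3cc2c1", "Oc1ccc2cc3ccccc3cc2c1",
               "Cc1ccc(-c2ccc(-c3ccccc3)cc2)cc1", "Nc1ccc2cc3ccccc3cc2c1",
               "c1ccc(-c2ccc3ccccc3c2)cc1", "Cc1ccc2c(c1)ccc1ccccc12",
               "Oc1ccc(-c2ccc(-c3ccccc3)cc2)cc1", "CCc1ccc2cc3ccccc3cc2c1"),
  r3_halo  = c("Clc1ccc2cc3ccccc3cc2c1", "Fc1ccc2cc3ccccc3cc2c1",
               "Brc1ccc2cc3ccccc3cc2c1",
               "Clc1ccc(-c2ccc(-c3ccccc3)cc2)cc1",
               "Clc1ccc2c(c1)ccc1ccccc12", "Fc1ccc(-c2ccc(-c3ccccc3)cc2)cc1",
               "Clc1ccc(-c2ccc3ccccc3c2)cc1", "Fc1ccc2c(c1)ccc1ccccc12",
               "Brc1ccc(-c2ccc(-c3ccccc3)cc2)cc1", "Cc1ccc2cc3cc(Cl)ccc3cc2c1",
               "Clc1ccc2nc3ccccc3cc2c1", "Brc1ccc2c(c1)ccc1ccccc12")
)

#' Deterministic toy molecule library
#'
#' Enumerates small valid molecules round-robin over the eight
#' (aromatic-ring count 0-3) x (halogenated yes/no) cells, so that any
#' `n_molecules >= 8` covers every cell and `n_molecules >= 24` gives at
#' least three members per cell. The enumeration is audited at build time:
#' every member must be valid, structurally distinct, and classified into
#' its claimed cell by the package's own ring/halogen perception.
#'
#' @param n_molecules library size (8 to 96, default 48).
#' @return molecule record data.frame with `ring_cell` and `halogen_cell`
#'   columns recording the enumeration cell.
#' @export
toy_molecule_library <- function(n_molecules = 48L) {
  n_molecules <- as.integer(n_molecules)
  max_n <- sum(lengths(.library_cells))
  if (n_molecules < length(.library_cells))
    stop("library of ", n_molecules, " cannot cover all ",
         length(.library_cells), " (ring, halogen) cells")
  if (n_molecules > max_n)
    stop("enumeration holds at most ", max_n, " molecules")
  cells <- .library_cells
  order_idx <- integer(0)
  smiles <- character(0)
  ring <- integer(0)
  halo <- logical(0)
  for (round in seq_len(max(lengths(cells)))) {
    for (ci in seq_along(cells)) {
      if (round <= length(cells[[ci]])) {
        smiles <- c(smiles, cells[[ci]][round])
        ring <- c(ring, (ci - 1L) %/% 2L)
        halo <- c(halo, ci %% 2L == 0L)
      }
    }
  }
  smiles <- smiles[seq_len(n_molecules)]
  ring <- ring[seq_len(n_molecules)]
  halo <- halo[seq_len(n_molecules)]
  recs <- molecule_records(smiles)
  if (!all(recs$is_valid))
    stop("internal: invalid library SMILES ",
         paste(smiles[!recs$is_valid], collapse = ", "))
  if (anyDuplicated(recs$canonical_smiles))
    stop("internal: duplicate library structures")
  got_ring <- count_aromatic_rings(recs)
  got_halo <- has_halogen(recs)
  if (!all(got_ring == ring) || !all(got_halo == halo))
    stop("internal: library cell audit failed for ",
         paste(smiles[got_ring != ring | got_halo != halo], collapse = ", "))
  recs$ring_cell <- ring
  recs$halogen_cell <- halo
  recs
}

# Run an expression under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Seeded multivariate Gaussian latent batch
#'
#' @param mean mean vector.
#' @param cov symmetric positive semidefinite covariance matrix.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return n x d numeric matrix.
#' @export
gaussian_latents <- function(mean, cov, n, seed) {
  d <- length(mean)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  if (max(abs(cov - t(cov))) > 1e-8) stop("covariance must be symmetric")
  eg <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
    stop("covariance must be positive semidefinite")
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), d)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * d), n, d)
    sweep(Z %*% t(L), 2, mean, "+")
  })
}

#' Affine-transformed target latents with known ground truth
#'
#' Draws `z` from a source Gaussian and emits `A_star z + b_star`; the ground
#' truth map is attached for adaptor-recovery tests.
#'
#' @param source_mean,source_cov source Gaussian parameters.
#' @param A_star square matrix; `b_star` vector.
#' @param n,seed draws and seed.
#' @return n x d matrix with attributes `A_star`, `b_star`.
#' @export
affine_target_latents <- function(source_mean, source_cov, A_star, b_star,
                                  n, seed) {
  A_star <- as.matrix(A_star)
  d <- length(source_mean)
  stopifnot(nrow(A_star) == d, ncol(A_star) == d, length(b_star) == d)
  Z <- gaussian_latents(source_mean, source_cov, n, seed)
  out <- sweep(Z %*% t(A_star), 2, b_star, "+")
  attr(out, "A_star") <- A_star
  attr(out, "b_star") <- b_star
  out
}
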