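# The encoder/decoder contract between molecules and the GAN's latent space.
# The production codec in the original setting is a frozen graph VAE; here a
# deterministic descriptor/nearest-neighbour codec provides the same contract
# (including 100% decode validity) so the whole pipeline runs and is testable
# without external model weights.

#' Construct a latent codec
#'
#' @param latent_dim latent dimensionality.
#' @param encode function: molecule records -> matrix (n x latent_dim).
#' @param decode function: matrix (n x latent_dim) -> molecule records.
#' @param id codec identifier string.
#' @return An object of class `"latent_codec"`.
#' @export
latent_codec <- function(latent_dim, encode, decode, id = "custom") {
  stopifnot(latent_dim >= 1, is.function(encode), is.function(decode))
  structure(list(latent_dim = as.integer(latent_dim),
                 encode = encode, decode = decode, id = id),
            class = "latent_codec")
}

#' Build the deterministic toy codec over a molecule library
#'
#' Each library molecule gets a physico-chemical descriptor row (heavy atoms,
#' aromatic/total rings, halogen count, H-bond donors/acceptors, rotatable
#' bonds, MW/100, logP, TPSA/10, per-element counts), zero-padded to
#' `latent_dim` and standardized column-wise to zero mean / unit variance
#' (constant columns are left centred). Encoding returns descriptor rows;
#' decoding maps a latent vector to the nearest library descriptor
#' (Euclidean), ties broken by lexicographically smallest canonical SMILES.
#' Descriptor collisions are resolved by a deterministic index coordinate in
#' the last latent dimension.
#'
#' @param library molecule record data.frame of at least 2 valid, distinct
#'   molecules.
#' @param latent_dim latent dimensionality (default 56, matching the
#'   generator output width).
#' @return A `"latent_codec"` with the library and descriptor matrix attached.
#' @export
build_toy_codec <- function(library, latent_dim = 56L) {
  .assert_valid(library)
  library <- library[!duplicated(library$canonical_smiles), , drop = FALSE]
  rownames(library) <- NULL
  if (nrow(library) < 2) stop("toy codec needs >= 2 distinct molecules")
  latent_dim <- as.integer(latent_dim)
  chem_warm(library$canonical_smiles)
  desc <- t(vapply(library$canonical_smiles, chem_descriptor,
                   numeric(length(chem_descriptor(library$canonical_smiles[1])))))
  if (latent_dim < ncol(desc)) {
    desc <- desc[, seq_len(latent_dim), drop = FALSE]
  } else if (latent_dim > ncol(desc)) {
    desc <- cbind(desc, matrix(0, nrow(desc), latent_dim - ncol(desc)))
  }
  # resolve exact descriptor collisions with an index coordinate
  key <- apply(desc, 1, paste, collapse = "|")
  if (anyDuplicated(key)) {
    desc[, latent_dim] <- desc[, latent_dim] + seq_len(nrow(desc)) *
      as.numeric(duplicated(key) | duplicated(key, fromLast = TRUE))
  }
  mu <- colMeans(desc)
  sdv <- apply(desc, 2, stats::sd)
  scl <- ifelse(sdv > 1e-12, sdv, 1)
  Z <- sweep(sweep(desc, 2, mu), 2, scl, "/")
  dimnames(Z) <- NULL
  lex_rank <- rank(library$canonical_smiles, ties.method = "first")

  enc <- function(records) {
    .assert_valid(records)
    idx <- match(records$canonical_smiles, library$canonical_smiles)
    if (anyNA(idx)) {
      stop("molecules outside the codec library: ",
           paste(unique(records$canonical_smiles[is.na(idx)]), collapse = ", "))
    }
    Z[idx, , drop = FALSE]
  }
  dec <- function(zs) {
    zs <- as.matrix(zs)
    if (ncol(zs) != latent_dim)
      stop("latent width ", ncol(zs), " != codec latent_dim ", latent_dim)
    # squared distances to all library descriptors
    d2 <- outer(rowSums(zs^2), rowSums(Z^2), "+") - 2 * zs %*% t(Z)
    idx <- apply(d2, 1, function(row) {
      tol <- 1e-9 * max(1, min(row))
      cand <- which(row <= min(row) + tol)
      cand[which.min(lex_rank[cand])]
    })
    out <- library[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  codec <- latent_codec(latent_dim, enc, dec, id = "toy-descriptor-nn")
  codec$library <- library
  codec$descriptors <- Z
  codec
}

#' Encode molecules into the latent space
#' @param codec a `"latent_codec"`.
#' @param records molecule record data.frame (all valid).
#' @return numeric matrix, one latent row per molecule, order preserved.
#' @export
encode <- function(codec, records) {
  stopifnot(inherits(codec, "latent_codec"))
  codec$encode(records)
}

#' Decode latent vectors into molecules
#' @param codec a `"latent_codec"`.
#' @param zs numeric matrix (n x latent_dim).
#' @return molecule record data.frame of n molecules.
#' @export
decode <- function(codec, zs) {
  stopifnot(inherits(codec, "latent_codec"))
  codec$decode(zs)
}
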