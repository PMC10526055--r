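# Internal chemistry layer. All molecule-level primitives (parsing,
# canonical SMILES, descriptors, fingerprints, ring perception) are delegated
# to OpenBabel via ChemmineR/ChemmineOB and memoised per canonical SMILES,
# so metric computations over generated multisets cost one chemistry call
# per distinct structure.

.chem <- new.env(parent = emptyenv())

chem_cache_reset <- function() {
  rm(list = ls(.chem), envir = .chem)
  invisible(NULL)
}

# OpenBabel accepts some malformed SMILES (e.g. unbalanced parentheses are
# silently dropped), so a strict syntactic screen runs first: token legality,
# balanced () and [], and paired ring-closure digits. Chemistry (valence,
# aromaticity) is still OpenBabel's job.
smiles_syntax_ok <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) return(FALSE)
  s <- trimws(s)
  if (!nzchar(s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  brk <- FALSE
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
    if (ch == "[") {
      if (brk) return(FALSE)
      brk <- TRUE
    }
    if (ch == "]") {
      if (!brk) return(FALSE)
      brk <- FALSE
    }
  }
  if (depth != 0L || brk) return(FALSE)
  # ring-closure labels must pair up (outside bracket atoms digits are ring
  # closures except when following % which opens a two-digit label)
  bare <- gsub("\\[[^]]*\\]", "A", s)
  labels <- character(0)
  i <- 1L
  cs <- strsplit(bare, "")[[1]]
  while (i <= length(cs)) {
    if (cs[i] == "%") {
      if (i + 2L > length(cs)) return(FALSE)
      labels <- c(labels, paste0(cs[i + 1L], cs[i + 2L]))
      i <- i + 3L
    } else {
      if (grepl("[0-9]", cs[i])) labels <- c(labels, cs[i])
      i <- i + 1L
    }
  }
  all(table(labels) %% 2L == 0L)
}

ob_canonical <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  out <- sub("[\t ].*$", "", sub("\n$", "", out))
  trimws(out)
}

# Canonicalize one SMILES string; "" signals failure.
chem_canonical <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) return("")
  # drop an optional tab-separated name column
  bare <- sub("[\t ].*$", "", trimws(smiles))
  if (!smiles_syntax_ok(bare)) return("")
  ob_canonical(bare)
}

chem_entry <- function(canon) {
  stopifnot(is.character(canon), length(canon) == 1L, nzchar(canon))
  if (!is.null(.chem[[canon]])) return(.chem[[canon]])
  chem_warm(canon)
  .chem[[canon]]
}

# Populate the cache for a set of canonical SMILES in one OpenBabel pass.
chem_warm <- function(canons) {
  canons <- unique(canons[nzchar(canons)])
  todo <- canons[vapply(canons, function(s) is.null(.chem[[s]]), logical(1))]
  if (length(todo) == 0L) return(invisible(NULL))
  nm <- paste0("m", seq_along(todo))
  smi <- stats::setNames(todo, nm)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    stop("cannot build a molecular graph for: ",
         paste(todo[!ok], collapse = ", "),
         " (molecules need at least two heavy atoms)")
  }
  props <- ChemmineR::propOB(sdf)
  rotb <- ChemmineR::smartsSearchOB(
    sdf, "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]", uniqueMatches = TRUE)
  ringlist <- suppressWarnings(
    ChemmineR::rings(sdf, upper = 20, type = "all", arom = TRUE))
  if (length(todo) == 1L) ringlist <- list(ringlist)
  for (i in seq_along(todo)) {
    counts <- tryCatch(ChemmineR::atomcount(sdf[i])[[1]],
                       error = function(e) integer(0))
    .chem[[todo[i]]] <- list(
      sdf = sdf[i],
      props = props[i, , drop = FALSE],
      rotb = unname(rotb[i]),
      counts = counts,
      ringinfo = ring_basis(ringlist[[i]]),
      fps = list()
    )
  }
  invisible(NULL)
}

# Minimal cycle basis (SSSR-style) from the all-rings enumeration: greedily
# admit rings smallest-first whose edge sets are GF(2)-independent of the
# rings already chosen. Returns per-basis-ring sizes and aromatic flags.
ring_basis <- function(ri) {
  if (is.null(ri$RINGS) || length(ri$RINGS) == 0L) {
    return(list(sizes = integer(0), aromatic = logical(0)))
  }
  ring_edges <- lapply(ri$RINGS, function(atoms) {
    nxt <- c(atoms[-1], atoms[1])
    unique(paste(pmin(atoms, nxt), pmax(atoms, nxt), sep = "|"))
  })
  universe <- unique(unlist(ring_edges))
  ord <- order(lengths(ring_edges))
  basis_rows <- list()   # reduced GF(2) vectors
  pivots <- integer(0)
  sizes <- integer(0)
  arom <- logical(0)
  for (k in ord) {
    v <- universe %in% ring_edges[[k]]
    for (j in seq_along(basis_rows)) {
      if (v[pivots[j]]) v <- xor(v, basis_rows[[j]])
    }
    if (any(v)) {
      basis_rows[[length(basis_rows) + 1L]] <- v
      pivots <- c(pivots, which(v)[1])
      sizes <- c(sizes, length(ri$RINGS[[k]]))
      arom <- c(arom, isTRUE(unname(ri$AROMATIC[k])))
    }
  }
  list(sizes = sizes, aromatic = arom)
}

halogen_elements <- c("F", "Cl", "Br", "I")

chem_halogen_count <- function(canon) {
  counts <- chem_entry(canon)$counts
  sum(counts[names(counts) %in% halogen_elements])
}

chem_aromatic_rings <- function(canon) {
  sum(chem_entry(canon)$ringinfo$aromatic)
}

chem_total_rings <- function(canon) {
  length(chem_entry(canon)$ringinfo$sizes)
}

chem_largest_ring <- function(canon) {
  s <- chem_entry(canon)$ringinfo$sizes
  if (length(s) == 0L) 0L else max(s)
}

# Named descriptor vector shared by the toy codec and the property scores.
chem_descriptor <- function(canon) {
  e <- chem_entry(canon)
  cnt <- function(el) {
    v <- e$counts[el]
    if (is.na(v)) 0 else as.numeric(v)
  }
  c(
    heavy_atoms  = sum(e$counts),
    arom_rings   = as.numeric(chem_aromatic_rings(canon)),
    total_rings  = as.numeric(chem_total_rings(canon)),
    halogens     = as.numeric(chem_halogen_count(canon)),
    hbd          = as.numeric(e$props$HBD),
    hba          = as.numeric(e$props$HBA2),
    rotb         = as.numeric(e$rotb),
    mw100        = as.numeric(e$props$MW) / 100,
    logp         = as.numeric(e$props$logP),
    tpsa10       = as.numeric(e$props$TPSA) / 10,
    nC = cnt("C"), nN = cnt("N"), nO = cnt("O"),
    nF = cnt("F"), nCl = cnt("Cl"), nBr = cnt("Br"), nS = cnt("S")
  )
}

# ECFP bit vector of length n_bits (power of two), OR-folded from OpenBabel's
# 4096-bit ECFP{2*radius}.
chem_ecfp <- function(canon, radius = 2L, n_bits = 2048L) {
  stopifnot(radius %in% c(1L, 2L, 3L))
  key <- paste0("r", radius, "_b", n_bits)
  e <- chem_entry(canon)
  if (!is.null(e$fps[[key]])) return(e$fps[[key]])
  fpname <- paste0("ECFP", 2L * radius)
  fpset <- ChemmineR::fingerprintOB(e$sdf, fpname)
  raw <- as.logical(fpset[[1]]@fp)
  bits <- raw
  while (length(bits) > n_bits) {
    half <- length(bits) / 2L
    bits <- bits[seq_len(half)] | bits[half + seq_len(half)]
  }
  e$fps[[key]] <- bits
  .chem[[canon]] <- e
  bits
}

chem_smarts_count <- function(canon, smarts) {
  e <- chem_entry(canon)
  unname(ChemmineR::smartsSearchOB(e$sdf, smarts, uniqueMatches = TRUE)[1])
}
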