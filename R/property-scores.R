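# Molecular property scoring: QED, penalized logP, a pool-calibrated
# synthetic-accessibility heuristic, min-max normalization, and the pluggable
# activity-scorer contract.

# Asymmetric double sigmoid desirability used by the quantitative estimate of
# drug-likeness, with the published parameter table (MW, ALOGP, HBA, HBD,
# PSA, ROTB, AROM, ALERTS) and the mean-weighting scheme.
.qed_ads_params <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 0.000000001,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  ROTB   = c(a = 0.010000000, b = 272.4121427, c = 2.558379970, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  AROM   = c(a = 3.217788970, b = 957.7374108, c = 2.274627939, d = 0.000000001,
             e = 1.317690384, f = 0.375760881, dmax = 312.3372610),
  ALERTS = c(a = 0.010000000, b = 1199.094025, c = -0.09002883, d = 0.000000001,
             e = 0.185904477, f = 0.875193782, dmax = 417.7253140)
)

.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_desirability <- function(x, which) {
  p <- .qed_ads_params[[which]]
  e1 <- 1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])
  e2 <- 1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])
  unname((p["a"] + p["b"] / e1 * (1 - 1 / e2)) / p["dmax"])
}

# Curated structural-alert SMARTS (common reactive / undesirable motifs).
.qed_alerts <- c(
  "[N+](=O)[O-]",          # nitro
  "N(=O)=O",               # nitro (uncharged form)
  "[CX3H1](=O)[#6]",       # aldehyde
  "C(=O)[Cl,Br,I]",        # acyl halide
  "N=[N+]=[N-]",           # azide
  "[#6]N=N[#6]",           # azo
  "N=C=O",                 # isocyanate
  "N=C=S",                 # isothiocyanate
  "[SH]",                  # thiol
  "[#6]OO[#6]",            # peroxide
  "C1OC1",                 # epoxide
  "C1NC1",                 # aziridine
  "[NX3][NX3]",            # hydrazine
  "C(=O)C(=O)",            # 1,2-dicarbonyl
  "[#6]=[#6][CX3](=O)[#6]",# Michael acceptor (enone)
  "S(=O)(=O)[Cl,Br]",      # sulfonyl halide
  "[I]",                   # iodine
  "[CH2]=[CH2]"            # ethylene fragment
)

qed_alert_count <- function(canon) {
  sum(vapply(.qed_alerts,
             function(p) chem_smarts_count(canon, p) > 0, logical(1)))
}

qed_properties <- function(canon) {
  d <- chem_descriptor(canon)
  c(MW = unname(d["mw100"]) * 100,
    ALOGP = unname(d["logp"]),
    HBA = unname(d["hba"]),
    HBD = unname(d["hbd"]),
    PSA = unname(d["tpsa10"]) * 10,
    ROTB = unname(d["rotb"]),
    AROM = unname(d["arom_rings"]),
    ALERTS = qed_alert_count(canon))
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of desirability-transformed descriptors
#' (molecular weight, logP, H-bond acceptors/donors, polar surface area,
#' rotatable bonds, aromatic rings, structural alerts), using the published
#' desirability parameters and mean weights. Descriptors are computed with
#' OpenBabel; the structural-alert set is the package's curated list, so
#' values can differ slightly from other toolkits on alert-bearing molecules.
#'
#' @param records molecule record data.frame; all records must be valid.
#' @return numeric vector of QED values in `[0, 1]`.
#' @export
qed <- function(records) {
  .assert_valid(records)
  chem_warm(records$canonical_smiles)
  vapply(records$canonical_smiles, function(canon) {
    props <- qed_properties(canon)
    d <- vapply(names(props),
                function(nm) qed_desirability(props[[nm]], nm), numeric(1))
    d <- pmax(d, 1e-10)
    w <- .qed_weights[names(props)]
    exp(sum(w * log(d)) / sum(w))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Octanol-water partition coefficient (logP)
#'
#' Wildman-Crippen atomic-contribution logP as implemented by OpenBabel.
#'
#' @param records molecule record data.frame; all records must be valid.
#' @return numeric vector.
#' @export
mol_logp <- function(records) {
  .assert_valid(records)
  chem_warm(records$canonical_smiles)
  vapply(records$canonical_smiles,
         function(s) as.numeric(chem_entry(s)$props$logP),
         numeric(1), USE.NAMES = FALSE)
}

# ---- synthetic accessibility ------------------------------------------------

#' Fit the pool-calibrated synthetic-accessibility model
#'
#' An Ertl-style accessibility heuristic: the fragment-familiarity term is the
#' mean log10 relative frequency (against the most common environment) of a
#' molecule's circular-environment fingerprint bits over a reference pool;
#' complexity penalties cover molecule size and macrocycles. The raw score is
#' mapped onto the conventional 1 (easy) to 10 (hard) scale.
#'
#' @param pool molecule record data.frame of reference molecules.
#' @param radius,n_bits fingerprint parameters for the environment bits.
#' @return An object of class `"sa_model"`.
#' @export
fit_sa_model <- function(pool, radius = 2L, n_bits = 2048L) {
  .assert_valid(pool)
  canons <- unique(pool$canonical_smiles)
  if (length(canons) < 2) stop("SA calibration needs at least 2 molecules")
  fpm <- fingerprint_matrix(canons, radius = radius, n_bits = n_bits)
  freq <- colSums(fpm)
  structure(list(log_freq = log10(pmax(freq, 0.5)),
                 log_fmax = log10(max(freq)),
                 radius = radius, n_bits = n_bits),
            class = "sa_model")
}

#' Raw synthetic-accessibility score (1 = easy, 10 = hard)
#'
#' @param records molecule record data.frame; all records must be valid.
#' @param model an `"sa_model"` from [fit_sa_model()].
#' @return numeric vector in `[1, 10]`.
#' @export
sa_raw <- function(records, model) {
  .assert_valid(records)
  stopifnot(inherits(model, "sa_model"))
  chem_warm(records$canonical_smiles)
  vapply(records$canonical_smiles, function(canon) {
    bits <- which(chem_ecfp(canon, model$radius, model$n_bits))
    frag <- if (length(bits)) {
      mean(model$log_freq[bits] - model$log_fmax)
    } else 0
    d <- chem_descriptor(canon)
    size_pen <- unname(d["heavy_atoms"])^1.005 - unname(d["heavy_atoms"])
    macro_pen <- if (chem_largest_ring(canon) > 8) log10(2) else 0
    raw <- frag - size_pen - macro_pen          # <= 0, lower = harder
    # fixed anchors: raw 0 -> 1 (easiest), raw -6 -> 10 (hardest)
    min(10, max(1, 1 + (-raw / 6) * 9))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Normalized synthetic accessibility in `[0, 1]`
#'
#' `(10 - SA_raw) / 9`; higher means easier to synthesize.
#'
#' @inheritParams sa_raw
#' @export
sa_normalized <- function(records, model) {
  (10 - sa_raw(records, model)) / 9
}

#' Penalized logP (raw scale)
#'
#' `logP - SA_raw - max(0, largest ring size - 6)`, the standard composition
#' from the latent-space molecule-optimization literature.
#'
#' @inheritParams sa_raw
#' @return numeric vector (unbounded).
#' @export
penalized_logp_raw <- function(records, model) {
  .assert_valid(records)
  chem_warm(records$canonical_smiles)
  cyc <- vapply(records$canonical_smiles,
                function(s) max(0, chem_largest_ring(s) - 6),
                numeric(1), USE.NAMES = FALSE)
  mol_logp(records) - sa_raw(records, model) - cyc
}

# ---- normalization ----------------------------------------------------------

#' Min-max score normalizer
#'
#' @param ref_min,ref_max reference range, `ref_max > ref_min`.
#' @return An object of class `"score_normalizer"`.
#' @export
score_normalizer <- function(ref_min, ref_max) {
  if (!is.finite(ref_min) || !is.finite(ref_max) || ref_max <= ref_min)
    stop("ref_max must exceed ref_min")
  structure(list(ref_min = ref_min, ref_max = ref_max),
            class = "score_normalizer")
}

#' Fit a normalizer from a pool of raw scores
#' @param values numeric vector of raw scores over a reference pool.
#' @export
fit_normalizer <- function(values) {
  score_normalizer(min(values), max(values))
}

#' Clip-normalize a score to `[0, 1]`
#' @param value numeric vector of raw scores.
#' @param norm a `"score_normalizer"`.
#' @export
normalize_score <- function(value, norm) {
  stopifnot(inherits(norm, "score_normalizer"))
  pmin(1, pmax(0, (value - norm$ref_min) / (norm$ref_max - norm$ref_min)))
}

#' Invert [normalize_score()] on interior points
#' @param value normalized scores in `[0, 1]`.
#' @param norm a `"score_normalizer"`.
#' @export
denormalize_score <- function(value, norm) {
  stopifnot(inherits(norm, "score_normalizer"))
  norm$ref_min + value * (norm$ref_max - norm$ref_min)
}

# ---- activity scorer contract ----------------------------------------------

.scorers <- new.env(parent = emptyenv())

#' Register an activity scorer plugin
#'
#' The activity contract maps molecules to bioactivity probabilities in
#' `[0, 1]` (e.g. a trained receptor-activity classifier). The package ships
#' no model weights; [mock_halogen_scorer()] is provided for tests.
#'
#' @param name scorer name.
#' @param fn function taking a molecule record data.frame and returning one
#'   probability per row.
#' @export
register_activity_scorer <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .scorers[[name]] <- fn
  invisible(name)
}

#' Score molecules with a registered activity scorer
#'
#' @param records molecule record data.frame.
#' @param name scorer name; defaults to the only registered scorer.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
activity_scores <- function(records, name = NULL) {
  avail <- ls(.scorers)
  if (is.null(name)) {
    if (length(avail) != 1)
      stop("no scorer registered for the activity-scorer contract; ",
           "use register_activity_scorer()")
    name <- avail
  }
  if (!name %in% avail)
    stop("no scorer registered for the activity-scorer contract under '",
         name, "'")
  p <- .scorers[[name]](records)
  if (length(p) != nrow(records) || any(p < 0 | p > 1))
    stop("activity scorer '", name,
         "' violated the contract (length or [0,1] range)")
  p
}

#' Deterministic mock activity scorer
#'
#' Returns 1 for halogen-bearing molecules, 0 otherwise. A stand-in used in
#' tests for the pluggable activity contract; it is synthetic and carries no
#' biological meaning.
#'
#' @param records molecule record data.frame; all records must be valid.
#' @export
mock_halogen_scorer <- function(records) {
  as.numeric(has_halogen(records))
}
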