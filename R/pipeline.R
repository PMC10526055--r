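# Orchestration of the four-stage workflow (pretrain -> finetune ->
# generate -> evaluate) on the self-contained toy codec, with a single
# human-editable config, deterministic per-stage seeds derived from one
# global seed, and a manifest recording provenance for every artifact.

#' Default pipeline configuration
#'
#' Stage sizes are toy-scale so the full workflow runs on one CPU in
#' minutes; the architecture and training defaults mirror [train_config()] /
#' [finetune_config()] semantics at reduced widths.
#'
#' @param seed global seed; per-stage seeds derive from it deterministically.
#' @return nested configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    library_size = 48L,
    latent_dim = 17L,
    noise_dim = 8L,
    gen_hidden = c(32L, 32L),
    disc_hidden = c(32L, 32L),
    pretrain = list(epochs = 300L, batch_size = 64L, learning_rate = 1e-3,
                    gp_lambda = 10, critic_steps = 5L, tile = 16L),
    finetune = list(epochs = 200L, batch_size = 1L, learning_rate = 2e-3,
                    gp_lambda = 10, critic_steps = 1L,
                    task = "halogen", shots = 5L),
    generate = list(n = 1000L),
    metrics = list(radius = 2L, n_bits = 2048L)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- utils::modifyList(unclass(pipeline_config()), yaml::read_yaml(path))
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config a `"pipeline_config"`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derivation, kept below 2^31.
stage_seed <- function(global_seed, stage_index) {
  as.integer((as.numeric(global_seed) * 10007 + stage_index * 97) %%
               2147483647)
}

#' Save / load a model checkpoint
#'
#' Checkpoints store network states (spec, weights, freeze flags), adaptor,
#' codec, history and the creating seed; reload is bit-exact.
#'
#' @param object named list of state objects.
#' @param path checkpoint file path (RDS).
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

#' Run the few-shot adaptation pipeline
#'
#' Executes the requested stages in order on the built-in toy library/codec.
#' Each stage writes deterministically named artifacts under `out_dir`
#' (library and generated SMILES, checkpoints, metric reports), plus the
#' resolved config and a JSON manifest with the config hash and per-stage
#' seeds. No stage mutates another stage's outputs.
#'
#' @param out_dir artifact directory (created if needed).
#' @param config a `"pipeline_config"` (or path to a YAML file).
#' @param stages subset of `c("pretrain", "finetune", "generate",
#'   "evaluate")`, executed in canonical order.
#' @param require_adapted error if `generate` runs without a fine-tune
#'   checkpoint (default `FALSE`: falls back to the identity adaptor, i.e.
#'   the pre-trained model).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         stages = c("pretrain", "finetune", "generate",
                                    "evaluate"),
                         require_adapted = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  write_pipeline_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   stages = list())

  library_ <- toy_molecule_library(config$library_size)
  codec <- build_toy_codec(library_, config$latent_dim)
  write_smiles_file(library_, file.path(out_dir, "library.smi"))
  paths <- list(pretrain = file.path(out_dir, "pretrain.rds"),
                finetune = file.path(out_dir, "finetune.rds"),
                generated = file.path(out_dir, "generated.smi"))

  if ("pretrain" %in% stages) {
    s <- stage_seed(config$seed, 1L)
    g <- build_mlp(mlp_spec(c(config$noise_dim, config$gen_hidden,
                              config$latent_dim), "tanh"), seed = s)
    d <- build_mlp(mlp_spec(c(config$latent_dim, config$disc_hidden, 1L),
                            "leaky_relu"), seed = s + 1L)
    tile <- max(1L, as.integer(config$pretrain$tile %||% 1L))
    pre_cfg <- config$pretrain
    pre_cfg$tile <- NULL
    cfg_t <- do.call(train_config,
                     c(pre_cfg, list(seed = s, noise_dim = config$noise_dim)))
    lat <- encode(codec, library_)
    real <- lat[rep(seq_len(nrow(lat)), tile), , drop = FALSE]
    fit <- pretrain(real, g, d, cfg_t)
    save_checkpoint(list(g = fit$g, d = fit$d, history = fit$history,
                         seed = s, config_hash = cfg_hash), paths$pretrain)
    utils::write.table(fit$history,
                       file.path(out_dir, "pretrain_history.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$stages$pretrain <- list(seed = s, epochs = cfg_t$epochs)
  }

  if ("finetune" %in% stages) {
    if (!file.exists(paths$pretrain))
      stop("missing pre-training checkpoint; run the 'pretrain' stage first")
    ck <- load_checkpoint(paths$pretrain)
    s <- stage_seed(config$seed, 2L)
    filtered <- filter_structure(library_, config$finetune$task)
    refs <- nested_subsample(filtered, sizes = config$finetune$shots,
                             seed = s, task = config$finetune$task)[[1]]$records
    cfg_f <- finetune_config(
      epochs = config$finetune$epochs,
      batch_size = config$finetune$batch_size,
      learning_rate = config$finetune$learning_rate,
      gp_lambda = config$finetune$gp_lambda,
      critic_steps = config$finetune$critic_steps,
      seed = s, noise_dim = config$noise_dim)
    ft <- finetune(refs, codec, ck$g, ck$d, init_adaptor(config$noise_dim),
                   freeze_policy(), cfg_f)
    save_checkpoint(list(adaptor = ft$adaptor, d = ft$d, g = ft$g,
                         refs = refs, history = ft$history,
                         census = ft$census, seed = s,
                         config_hash = cfg_hash), paths$finetune)
    write_smiles_file(refs, file.path(out_dir, "references.smi"))
    manifest$stages$finetune <- list(seed = s, task = config$finetune$task,
                                     shots = config$finetune$shots)
  }

  if ("generate" %in% stages) {
    if (!file.exists(paths$pretrain))
      stop("missing pre-training checkpoint; run the 'pretrain' stage first")
    ck <- load_checkpoint(paths$pretrain)
    if (file.exists(paths$finetune)) {
      adaptor <- load_checkpoint(paths$finetune)$adaptor
      adapted <- TRUE
    } else {
      if (require_adapted)
        stop("no fine-tune checkpoint; run the 'finetune' stage first ",
             "(or drop require_adapted)")
      adaptor <- init_adaptor(config$noise_dim)
      adapted <- FALSE
    }
    s <- stage_seed(config$seed, 3L)
    gen <- generate_molecules(adaptor, ck$g, codec,
                              n = config$generate$n, seed = s)
    write_smiles_file(gen, paths$generated, valid_only = FALSE)
    manifest$stages$generate <- list(seed = s, n = config$generate$n,
                                     adapted = adapted)
  }

  if ("evaluate" %in% stages) {
    if (!file.exists(paths$generated))
      stop("missing generated molecules; run the 'generate' stage first")
    gen <- parse_smiles_file(paths$generated)
    sa <- fit_sa_model(library_)
    pred <- structure_predicate(
      if (config$finetune$task == "halogen") "halogen" else
        config$finetune$task)
    report <- evaluate_molecules(gen, predicate = pred, sa_model = sa,
                                 radius = config$metrics$radius,
                                 n_bits = config$metrics$n_bits)
    write_metric_report(report, file.path(out_dir, "report.tsv"))
    manifest$stages$evaluate <- list(
      diversity = report$diversity, uniqueness = report$uniqueness,
      quality = report$quality)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
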