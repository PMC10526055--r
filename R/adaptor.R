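# Few-shot generative domain adaptation: the affine molecule adaptor
# z' = A z + b on the generator's input noise, the freezing policy (generator
# fully frozen, critic trainable only in its last n layers), the fine-tuning
# loop, constrained generation, and the two latent-space baselines
# (pairwise interpolation and radius sampling around references).

#' Initialize the molecule adaptor
#'
#' `A = I`, `b = 0`, so the adapted model initially reproduces the
#' pre-trained model exactly.
#'
#' @param noise_dim noise dimensionality (>= 1).
#' @return An object of class `"adaptor"` with fields `A` and `b`.
#' @export
init_adaptor <- function(noise_dim) {
  noise_dim <- as.integer(noise_dim)
  if (noise_dim < 1) stop("noise_dim must be >= 1")
  structure(list(A = diag(noise_dim), b = numeric(noise_dim)),
            class = "adaptor")
}

#' Apply the adaptor's affine map to a noise batch
#'
#' Row-wise `z' = A z + b`.
#'
#' @param z noise batch (n x noise_dim).
#' @param a an `"adaptor"`.
#' @return transformed noise batch.
#' @export
adaptor_forward <- function(z, a) {
  stopifnot(inherits(a, "adaptor"))
  z <- as.matrix(z)
  if (ncol(z) != ncol(a$A))
    stop("noise width ", ncol(z), " != adaptor dimension ", ncol(a$A))
  sweep(z %*% t(a$A), 2, a$b, "+")
}

adaptor_adam_init <- function(a) {
  list(mA = a$A * 0, vA = a$A * 0, mb = a$b * 0, vb = a$b * 0, t = 0L)
}

adaptor_adam_step <- function(a, grads, opt, lr, betas = c(0, 0.9),
                              eps = 1e-8) {
  b1 <- betas[1]; b2 <- betas[2]
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  opt$mA <- b1 * opt$mA + (1 - b1) * grads$dA
  opt$vA <- b2 * opt$vA + (1 - b2) * grads$dA^2
  a$A <- a$A - lr * (opt$mA / c1) / (sqrt(opt$vA / c2) + eps)
  opt$mb <- b1 * opt$mb + (1 - b1) * grads$db
  opt$vb <- b2 * opt$vb + (1 - b2) * grads$db^2
  a$b <- a$b - lr * (opt$mb / c1) / (sqrt(opt$vb / c2) + eps)
  list(adaptor = a, opt = opt)
}

#' Fine-tuning freeze policy
#'
#' The generator is fully frozen; only the last
#' `discriminator_trainable_last_n` critic layers (default 2) and the
#' adaptor are trained.
#'
#' @param generator_trainable keep generator trainable (default `FALSE`).
#' @param discriminator_trainable_last_n number of trailing critic weight
#'   layers left trainable (default 2).
#' @param adaptor_trainable train the adaptor (default `TRUE`).
#' @return A `"freeze_policy"` list.
#' @export
freeze_policy <- function(generator_trainable = FALSE,
                          discriminator_trainable_last_n = 2L,
                          adaptor_trainable = TRUE) {
  structure(list(
    generator_trainable = isTRUE(generator_trainable),
    discriminator_trainable_last_n =
      as.integer(discriminator_trainable_last_n),
    adaptor_trainable = isTRUE(adaptor_trainable)),
    class = "freeze_policy")
}

#' Apply a freeze policy to generator and critic
#'
#' @param g,d `"mlp"` states.
#' @param policy a [freeze_policy()].
#' @return `list(g, d, census)` where `census` reports trainable parameter
#'   counts per component.
#' @export
apply_freeze <- function(g, d, policy) {
  stopifnot(inherits(policy, "freeze_policy"))
  n_d <- length(d$W)
  n_last <- policy$discriminator_trainable_last_n
  if (n_last < 0 || n_last > n_d)
    stop("discriminator_trainable_last_n (", n_last,
         ") exceeds critic layer count (", n_d, ")")
  g$frozen <- rep(!policy$generator_trainable, length(g$W))
  d$frozen <- rep(TRUE, n_d)
  if (n_last > 0) d$frozen[(n_d - n_last + 1L):n_d] <- FALSE
  census <- data.frame(
    component = c("generator", "discriminator", "adaptor"),
    trainable = c(n_parameters(g, trainable_only = TRUE),
                  n_parameters(d, trainable_only = TRUE),
                  if (policy$adaptor_trainable)
                    ncol(g$W[[1]])^2 + ncol(g$W[[1]]) else 0),
    total = c(n_parameters(g), n_parameters(d),
              ncol(g$W[[1]])^2 + ncol(g$W[[1]])))
  list(g = g, d = d, census = census)
}

#' Fine-tuning configuration
#'
#' Defaults follow the published fine-tuning setup: 40 epochs, mini-batch 1,
#' Adam at the pre-training rate. `critic_steps` defaults to 1 (each
#' reference step updates critic and adaptor together), and `ema_decay`
#' defaults to 0: few-shot runs take only a few hundred steps, too short
#' for weight averaging to be unbiased. `gen_lr_factor` scales the
#' adaptor/generator learning rate relative to the critic's (a two-time-scale
#' schedule; 1 keeps them equal). `polyak_tail` in (0, 1] replaces the
#' returned adaptor by the uniform average of the adaptor iterates over that
#' final fraction of updates (Polyak-Ruppert tail averaging; it spans several
#' cycles of the slow adversarial oscillation, unlike a short EMA window).
#'
#' @inheritParams train_config
#' @export
finetune_config <- function(epochs = 40L, batch_size = 1L,
                            learning_rate = 1e-3, gp_lambda = 10,
                            critic_steps = 1L, adam_betas = c(0, 0.9),
                            seed = 1L, noise_dim = 100L,
                            lr_decay = c("linear", "none"),
                            ema_decay = 0, gen_lr_factor = 1,
                            polyak_tail = 0) {
  cfg <- train_config(epochs, batch_size, learning_rate, gp_lambda,
                      critic_steps, adam_betas, seed, noise_dim, lr_decay,
                      ema_decay)
  cfg$gen_lr_factor <- gen_lr_factor
  stopifnot(polyak_tail >= 0, polyak_tail <= 1)
  cfg$polyak_tail <- polyak_tail
  class(cfg) <- c("finetune_config", "train_config")
  cfg
}

#' Few-shot fine-tuning of the molecule adaptor
#'
#' Real batches are encodings of the reference molecules (sampled with
#' replacement, so 5-shot and 100-shot share one code path); fake batches are
#' `G(A z + b)`. The objective is the same gradient-penalty Wasserstein loss
#' as in pre-training. The generator is returned bit-identical; frozen critic
#' layers are bit-identical.
#'
#' @param refs molecule record data.frame of reference drugs (>= 1 valid).
#' @param codec `"latent_codec"` used to encode references.
#' @param g,d pre-trained generator/critic.
#' @param a adaptor (usually [init_adaptor()]).
#' @param policy a [freeze_policy()].
#' @param cfg a [finetune_config()].
#' @return `list(adaptor, d, g, history, census)`.
#' @export
finetune <- function(refs, codec, g, d, a, policy = freeze_policy(),
                     cfg = finetune_config()) {
  refs <- refs[refs$is_valid, , drop = FALSE]
  if (nrow(refs) == 0) stop("zero valid reference molecules")
  real <- encode(codec, refs)
  if (ncol(real) != g$spec$widths[length(g$spec$widths)])
    stop("codec latent width does not match generator output width")
  finetune_latents(real, g, d, a, policy, cfg)
}

#' Few-shot fine-tuning directly on reference latent vectors
#'
#' The latent-space core of [finetune()], useful when references are already
#' encoded (or synthetic latent fixtures are used).
#'
#' @param real_latents matrix (n_refs x latent_dim) of reference latents.
#' @inheritParams finetune
#' @return `list(adaptor, d, g, history, census)`.
#' @export
finetune_latents <- function(real_latents, g, d, a,
                             policy = freeze_policy(),
                             cfg = finetune_config()) {
  real <- as.matrix(real_latents)
  if (nrow(real) == 0) stop("zero reference latents")
  if (ncol(real) != g$spec$widths[length(g$spec$widths)])
    stop("latent width does not match generator output width")
  if (ncol(a$A) != g$spec$widths[1])
    stop("adaptor dimension does not match generator noise width")
  fz <- apply_freeze(g, d, policy)
  g <- fz$g; d <- fz$d
  n <- nrow(real)
  with_seed(cfg$seed, {
    opt_d <- adam_init(d)
    opt_a <- adaptor_adam_init(a)
    opt_g <- adam_init(g)
    ema <- list(A = a$A, b = a$b)
    total_updates <- max(1L, (cfg$epochs *
      max(1L, nrow(real) %/% cfg$batch_size)) %/% cfg$critic_steps)
    tail_from <- total_updates - floor(cfg$polyak_tail * total_updates) + 1L
    tail_sum <- list(A = a$A * 0, b = a$b * 0)
    tail_n <- 0L
    upd_i <- 0L
    hist <- vector("list", max(cfg$epochs, 0L))
    steps_per_epoch <- max(1L, n %/% cfg$batch_size)
    step_i <- 0L
    z0 <- matrix(stats::rnorm(cfg$batch_size * cfg$noise_dim),
                 cfg$batch_size, cfg$noise_dim)
    last_gen_loss <- generator_loss(d, mlp_forward(g, adaptor_forward(z0, a))$out)
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- if (cfg$lr_decay == "linear")
        cfg$learning_rate * (1 - (ep - 1) / cfg$epochs) else cfg$learning_rate
      closses <- gps <- numeric(steps_per_epoch)
      glosses <- numeric(0)
      for (bi in seq_len(steps_per_epoch)) {
        idx <- sample.int(n, cfg$batch_size, replace = TRUE)
        real_b <- real[idx, , drop = FALSE]
        z <- sample_noise(cfg$batch_size, cfg$noise_dim)
        fake_b <- mlp_forward(g, adaptor_forward(z, a))$out
        cu <- critic_update(d, opt_d, real_b, fake_b, cfg, lr = lr_ep)
        d <- cu$d; opt_d <- cu$opt
        closses[bi] <- cu$loss; gps[bi] <- cu$gp
        step_i <- step_i + 1L
        if (step_i %% cfg$critic_steps == 0L) {
          z <- sample_noise(cfg$batch_size, cfg$noise_dim)
          glf <- if (is.null(cfg$gen_lr_factor)) 1 else cfg$gen_lr_factor
          if (policy$adaptor_trainable) {
            gu <- generator_update(g, d, opt_g, z, cfg,
                                   adaptor = a, opt_a = opt_a,
                                   lr = lr_ep * glf)
            a <- gu$adaptor; opt_a <- gu$opt_a
            if (cfg$ema_decay > 0) {
              ema$A <- cfg$ema_decay * ema$A + (1 - cfg$ema_decay) * a$A
              ema$b <- cfg$ema_decay * ema$b + (1 - cfg$ema_decay) * a$b
            }
            upd_i <- upd_i + 1L
            if (cfg$polyak_tail > 0 && upd_i >= tail_from) {
              tail_sum$A <- tail_sum$A + a$A
              tail_sum$b <- tail_sum$b + a$b
              tail_n <- tail_n + 1L
            }
          } else {
            gu <- generator_update(g, d, opt_g, z, cfg, lr = lr_ep * glf)
            g <- gu$g; opt_g <- gu$opt_g
          }
          glosses <- c(glosses, gu$loss)
          last_gen_loss <- gu$loss
        }
      }
      hist[[ep]] <- data.frame(
        epoch = ep, critic_loss = mean(closses),
        gen_loss = if (length(glosses)) mean(glosses) else last_gen_loss,
        gp = mean(gps))
    }
    a_last <- a
    if (cfg$polyak_tail > 0 && tail_n > 0) {
      a$A <- tail_sum$A / tail_n
      a$b <- tail_sum$b / tail_n
    } else if (cfg$ema_decay > 0) {
      a$A <- ema$A
      a$b <- ema$b
    }
    list(adaptor = a, adaptor_last = a_last, d = d, g = g,
         history = if (cfg$epochs > 0) do.call(rbind, hist) else
           data.frame(epoch = integer(0), critic_loss = numeric(0),
                      gen_loss = numeric(0), gp = numeric(0)),
         census = fz$census)
  })
}

#' Generate molecules through the adapted model
#'
#' Samples `z ~ N(0, I)`, applies the adaptor and generator, and decodes the
#' resulting latent vectors: `M_gen = decode(G(A z + b))`.
#'
#' @param a adaptor.
#' @param g generator.
#' @param codec latent codec used for decoding.
#' @param n number of molecules (default 1000).
#' @param seed RNG seed.
#' @return molecule record data.frame of exactly `n` records.
#' @export
generate_molecules <- function(a, g, codec, n = 1000L, seed = 1L) {
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  if (n == 0L) return(molecule_records(character(0)))
  noise_dim <- g$spec$widths[1]
  z <- with_seed(seed, sample_noise(n, noise_dim))
  lat <- mlp_forward(g, adaptor_forward(z, a))$out
  decode(codec, lat)
}

#' Latent generation (no decoding) through the adapted model
#' @inheritParams generate_molecules
#' @return latent matrix (n x latent_dim).
#' @export
generate_latents <- function(a, g, n, seed = 1L) {
  z <- with_seed(seed, sample_noise(n, g$spec$widths[1]))
  mlp_forward(g, adaptor_forward(z, a))$out
}

#' Baseline: pairwise interpolation between reference latents
#'
#' Uniformly samples an ordered pair (i != j) and t ~ U(0,1), emitting
#' `t z_i + (1 - t) z_j`.
#'
#' @param ref_latents matrix of >= 2 reference latent rows.
#' @param n number of outputs.
#' @param seed RNG seed.
#' @export
baseline_interpolate <- function(ref_latents, n, seed = 1L) {
  ref_latents <- as.matrix(ref_latents)
  k <- nrow(ref_latents)
  if (k < 2) stop("interpolation needs >= 2 references")
  with_seed(seed, {
    i <- sample.int(k, n, replace = TRUE)
    j <- sample.int(k - 1L, n, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)       # j != i, uniform over the rest
    t <- stats::runif(n)
    t * ref_latents[i, , drop = FALSE] +
      (1 - t) * ref_latents[j, , drop = FALSE]
  })
}

#' Baseline: uniform sampling in L2 balls around reference latents
#'
#' Picks a reference uniformly and adds a perturbation drawn uniformly from
#' the L2 ball of the given radius.
#'
#' @param ref_latents matrix of reference latent rows.
#' @param radius ball radius (>= 0); the published experiments use 0.5, 1
#'   and 2.
#' @param n number of outputs.
#' @param seed RNG seed.
#' @export
baseline_random_sample <- function(ref_latents, radius, n, seed = 1L) {
  ref_latents <- as.matrix(ref_latents)
  k <- nrow(ref_latents)
  if (k < 1) stop("empty reference set")
  if (radius < 0) stop("radius must be >= 0")
  dim_ <- ncol(ref_latents)
  with_seed(seed, {
    i <- sample.int(k, n, replace = TRUE)
    dirs <- matrix(stats::rnorm(n * dim_), n, dim_)
    dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
    r <- radius * stats::runif(n)^(1 / dim_)
    ref_latents[i, , drop = FALSE] + dirs * r
  })
}
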