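# Wasserstein GAN with gradient penalty on molecule latent vectors: the
# critic loss
#   L = E[D(r_G)] - E[D(r_E)] + lambda * E[(||grad_rhat D(rhat)||_2 - 1)^2]
# with rhat drawn uniformly on segments between paired real and generated
# latents, alternating Adam updates (n_critic critic steps per generator
# step), and noise z ~ N(0, I).

#' Pre-training configuration
#'
#' Defaults follow the published training setup (200 epochs, mini-batch 128,
#' Adam at 1e-3) and the standard gradient-penalty settings
#' (`gp_lambda = 10`, 5 critic steps per generator step, Adam betas (0, 0.9)).
#'
#' @param epochs,batch_size,learning_rate,gp_lambda,critic_steps,seed scalars.
#' @param adam_betas length-2 numeric.
#' @param noise_dim generator input width (default 100).
#' @param lr_decay `"linear"` (default) anneals the learning rate linearly
#'   to zero over the epochs, the usual gradient-penalty training practice;
#'   `"none"` keeps it constant.
#' @param ema_decay exponential-moving-average decay for the returned
#'   generator weights (Polyak averaging, standard GAN practice; it removes
#'   the residual parameter cycling of adversarial training). Set to 0 to
#'   return the last iterate.
#' @return A `"train_config"` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 128L,
                         learning_rate = 1e-3, gp_lambda = 10,
                         critic_steps = 5L, adam_betas = c(0, 0.9),
                         seed = 1L, noise_dim = 100L,
                         lr_decay = c("linear", "none"), ema_decay = 0.998) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, gp_lambda = gp_lambda,
              critic_steps = as.integer(critic_steps),
              adam_betas = adam_betas, seed = as.integer(seed),
              noise_dim = as.integer(noise_dim),
              lr_decay = match.arg(lr_decay), ema_decay = ema_decay)
  if (cfg$epochs < 0 || cfg$batch_size < 1 || cfg$learning_rate <= 0 ||
      cfg$gp_lambda < 0 || cfg$critic_steps < 1 ||
      cfg$ema_decay < 0 || cfg$ema_decay >= 1)
    stop("invalid training configuration")
  structure(cfg, class = "train_config")
}

#' Generator forward pass
#'
#' Tanh hidden layers, linear output of width `latent_dim`.
#'
#' @param g generator `"mlp"`.
#' @param z noise batch (n x noise_dim).
#' @return latent batch (n x latent_dim).
#' @export
generator_forward <- function(g, z) {
  mlp_forward(g, z)$out
}

#' Critic (discriminator) forward pass
#'
#' LeakyReLU (slope 0.2) hidden layers and a linear scalar output — an
#' unbounded Wasserstein critic, no sigmoid.
#'
#' @param d critic `"mlp"`.
#' @param x latent batch (n x latent_dim).
#' @return numeric vector of critic scores.
#' @export
discriminator_forward <- function(d, x) {
  as.numeric(mlp_forward(d, x)$out)
}

# Gradient-penalty internals on a fixed interpolate batch. Returns the
# penalty value and its gradients with respect to the critic parameters.
# The parameter gradients use the closed-form double backprop for
# piecewise-linear hidden activations (the activation pattern is locally
# constant, so its derivative vanishes almost everywhere, matching
# reverse-mode autodiff).
gp_terms <- function(d, Xhat, gp_lambda) {
  B <- nrow(Xhat)
  cache <- mlp_forward(d, Xhat, keep = TRUE)
  cig <- critic_input_gradient(d, cache)
  norms <- sqrt(rowSums(cig$G^2))
  penalty <- gp_lambda * mean((norms - 1)^2)
  # u = dP/dG rows
  u <- (2 * gp_lambda / B) * ((norms - 1) / pmax(norms, 1e-12)) * cig$G
  n_layers <- length(d$W)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  Q <- u
  for (k in seq_len(n_layers)) {
    dW[[k]] <- t(cig$V[[k]]) %*% Q
    db[[k]] <- numeric(length(d$b[[k]]))
    if (k < n_layers) Q <- (Q %*% t(d$W[[k]])) * cache$S[[k]]
  }
  list(penalty = penalty, dW = dW, db = db)
}

draw_interpolates <- function(real, fake) {
  B <- nrow(real)
  eps <- stats::runif(B)
  eps * real + (1 - eps) * fake
}

#' Gradient penalty of a critic on a real/fake batch pair
#'
#' Draws one epsilon ~ U(0,1) per row, forms the interpolates
#' `rhat = eps * real + (1 - eps) * fake`, and returns
#' `gp_lambda * mean((||grad_rhat D(rhat)|| - 1)^2)`.
#'
#' @param d critic `"mlp"`.
#' @param real,fake matrices of equal dimension.
#' @param gp_lambda penalty coefficient (default 10).
#' @param seed optional seed for the epsilon draw; if `NULL` the current RNG
#'   stream is used.
#' @return penalty value (>= 0).
#' @export
gradient_penalty <- function(d, real, fake, gp_lambda = 10, seed = NULL) {
  real <- as.matrix(real); fake <- as.matrix(fake)
  if (!all(dim(real) == dim(fake))) stop("real/fake batch mismatch")
  Xhat <- if (is.null(seed)) draw_interpolates(real, fake) else
    with_seed(seed, draw_interpolates(real, fake))
  gp_terms(d, Xhat, gp_lambda)$penalty
}

#' Critic loss (Wasserstein + gradient penalty)
#'
#' @inheritParams gradient_penalty
#' @return `mean D(fake) - mean D(real) + gradient_penalty`.
#' @export
critic_loss <- function(d, real, fake, gp_lambda = 10, seed = NULL) {
  real <- as.matrix(real); fake <- as.matrix(fake)
  if (nrow(real) == 0 || nrow(fake) == 0) stop("empty batch")
  if (!all(dim(real) == dim(fake))) stop("real/fake batch mismatch")
  mean(discriminator_forward(d, fake)) -
    mean(discriminator_forward(d, real)) +
    gradient_penalty(d, real, fake, gp_lambda, seed)
}

#' Generator loss
#'
#' @param d critic `"mlp"`.
#' @param fake generated latent batch.
#' @return `-mean D(fake)`.
#' @export
generator_loss <- function(d, fake) {
  fake <- as.matrix(fake)
  if (nrow(fake) == 0) stop("empty batch")
  -mean(discriminator_forward(d, fake))
}

# One critic Adam update on (real, fake). Returns updated critic/optimizer
# and the loss components.
critic_update <- function(d, opt_d, real, fake, cfg, lr = cfg$learning_rate) {
  B <- nrow(real)
  cache_f <- mlp_forward(d, fake, keep = TRUE)
  cache_r <- mlp_forward(d, real, keep = TRUE)
  gp <- gp_terms(d, draw_interpolates(real, fake), cfg$gp_lambda)
  bf <- mlp_backprop(d, cache_f, matrix(1 / B, B, 1))
  br <- mlp_backprop(d, cache_r, matrix(-1 / B, B, 1))
  grads <- list(
    dW = mapply(function(a, b, c) a + b + c, bf$dW, br$dW, gp$dW,
                SIMPLIFY = FALSE),
    db = mapply(function(a, b, c) a + b + c, bf$db, br$db, gp$db,
                SIMPLIFY = FALSE)
  )
  st <- adam_step(d, grads, opt_d, lr, cfg$adam_betas)
  loss <- mean(cache_f$out) - mean(cache_r$out) + gp$penalty
  list(d = st$net, opt = st$opt, loss = loss, gp = gp$penalty)
}

# One generator/adaptor Adam update. When `adaptor`/`opt_a` are supplied the
# generator is left untouched and only (A, b) receive gradients; otherwise
# the generator's unfrozen layers are updated.
generator_update <- function(g, d, opt_g, Z, cfg, adaptor = NULL,
                             opt_a = NULL, lr = cfg$learning_rate) {
  B <- nrow(Z)
  Zp <- if (is.null(adaptor)) Z else adaptor_forward(Z, adaptor)
  cache_g <- mlp_forward(g, Zp, keep = TRUE)
  cache_d <- mlp_forward(d, cache_g$out, keep = TRUE)
  loss <- -mean(cache_d$out)
  bp_d <- mlp_backprop(d, cache_d, matrix(-1 / B, B, 1))
  bp_g <- mlp_backprop(g, cache_g, bp_d$dX)
  if (is.null(adaptor)) {
    st <- adam_step(g, bp_g, opt_g, lr, cfg$adam_betas)
    list(g = st$net, opt_g = st$opt, adaptor = NULL, opt_a = NULL,
         loss = loss)
  } else {
    grads <- list(dA = t(bp_g$dX) %*% Z, db = colSums(bp_g$dX))
    st <- adaptor_adam_step(adaptor, grads, opt_a, lr, cfg$adam_betas)
    list(g = g, opt_g = opt_g, adaptor = st$adaptor, opt_a = st$opt,
         loss = loss)
  }
}

#' WGAN-GP pre-training on real latent vectors
#'
#' Alternates `critic_steps` critic updates per generator update with Adam,
#' drawing noise z ~ N(0, I). Fully reproducible from `cfg$seed`.
#'
#' @param real_latents matrix (n x latent_dim) of encoder-produced latents.
#' @param g,d generator and critic `"mlp"` states.
#' @param cfg a [train_config()].
#' @return `list(g, d, history, g_last)`; `g` carries the EMA-averaged
#'   weights (see `ema_decay`), `g_last` the final iterate, and `history`
#'   one row per epoch with mean critic loss, generator loss and gradient
#'   penalty.
#' @export
pretrain <- function(real_latents, g, d, cfg) {
  real_latents <- as.matrix(real_latents)
  n <- nrow(real_latents)
  if (cfg$batch_size > n)
    stop("batch_size (", cfg$batch_size, ") exceeds dataset size (", n, ")")
  if (ncol(real_latents) != g$spec$widths[length(g$spec$widths)])
    stop("latent width mismatch between data and generator output")
  if (cfg$epochs == 0L)
    return(list(g = g, d = d,
                history = data.frame(epoch = integer(0),
                                     critic_loss = numeric(0),
                                     gen_loss = numeric(0),
                                     gp = numeric(0))))
  with_seed(cfg$seed, {
    opt_g <- adam_init(g)
    opt_d <- adam_init(d)
    ema <- list(W = g$W, b = g$b)
    hist <- vector("list", cfg$epochs)
    step_i <- 0L
    z0 <- matrix(stats::rnorm(cfg$batch_size * cfg$noise_dim),
                 cfg$batch_size, cfg$noise_dim)
    last_gen_loss <- generator_loss(d, mlp_forward(g, z0)$out)
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- if (cfg$lr_decay == "linear")
        cfg$learning_rate * (1 - (ep - 1) / cfg$epochs) else cfg$learning_rate
      perm <- sample(n)
      n_batches <- n %/% cfg$batch_size
      closses <- gps <- numeric(n_batches)
      glosses <- numeric(0)
      for (bi in seq_len(n_batches)) {
        idx <- perm[((bi - 1L) * cfg$batch_size + 1L):(bi * cfg$batch_size)]
        real_b <- real_latents[idx, , drop = FALSE]
        z <- matrix(stats::rnorm(cfg$batch_size * cfg$noise_dim),
                    cfg$batch_size, cfg$noise_dim)
        fake_b <- mlp_forward(g, z)$out
        cu <- critic_update(d, opt_d, real_b, fake_b, cfg, lr = lr_ep)
        d <- cu$d; opt_d <- cu$opt
        closses[bi] <- cu$loss; gps[bi] <- cu$gp
        step_i <- step_i + 1L
        if (step_i %% cfg$critic_steps == 0L) {
          z <- matrix(stats::rnorm(cfg$batch_size * cfg$noise_dim),
                      cfg$batch_size, cfg$noise_dim)
          gu <- generator_update(g, d, opt_g, z, cfg, lr = lr_ep)
          g <- gu$g; opt_g <- gu$opt_g
          if (cfg$ema_decay > 0) {
            ema$W <- mapply(function(e, w) cfg$ema_decay * e +
                              (1 - cfg$ema_decay) * w, ema$W, g$W,
                            SIMPLIFY = FALSE)
            ema$b <- mapply(function(e, w) cfg$ema_decay * e +
                              (1 - cfg$ema_decay) * w, ema$b, g$b,
                            SIMPLIFY = FALSE)
          }
          glosses <- c(glosses, gu$loss)
          last_gen_loss <- gu$loss
        }
      }
      hist[[ep]] <- data.frame(
        epoch = ep,
        critic_loss = mean(closses),
        gen_loss = if (length(glosses)) mean(glosses) else last_gen_loss,
        gp = mean(gps))
    }
    g_last <- g
    if (cfg$ema_decay > 0) {
      g$W <- ema$W
      g$b <- ema$b
    }
    list(g = g, d = d, history = do.call(rbind, hist), g_last = g_last)
  })
}

#' Draw generator noise
#' @param n batch size.
#' @param noise_dim noise width.
#' @export
sample_noise <- function(n, noise_dim) {
  matrix(stats::rnorm(n * noise_dim), n, noise_dim)
}
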