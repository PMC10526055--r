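# Minimal dense-network machinery in base R matrices: specs, fan-in-scaled
# initialization, forward passes with activation caches, reverse-mode
# gradients, and Adam. Written for the small MLPs used here (a few hundred
# units); everything is vectorized over the batch dimension.

#' Multilayer-perceptron specification
#'
#' `widths` includes the input and output widths, so `length(widths) - 1`
#' weight layers are created. Hidden layers use `hidden_activation`; the
#' output layer is always linear (latent vectors and critic scores are
#' unbounded).
#'
#' @param widths integer vector of layer widths (>= 2 entries, all positive).
#' @param hidden_activation `"tanh"` or `"leaky_relu"` (slope 0.2).
#' @return An object of class `"mlp_spec"`.
#' @export
mlp_spec <- function(widths, hidden_activation = c("tanh", "leaky_relu")) {
  hidden_activation <- match.arg(hidden_activation)
  widths <- as.integer(widths)
  if (length(widths) < 2) stop("mlp_spec needs at least 2 widths")
  if (any(widths <= 0)) stop("all widths must be positive")
  structure(list(widths = widths, hidden_activation = hidden_activation),
            class = "mlp_spec")
}

#' Default generator architecture
#' @param noise_dim input noise width (default 100).
#' @param latent_dim output latent width (default 56).
#' @export
generator_spec <- function(noise_dim = 100L, latent_dim = 56L) {
  mlp_spec(c(noise_dim, 128L, 256L, 256L, 512L, 256L, latent_dim), "tanh")
}

#' Default critic architecture
#' @param latent_dim input latent width (default 56).
#' @export
discriminator_spec <- function(latent_dim = 56L) {
  mlp_spec(c(latent_dim, 128L, 256L, 128L, 1L), "leaky_relu")
}

.leaky_slope <- 0.2

#' Initialize MLP parameters
#'
#' Fan-in-scaled Gaussian weights (`sd = 1/sqrt(fan_in)`), zero biases.
#' Reproducible from `seed`; the caller's RNG state is untouched.
#'
#' @param spec an `"mlp_spec"`.
#' @param seed integer seed.
#' @return An object of class `"mlp"` with per-layer weight matrices `W`
#'   (out x in), bias vectors `b`, and `frozen` flags (all `FALSE`).
#' @export
build_mlp <- function(spec, seed) {
  stopifnot(inherits(spec, "mlp_spec"))
  n_layers <- length(spec$widths) - 1L
  with_seed(seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (i in seq_len(n_layers)) {
      fan_in <- spec$widths[i]
      fan_out <- spec$widths[i + 1L]
      W[[i]] <- matrix(stats::rnorm(fan_out * fan_in, sd = 1 / sqrt(fan_in)),
                       fan_out, fan_in)
      b[[i]] <- numeric(fan_out)
    }
    structure(list(spec = spec, W = W, b = b,
                   frozen = rep(FALSE, n_layers)),
              class = "mlp")
  })
}

#' Number of parameters in an MLP
#' @param net an `"mlp"`.
#' @param trainable_only count only unfrozen layers.
#' @export
n_parameters <- function(net, trainable_only = FALSE) {
  idx <- if (trainable_only) which(!net$frozen) else seq_along(net$W)
  sum(vapply(idx, function(i) length(net$W[[i]]) + length(net$b[[i]]),
             numeric(1)))
}

act_fun <- function(kind, a) {
  if (kind == "tanh") tanh(a) else ifelse(a > 0, a, .leaky_slope * a)
}
act_deriv <- function(kind, a, h) {
  if (kind == "tanh") 1 - h^2 else ifelse(a > 0, 1, .leaky_slope)
}

# Forward pass. X is batch x input. Returns list(out, cache) where cache
# holds per-layer pre-activations A, activations H (H[[1]] = X) and hidden
# derivative masks S.
mlp_forward <- function(net, X, keep = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != net$spec$widths[1])
    stop("input width ", ncol(X), " != spec input width ", net$spec$widths[1])
  n_layers <- length(net$W)
  kind <- net$spec$hidden_activation
  H <- if (keep) vector("list", n_layers + 1L) else NULL
  S <- if (keep) vector("list", n_layers) else NULL
  h <- X
  if (keep) H[[1]] <- X
  for (i in seq_len(n_layers)) {
    a <- h %*% t(net$W[[i]])
    a <- sweep(a, 2, net$b[[i]], "+")
    if (i < n_layers) {
      h <- act_fun(kind, a)
      if (keep) S[[i]] <- act_deriv(kind, a, h)
    } else {
      h <- a
      if (keep) S[[i]] <- matrix(1, nrow(a), ncol(a))
    }
    if (keep) H[[i + 1L]] <- h
  }
  if (keep) list(out = h, H = H, S = S) else list(out = h)
}

# Reverse-mode gradients from upstream dOut (batch x out). Returns per-layer
# dW/db and the gradient with respect to the input batch.
mlp_backprop <- function(net, cache, dOut) {
  n_layers <- length(net$W)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  delta <- dOut  # d loss / d A_L (output layer linear)
  for (i in rev(seq_len(n_layers))) {
    dW[[i]] <- t(delta) %*% cache$H[[i]]
    db[[i]] <- colSums(delta)
    if (i > 1L) {
      delta <- (delta %*% net$W[[i]]) * cache$S[[i - 1L]]
    } else {
      dX <- delta %*% net$W[[1L]]
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# Gradient of the scalar critic output with respect to its input, for every
# row of the batch. Also returns the per-layer backprop masks V (V[[i]] =
# dD/dA_i) reused by the gradient-penalty parameter gradients.
critic_input_gradient <- function(net, cache) {
  n_layers <- length(net$W)
  V <- vector("list", n_layers)
  B <- nrow(cache$H[[1]])
  V[[n_layers]] <- matrix(1, B, 1)
  if (n_layers > 1) {
    for (i in rev(seq_len(n_layers - 1L))) {
      V[[i]] <- (V[[i + 1L]] %*% net$W[[i + 1L]]) * cache$S[[i]]
    }
  }
  list(G = V[[1L]] %*% net$W[[1L]], V = V)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(x) x * 0),
       vb = lapply(net$b, function(x) x * 0),
       t = 0L)
}

# One Adam step over the unfrozen layers of `net`.
adam_step <- function(net, grads, opt, lr, betas = c(0, 0.9), eps = 1e-8) {
  b1 <- betas[1]; b2 <- betas[2]
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (i in which(!net$frozen)) {
    opt$mW[[i]] <- b1 * opt$mW[[i]] + (1 - b1) * grads$dW[[i]]
    opt$vW[[i]] <- b2 * opt$vW[[i]] + (1 - b2) * grads$dW[[i]]^2
    net$W[[i]] <- net$W[[i]] -
      lr * (opt$mW[[i]] / c1) / (sqrt(opt$vW[[i]] / c2) + eps)
    opt$mb[[i]] <- b1 * opt$mb[[i]] + (1 - b1) * grads$db[[i]]
    opt$vb[[i]] <- b2 * opt$vb[[i]] + (1 - b2) * grads$db[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (opt$mb[[i]] / c1) / (sqrt(opt$vb[[i]] / c2) + eps)
  }
  list(net = net, opt = opt)
}
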