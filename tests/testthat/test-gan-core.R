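test_that("mlp construction counts parameters and is seed-reproducible", {
  spec <- mlp_spec(c(2, 3, 1), "leaky_relu")
  net <- build_mlp(spec, seed = 1)
  expect_equal(n_parameters(net), (2 + 1) * 3 + (3 + 1) * 1)   # 13
  net2 <- build_mlp(spec, seed = 1)
  expect_identical(net$W, net2$W)
  net3 <- build_mlp(spec, seed = 2)
  expect_false(identical(net$W, net3$W))
  expect_error(mlp_spec(c(5)), "at least 2")
  expect_error(mlp_spec(c(4, 0, 1)), "positive")
})

test_that("forward passes obey their closed forms", {
  # zero parameters -> zero outputs, shape preserved
  g <- build_mlp(mlp_spec(c(3, 4, 2), "tanh"), seed = 1)
  g$W <- lapply(g$W, function(w) w * 0)
  z <- matrix(rnorm(15), 5, 3)
  out <- generator_forward(g, z)
  expect_equal(dim(out), c(5L, 2L))
  expect_true(all(out == 0))
  # single hidden layer with identity-like weights: output = tanh(input)
  g2 <- build_mlp(mlp_spec(c(2, 2, 2), "tanh"), seed = 1)
  g2$W[[1]] <- diag(2); g2$W[[2]] <- diag(2)
  g2$b <- lapply(g2$b, function(b) b * 0)
  z2 <- matrix(c(0.3, -1.2, 0.8, 0.1), 2, 2)
  expect_equal(generator_forward(g2, z2), tanh(z2), tolerance = 1e-12)
  # linear critic with no hidden layer: score = w . x, and doubles with x
  d <- build_mlp(mlp_spec(c(3, 1), "leaky_relu"), seed = 1)
  x <- matrix(rnorm(12), 4, 3)
  s <- discriminator_forward(d, x)
  expect_equal(s, as.numeric(x %*% t(d$W[[1]])), tolerance = 1e-12)  # b = 0
  expect_equal(discriminator_forward(d, 2 * x), 2 * s, tolerance = 1e-12)
  expect_error(generator_forward(g, matrix(0, 2, 7)), "width")
})

test_that("gradient penalty matches the analytic value for linear critics", {
  set.seed(99)
  real <- matrix(rnorm(16), 8, 2)
  fake <- matrix(rnorm(16), 8, 2)
  lin <- build_mlp(mlp_spec(c(2, 1), "leaky_relu"), seed = 1)
  # D(x) = 2 x1: ||grad|| = 2 everywhere -> penalty = lambda (2-1)^2
  lin$W[[1]][] <- c(2, 0); lin$b[[1]] <- 0
  expect_equal(gradient_penalty(lin, real, fake, 10, seed = 5), 10,
               tolerance = 1e-12)
  expect_equal(gradient_penalty(lin, real, fake, 0, seed = 5), 0)
  # random linear critics: penalty = lambda (||w|| - 1)^2
  for (i in 1:20) {
    w <- rnorm(2)
    lin$W[[1]][] <- w
    expect_equal(gradient_penalty(lin, real, fake, 10, seed = i),
                 10 * (sqrt(sum(w^2)) - 1)^2, tolerance = 1e-6)
  }
  # unit-norm weight vector: exactly zero
  lin$W[[1]][] <- c(0.6, 0.8)
  expect_equal(gradient_penalty(lin, real, fake, 10, seed = 2), 0,
               tolerance = 1e-12)
  expect_error(gradient_penalty(lin, real, matrix(0, 3, 2), 10), "mismatch")
})

test_that("losses obey the Wasserstein closed forms for constant critics", {
  # constant critic D = c: zero input gradient -> penalty = lambda per sample
  d <- build_mlp(mlp_spec(c(2, 3, 1), "leaky_relu"), seed = 4)
  d$W <- lapply(d$W, function(w) w * 0)
  d$b[[2]] <- 1.5
  real <- matrix(rnorm(10), 5, 2)
  fake <- matrix(rnorm(10), 5, 2)
  lam <- 10
  expect_equal(critic_loss(d, real, fake, lam, seed = 1), lam,
               tolerance = 1e-12)       # W-term cancels, penalty = lambda
  expect_equal(generator_loss(d, fake), -1.5, tolerance = 1e-12)
  # identical real and fake batches: Wasserstein term is 0 for any critic
  d2 <- build_mlp(mlp_spec(c(2, 4, 1), "leaky_relu"), seed = 8)
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(critic_loss(d2, x, x, 0, seed = 1), 0, tolerance = 1e-12)
  expect_error(critic_loss(d2, x[0, ], x[0, ], 10), "empty")
})

test_that("critic and adaptor analytic gradients agree with finite differences", {
  am <- asNamespace("adaptmol")
  set.seed(21)
  d <- build_mlp(mlp_spec(c(3, 6, 4, 1), "leaky_relu"), seed = 13)
  real <- matrix(rnorm(8 * 3), 8)
  fake <- matrix(rnorm(8 * 3), 8)
  eps <- runif(8)
  Xhat <- eps * real + (1 - eps) * fake
  lam <- 10
  obj <- function(dd) {
    am$gp_terms(dd, Xhat, lam)$penalty +
      mean(discriminator_forward(dd, fake)) -
      mean(discriminator_forward(dd, real))
  }
  cf <- am$mlp_forward(d, fake, keep = TRUE)
  cr <- am$mlp_forward(d, real, keep = TRUE)
  gp <- am$gp_terms(d, Xhat, lam)
  bf <- am$mlp_backprop(d, cf, matrix(1 / 8, 8, 1))
  br <- am$mlp_backprop(d, cr, matrix(-1 / 8, 8, 1))
  h <- 1e-6
  for (li in 1:3) {
    dW <- bf$dW[[li]] + br$dW[[li]] + gp$dW[[li]]
    for (trial in 1:4) {
      i <- sample(length(d$W[[li]]), 1)
      dp <- d; dp$W[[li]][i] <- dp$W[[li]][i] + h
      dm <- d; dm$W[[li]][i] <- dm$W[[li]][i] - h
      fd <- (obj(dp) - obj(dm)) / (2 * h)
      expect_equal(dW[i], fd, tolerance = 1e-4)
    }
  }
  # adaptor gradients through a frozen tanh generator
  g <- build_mlp(mlp_spec(c(3, 5, 2), "tanh"), seed = 2)
  a <- init_adaptor(3)
  a$A <- a$A + matrix(rnorm(9, 0, 0.1), 3)
  a$b <- rnorm(3, 0, 0.1)
  Z <- matrix(rnorm(7 * 3), 7)
  d2 <- build_mlp(mlp_spec(c(2, 4, 1), "leaky_relu"), seed = 5)
  objg <- function(aa)
    generator_loss(d2, am$mlp_forward(g, adaptor_forward(Z, aa))$out)
  cg <- am$mlp_forward(g, adaptor_forward(Z, a), keep = TRUE)
  cd <- am$mlp_forward(d2, cg$out, keep = TRUE)
  bpd <- am$mlp_backprop(d2, cd, matrix(-1 / 7, 7, 1))
  bpg <- am$mlp_backprop(g, cg, bpd$dX)
  dA <- t(bpg$dX) %*% Z
  db <- colSums(bpg$dX)
  for (trial in 1:5) {
    i <- sample(9, 1)
    ap <- a; ap$A[i] <- ap$A[i] + h
    amn <- a; amn$A[i] <- amn$A[i] - h
    expect_equal(dA[i], (objg(ap) - objg(amn)) / (2 * h), tolerance = 1e-5)
  }
  for (i in 1:3) {
    ap <- a; ap$b[i] <- ap$b[i] + h
    amn <- a; amn$b[i] <- amn$b[i] - h
    expect_equal(db[i], (objg(ap) - objg(amn)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("pretraining contracts: epoch-0 no-op, determinism, finite history", {
  real <- gaussian_latents(c(0, 0), diag(2), 64, seed = 1)
  g <- build_mlp(mlp_spec(c(4, 8, 2), "tanh"), seed = 1)
  d <- build_mlp(mlp_spec(c(2, 8, 1), "leaky_relu"), seed = 2)
  cfg0 <- train_config(epochs = 0, batch_size = 16, seed = 5, noise_dim = 4)
  fit0 <- pretrain(real, g, d, cfg0)
  expect_identical(fit0$g, g)
  expect_identical(fit0$d, d)
  expect_equal(nrow(fit0$history), 0)
  cfg <- train_config(epochs = 5, batch_size = 16, seed = 5, noise_dim = 4)
  fit1 <- pretrain(real, g, d, cfg)
  fit2 <- pretrain(real, g, d, cfg)
  expect_identical(fit1$g$W, fit2$g$W)
  expect_identical(fit1$d$W, fit2$d$W)
  expect_equal(nrow(fit1$history), 5)
  expect_true(all(is.finite(as.matrix(fit1$history))))
  expect_error(pretrain(real, g, d,
                        train_config(epochs = 1, batch_size = 128,
                                     noise_dim = 4)),
               "exceeds")
})
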