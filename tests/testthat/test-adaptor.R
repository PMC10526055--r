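test_that("adaptor initializes to the identity map", {
  a <- init_adaptor(3)
  expect_equal(a$A, diag(3))
  expect_equal(a$b, rep(0, 3))
  z <- matrix(rnorm(12), 4, 3)
  expect_equal(adaptor_forward(z, a), z)
  expect_error(init_adaptor(0), ">= 1")
})

test_that("adaptor forward is the row-wise affine map", {
  a <- init_adaptor(2)
  a$A <- matrix(c(2, 0, 0, 3), 2, byrow = TRUE)
  a$b <- c(1, -1)
  expect_equal(adaptor_forward(matrix(c(1, 1), 1), a),
               matrix(c(3, 2), 1))
  expect_equal(adaptor_forward(matrix(0, 1, 2), a), matrix(a$b, 1))
  expect_error(adaptor_forward(matrix(0, 1, 5), a), "dimension")
})

test_that("freeze policy freezes the generator and all but the last n critic layers", {
  g <- build_mlp(generator_spec(10, 8), seed = 1)
  d <- build_mlp(discriminator_spec(8), seed = 2)
  fz <- apply_freeze(g, d, freeze_policy())
  expect_true(all(fz$g$frozen))
  expect_equal(fz$d$frozen, c(TRUE, TRUE, FALSE, FALSE))
  census <- fz$census
  expect_equal(census$trainable[census$component == "generator"], 0)
  expect_equal(census$trainable[census$component == "discriminator"],
               (256 + 1) * 128 + (128 + 1) * 1)
  expect_equal(census$trainable[census$component == "adaptor"], 10^2 + 10)
  # n = 0: only the adaptor is trainable
  fz0 <- apply_freeze(g, d, freeze_policy(discriminator_trainable_last_n = 0))
  expect_true(all(fz0$d$frozen))
  expect_error(apply_freeze(g, d,
                            freeze_policy(discriminator_trainable_last_n = 9)),
               "exceeds")
})

test_that("fine-tuning honours the freeze contract bit-exactly", {
  lib <- test_library(24)
  codec <- build_toy_codec(lib, 17L)
  g <- build_mlp(mlp_spec(c(6, 16, 17), "tanh"), seed = 3)
  d <- build_mlp(mlp_spec(c(17, 16, 8, 1), "leaky_relu"), seed = 4)
  refs <- filter_structure(lib, "halogen")[1:5, ]
  cfg <- finetune_config(epochs = 3, seed = 9, noise_dim = 6)
  ft <- finetune(refs, codec, g, d, init_adaptor(6), freeze_policy(), cfg)
  expect_identical(param_hash(ft$g), param_hash(g))
  expect_identical(param_hash(ft$d, layers = 1), param_hash(d, layers = 1))
  expect_false(identical(param_hash(ft$d, layers = 2:3),
                         param_hash(d, layers = 2:3)))
  expect_false(identical(ft$adaptor$A, diag(6)))
  expect_equal(nrow(ft$history), 3)
  # reproducibility
  ft2 <- finetune(refs, codec, g, d, init_adaptor(6), freeze_policy(), cfg)
  expect_identical(ft$adaptor, ft2$adaptor)
  expect_identical(ft$d$W, ft2$d$W)
  expect_error(finetune(recs("C(C"), codec, g, d, init_adaptor(6)),
               "zero valid")
})

test_that("identity adaptor reproduces pre-trained generation bit-exactly", {
  lib <- test_library(24)
  codec <- build_toy_codec(lib, 17L)
  g <- build_mlp(mlp_spec(c(6, 16, 17), "tanh"), seed = 31)
  gen_pre <- generate_molecules(init_adaptor(6), g, codec, n = 50, seed = 7)
  gen_id <- generate_molecules(init_adaptor(6), g, codec, n = 50, seed = 7)
  expect_identical(gen_pre$canonical_smiles, gen_id$canonical_smiles)
  expect_equal(nrow(gen_pre), 50)
  expect_true(all(gen_pre$is_valid))
  expect_equal(nrow(generate_molecules(init_adaptor(6), g, codec, 0, 1)), 0)
})

test_that("interpolation baseline stays on segments between references", {
  refs <- matrix(c(0, 0, 1, 1, 0, 2), 3, 2, byrow = TRUE)
  out <- baseline_interpolate(refs, 200, seed = 5)
  expect_equal(nrow(out), 200)
  # every output is an affine combination of one reference pair
  on_segment <- apply(out, 1, function(p) {
    ok <- FALSE
    for (i in 1:2) {
      for (j in (i + 1):3) {
        v <- refs[j, ] - refs[i, ]
        t <- sum((p - refs[i, ]) * v) / sum(v * v)
        if (t >= -1e-9 && t <= 1 + 1e-9 &&
            sqrt(sum((refs[i, ] + t * v - p)^2)) < 1e-9) ok <- TRUE
      }
    }
    ok
  })
  expect_true(all(on_segment))
  same <- matrix(1, 4, 2)
  out2 <- baseline_interpolate(same, 10, seed = 1)
  expect_true(all(abs(out2 - 1) < 1e-12))
  expect_error(baseline_interpolate(refs[1, , drop = FALSE], 5), ">= 2")
})

test_that("radius sampling baseline stays in the union of reference balls", {
  refs <- matrix(rnorm(10), 5, 2)
  out <- baseline_random_sample(refs, radius = 0.5, n = 300, seed = 2)
  expect_equal(nrow(out), 300)
  dmin <- apply(out, 1, function(p)
    min(sqrt(rowSums(sweep(refs, 2, p)^2))))
  expect_true(all(dmin <= 0.5 + 1e-9))
  out0 <- baseline_random_sample(refs, radius = 0, n = 50, seed = 3)
  d0 <- apply(out0, 1, function(p)
    min(sqrt(rowSums(sweep(refs, 2, p)^2))))
  expect_true(all(d0 < 1e-12))
  expect_error(baseline_random_sample(refs[0, , drop = FALSE], 1, 5),
               "empty")
})
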