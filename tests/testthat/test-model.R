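test_that("channel doubling reaches the reference bottleneck widths", {
  full <- model_config(levels = 5L, base_channels = 30L)
  expect_identical(full$channels[5], 480L)
  desk <- model_config(levels = 4L, base_channels = 8L)
  expect_identical(desk$channels[4], 64L)
})

test_that("every encoder/decoder convolution carries its own dropout layer", {
  m <- build_model(model_config(), seed = 1L)
  lys <- m$layers
  expect_true(all(vapply(lys[names(lys) != "out"], `[[`, TRUE, "dropout")))
  expect_false(lys$out$dropout)
  p <- dropout_probabilities(m)
  expect_true(all(p > 0 & p < 1))
  rng <- model_config()$dropout_init_range
  expect_true(all(p >= rng[1] & p <= rng[2]))
})

test_that("forward output is a softmax and deterministic without dropout", {
  m <- build_model(model_config(levels = 3L, base_channels = 4L), seed = 2L)
  X <- matrix(runif(2 * 16 * 16), ncol = 1)
  out1 <- unet_forward(m, X, 2L, 16L, 16L)$probs
  out2 <- unet_forward(m, X, 2L, 16L, 16L)$probs
  expect_identical(out1, out2)
  expect_lt(max(abs(rowSums(out1) - 1)), 1e-5)
  expect_true(all(out1 >= 0 & out1 <= 1))
})

test_that("stochastic passes differ across dropout draws but share the softmax invariant", {
  m <- build_model(model_config(levels = 3L, base_channels = 4L), seed = 2L)
  X <- matrix(runif(16 * 16), ncol = 1)
  set.seed(1); n1 <- sample_dropout_noise(m, 1L)
  set.seed(2); n2 <- sample_dropout_noise(m, 1L)
  o1 <- unet_forward(m, X, 1L, 16L, 16L, noise = n1)$probs
  o2 <- unet_forward(m, X, 1L, 16L, 16L, noise = n2)$probs
  expect_false(identical(o1, o2))
  expect_lt(max(abs(rowSums(o1) - 1)), 1e-5)
})

test_that("incompatible image sizes raise an explicit shape error", {
  m <- build_model(model_config(levels = 4L), seed = 1L)
  X <- matrix(runif(20 * 20), ncol = 1)
  expect_error(unet_forward(m, X, 1L, 20L, 20L), "divisible")
})

test_that("analytic gradients match finite differences through all layer types", {
  set.seed(42)
  cfg <- model_config(levels = 2L, base_channels = 4L,
                      dropout_reg_scale = 1e-3, weight_reg_scale = 1e-3)
  m <- build_model(cfg, seed = 3L)
  H <- W <- 8L; B <- 2L
  X <- matrix(runif(B * H * W), ncol = 1)
  y <- sample(0:3, B * H * W, replace = TRUE)
  noise <- sample_dropout_noise(m, B)
  loss_and_grad <- function(model) {
    fwd <- unet_forward(model, X, B, H, W, noise = noise, keep_cache = TRUE)
    lo <- segqa:::ce_loss(fwd$probs, y)
    reg <- segqa:::add_regularizer(model,
                                   segqa:::unet_backward(model, fwd$cache, lo$dZ))
    list(loss = lo$loss + reg$loss, grads = reg$grads)
  }
  base <- loss_and_grad(m)
  eps <- 1e-6
  worst <- 0
  for (ln in names(m$params)) {
    for (pn in names(m$params[[ln]])) {
      p <- m$params[[ln]][[pn]]
      for (i in if (length(p) > 4) sample(length(p), 4) else seq_along(p)) {
        m2 <- m
        m2$params[[ln]][[pn]][i] <- p[i] + eps
        lp <- loss_and_grad(m2)$loss
        m2$params[[ln]][[pn]][i] <- p[i] - eps
        lm <- loss_and_grad(m2)$loss
        num <- (lp - lm) / (2 * eps)
        ana <- base$grads[[ln]][[pn]][i]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training reduces the loss and keeps dropout probabilities in (0,1)", {
  cohort <- generate_cohort(phantom_spec(32L, "ID", seed = 3L), n_scans = 4L,
                            slices_per_scan = 2L)
  m <- build_model(model_config(levels = 3L, base_channels = 4L), seed = 1L)
  fit <- train_model(m, cohort, train_config(epochs = 3L, batch_size = 4L,
                                             val_scans = 1L, seed = 2L))
  expect_true(fit$trained)
  expect_lt(tail(fit$loss_trace$train_loss, 1), fit$loss_trace$train_loss[1])
  expect_true(all(fit$dropout_probs > 0 & fit$dropout_probs < 1))
  expect_gt(mean(fit$dropout_probs), 0)
  expect_lt(mean(fit$dropout_probs), 1)
})

test_that("zero epochs and over-large validation splits are rejected", {
  cohort <- generate_cohort(phantom_spec(32L, "ID", seed = 3L), n_scans = 2L,
                            slices_per_scan = 2L)
  m <- build_model(model_config(levels = 3L, base_channels = 4L), seed = 1L)
  expect_error(train_config(epochs = 0L), "epochs")
  expect_error(train_model(m, cohort,
                           train_config(epochs = 1L, val_scans = 2L)),
               "too few scans")
})
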