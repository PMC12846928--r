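# A tiny trained model shared by the inference tests (3 levels, 32 px).
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(phantom_spec(32L, "ID", seed = 3L),
                                n_scans = 4L, slices_per_scan = 2L)
      m <- build_model(model_config(levels = 3L, base_channels = 4L), seed = 1L)
      cache <<- train_model(m, cohort,
                            train_config(epochs = 2L, batch_size = 4L,
                                         val_scans = 1L, seed = 2L))
    }
    cache
  }
})

test_that("ensembles default to T = 50 and are seed-reproducible", {
  expect_identical(formals(sample_ensemble)$T, 50L)
  m <- tiny_model()
  img <- generate_phantom(phantom_spec(32L, "ID", seed = 9L))$image
  e1 <- sample_ensemble(m, img, T = 4L, seed = 11L)
  e2 <- sample_ensemble(m, img, T = 4L, seed = 11L)
  expect_identical(e1$samples, e2$samples)
  e3 <- sample_ensemble(m, img, T = 4L, seed = 12L)
  expect_false(identical(e1$samples, e3$samples))
})

test_that("a single-sample ensemble has mean equal to that sample", {
  m <- tiny_model()
  img <- generate_phantom(phantom_spec(32L, "ID", seed = 9L))$image
  e <- sample_ensemble(m, img, T = 1L, seed = 5L)
  mp <- mean_and_binarize(e)
  expect_equal(mp$mean_probs[1, , ], e$samples[1, 1, , ], tolerance = 1e-15)
})

test_that("untrained models are refused at inference", {
  m <- build_model(model_config(levels = 3L, base_channels = 4L), seed = 1L)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_error(sample_ensemble(m, img), "not been trained")
})

test_that("volume ensembles agree with the batching contract", {
  m <- tiny_model()
  vol <- generate_cohort(phantom_spec(32L, "ID", seed = 7L), 1L, 3L)[[1]]$image
  ens <- sample_ensemble_volume(m, vol, T = 3L, seed = 2L)
  expect_length(ens, 3L)
  for (e in ens) expect_identical(dim(e$samples), c(3L, 4L, 32L, 32L))
})

test_that("mean probabilities stay normalised and argmax breaks ties low", {
  set.seed(14)
  ens <- random_ensemble(T = 7L, H = 8L, W = 8L)
  mp <- mean_and_binarize(ens)
  sums <- apply(mp$mean_probs, c(2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # hand-built tie cases
  tie <- array(0, c(2, 4, 1, 2))
  tie[1, , 1, 1] <- c(1, 0, 0, 0); tie[2, , 1, 1] <- c(0, 0, 1, 0)
  tie[1, , 1, 2] <- c(0.25, 0.25, 0.25, 0.25)
  tie[2, , 1, 2] <- c(0.25, 0.25, 0.25, 0.25)
  mp2 <- mean_and_binarize(prediction_ensemble(tie))
  expect_identical(mp2$label_mask[1, 1], 0L)   # (0.5, 0, 0.5, 0) -> class 0
  expect_identical(mp2$label_mask[1, 2], 0L)   # all-way tie -> background
  # strict argmax case
  one <- array(0, c(1, 4, 1, 1)); one[1, , 1, 1] <- c(0.4, 0.3, 0.2, 0.1)
  expect_identical(mean_and_binarize(prediction_ensemble(one))$label_mask[1, 1], 0L)
})

test_that("ensemble validation rejects unnormalised or out-of-range samples", {
  bad <- array(0.3, c(2, 4, 2, 2))
  expect_error(prediction_ensemble(bad), "sum to 1")
  neg <- array(c(-0.2, 0.6, 0.3, 0.3), c(1, 4, 1, 1))
  expect_error(prediction_ensemble(neg), "\\[0, 1\\]")
})

test_that("sharp simulated ensembles are recovered exactly by binarization", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 21L))$mask
  ens <- simulate_ensemble(ensemble_sim_spec(truth, T = 2L, sigma_epistemic = 0,
                                             sigma_aleatoric = 0.2, seed = 2L))
  pred <- mean_and_binarize(ens)$label_mask
  interior <- segqa:::boundary_free_interior(truth)
  expect_identical(pred[interior], truth[interior])
})
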