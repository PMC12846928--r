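#' Construct a prediction ensemble
#'
#' Container for `T` stochastic per-pixel class-probability maps, the raw
#' material of all uncertainty estimates. Each sample's per-pixel class
#' probabilities must sum to 1 (within 1e-6).
#'
#' @param samples Array of shape `(T, C, H, W)` of class probabilities.
#' @param class_names Ordered class labels.
#' @param provenance List recording where the samples came from (checkpoint
#'   id and seed, or simulator spec).
#' @return A `prediction_ensemble` object.
#' @export
prediction_ensemble <- function(samples, class_names = seg_classes(),
                                provenance = list()) {
  stopifnot(is.array(samples), length(dim(samples)) == 4L,
            dim(samples)[1] >= 1L, dim(samples)[2] == length(class_names))
  if (min(samples) < -1e-9 || max(samples) > 1 + 1e-9) {
    stop("ensemble probabilities must lie in [0, 1]")
  }
  flat <- aperm(samples, c(2, 1, 3, 4))
  dim(flat) <- c(dim(samples)[2], length(samples) / dim(samples)[2])
  sums <- colSums(flat)
  if (max(abs(sums - 1)) > 1e-6) {
    stop("each sample's per-pixel class probabilities must sum to 1 (tol 1e-6)")
  }
  structure(list(samples = samples, T = dim(samples)[1],
                 class_names = class_names, provenance = provenance),
            class = "prediction_ensemble")
}

#' @export
print.prediction_ensemble <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<prediction_ensemble> T=%d samples, %d classes, %dx%d pixels (%s)\n",
              d[1], d[2], d[3], d[4],
              if (length(x$provenance)) x$provenance$kind else "unknown origin"))
  invisible(x)
}

#' Monte Carlo dropout ensemble for one image
#'
#' Runs `T` stochastic forward passes with concrete dropout active (default
#' `T = 50`, the number of passes at which ensemble accuracy stabilises) and
#' collects the per-pass softmax maps.
#'
#' @param model A trained `seg_unet`.
#' @param image H x W numeric matrix.
#' @param T Number of stochastic passes (>= 1).
#' @param seed Integer seed; the same seed reproduces the ensemble exactly.
#' @return A [prediction_ensemble()].
#' @export
sample_ensemble <- function(model, image, T = 50L, seed = 1L) {
  stopifnot(inherits(model, "seg_unet"), is.matrix(image), is_count(T))
  if (!isTRUE(model$trained)) stop("model has not been trained")
  H <- nrow(image); W <- ncol(image)
  X <- matrix(as.vector(image), ncol = 1L)
  samples <- array(0, c(T, SEG_N_CLASSES, H, W))
  with_rng(seed, {
    for (t in seq_len(T)) {
      noise <- sample_dropout_noise(model, 1L)
      P <- unet_forward(model, X, 1L, H, W, noise = noise)$probs
      for (c in seq_len(SEG_N_CLASSES)) samples[t, c, , ] <- matrix(P[, c], H, W)
    }
  })
  prediction_ensemble(samples, provenance = list(kind = "mc_dropout", T = T,
                                                 seed = seed))
}

#' Monte Carlo dropout ensembles for a multi-slice scan
#'
#' Equivalent to calling [sample_ensemble()] per slice, but batches all
#' slices through the network together on each stochastic pass (one shared
#' dropout draw per pass and slice).
#'
#' @param model A trained `seg_unet`.
#' @param volume `(S, H, W)` image array.
#' @param T Number of stochastic passes.
#' @param seed Integer seed.
#' @return A list of `S` [prediction_ensemble()] objects.
#' @export
sample_ensemble_volume <- function(model, volume, T = 50L, seed = 1L) {
  stopifnot(inherits(model, "seg_unet"), length(dim(volume)) == 3L, is_count(T))
  if (!isTRUE(model$trained)) stop("model has not been trained")
  S <- dim(volume)[1]; H <- dim(volume)[2]; W <- dim(volume)[3]
  X <- matrix(as.vector(aperm(volume, c(2, 3, 1))), ncol = 1L)
  samples <- lapply(seq_len(S), function(s) array(0, c(T, SEG_N_CLASSES, H, W)))
  with_rng(seed, {
    for (t in seq_len(T)) {
      noise <- sample_dropout_noise(model, S)
      P <- unet_forward(model, X, S, H, W, noise = noise)$probs
      for (s in seq_len(S)) {
        rows <- ((s - 1) * H * W + 1):(s * H * W)
        for (c in seq_len(SEG_N_CLASSES)) {
          samples[[s]][t, c, , ] <- matrix(P[rows, c], H, W)
        }
      }
    }
  })
  lapply(samples, prediction_ensemble,
         provenance = list(kind = "mc_dropout", T = T, seed = seed))
}

#' Average an ensemble and binarize by highest class probability
#'
#' The model prediction is the arithmetic mean over the `T` stochastic
#' outputs; the label mask assigns each pixel the class with the highest mean
#' probability, with ties broken toward the lowest class index (so
#' background wins all-way ties).
#'
#' @param ensemble A [prediction_ensemble()].
#' @return A `mean_prediction` list with `mean_probs` (`C x H x W`) and
#'   `label_mask` (H x W integer matrix).
#' @export
mean_and_binarize <- function(ensemble) {
  stopifnot(inherits(ensemble, "prediction_ensemble"))
  d <- dim(ensemble$samples)
  Tn <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  flat <- ensemble$samples
  dim(flat) <- c(Tn, C * H * W)
  mean_probs <- array(colMeans(flat), c(C, H, W))
  pm <- matrix(aperm(mean_probs, c(2, 3, 1)), H * W, C)
  lab <- matrix(max.col(pm, ties.method = "first") - 1L, H, W)
  structure(list(mean_probs = mean_probs, label_mask = lab,
                 class_names = ensemble$class_names),
            class = "mean_prediction")
}
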