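#' Specification for a simulated prediction ensemble
#'
#' Builds stochastic softmax ensembles directly from a ground-truth label
#' mask, without any network: per-class logits are signed distances to the
#' class boundary divided by `sigma_aleatoric` (clipped to +/- 10), and each
#' Monte Carlo sample adds zero-mean Gaussian logit jitter of scale
#' `sigma_epistemic`. The aleatoric scale controls boundary softening (hence
#' predictive entropy at the borders); the epistemic scale controls
#' inter-sample disagreement (hence mutual information). This gives every
#' downstream stage a controllable test bed that behaves like Monte Carlo
#' dropout output.
#'
#' @param ground_truth Integer label mask (H x W, labels 0..3).
#' @param T Number of Monte Carlo samples (>= 1; default 50).
#' @param sigma_epistemic Per-sample logit jitter scale (>= 0).
#' @param sigma_aleatoric Boundary softening length in pixels (>= 0).
#' @param seed Integer seed.
#' @return An `ensemble_sim_spec` object.
#' @export
ensemble_sim_spec <- function(ground_truth, T = 50L, sigma_epistemic = 0.5,
                              sigma_aleatoric = 1.0, seed = 1L) {
  stopifnot(is.matrix(ground_truth), is_count(T),
            sigma_epistemic >= 0, sigma_aleatoric >= 0)
  check_label_mask(ground_truth, what = "ground_truth")
  structure(list(ground_truth = ground_truth, T = as.integer(T),
                 sigma_epistemic = sigma_epistemic,
                 sigma_aleatoric = sigma_aleatoric, seed = as.integer(seed)),
            class = "ensemble_sim_spec")
}

# Signed Euclidean distance into each class region (positive inside),
# computed with distance transforms.
signed_class_distances <- function(mask, n_classes = SEG_N_CLASSES) {
  out <- matrix(0, length(mask), n_classes)
  for (c in seq_len(n_classes) - 1L) {
    m <- mask == c
    if (!any(m)) { out[, c + 1L] <- -Inf; next }
    if (all(m)) { out[, c + 1L] <- Inf; next }
    d_in <- EBImage::distmap(EBImage::Image(m * 1), metric = "euclidean")
    d_out <- EBImage::distmap(EBImage::Image((1 - m) * 1), metric = "euclidean")
    out[, c + 1L] <- as.vector(EBImage::imageData(d_in)) -
      as.vector(EBImage::imageData(d_out))
  }
  out
}

#' Simulate a Monte Carlo prediction ensemble from a label mask
#'
#' @param spec An [ensemble_sim_spec()].
#' @return A [prediction_ensemble()] with `spec$T` samples.
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_sim_spec"))
  mask <- spec$ground_truth
  H <- nrow(mask); W <- ncol(mask); C <- SEG_N_CLASSES
  sd0 <- signed_class_distances(mask)
  base <- if (spec$sigma_aleatoric > 0) sd0 / spec$sigma_aleatoric else sign(sd0) * 10
  base <- pmin(pmax(base, -10), 10)
  samples <- array(0, c(spec$T, C, H, W))
  with_rng(spec$seed, {
    for (t in seq_len(spec$T)) {
      L <- base
      if (spec$sigma_epistemic > 0) {
        L <- L + matrix(rnorm(length(base), sd = spec$sigma_epistemic),
                        nrow(base), ncol(base))
      }
      P <- softmax_rows(L)
      for (c in seq_len(C)) samples[t, c, , ] <- matrix(P[, c], H, W)
    }
  })
  prediction_ensemble(samples, provenance = list(kind = "simulated",
                                                 spec = spec[setdiff(names(spec), "ground_truth")]))
}
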