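# Shared flat statistics for an ensemble: mean probabilities, predictive
# entropy, expected per-sample entropy, mutual information, per-class PE.
ens_stats <- function(ensemble) {
  d <- dim(ensemble$samples)
  Tn <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  flat <- ensemble$samples
  dim(flat) <- c(Tn, C * H * W)
  pbar <- colMeans(flat)                       # length C*H*W, class fastest
  pcpe_flat <- -xlogx(pbar)
  dim(pcpe_flat) <- c(C, H * W)
  pe <- colSums(pcpe_flat)
  ent_terms <- -xlogx(flat)                    # (T, C*H*W)
  dim(ent_terms) <- c(Tn * C, H * W)           # fold T and C together
  # expected entropy: mean over T of the per-sample entropies (sum over C)
  ee <- colSums(ent_terms) / Tn
  mi_raw <- pe - ee
  if (min(mi_raw) < -1e-9) {
    warning(sprintf("mutual information fell below 0 by %.3g before clipping",
                    -min(mi_raw)))
  }
  mi <- pmax(mi_raw, 0)
  # identical samples must give MI exactly 0: summation-order round-off
  # (|MI| < 1e-12, far below any meaningful ensemble disagreement) is snapped
  mi[mi < 1e-12] <- 0
  list(C = C, H = H, W = W, pbar = matrix(pbar, C, H * W), pe = pe, ee = ee,
       mi = mi, pcpe = pcpe_flat)
}

#' Uncertainty maps from a prediction ensemble
#'
#' Computes, per pixel: the predictive entropy (the entropy of the
#' sample-averaged class distribution, capturing total predictive
#' uncertainty), the expected entropy (mean per-sample entropy), their
#' difference the mutual information (epistemic uncertainty), and the
#' per-class predictive entropy terms obtained by omitting the class
#' summation. All entropies are in nats; per pixel it always holds that
#' 0 <= MI <= PE <= log(4), and PE equals the sum of the per-class terms.
#' Negative MI from floating-point cancellation is clipped to 0 (its
#' magnitude is checked to be below 1e-9).
#'
#' @param ensemble A [prediction_ensemble()].
#' @return An `uncertainty_maps` object with fields `pe`, `mi`,
#'   `expected_entropy` (H x W matrices) and `per_class_pe` (`C x H x W`).
#' @export
uncertainty_maps <- function(ensemble) {
  stopifnot(inherits(ensemble, "prediction_ensemble"))
  st <- ens_stats(ensemble)
  structure(list(pe = matrix(st$pe, st$H, st$W),
                 mi = matrix(st$mi, st$H, st$W),
                 expected_entropy = matrix(st$ee, st$H, st$W),
                 per_class_pe = array(st$pcpe, c(st$C, st$H, st$W)),
                 class_names = ensemble$class_names),
            class = "uncertainty_maps")
}

#' @export
print.uncertainty_maps <- function(x, ...) {
  cat(sprintf("<uncertainty_maps> %dx%d px; mean PE %.4f, mean MI %.4f (nats)\n",
              nrow(x$pe), ncol(x$pe), mean(x$pe), mean(x$mi)))
  invisible(x)
}

#' Predictive entropy map
#'
#' The entropy of the mean predictive distribution,
#' `-sum_c pbar_c log pbar_c` with `pbar_c` the sample mean of the class-`c`
#' probability and the convention `0 log 0 = 0`.
#'
#' @param ensemble A [prediction_ensemble()].
#' @return H x W matrix of predictive entropies (nats).
#' @export
predictive_entropy <- function(ensemble) {
  uncertainty_maps(ensemble)$pe
}

#' Mutual information map
#'
#' Predictive entropy minus expected entropy:
#' `MI = PE + (1/T) sum_{c,t} p_{c,t} log p_{c,t}`. Zero when all samples
#' agree; grows with inter-sample disagreement (epistemic uncertainty).
#'
#' @param ensemble A [prediction_ensemble()].
#' @return H x W matrix of mutual information values (nats).
#' @export
mutual_information <- function(ensemble) {
  uncertainty_maps(ensemble)$mi
}

#' Expected per-sample entropy map
#'
#' @param ensemble A [prediction_ensemble()].
#' @return H x W matrix (nats).
#' @export
expected_entropy <- function(ensemble) {
  uncertainty_maps(ensemble)$expected_entropy
}

#' Per-class predictive entropy
#'
#' The single-class term `-pbar_c log pbar_c`, i.e. the predictive entropy
#' with the class summation omitted. Bounded above by `1/e ~ 0.368`,
#' attained at `pbar_c = 1/e`.
#'
#' @param ensemble A [prediction_ensemble()].
#' @return `C x H x W` array (nats).
#' @export
per_class_pe <- function(ensemble) {
  uncertainty_maps(ensemble)$per_class_pe
}
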