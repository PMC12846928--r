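# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the current stream.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed below 2^31, safe in double arithmetic.
derive_seed <- function(master, salt) {
  as.integer(((as.numeric(master) %% 1000003) * 69069 + as.numeric(salt) * 7919 + 1) %%
               2147483629)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p) - log1p(-p)

# x * log(x) with the 0 * log(0) := 0 convention, evaluated by masking rather
# than by adding an epsilon so that exact zeros stay exact.
xlogx <- function(x) {
  out <- x * log(x)
  out[x <= 0] <- 0
  out
}

# Row-wise softmax of an N x C matrix, numerically stabilised.
softmax_rows <- function(z) {
  mx <- z[, 1L]
  for (c in seq_len(ncol(z))[-1L]) mx <- pmax(mx, z[, c])
  e <- exp(z - mx)
  e / rowSums(e)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

# Pixels whose whole (2*margin+1)^2 neighbourhood carries one label, i.e.
# pixels away from any structure boundary (image border excluded).
boundary_free_interior <- function(mask, margin = 2L) {
  H <- nrow(mask); W <- ncol(mask)
  ok <- matrix(FALSE, H, W)
  rr <- (margin + 1L):(H - margin)
  cc <- (margin + 1L):(W - margin)
  ok[rr, cc] <- TRUE
  for (dy in -margin:margin) {
    for (dx in -margin:margin) {
      if (dy == 0 && dx == 0) next
      same <- mask[rr + dy, cc + dx] == mask[rr, cc]
      ok[rr, cc] <- ok[rr, cc] & same
    }
  }
  ok
}

check_label_mask <- function(mask, n_classes = SEG_N_CLASSES, what = "mask") {
  v <- as.vector(mask)
  if (any(v != floor(v)) || any(v < 0) || any(v > n_classes - 1L)) {
    stop(sprintf("%s must contain integer labels in 0..%d", what, n_classes - 1L))
  }
  invisible(TRUE)
}
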