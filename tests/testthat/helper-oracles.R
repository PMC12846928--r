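# Independent scalar-loop oracles used to cross-check the vectorized
# implementations. Deliberately written as naive per-element loops from the
# defining formulas.

plogp <- function(p) if (p > 0) p * log(p) else 0

# Uncertainty measures for one ensemble, pixel by pixel and term by term.
oracle_uncertainty <- function(samples) {
  d <- dim(samples)  # (T, C, H, W)
  pe <- mi <- ee <- matrix(0, d[3], d[4])
  pcpe <- array(0, d[2:4])
  for (i in seq_len(d[3])) {
    for (j in seq_len(d[4])) {
      s_entropy <- 0
      for (t in seq_len(d[1])) {
        ht <- 0
        for (c in seq_len(d[2])) ht <- ht - plogp(samples[t, c, i, j])
        s_entropy <- s_entropy + ht
      }
      ee[i, j] <- s_entropy / d[1]
      h <- 0
      for (c in seq_len(d[2])) {
        pbar <- 0
        for (t in seq_len(d[1])) pbar <- pbar + samples[t, c, i, j]
        pbar <- pbar / d[1]
        pcpe[c, i, j] <- -plogp(pbar)
        h <- h - plogp(pbar)
      }
      pe[i, j] <- h
      mi[i, j] <- max(h - ee[i, j], 0)
    }
  }
  list(pe = pe, mi = mi, ee = ee, pcpe = pcpe)
}

# Random valid ensemble (Dirichlet-like rows via normalised exponentials).
random_ensemble <- function(T = 10L, H = 16L, W = 16L, C = 4L) {
  samples <- array(0, c(T, C, H, W))
  for (t in seq_len(T)) {
    m <- matrix(exp(rnorm(H * W * C)), H * W, C)
    m <- m / rowSums(m)
    for (c in seq_len(C)) samples[t, c, , ] <- matrix(m[, c], H, W)
  }
  prediction_ensemble(samples)
}

# Brute-force surface distances: all boundary-pixel pairs, double loop.
oracle_surface_distances <- function(pred, truth, spacing = c(1, 1)) {
  bnd <- function(m) {
    out <- NULL
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        if (!m[i, j]) next
        nb <- c(if (i > 1) m[i - 1, j] else FALSE,
                if (i < nrow(m)) m[i + 1, j] else FALSE,
                if (j > 1) m[i, j - 1] else FALSE,
                if (j < ncol(m)) m[i, j + 1] else FALSE)
        if (!all(nb)) out <- rbind(out, c(i, j))
      }
    }
    out
  }
  A <- bnd(pred > 0); B <- bnd(truth > 0)
  dmin <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(a) {
      best <- Inf
      for (b in seq_len(nrow(Q))) {
        dd <- sqrt(sum(((P[a, ] - Q[b, ]) * spacing)^2))
        if (dd < best) best <- dd
      }
      best
    }, 0)
  }
  pool <- c(dmin(A, B), dmin(B, A))
  list(hd95 = unname(quantile(pool, 0.95, type = 7)), msd = mean(pool))
}

# Random connected-ish blob mask containing at least one pixel.
random_mask <- function(H = 16L, W = 16L, p = 0.3) {
  repeat {
    m <- matrix(runif(H * W) < p, H, W)
    if (any(m)) return(m)
  }
}
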