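#' Configuration for the dropout U-Net
#'
#' Describes a 2D U-Net for four-class segmentation in which every
#' convolution of the encoder and decoder is followed by a spatial concrete
#' dropout layer with its own learnable dropout probability. Channel counts
#' double at every encoder level, so the bottleneck carries
#' `base_channels * 2^(levels - 1)` channels (e.g. 30 first-layer channels and
#' five levels give a 480-channel bottleneck; the desk-scale default of 8
#' channels and four levels gives 64).
#'
#' @param levels Encoder/decoder depth (>= 2). Inputs must be divisible by
#'   `2^(levels - 1)`.
#' @param base_channels Channels in the first encoder stage (>= 4).
#' @param convs_per_stage Convolutions per stage (default 2).
#' @param leaky_slope Negative slope of the leaky ReLU activations.
#' @param class_count Number of output classes; fixed at 4.
#' @param dropout_init_range Interval from which initial dropout
#'   probabilities are drawn, strictly inside (0, 1).
#' @param concrete_temperature Temperature of the concrete (relaxed
#'   Bernoulli) dropout masks.
#' @param dropout_reg_scale Scale of the dropout-probability entropy
#'   regularizer.
#' @param weight_reg_scale Scale of the dropout-coupled weight decay term.
#' @return A `model_config` list.
#' @export
model_config <- function(levels = 4L, base_channels = 8L, convs_per_stage = 2L,
                         leaky_slope = 1e-2, class_count = 4L,
                         dropout_init_range = c(0.02, 0.06),
                         concrete_temperature = 0.1,
                         dropout_reg_scale = 1e-5,
                         weight_reg_scale = 1e-6) {
  stopifnot(is_count(levels), levels >= 2,
            is_count(base_channels), base_channels >= 4,
            is_count(convs_per_stage), convs_per_stage >= 1,
            leaky_slope >= 0, class_count == 4L,
            length(dropout_init_range) == 2L,
            all(dropout_init_range > 0), all(dropout_init_range < 1),
            dropout_init_range[1] <= dropout_init_range[2],
            concrete_temperature > 0,
            dropout_reg_scale >= 0, weight_reg_scale >= 0)
  cfg <- list(levels = as.integer(levels),
              base_channels = as.integer(base_channels),
              convs_per_stage = as.integer(convs_per_stage),
              leaky_slope = leaky_slope, class_count = 4L,
              dropout_init_range = dropout_init_range,
              concrete_temperature = concrete_temperature,
              dropout_reg_scale = dropout_reg_scale,
              weight_reg_scale = weight_reg_scale)
  cfg$channels <- as.integer(base_channels * 2^(seq_len(levels) - 1L))
  class(cfg) <- "model_config"
  cfg
}

# Ordered description of every convolution in the network: name, input and
# output channels, and whether a concrete-dropout layer follows it.
unet_layers <- function(config) {
  L <- config$levels; K <- config$convs_per_stage; ch <- config$channels
  layers <- list()
  add <- function(name, cin, cout, dropout = TRUE) {
    layers[[length(layers) + 1L]] <<- list(name = name, cin = cin, cout = cout,
                                           dropout = dropout)
  }
  for (l in seq_len(L)) { # encoder stages; stage L is the bottleneck
    cin <- if (l == 1L) 1L else ch[l - 1L]
    for (k in seq_len(K)) {
      add(sprintf("enc%d_conv%d", l, k), if (k == 1L) cin else ch[l], ch[l])
    }
  }
  for (l in seq(L - 1L, 1L)) { # decoder stages
    add(sprintf("dec%d_up", l), ch[l + 1L], ch[l])
    for (k in seq_len(K)) {
      add(sprintf("dec%d_conv%d", l, k), if (k == 1L) 2L * ch[l] else ch[l], ch[l])
    }
  }
  add("out", ch[1L], config$class_count, dropout = FALSE)
  names(layers) <- vapply(layers, `[[`, "", "name")
  layers
}

#' Build a stochastic segmentation U-Net
#'
#' Initialises the network weights (He initialisation) and one learnable
#' concrete-dropout probability per convolution, drawn uniformly from
#' `config$dropout_init_range`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialisation.
#' @return A `seg_unet` object (untrained).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  layers <- unet_layers(config)
  params <- with_rng(seed, {
    lapply(layers, function(ly) {
      if (ly$name == "out") {
        list(W = matrix(rnorm(ly$cin * ly$cout, sd = sqrt(2 / ly$cin)),
                        ly$cin, ly$cout),
             b = numeric(ly$cout))
      } else {
        p0 <- runif(1, config$dropout_init_range[1], config$dropout_init_range[2])
        list(W = matrix(rnorm(9 * ly$cin * ly$cout, sd = sqrt(2 / (9 * ly$cin))),
                        9 * ly$cin, ly$cout),
             b = numeric(ly$cout),
             dlogit = logit(p0))
      }
    })
  })
  structure(list(config = config, params = params, layers = layers,
                 channels = config$channels, trained = FALSE,
                 loss_trace = NULL, dropout_probs = NULL),
            class = "seg_unet")
}

#' @export
print.seg_unet <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, function(p) sum(lengths(lapply(p, as.numeric))), 0))
  cat(sprintf("<seg_unet> %d levels, channels %s, %d parameters, %s\n",
              cfg$levels, paste(x$channels, collapse = "-"), round(np),
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$dropout_probs)) {
    cat(sprintf("  mean learned dropout probability: %.3f\n",
                mean(x$dropout_probs)))
  }
  invisible(x)
}

#' Learned dropout probabilities
#'
#' @param model A `seg_unet`.
#' @return Named numeric vector of per-layer dropout probabilities.
#' @export
dropout_probabilities <- function(model) {
  stopifnot(inherits(model, "seg_unet"))
  ps <- vapply(model$params, function(p)
    if (is.null(p$dlogit)) NA_real_ else sigmoid(p$dlogit), 0)
  ps[!is.na(ps)]
}

#' Sample concrete-dropout noise for one stochastic pass
#'
#' @param model A `seg_unet`.
#' @param batch Number of images in the batch (one mask per image & channel).
#' @return Named list of uniform(0,1) matrices, one per dropout layer.
#' @export
sample_dropout_noise <- function(model, batch) {
  lys <- Filter(function(ly) ly$dropout, model$layers)
  setNames(lapply(lys, function(ly)
    matrix(runif(batch * ly$cout), batch, ly$cout)), names(lys))
}

# One conv -> concrete dropout -> leaky ReLU block.
conv_block_fwd <- function(params, ly, X, B, H, W, noise, tmp, slope, keep_cache) {
  Y1 <- conv3_fwd(X, params$W, params$b, B, H, W)
  if (!is.null(noise)) {
    p <- sigmoid(params$dlogit)
    u <- noise[[ly$name]]
    z <- sigmoid((logit(p) + logit(u)) / tmp)
    keep <- (1 - z) / (1 - p)
    keeprows <- keep[rep(seq_len(B), each = H * W), , drop = FALSE]
    Y2 <- Y1 * keeprows
  } else {
    z <- NULL; keeprows <- NULL; Y2 <- Y1
  }
  actmul <- slope + (1 - slope) * (Y2 > 0)
  Y3 <- Y2 * actmul
  cache <- if (keep_cache) list(X = X, Y1 = Y1, z = z, keeprows = keeprows,
                                actmul = actmul, B = B, H = H, W = W) else NULL
  list(Y = Y3, cache = cache)
}

conv_block_bwd <- function(params, ly, dY3, cache, tmp, slope) {
  dY2 <- dY3 * cache$actmul
  dtheta <- 0
  if (!is.null(cache$keeprows)) {
    dY1 <- dY2 * cache$keeprows
    p <- sigmoid(params$dlogit)
    s <- rowsum(dY2 * cache$Y1,
                group = rep(seq_len(cache$B), each = cache$H * cache$W))
    z <- cache$z
    dz_dp <- z * (1 - z) / (tmp * p * (1 - p))
    dkeep_dp <- (-dz_dp * (1 - p) + (1 - z)) / (1 - p)^2
    dtheta <- sum(s * dkeep_dp) * p * (1 - p)
  } else {
    dY1 <- dY2
  }
  g <- conv3_bwd(cache$X, dY1, params$W, cache$B, cache$H, cache$W)
  list(dX = g$dX, dW = g$dW, db = as.numeric(g$db), dtheta = dtheta)
}

#' Stochastic U-Net forward pass
#'
#' @param model A `seg_unet`.
#' @param X Input features: `(B*H*W) x 1` matrix (pixels image-major,
#'   column-major within each image, i.e. `as.vector()` of an H x W matrix).
#' @param B,H,W Batch size and image dimensions.
#' @param noise Dropout noise from [sample_dropout_noise()], or `NULL` for a
#'   deterministic pass with dropout disabled.
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @return List with `probs` (`(B*H*W) x 4` softmax output) and (optionally)
#'   `cache`.
#' @export
unet_forward <- function(model, X, B, H, W, noise = NULL, keep_cache = FALSE) {
  cfg <- model$config
  L <- cfg$levels; K <- cfg$convs_per_stage
  div <- 2^(L - 1L)
  if (H %% div != 0 || W %% div != 0) {
    stop(sprintf("image size %dx%d is not divisible by 2^(levels-1) = %d", H, W, div))
  }
  stopifnot(nrow(X) == B * H * W, ncol(X) == 1L)
  tmp <- cfg$concrete_temperature; slope <- cfg$leaky_slope
  pars <- model$params; lys <- model$layers
  caches <- list(); skips <- list(); dims <- list()
  cur <- X; h <- H; w <- W
  for (l in seq_len(L)) {
    for (k in seq_len(K)) {
      nm <- sprintf("enc%d_conv%d", l, k)
      r <- conv_block_fwd(pars[[nm]], lys[[nm]], cur, B, h, w, noise, tmp, slope,
                          keep_cache)
      cur <- r$Y; caches[[nm]] <- r$cache
    }
    if (l < L) {
      skips[[l]] <- cur; dims[[l]] <- c(h, w)
      mp <- maxpool2_fwd(cur, B, h, w)
      caches[[sprintf("pool%d", l)]] <- list(amax = mp$amax, Nin = nrow(cur),
                                             h = h, w = w)
      cur <- mp$Y; h <- h %/% 2L; w <- w %/% 2L
    }
  }
  for (l in seq(L - 1L, 1L)) {
    cur <- upsample2_fwd(cur, B, h, w)
    h <- 2L * h; w <- 2L * w
    nm <- sprintf("dec%d_up", l)
    r <- conv_block_fwd(pars[[nm]], lys[[nm]], cur, B, h, w, noise, tmp, slope,
                        keep_cache)
    cur <- r$Y; caches[[nm]] <- r$cache
    nup <- ncol(cur)
    cur <- cbind(cur, skips[[l]])
    caches[[sprintf("cat%d", l)]] <- nup
    for (k in seq_len(K)) {
      nm <- sprintf("dec%d_conv%d", l, k)
      r <- conv_block_fwd(pars[[nm]], lys[[nm]], cur, B, h, w, noise, tmp, slope,
                          keep_cache)
      cur <- r$Y; caches[[nm]] <- r$cache
    }
  }
  logits <- sweep(cur %*% pars$out$W, 2L, pars$out$b, "+")
  probs <- softmax_rows(logits)
  if (keep_cache) caches$out <- list(X = cur)
  list(probs = probs,
       cache = if (keep_cache) list(caches = caches, B = B, H = H, W = W) else NULL)
}

# Backward pass; dZ is the gradient w.r.t. the pre-softmax logits.
unet_backward <- function(model, cache, dZ) {
  cfg <- model$config
  L <- cfg$levels; K <- cfg$convs_per_stage
  tmp <- cfg$concrete_temperature; slope <- cfg$leaky_slope
  pars <- model$params; lys <- model$layers; cs <- cache$caches
  B <- cache$B
  grads <- list()
  grads$out <- list(W = t(cs$out$X) %*% dZ, b = colSums(dZ))
  d <- dZ %*% t(pars$out$W)
  dskips <- list()
  for (l in seq_len(L - 1L)) {
    for (k in seq(K, 1L)) {
      nm <- sprintf("dec%d_conv%d", l, k)
      g <- conv_block_bwd(pars[[nm]], lys[[nm]], d, cs[[nm]], tmp, slope)
      grads[[nm]] <- list(W = g$dW, b = g$db, dlogit = g$dtheta)
      d <- g$dX
    }
    nup <- cs[[sprintf("cat%d", l)]]
    dskips[[l]] <- d[, (nup + 1L):ncol(d), drop = FALSE]
    d <- d[, seq_len(nup), drop = FALSE]
    nm <- sprintf("dec%d_up", l)
    g <- conv_block_bwd(pars[[nm]], lys[[nm]], d, cs[[nm]], tmp, slope)
    grads[[nm]] <- list(W = g$dW, b = g$db, dlogit = g$dtheta)
    pc <- cs[[nm]]
    d <- upsample2_bwd(g$dX, B, pc$H %/% 2L, pc$W %/% 2L)
  }
  for (l in seq(L, 1L)) {
    if (l < L) {
      pl <- cs[[sprintf("pool%d", l)]]
      d <- maxpool2_bwd(d, pl$amax, pl$Nin)
      d <- d + dskips[[l]]
    }
    for (k in seq(K, 1L)) {
      nm <- sprintf("enc%d_conv%d", l, k)
      g <- conv_block_bwd(pars[[nm]], lys[[nm]], d, cs[[nm]], tmp, slope)
      grads[[nm]] <- list(W = g$dW, b = g$db, dlogit = g$dtheta)
      d <- g$dX
    }
  }
  grads
}

# Cross-entropy loss over pixels plus its gradient w.r.t. the logits.
ce_loss <- function(probs, labels) {
  n <- nrow(probs)
  idx <- cbind(seq_len(n), as.integer(labels) + 1L)
  p <- pmax(probs[idx], 1e-12)
  loss <- -mean(log(p))
  dZ <- probs
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dZ = dZ / n)
}

# Concrete-dropout regularizer (weight decay coupled to the keep probability
# plus the dropout-probability entropy term) and its gradients, added in
# place to `grads`.
add_regularizer <- function(model, grads) {
  cfg <- model$config
  wr <- cfg$weight_reg_scale; dr <- cfg$dropout_reg_scale
  loss <- 0
  for (nm in names(model$layers)) {
    pr <- model$params[[nm]]
    if (is.null(pr$dlogit)) next
    p <- sigmoid(pr$dlogit)
    K <- ncol(pr$W)
    sw <- sum(pr$W^2)
    loss <- loss + wr * sw / (1 - p) + dr * K * (p * log(p) + (1 - p) * log(1 - p))
    grads[[nm]]$W <- grads[[nm]]$W + 2 * wr * pr$W / (1 - p)
    grads[[nm]]$dlogit <- grads[[nm]]$dlogit +
      (wr * sw / (1 - p)^2 + dr * K * (log(p) - log(1 - p))) * p * (1 - p)
  }
  list(loss = loss, grads = grads)
}

#' Deterministic single-pass prediction
#'
#' Runs the network with dropout disabled (each concrete-dropout layer passes
#' activations through unscaled, its expected behaviour).
#'
#' @param model A trained `seg_unet`.
#' @param image An H x W numeric matrix, or a `(S, H, W)` volume.
#' @return For a matrix, an `(H*W) x 4` probability matrix; for a volume, a
#'   list of such matrices.
#' @export
predict_probs <- function(model, image) {
  if (is.matrix(image)) {
    h <- nrow(image); w <- ncol(image)
    unet_forward(model, matrix(as.vector(image), ncol = 1L), 1L, h, w)$probs
  } else {
    stopifnot(length(dim(image)) == 3L)
    s <- dim(image)[1]; h <- dim(image)[2]; w <- dim(image)[3]
    X <- matrix(as.vector(aperm(image, c(2, 3, 1))), ncol = 1L)
    P <- unet_forward(model, X, s, h, w)$probs
    lapply(seq_len(s), function(b) P[((b - 1) * h * w + 1):(b * h * w), , drop = FALSE])
  }
}
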