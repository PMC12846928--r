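#' Training configuration
#'
#' The full-scale reference recipe is 20 epochs, batch size 8,
#' Adam at learning rate 1e-4, left-right flip augmentation with probability
#' 0.5 and a cross-entropy loss. The desk-scale default used here keeps
#' everything except the learning rate, which is raised to 1e-3 because the
#' desk-scale study performs only a few hundred optimisation steps (see the
#' methods vignette).
#'
#' @param epochs Number of passes over the training slices (>= 1).
#' @param batch_size Slices per optimisation step.
#' @param lr Peak Adam learning rate. The schedule warms up linearly over
#'   the first tenth of the steps and then decays with a cosine to a tenth
#'   of the peak.
#' @param flip_prob Probability of left-right flipping each slice.
#' @param loss Loss function; only `"cross-entropy"` is supported.
#' @param ema_decay Per-step decay of the exponential moving average of the
#'   weights, applied over the final quarter of the optimisation; the
#'   averaged weights are returned as the trained model (tail Polyak
#'   averaging). `0` disables averaging.
#' @param val_scans Number of scans held out for validation (split is by
#'   scan: slices of one scan are never divided across partitions).
#' @param seed Integer seed for shuffling, augmentation and dropout noise.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 20L, batch_size = 8L, lr = 1e-2,
                         flip_prob = 0.5, loss = "cross-entropy",
                         val_scans = 2L, ema_decay = 0.98, seed = 1L) {
  if (!is_count(epochs)) stop("epochs must be an integer >= 1")
  stopifnot(is_count(batch_size), lr > 0, flip_prob >= 0, flip_prob <= 1,
            identical(loss, "cross-entropy"), is_count(val_scans) || val_scans == 0,
            ema_decay >= 0, ema_decay < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, flip_prob = flip_prob, loss = loss,
                 val_scans = as.integer(val_scans), ema_decay = ema_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Exponential moving average of two parameter lists.
ema_update <- function(avg, params, decay) {
  for (ln in names(params)) {
    for (pn in names(params[[ln]])) {
      avg[[ln]][[pn]] <- decay * avg[[ln]][[pn]] + (1 - decay) * params[[ln]][[pn]]
    }
  }
  avg
}

# Adam update, walking the nested parameter list in place.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (ln in names(params)) {
    gl <- grads[[ln]]
    for (pn in names(params[[ln]])) {
      gname <- if (pn == "dlogit") "dlogit" else pn
      g <- gl[[if (pn == "W") "W" else if (pn == "b") "b" else "dlogit"]]
      if (is.null(g)) next
      key <- paste(ln, pn, sep = ".")
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / corr1
      vhat <- state$v[[key]] / corr2
      params[[ln]][[pn]] <- params[[ln]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  params
}

# Stack a list of slices (image matrix + label matrix) into batch form.
stack_batch <- function(slices) {
  X <- matrix(unlist(lapply(slices, function(s) as.vector(s$image)),
                     use.names = FALSE), ncol = 1L)
  y <- unlist(lapply(slices, function(s) as.vector(s$mask)), use.names = FALSE)
  list(X = X, y = as.integer(y))
}

cohort_slices <- function(scans) {
  out <- list()
  for (sc in scans) {
    S <- dim(sc$image)[1]
    for (s in seq_len(S)) {
      out[[length(out) + 1L]] <- list(image = sc$image[s, , ],
                                      mask = sc$mask[s, , ])
    }
  }
  out
}

#' Train the dropout U-Net on a phantom cohort
#'
#' Splits the cohort by scan (the last `val_scans` scans form the validation
#' set; no slice of a validation scan is ever used for training), then runs
#' mini-batch Adam on the cross-entropy loss with concrete-dropout noise
#' active and left-right flip augmentation.
#'
#' @param model A `seg_unet` from [build_model()].
#' @param cohort A list of scans as produced by [generate_cohort()].
#' @param config A [train_config()].
#' @return The trained model, with `$loss_trace` (per-epoch mean training
#'   loss and validation loss), `$dropout_probs` (learned per-layer dropout
#'   probabilities) and `$trained = TRUE`.
#' @export
train_model <- function(model, cohort, config = train_config()) {
  stopifnot(inherits(model, "seg_unet"), inherits(config, "train_config"))
  if (config$epochs < 1) stop("epochs must be >= 1")
  n <- length(cohort)
  if (n <= config$val_scans) stop("cohort has too few scans for the validation split")
  train_scans <- cohort[seq_len(n - config$val_scans)]
  val_scans <- if (config$val_scans > 0) cohort[(n - config$val_scans + 1):n] else list()
  tr <- cohort_slices(train_scans)
  va <- cohort_slices(val_scans)
  H <- nrow(tr[[1]]$image); W <- ncol(tr[[1]]$image)
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  params <- model$params
  avg <- NULL
  # initialise the output bias at the log class priors of the training set,
  # so rare structures start from calibrated rather than uniform odds
  freq <- tabulate(unlist(lapply(tr, function(s) as.vector(s$mask))) + 1L,
                   nbins = SEG_N_CLASSES)
  params$out$b <- log(pmax(freq, 1) / sum(freq))
  steps_per_epoch <- ceiling(length(tr) / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  warmup <- max(1L, round(0.1 * total_steps))
  lr_at <- function(step) {
    if (step <= warmup) return(config$lr * step / warmup)
    frac <- (step - warmup) / max(1L, total_steps - warmup)
    config$lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * frac)))
  }
  with_rng(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(tr))
      losses <- c()
      for (start in seq(1L, length(tr), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(tr))]
        sl <- tr[idx]
        flip <- runif(length(sl)) < config$flip_prob
        for (i in which(flip)) {
          sl[[i]]$image <- sl[[i]]$image[, W:1]
          sl[[i]]$mask <- sl[[i]]$mask[, W:1]
        }
        bt <- stack_batch(sl)
        model$params <- params
        noise <- sample_dropout_noise(model, length(sl))
        fwd <- unet_forward(model, bt$X, length(sl), H, W, noise = noise,
                            keep_cache = TRUE)
        lo <- ce_loss(fwd$probs, bt$y)
        if (!is.finite(lo$loss)) {
          stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate", ep))
        }
        grads <- unet_backward(model, fwd$cache, lo$dZ)
        reg <- add_regularizer(model, grads)
        losses <- c(losses, lo$loss + reg$loss)
        params <- adam_step(params, reg$grads, state, lr_at(state$t + 1L))
        if (config$ema_decay > 0 && state$t >= 0.75 * total_steps) {
          avg <- if (is.null(avg)) params else
            ema_update(avg, params, config$ema_decay)
        }
      }
      model$params <- if (!is.null(avg)) avg else params
      vloss <- NA_real_
      if (length(va) > 0) {
        bt <- stack_batch(va)
        fwd <- unet_forward(model, bt$X, length(va), H, W)
        vloss <- ce_loss(fwd$probs, bt$y)$loss
      }
      trace <- rbind(trace, data.frame(epoch = ep, train_loss = mean(losses),
                                       val_loss = vloss))
    }
  })
  model$params <- if (!is.null(avg)) avg else params
  model$trained <- TRUE
  model$loss_trace <- trace
  model$dropout_probs <- dropout_probabilities(model)
  model
}
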