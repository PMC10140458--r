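#' Attention-MIL model configuration
#'
#' The attention-based multiple-instance learning head: each tile feature
#' vector is embedded into 256 dimensions (linear + ReLU, then a second
#' linear layer), per-tile attention weights are computed as
#' `a_k = softmax_k(w' tanh(V h_k))` with `V` 128 x 256 and `w` length 128,
#' the bag summary is the attention-weighted sum `h_sum = sum_k a_k h_k`,
#' and the summary is classified through batch normalization, dropout
#' (p = 0.5) and a linear layer with two outputs followed by softmax.
#'
#' @param input_dim Tile feature dimension D (plus 4 when clinical
#'   covariates are attached).
#' @param embed_dim Embedding width (256).
#' @param attn_hidden Attention hidden width (128).
#' @param n_classes Number of classes (2).
#' @param dropout_p Dropout probability in the classifier.
#' @param k_tiles Maximum tiles resampled per bag per training epoch (512).
#' @export
attmil_config <- function(input_dim, embed_dim = 256L, attn_hidden = 128L,
                          n_classes = 2L, dropout_p = 0.5, k_tiles = 512L) {
  stopifnot(input_dim >= 1L, embed_dim >= 1L, attn_hidden >= 1L,
            n_classes == 2L, dropout_p >= 0, dropout_p < 1, k_tiles >= 1L)
  structure(list(input_dim = as.integer(input_dim),
                 embed_dim = as.integer(embed_dim),
                 attn_hidden = as.integer(attn_hidden),
                 n_classes = 2L, dropout_p = dropout_p,
                 k_tiles = as.integer(k_tiles)),
            class = "attmil_config")
}

#' Initialize attention-MIL parameters
#'
#' Linear layers use the fan-in uniform initialization
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)); batch-norm starts at identity
#' (gamma = 1, beta = 0, running mean 0 / variance 1).
#'
#' @param cfg An [attmil_config()].
#' @param seed Integer seed.
#' @export
init_attmil_params <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "attmil_config"))
  with_seed(seed, {
    lin <- function(fan_in, nr, nc = NULL) {
      b <- 1 / sqrt(fan_in)
      if (is.null(nc)) stats::runif(nr, -b, b)
      else matrix(stats::runif(nr * nc, -b, b), nr, nc)
    }
    d <- cfg$input_dim; e <- cfg$embed_dim; a <- cfg$attn_hidden
    structure(list(
      W1 = lin(d, d, e), b1 = lin(d, e),
      W2 = lin(e, e, e), b2 = lin(e, e),
      V = lin(e, a, e), w = lin(e, a),
      bn_gamma = rep(1, e), bn_beta = rep(0, e),
      bn_mean = rep(0, e), bn_var = rep(1, e),
      Wc = lin(e, e, cfg$n_classes), bc = lin(e, cfg$n_classes),
      config = cfg),
      class = "attmil_params")
  })
}

#' Embed tile features into the 256-dimensional MIL space
#'
#' `h_k = Linear2(ReLU(Linear1(x_k)))`, applied row-wise.
#'
#' @param features K x D matrix.
#' @param params An `attmil_params`.
#' @return K x embed_dim matrix of tile embeddings.
#' @export
embed_tiles <- function(features, params) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(params$W1)) {
    stop("feature dimension ", ncol(features), " does not match model (",
         nrow(params$W1), ")", call. = FALSE)
  }
  H1 <- pmax(sweep(features %*% params$W1, 2L, params$b1, "+"), 0)
  sweep(H1 %*% params$W2, 2L, params$b2, "+")
}

#' Per-tile attention weights
#'
#' `a_k = exp(w' tanh(V h_k)) / sum_j exp(w' tanh(V h_j))`, computed with
#' max-subtraction for numerical stability. Weights are positive and sum
#' to one.
#'
#' @param h K x embed_dim matrix of tile embeddings.
#' @param V attn_hidden x embed_dim matrix.
#' @param w Length attn_hidden vector.
#' @return Length-K attention vector.
#' @export
attention_weights <- function(h, V, w) {
  h <- as.matrix(h)
  stopifnot(nrow(h) >= 1L)
  logits <- as.vector(tanh(h %*% t(V)) %*% w)
  softmax_vec(logits)
}

#' Attention-weighted MIL pooling
#'
#' `h_sum = sum_k a_k h_k`. With uniform attention this is the arithmetic
#' mean of the embeddings, which is exactly the mean-pooling baseline.
#'
#' @param h K x embed_dim matrix.
#' @param a Length-K normalized attention vector.
#' @return Length embed_dim summary vector.
#' @export
attention_pool <- function(h, a) {
  h <- as.matrix(h)
  stopifnot(length(a) == nrow(h))
  as.vector(crossprod(h, a))
}

#' Classify bag summaries
#'
#' Batch normalization, dropout and a two-output linear layer followed by
#' softmax. At inference (`training = FALSE`, the default) dropout is
#' disabled and normalization uses the stored running statistics, so the
#' output is deterministic.
#'
#' @param h_sum A length-embed_dim vector or a batch matrix (rows =
#'   patients).
#' @param params An `attmil_params`.
#' @param training Use batch statistics and dropout (training mode).
#' @return Matrix of per-class probabilities, one row per input row.
#' @export
classify_summary <- function(h_sum, params, training = FALSE) {
  Z <- if (is.matrix(h_sum)) h_sum else matrix(h_sum, nrow = 1L)
  eps <- 1e-5
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(sweep(Z, 2L, mu)^2)
  } else {
    mu <- params$bn_mean; v <- params$bn_var
  }
  Xh <- sweep(sweep(Z, 2L, mu), 2L, sqrt(v + eps), "/")
  Y <- sweep(sweep(Xh, 2L, params$bn_gamma, "*"), 2L, params$bn_beta, "+")
  if (training && params$config$dropout_p > 0) {
    p <- params$config$dropout_p
    M <- matrix(stats::rbinom(length(Y), 1L, 1 - p), nrow(Y), ncol(Y)) / (1 - p)
    Y <- Y * M
  }
  logits <- sweep(Y %*% params$Wc, 2L, params$bc, "+")
  softmax_rows(logits)
}

#' Forward pass of the attention-MIL model on one bag
#'
#' Embedding, attention, pooling and classification composed; the per-tile
#' attention is returned for explainability. The score is invariant to any
#' permutation of the bag rows.
#'
#' @param bag A [feature_bag()].
#' @param params An `attmil_params`.
#' @param tile_scores Also compute per-tile scores via
#'   [tile_level_scores()].
#' @return A `bag_prediction`: `patient_id`, `score` (positive-class
#'   probability), `attention`, `tile_coords`, optional `tile_scores`.
#' @export
forward_bag <- function(bag, params, tile_scores = FALSE) {
  stopifnot(inherits(bag, "feature_bag"))
  H <- embed_tiles(bag$features, params)
  a <- attention_weights(H, params$V, params$w)
  hs <- attention_pool(H, a)
  probs <- classify_summary(hs, params)
  out <- structure(list(patient_id = bag$patient_id, score = probs[1L, 2L],
                        attention = a, tile_coords = bag$tile_coords,
                        label = bag$label),
                   class = "bag_prediction")
  if (tile_scores) out$tile_scores <- tile_scores_from_h(H, params)
  out
}

tile_scores_from_h <- function(H, params) {
  classify_summary(H, params)[, 2L]
}

#' Per-tile classification scores
#'
#' Each tile's embedding h_k is routed through the classification block as
#' a singleton summary (inference-mode batch normalization), giving the
#' "MSI-ness"-style per-tile probability used in prediction heatmaps. For a
#' singleton bag this equals the bag score.
#'
#' @param bag A [feature_bag()].
#' @param params An `attmil_params`.
#' @return Length-K vector of positive-class probabilities.
#' @export
tile_level_scores <- function(bag, params) {
  tile_scores_from_h(embed_tiles(bag$features, params), params)
}

#' Training configuration for the attention-MIL model
#'
#' Defaults follow the reference protocol: 32 patients per batch, 32
#' epochs, maximal learning rate 1e-4 reached after 8 epochs (one-cycle:
#' rise from lr_max/25, fall to lr_max/10000), AdamW (beta2 = 0.99,
#' epsilon = 1e-5, decoupled weight decay 0.01) with beta1 cycled
#' 0.95 -> 0.85 -> 0.95 on the same periodicity, and cross-entropy weighted
#' by inverse class frequency.
#'
#' @param batch_size Patients per minibatch.
#' @param epochs Total epochs.
#' @param lr_max Maximal learning rate.
#' @param warmup_epochs Epochs of the rising phase.
#' @param beta1_range Endpoints of the cycled first moment.
#' @param beta2,eps Adam second-moment decay and epsilon.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param seed Master seed (fans out to sampling, init, dropout).
#' @export
attmil_train_config <- function(batch_size = 32L, epochs = 32L,
                                lr_max = 1e-4, warmup_epochs = 8L,
                                beta1_range = c(0.95, 0.85), beta2 = 0.99,
                                eps = 1e-5, weight_decay = 0.01, seed = 1L) {
  stopifnot(epochs >= warmup_epochs, batch_size >= 1L, lr_max > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_max = lr_max,
                 warmup_epochs = as.integer(warmup_epochs),
                 beta1_range = beta1_range, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "attmil_train_config")
}

#' One-cycle schedules
#'
#' Learning rate as a function of the (continuous) epoch position: cosine
#' rise from `lr_max/25` at epoch 0 to `lr_max` at `warmup_epochs`, cosine
#' fall to `lr_max/10000` at the final epoch. `one_cycle_beta1()` cycles the
#' Adam first moment between its endpoints with the same periodicity.
#'
#' @param epoch Continuous epoch position in \[0, epochs\].
#' @param cfg An [attmil_train_config()].
#' @export
one_cycle_lr <- function(epoch, cfg) {
  lo1 <- cfg$lr_max / 25; lo2 <- cfg$lr_max / 10000
  wu <- cfg$warmup_epochs
  if (epoch <= wu) {
    u <- if (wu > 0) epoch / wu else 1
    lo1 + (cfg$lr_max - lo1) * (1 - cos(pi * u)) / 2
  } else {
    u <- (epoch - wu) / (cfg$epochs - wu)
    lo2 + (cfg$lr_max - lo2) * (1 + cos(pi * u)) / 2
  }
}

#' @rdname one_cycle_lr
#' @export
one_cycle_beta1 <- function(epoch, cfg) {
  b <- cfg$beta1_range
  wu <- cfg$warmup_epochs
  if (epoch <= wu) {
    u <- if (wu > 0) epoch / wu else 1
    b[1] + (b[2] - b[1]) * (1 - cos(pi * u)) / 2
  } else {
    u <- (epoch - wu) / (cfg$epochs - wu)
    b[2] + (b[1] - b[2]) * (1 - cos(pi * u)) / 2
  }
}

# Inverse-class-frequency weights, one per class {0, 1}.
class_weights <- function(labels) {
  n <- table(factor(labels, levels = c(0L, 1L)))
  if (any(n == 0)) {
    stop("training labels contain a single class; class weights undefined",
         call. = FALSE)
  }
  w <- sum(n) / (2 * as.numeric(n))
  names(w) <- c("0", "1")
  w
}

# Forward + cache for one bag (training path).
attmil_bag_forward <- function(X, params) {
  A <- sweep(X %*% params$W1, 2L, params$b1, "+")
  H1 <- pmax(A, 0)
  H <- sweep(H1 %*% params$W2, 2L, params$b2, "+")
  Tm <- tanh(H %*% t(params$V))
  a <- softmax_vec(as.vector(Tm %*% params$w))
  hsum <- as.vector(crossprod(H, a))
  list(X = X, H1 = H1, H = H, Tm = Tm, a = a, hsum = hsum)
}

# Backward through pooling, attention and embedding for one bag.
attmil_bag_backward <- function(cache, dhsum, params, grads) {
  H <- cache$H; a <- cache$a; Tm <- cache$Tm
  da <- as.vector(H %*% dhsum)
  dH <- outer(a, dhsum)
  dlogit <- a * (da - sum(a * da))
  dTm <- outer(dlogit, params$w)
  dPre <- dTm * (1 - Tm^2)
  grads$w <- grads$w + as.vector(crossprod(Tm, dlogit))
  grads$V <- grads$V + crossprod(dPre, H)
  dH <- dH + dPre %*% params$V
  grads$W2 <- grads$W2 + crossprod(cache$H1, dH)
  grads$b2 <- grads$b2 + colSums(dH)
  dH1 <- (dH %*% t(params$W2)) * (cache$H1 > 0)
  grads$W1 <- grads$W1 + crossprod(cache$X, dH1)
  grads$b1 <- grads$b1 + colSums(dH1)
  grads
}

zero_grads <- function(params) {
  g <- lapply(params[c("W1", "b1", "W2", "b2", "V", "w",
                       "bn_gamma", "bn_beta", "Wc", "bc")],
              function(p) p * 0)
  g
}

#' Train the attention-MIL model
#'
#' Full training procedure: every epoch each bag is resampled to at most
#' `k_tiles` tiles, patients are shuffled into minibatches, and the
#' class-weighted cross-entropy is minimized with AdamW under the one-cycle
#' learning-rate and beta1 schedules (see [attmil_train_config()]). The
#' classifier's batch normalization uses batch statistics during training
#' and updates running statistics (momentum 0.1) for inference. An optional
#' validation set is scored each epoch for monitoring only — no early
#' stopping or model selection; the final-epoch parameters are the model.
#'
#' @param bags List of labeled [feature_bag()]s (training set).
#' @param cfg An [attmil_train_config()].
#' @param model_cfg An [attmil_config()]; defaults to the bag dimension.
#' @param val_bags Optional labeled bags for per-epoch monitoring.
#' @param verbose Print per-epoch losses.
#' @return An `attmil_fit`: `params`, `log` (per-epoch data frame),
#'   `class_weights`, `cfg`, `model_cfg`.
#' @export
train_attmil <- function(bags, cfg = attmil_train_config(),
                         model_cfg = NULL, val_bags = NULL,
                         verbose = FALSE) {
  stopifnot(length(bags) >= 2L)
  labels <- vapply(bags, function(b) b$label, integer(1L))
  if (min(table(factor(labels, levels = c(0L, 1L)))) < 2) {
    stop("need at least 2 patients per class to train", call. = FALSE)
  }
  d <- ncol(bags[[1L]]$features)
  if (is.null(model_cfg)) model_cfg <- attmil_config(input_dim = d)
  wgt <- class_weights(labels)
  params <- init_attmil_params(model_cfg, derive_seed(cfg$seed, "init"))
  opt <- list(m = zero_grads(params), v = zero_grads(params), t = 0L)
  decayed <- c("W1", "W2", "V", "w", "Wc")   # no decay on biases/batch-norm
  n <- length(bags)
  n_batches <- ceiling(n / cfg$batch_size)
  log <- vector("list", cfg$epochs)
  set.seed(derive_seed(cfg$seed, "epochs"))
  for (epoch in seq_len(cfg$epochs)) {
    order_idx <- sample.int(n)
    epoch_bags <- lapply(bags, sample_bag, k = model_cfg$k_tiles)
    epoch_loss <- 0; n_seen <- 0
    for (b in seq_len(n_batches)) {
      idx <- order_idx[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      pos <- (epoch - 1L) + (b - 1L) / n_batches
      lr <- one_cycle_lr(pos, cfg)
      beta1 <- one_cycle_beta1(pos, cfg)
      caches <- lapply(epoch_bags[idx], function(bg) {
        attmil_bag_forward(bg$features, params)
      })
      Z <- do.call(rbind, lapply(caches, function(c) c$hsum))
      B <- nrow(Z)
      y <- labels[idx]
      wv <- wgt[as.character(y)]
      # batch norm (training statistics)
      mu <- colMeans(Z)
      vpop <- colMeans(sweep(Z, 2L, mu)^2)
      invstd <- 1 / sqrt(vpop + cfg$eps)
      Xh <- sweep(sweep(Z, 2L, mu), 2L, invstd, "*")
      Y <- sweep(sweep(Xh, 2L, params$bn_gamma, "*"), 2L, params$bn_beta, "+")
      # running statistics (unbiased variance, momentum 0.1)
      vub <- if (B > 1L) vpop * B / (B - 1L) else vpop
      params$bn_mean <- 0.9 * params$bn_mean + 0.1 * mu
      params$bn_var <- 0.9 * params$bn_var + 0.1 * vub
      # dropout
      p <- model_cfg$dropout_p
      M <- if (p > 0) {
        matrix(stats::rbinom(length(Y), 1L, 1 - p), B, ncol(Y)) / (1 - p)
      } else matrix(1, B, ncol(Y))
      Zd <- Y * M
      logits <- sweep(Zd %*% params$Wc, 2L, params$bc, "+")
      P <- softmax_rows(logits)
      py <- P[cbind(seq_len(B), y + 1L)]
      loss <- sum(wv * -log(pmax(py, 1e-12))) / sum(wv)
      epoch_loss <- epoch_loss + loss * B; n_seen <- n_seen + B
      # backward
      dlogits <- P
      dlogits[cbind(seq_len(B), y + 1L)] <-
        dlogits[cbind(seq_len(B), y + 1L)] - 1
      dlogits <- dlogits * (wv / sum(wv))
      grads <- zero_grads(params)
      grads$Wc <- crossprod(Zd, dlogits)
      grads$bc <- colSums(dlogits)
      dZd <- dlogits %*% t(params$Wc)
      dY <- dZd * M
      grads$bn_gamma <- colSums(dY * Xh)
      grads$bn_beta <- colSums(dY)
      dXh <- sweep(dY, 2L, params$bn_gamma, "*")
      sum_dxh <- colSums(dXh)
      sum_dxh_xh <- colSums(dXh * Xh)
      dZ <- sweep(B * dXh, 2L, sum_dxh, "-") -
        sweep(Xh, 2L, sum_dxh_xh, "*")
      dZ <- sweep(dZ, 2L, invstd / B, "*")
      for (i in seq_len(B)) {
        grads <- attmil_bag_backward(caches[[i]], dZ[i, ], params, grads)
      }
      # AdamW step
      opt$t <- opt$t + 1L
      for (nm in names(grads)) {
        g <- grads[[nm]]
        opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
        opt$v[[nm]] <- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * g^2
        mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
        vhat <- opt$v[[nm]] / (1 - cfg$beta2^opt$t)
        upd <- mhat / (sqrt(vhat) + cfg$eps)
        if (nm %in% decayed) upd <- upd + cfg$weight_decay * params[[nm]]
        params[[nm]] <- params[[nm]] - lr * upd
      }
    }
    val_loss <- NA_real_
    if (!is.null(val_bags)) {
      vl <- vapply(val_bags, function(bg) {
        pr <- forward_bag(bg, params)
        wv <- wgt[as.character(bg$label)]
        p <- if (bg$label == 1L) pr$score else 1 - pr$score
        c(wv * -log(pmax(p, 1e-12)), wv)
      }, numeric(2L))
      val_loss <- sum(vl[1L, ]) / sum(vl[2L, ])
    }
    log[[epoch]] <- data.frame(epoch = epoch,
                               train_loss = epoch_loss / n_seen,
                               val_loss = val_loss,
                               lr = one_cycle_lr(epoch - 1L, cfg))
    if (verbose) {
      message(sprintf("epoch %02d  train %.4f  val %.4f", epoch,
                      epoch_loss / n_seen, val_loss))
    }
  }
  structure(list(params = params, log = do.call(rbind, log),
                 class_weights = wgt, cfg = cfg, model_cfg = model_cfg),
            class = "attmil_fit")
}

#' Score a cohort of bags with a trained model
#'
#' @param fit An `attmil_fit` (or bare `attmil_params`).
#' @param bags List of [feature_bag()]s.
#' @param model_id,cohort Tags for the score table.
#' @return A score-table data frame (`patient_id`, `label`, `score`,
#'   `model_id`, `cohort`).
#' @export
predict_bags <- function(fit, bags, model_id = "attmil", cohort = "cohort") {
  params <- if (inherits(fit, "attmil_fit")) fit$params else fit
  rows <- lapply(bags, function(b) {
    pr <- forward_bag(b, params)
    data.frame(patient_id = b$patient_id,
               label = if (is.null(b$label)) NA_integer_ else b$label,
               score = pr$score, model_id = model_id, cohort = cohort,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Save / load a model checkpoint
#'
#' A single-file archive holding all parameter arrays, the model and
#' training configurations, class weights and (optionally) the fitted
#' clinical-encoder statistics, version-tagged.
#'
#' @param fit An `attmil_fit`.
#' @param path Destination file.
#' @param clinical_encoder Optional fitted `clinical_encoder`.
#' @export
save_checkpoint <- function(fit, path, clinical_encoder = NULL) {
  saveRDS(list(format = "wsimil-checkpoint", version = 1L, fit = fit,
               clinical_encoder = clinical_encoder), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- readRDS(path)
  if (!identical(p$format, "wsimil-checkpoint")) {
    stop(path, " is not a model checkpoint", call. = FALSE)
  }
  p
}
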