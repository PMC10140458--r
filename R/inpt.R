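# --- minimal convolutional building blocks (im2col) -------------------------
# All spatial layers operate on h x w x c arrays; 3x3 kernels, stride 1,
# zero padding 1. Weight layout: (9 * c_in) x c_out.

im2col3 <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; cin <- dim(x)[3L]
  p <- array(0, c(h + 2L, w + 2L, cin))
  p[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, h * w, 9L * cin)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    block <- p[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx), , drop = FALSE]
    cols[, ((k - 1L) * cin + 1L):(k * cin)] <- matrix(block, h * w, cin)
  }
  cols
}

col2im3 <- function(dcols, h, w, cin) {
  p <- array(0, c(h + 2L, w + 2L, cin))
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    blk <- array(dcols[, ((k - 1L) * cin + 1L):(k * cin)], c(h, w, cin))
    p[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx), ] <-
      p[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx), ] + blk
  }
  p[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

conv3_fwd <- function(x, W, b) {
  h <- dim(x)[1L]; w <- dim(x)[2L]
  cols <- im2col3(x)
  out <- sweep(cols %*% W, 2L, b, "+")
  list(out = array(out, c(h, w, ncol(W))), cols = cols)
}

conv3_bwd <- function(cache_cols, dout, W, cin) {
  h <- dim(dout)[1L]; w <- dim(dout)[2L]
  dmat <- matrix(dout, h * w, dim(dout)[3L])
  list(dW = crossprod(cache_cols, dmat), db = colSums(dmat),
       dx = col2im3(dmat %*% t(W), h, w, cin))
}

avgpool2_fwd <- function(x) {
  h <- dim(x)[1L] %/% 2L; w <- dim(x)[2L] %/% 2L
  x <- x[seq_len(2L * h), seq_len(2L * w), , drop = FALSE]
  (x[seq(1L, 2L * h, 2L), seq(1L, 2L * w, 2L), , drop = FALSE] +
     x[seq(2L, 2L * h, 2L), seq(1L, 2L * w, 2L), , drop = FALSE] +
     x[seq(1L, 2L * h, 2L), seq(2L, 2L * w, 2L), , drop = FALSE] +
     x[seq(2L, 2L * h, 2L), seq(2L, 2L * w, 2L), , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy, h, w) {
  cin <- dim(dy)[3L]
  dx <- array(0, c(h, w, cin))
  hp <- dim(dy)[1L]; wp <- dim(dy)[2L]
  g <- dy / 4
  dx[seq(1L, 2L * hp, 2L), seq(1L, 2L * wp, 2L), ] <- g
  dx[seq(2L, 2L * hp, 2L), seq(1L, 2L * wp, 2L), ] <- g
  dx[seq(1L, 2L * hp, 2L), seq(2L, 2L * wp, 2L), ] <- g
  dx[seq(2L, 2L * hp, 2L), seq(2L, 2L * wp, 2L), ] <- g
  dx
}

# --- backbones --------------------------------------------------------------

#' Tile-classifier backbones
#'
#' The tile-level classifier is pluggable behind a small contract: parameter
#' initialization, a forward pass from a prepared image array to two-class
#' logits, the matching backward pass, named parameter groups ordered
#' shallowest to deepest (for discriminative learning-rate slices), the head
#' parameter names (for the head-only warmup stage), and — when the
#' architecture has spatial feature maps — a designated convolutional
#' feature layer for Grad-CAM.
#'
#' `backbone_tiny_resnet()` is the default test-scale backbone: a compact
#' residual CNN (3x3 stem convolution, one residual block, global average
#' pooling, linear head) that trains in seconds on a CPU; no pretrained
#' weights are required or downloaded. `backbone_linear()` flattens the
#' input into a logistic-regression-style linear classifier; it has no
#' spatial feature maps, so Grad-CAM refuses it.
#'
#' @param input_px Input edge length the backbone expects.
#' @param channels Stem width of the residual backbone.
#' @name backbones
NULL

#' @rdname backbones
#' @export
backbone_tiny_resnet <- function(input_px = 32L, channels = 8L) {
  C <- as.integer(channels)
  structure(list(
    name = "tiny-resnet", input_px = as.integer(input_px),
    groups = list(stem = c("Ws", "bs"),
                  block = c("Wb1", "bb1", "Wb2", "bb2"),
                  head = c("Wh", "bh")),
    head = c("Wh", "bh"),
    has_feature_maps = TRUE,
    init = function(seed = 1L) {
      with_seed(seed, {
        he <- function(fan_in, nr, nc) {
          matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
        }
        list(Ws = he(27, 27L, C), bs = rep(0, C),
             Wb1 = he(9 * C, 9L * C, C), bb1 = rep(0, C),
             Wb2 = he(9 * C, 9L * C, C), bb2 = rep(0, C),
             Wh = he(C, C, 2L), bh = rep(0, 2L))
      })
    },
    forward = function(params, x) {
      c1 <- conv3_fwd(x, params$Ws, params$bs)
      r1 <- pmax(c1$out, 0)
      p1 <- avgpool2_fwd(r1)
      c2 <- conv3_fwd(p1, params$Wb1, params$bb1)
      r2 <- pmax(c2$out, 0)
      c3 <- conv3_fwd(r2, params$Wb2, params$bb2)
      feat <- pmax(c3$out + p1, 0)            # residual connection
      g <- apply(feat, 3L, mean)              # global average pool
      logits <- as.vector(g %*% params$Wh + params$bh)
      list(logits = logits, feature_maps = feat,
           cache = list(x = x, c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
                        c3 = c3, feat = feat, g = g))
    },
    backward = function(params, cache, dlogits, to_features_only = FALSE) {
      hw <- dim(cache$feat)[1L] * dim(cache$feat)[2L]
      dg <- as.vector(params$Wh %*% dlogits)
      dfeat <- array(rep(dg / hw, each = hw), dim = dim(cache$feat))
      dfeat <- dfeat * (cache$feat > 0)
      if (to_features_only) return(list(dfeat = dfeat))
      dWh <- outer(cache$g, dlogits); dbh <- dlogits
      b3 <- conv3_bwd(cache$c3$cols, dfeat, params$Wb2, dim(cache$r2)[3L])
      dr2 <- b3$dx * (cache$c2$out > 0)
      b2 <- conv3_bwd(cache$c2$cols, dr2, params$Wb1, dim(cache$p1)[3L])
      dp1 <- b2$dx + dfeat                    # skip-connection gradient
      dr1 <- avgpool2_bwd(dp1, dim(cache$r1)[1L], dim(cache$r1)[2L])
      dr1 <- dr1 * (cache$c1$out > 0)
      b1 <- conv3_bwd(cache$c1$cols, dr1, params$Ws, 3L)
      list(grads = list(Ws = b1$dW, bs = b1$db, Wb1 = b2$dW, bb1 = b2$db,
                        Wb2 = b3$dW, bb2 = b3$db, Wh = dWh, bh = dbh))
    }),
    class = "tile_backbone")
}

#' @rdname backbones
#' @export
backbone_linear <- function(input_px = 32L) {
  n_in <- as.integer(input_px)^2 * 3L
  structure(list(
    name = "linear", input_px = as.integer(input_px),
    groups = list(head = c("W", "b")),
    head = c("W", "b"),
    has_feature_maps = FALSE,
    init = function(seed = 1L) {
      with_seed(seed, list(W = matrix(stats::rnorm(n_in * 2L,
                                                   sd = 1 / sqrt(n_in)),
                                      n_in, 2L),
                           b = rep(0, 2L)))
    },
    forward = function(params, x) {
      v <- as.vector(x)
      list(logits = as.vector(v %*% params$W + params$b), feature_maps = NULL,
           cache = list(v = v))
    },
    backward = function(params, cache, dlogits, to_features_only = FALSE) {
      if (to_features_only) {
        stop("linear backbone has no spatial feature maps", call. = FALSE)
      }
      list(grads = list(W = outer(cache$v, dlogits), b = dlogits))
    }),
    class = "tile_backbone")
}

# --- training ---------------------------------------------------------------

#' Training configuration for the tile-classifier baseline
#'
#' Reference protocol: the replaced classification head is fine-tuned for
#' one epoch (all other parameters frozen) at learning rate 2e-3; then the
#' full network trains for 32 epochs under a one-cycle schedule in which
#' per-depth maximal learning rates are set in equally spaced slices from
#' `lr_max` = 1e-3 (deepest layer group) down to `lr_max/100` (shallowest),
#' rising from 1/5 of each maximum over 10 epochs and falling to 1/10000 of
#' it over the remainder, with Adam beta1 cycled 0.95 -> 0.85 -> 0.95.
#' Training tiles are augmented by random rotations (p = 0.75, up to 360
#' degrees) and vertical flips (p = 0.5); evaluation applies no
#' augmentation. Cross-entropy is weighted by inverse class frequency.
#'
#' @param backbone A [backbone_tiny_resnet()]-style backbone.
#' @param batch_size Tiles per minibatch.
#' @param epochs_head,epochs_full Stage lengths.
#' @param lr_head Stage-1 head learning rate.
#' @param lr_max Stage-2 maximal learning rate of the deepest slice.
#' @param slice_div Ratio between deepest and shallowest slice maxima.
#' @param warmup_epochs Rising-phase length of stage 2.
#' @param rotate_p,vflip_p Augmentation probabilities.
#' @param beta1_range,beta2,eps,weight_decay AdamW hyperparameters.
#' @param seed Master seed.
#' @export
inpt_train_config <- function(backbone = backbone_tiny_resnet(),
                              batch_size = 92L, epochs_head = 1L,
                              epochs_full = 32L, lr_head = 2e-3,
                              lr_max = 1e-3, slice_div = 100,
                              warmup_epochs = 10L, rotate_p = 0.75,
                              vflip_p = 0.5, beta1_range = c(0.95, 0.85),
                              beta2 = 0.99, eps = 1e-5, weight_decay = 0.01,
                              seed = 1L) {
  stopifnot(inherits(backbone, "tile_backbone"),
            epochs_full >= warmup_epochs)
  structure(list(backbone = backbone, batch_size = as.integer(batch_size),
                 epochs_head = as.integer(epochs_head),
                 epochs_full = as.integer(epochs_full),
                 lr_head = lr_head, lr_max = lr_max, slice_div = slice_div,
                 warmup_epochs = as.integer(warmup_epochs),
                 rotate_p = rotate_p, vflip_p = vflip_p,
                 beta1_range = beta1_range, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "inpt_train_config")
}

#' Per-group maximal learning rates (discriminative slices)
#'
#' Equally spaced from `lr_max / slice_div` for the shallowest group up to
#' `lr_max` for the deepest.
#'
#' @param cfg An [inpt_train_config()].
#' @export
lr_slices <- function(cfg) {
  g <- names(cfg$backbone$groups)
  n <- length(g)
  lrs <- if (n == 1L) cfg$lr_max else {
    seq(cfg$lr_max / cfg$slice_div, cfg$lr_max, length.out = n)
  }
  names(lrs) <- g
  lrs
}

# one-cycle multiplier in [0,1]-ish: start/5 -> max -> max/10000
inpt_cycle_lr <- function(pos, lr_top, warm, total) {
  lo1 <- lr_top / 5; lo2 <- lr_top / 10000
  if (pos <= warm) {
    u <- if (warm > 0) pos / warm else 1
    lo1 + (lr_top - lo1) * (1 - cos(pi * u)) / 2
  } else {
    u <- (pos - warm) / (total - warm)
    lo2 + (lr_top - lo2) * (1 + cos(pi * u)) / 2
  }
}

# random rotation / vertical flip on a raw 0..255 RGB array
augment_tile <- function(px, rotate_p, vflip_p) {
  if (stats::runif(1L) < rotate_p) {
    ang <- stats::runif(1L, 0, 360)
    img <- EBImage::rotate(as_ebimage(px), ang,
                           output.dim = c(ncol(px), nrow(px)),
                           bg.col = "white")
    px <- pmin(pmax(from_ebimage(img), 0), 255)
  }
  if (stats::runif(1L) < vflip_p) px <- px[rev(seq_len(nrow(px))), , , drop = FALSE]
  px
}

#' Train the tile-level classifier (mean-pooling baseline)
#'
#' Every tile inherits its slide's label. Stage 1 trains only the
#' classification head for one epoch; stage 2 unfreezes everything and
#' trains under the sliced one-cycle schedule (see [inpt_train_config()]).
#'
#' @param tiles List of raw RGB tile arrays (0..255) or `tile_record`s.
#' @param labels Integer 0/1 tile labels (inherited from slides).
#' @param cfg An [inpt_train_config()].
#' @param verbose Print epoch losses.
#' @return An `inpt_fit` with `params`, `backbone`, `log`, `class_weights`.
#' @export
train_inpt <- function(tiles, labels, cfg = inpt_train_config(),
                       verbose = FALSE) {
  stopifnot(length(tiles) == length(labels), length(tiles) >= 2L)
  wgt <- class_weights(labels)
  bb <- cfg$backbone
  params <- bb$init(derive_seed(cfg$seed, "init"))
  raw <- lapply(tiles, function(t) if (inherits(t, "tile_record")) t$pixels else t)
  n <- length(raw)
  opt <- list(m = lapply(params, function(p) p * 0),
              v = lapply(params, function(p) p * 0), t = 0L)
  biases <- stats::setNames(grepl("^b", names(params)), names(params))
  run_epoch <- function(epoch_pos, total, warm, trainable, lr_fixed = NULL,
                        augment = TRUE) {
    order_idx <- sample.int(n)
    n_batches <- ceiling(n / cfg$batch_size)
    loss_sum <- 0
    for (b in seq_len(n_batches)) {
      idx <- order_idx[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      pos <- epoch_pos + (b - 1L) / n_batches
      beta1 <- one_cycle_beta1(pos, list(beta1_range = cfg$beta1_range,
                                         warmup_epochs = warm,
                                         epochs = total))
      grads <- lapply(params, function(p) p * 0)
      bl <- 0; wsum <- 0
      for (i in idx) {
        px <- raw[[i]]
        if (augment) px <- augment_tile(px, cfg$rotate_p, cfg$vflip_p)
        x <- prepare_model_input(px, out_px = bb$input_px)
        fw <- bb$forward(params, x)
        p <- softmax_vec(fw$logits)
        y <- labels[i]
        wv <- wgt[as.character(y)]
        bl <- bl + wv * -log(max(p[y + 1L], 1e-12)); wsum <- wsum + wv
        dl <- p; dl[y + 1L] <- dl[y + 1L] - 1
        g <- bb$backward(params, fw$cache, dl * wv)$grads
        for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
      }
      loss_sum <- loss_sum + bl
      grads <- lapply(grads, function(g) g / wsum)
      opt$t <<- opt$t + 1L
      slices <- lr_slices(cfg)
      for (gr in names(bb$groups)) {
        for (nm in bb$groups[[gr]]) {
          if (!nm %in% trainable) next
          lr <- if (!is.null(lr_fixed)) lr_fixed else {
            inpt_cycle_lr(pos, slices[[gr]], warm, total)
          }
          g <- grads[[nm]]
          opt$m[[nm]] <<- beta1 * opt$m[[nm]] + (1 - beta1) * g
          opt$v[[nm]] <<- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * g^2
          mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
          vhat <- opt$v[[nm]] / (1 - cfg$beta2^opt$t)
          upd <- mhat / (sqrt(vhat) + cfg$eps)
          if (!biases[[nm]]) upd <- upd + cfg$weight_decay * params[[nm]]
          params[[nm]] <<- params[[nm]] - lr * upd
        }
      }
    }
    loss_sum / sum(wgt[as.character(labels)])
  }
  set.seed(derive_seed(cfg$seed, "train"))
  log <- list()
  # stage 1: head only, frozen body
  for (e in seq_len(cfg$epochs_head)) {
    l <- run_epoch(e - 1L, cfg$epochs_head, 0L, trainable = bb$head,
                   lr_fixed = cfg$lr_head)
    log[[length(log) + 1L]] <- data.frame(stage = "head", epoch = e,
                                          train_loss = l)
    if (verbose) message(sprintf("head  epoch %02d loss %.4f", e, l))
  }
  # stage 2: full model, one-cycle slices
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p * 0)
  opt$v <- lapply(params, function(p) p * 0)
  for (e in seq_len(cfg$epochs_full)) {
    l <- run_epoch(e - 1L, cfg$epochs_full, cfg$warmup_epochs,
                   trainable = names(params))
    log[[length(log) + 1L]] <- data.frame(stage = "full", epoch = e,
                                          train_loss = l)
    if (verbose) message(sprintf("full  epoch %02d loss %.4f", e, l))
  }
  structure(list(params = params, backbone = bb, log = do.call(rbind, log),
                 class_weights = wgt, cfg = cfg),
            class = "inpt_fit")
}

#' Predict per-tile positive-class probabilities
#'
#' Deterministic at inference: no augmentation, no dropout.
#'
#' @param tiles List of raw RGB arrays or `tile_record`s.
#' @param fit An `inpt_fit`.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_tiles <- function(tiles, fit) {
  stopifnot(inherits(fit, "inpt_fit"))
  vapply(tiles, function(t) {
    px <- if (inherits(t, "tile_record")) t$pixels else t
    x <- prepare_model_input(px, out_px = fit$backbone$input_px)
    softmax_vec(fit$backbone$forward(fit$params, x)$logits)[2L]
  }, 0)
}

#' Mean-pool tile scores to patient level
#'
#' @param tile_scores Numeric tile probabilities.
#' @param patient_ids Patient of each tile.
#' @return Named vector of per-patient mean scores.
#' @export
mean_pool_patient <- function(tile_scores, patient_ids) {
  stopifnot(length(tile_scores) == length(patient_ids))
  if (any(is.na(tile_scores))) stop("tile scores contain NA", call. = FALSE)
  tab <- table(patient_ids)
  if (any(tab == 0)) {
    stop("patients with zero tiles: ",
         paste(names(tab)[tab == 0], collapse = ", "), call. = FALSE)
  }
  vapply(split(tile_scores, patient_ids), mean, 0)
}
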