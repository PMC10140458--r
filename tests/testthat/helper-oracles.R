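# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# AUROC by exhaustive comparison of all positive/negative pairs.
auroc_pairwise <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# AUPRC by an exhaustive threshold sweep over the distinct scores.
auprc_sweep <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  rec_prev <- 0
  area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    prec <- tp / (tp + fp)
    rec <- tp / sum(labels == 1L)
    area <- area + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  area
}

# Variance of the 3x3 Laplacian response with replicate borders, written as
# an explicit double loop.
blur_score_bruteforce <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  at <- function(i, j) gray[min(max(i, 1L), h), min(max(j, 1L), w)]
  lap <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    lap[i, j] <- at(i - 1L, j) + at(i + 1L, j) + at(i, j - 1L) +
      at(i, j + 1L) - 4 * at(i, j)
  }
  stats::var(as.vector(lap))
}

# Luma conversion written out independently of the package helper.
to_gray_oracle <- function(px) {
  0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
}

# A pink tissue-like tile with `n` separated dark ellipse outlines.
tile_with_ellipses <- function(n = 6L, edge = 96L) {
  px <- array(0, c(edge, edge, 3L))
  px[, , 1L] <- 230; px[, , 2L] <- 180; px[, , 3L] <- 200
  centers <- expand.grid(cy = seq(16, edge - 16, length.out = 3),
                         cx = seq(16, edge - 16, length.out = 3))
  xs <- matrix(rep(seq_len(edge), each = edge), edge, edge)
  ys <- matrix(rep(seq_len(edge), times = edge), edge, edge)
  for (i in seq_len(n)) {
    r2 <- ((xs - centers$cx[i]) / 8)^2 + ((ys - centers$cy[i]) / 6)^2
    ring <- r2 >= 0.6 & r2 <= 1
    for (c in 1:3) {
      ch <- px[, , c]
      ch[ring] <- c(60, 40, 90)[c]
      px[, , c] <- ch
    }
  }
  px
}

# Tiny labeled bag fixture.
toy_bag <- function(K = 4L, D = 3L, label = 1L, seed = 1L,
                    patient = "P1") {
  set.seed(seed)
  feature_bag(patient, patient, matrix(rnorm(K * D), K, D),
              cbind(seq_len(K) - 1L, 0L), label = label)
}
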