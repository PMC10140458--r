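test_that("tile embedding is the two-layer map applied row-wise", {
  cfg <- attmil_config(input_dim = 3L, embed_dim = 4L, attn_hidden = 2L)
  params <- init_attmil_params(cfg, seed = 1L)
  # zero weights and biases -> zero embeddings
  p0 <- params
  p0$W1[] <- 0; p0$b1[] <- 0; p0$W2[] <- 0; p0$b2[] <- 0
  expect_true(all(embed_tiles(matrix(rnorm(9), 3, 3), p0) == 0))
  # a duplicated tile embeds to identical rows
  X <- matrix(c(1, -2, 0.5), 4, 3, byrow = TRUE)
  H <- embed_tiles(X, params)
  expect_equal(H[1L, ], H[4L, ])
  # matrix-algebra oracle, written out longhand
  set.seed(3)
  X <- matrix(rnorm(9), 3, 3)
  H <- embed_tiles(X, params)
  for (k in 1:3) {
    a1 <- pmax(as.vector(X[k, ] %*% params$W1) + params$b1, 0)
    expect_equal(H[k, ], as.vector(a1 %*% params$W2) + params$b2,
                 tolerance = 1e-12)
  }
  expect_error(embed_tiles(matrix(0, 2, 7), params), "dimension")
})

test_that("attention weights are the softmax of w' tanh(V h)", {
  # singleton
  expect_equal(attention_weights(matrix(1, 1, 2), matrix(1, 1, 2), 1), 1)
  # identical tiles share attention uniformly
  h <- matrix(rep(c(0.3, -0.7), each = 5L), 5, 2)
  a <- attention_weights(h, matrix(c(0.5, -1), 1, 2), 2)
  expect_equal(a, rep(0.2, 5L), tolerance = 1e-12)
  # closed-form logits (0, ln 2, ln 4) -> (1/7, 2/7, 4/7)
  V <- matrix(c(1, 0), 1, 2)
  w <- 2
  hvals <- atanh(c(0, log(2), log(4)) / 2)
  h <- cbind(hvals, 0)
  expect_equal(attention_weights(h, V, w), c(1, 2, 4) / 7, tolerance = 1e-12)
})

test_that("attention pooling is the weighted row sum", {
  h <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(attention_pool(h, c(1, 0)), c(1, 2))
  expect_equal(attention_pool(h, c(0.5, 0.5)), colMeans(h))
  expect_equal(attention_pool(h, c(0.25, 0.75)),
               0.25 * c(1, 2) + 0.75 * c(3, 4))
})

test_that("the classifier block reduces to softmax arithmetic at identity", {
  cfg <- attmil_config(input_dim = 2L, embed_dim = 2L, attn_hidden = 2L)
  params <- init_attmil_params(cfg, seed = 1L)
  params$Wc[] <- 0; params$bc[] <- 0
  expect_equal(unname(classify_summary(c(3, -1), params)[1L, ]), c(0.5, 0.5))
  # logits (1, -1) -> (0.8808, 0.1192); bn is identity at running stats 0/1
  params$Wc <- matrix(c(1, -1), 2, 2, byrow = TRUE)
  params$Wc[2L, ] <- 0
  out <- classify_summary(c(1, 0), params)
  expect_equal(unname(out[1L, ]), c(0.8808, 0.1192), tolerance = 1e-3)
  # inference is deterministic
  expect_identical(classify_summary(c(1, 0), params),
                   classify_summary(c(1, 0), params))
})

test_that("bag forward composes the stages and ignores tile order", {
  cfg <- attmil_config(input_dim = 6L, embed_dim = 8L, attn_hidden = 4L)
  params <- init_attmil_params(cfg, seed = 5L)
  bag <- toy_bag(K = 7L, D = 6L, seed = 2L)
  pr <- forward_bag(bag, params)
  # oracle: explicit stage-by-stage composition
  H <- embed_tiles(bag$features, params)
  a <- attention_weights(H, params$V, params$w)
  hs <- attention_pool(H, a)
  expect_equal(pr$score, classify_summary(hs, params)[1L, 2L],
               tolerance = 1e-12)
  # permutation invariance
  perm <- c(3L, 1L, 7L, 5L, 2L, 6L, 4L)
  bagp <- feature_bag(bag$patient_id, bag$slide_id,
                      bag$features[perm, ], bag$tile_coords[perm, ],
                      label = bag$label)
  expect_equal(forward_bag(bagp, params)$score, pr$score, tolerance = 1e-9)
  # a bag of identical tiles scores like the singleton bag
  one <- bag$features[3L, , drop = FALSE]
  same <- feature_bag("p", "p", one[rep(1L, 5L), ], cbind(0:4, 0L))
  single <- feature_bag("p", "p", one, cbind(0L, 0L))
  expect_equal(forward_bag(same, params)$score,
               forward_bag(single, params)$score, tolerance = 1e-12)
})

test_that("attention properties hold across random parameter draws", {
  for (i in 1:100) {
    cfg <- attmil_config(input_dim = 5L, embed_dim = 6L, attn_hidden = 3L)
    params <- init_attmil_params(cfg, seed = i)
    set.seed(1000 + i)
    K <- sample(2:9, 1L)
    H <- matrix(rnorm(K * 6L), K, 6L)
    a <- attention_weights(H, params$V, params$w)
    expect_equal(sum(a), 1, tolerance = 1e-5)
    expect_true(all(a > 0))
    # uniform attention equals mean pooling
    expect_equal(attention_pool(H, rep(1 / K, K)), colMeans(H),
                 tolerance = 1e-12)
  }
})

test_that("tile-level scores route singleton summaries consistently", {
  cfg <- attmil_config(input_dim = 4L, embed_dim = 6L, attn_hidden = 3L)
  params <- init_attmil_params(cfg, seed = 9L)
  bag <- toy_bag(K = 5L, D = 4L, seed = 3L)
  ts <- tile_level_scores(bag, params)
  # oracle: loop each tile through forward_bag as a 1-bag
  for (k in 1:5) {
    single <- feature_bag("p", "p", bag$features[k, , drop = FALSE],
                          cbind(0L, 0L))
    expect_equal(ts[k], forward_bag(single, params)$score, tolerance = 1e-12)
  }
  # identical tiles give identical scores
  same <- feature_bag("p", "p", bag$features[rep(2L, 4L), ], cbind(0:3, 0L))
  expect_equal(stats::var(tile_level_scores(same, params)), 0)
})

test_that("training gradients match finite differences end to end", {
  # loss of a 3-bag batch under fixed dropout mask, differentiated by hand
  # in train_attmil's batch path vs. central differences
  cfg <- attmil_config(input_dim = 4L, embed_dim = 5L, attn_hidden = 3L,
                       dropout_p = 0)
  params <- init_attmil_params(cfg, seed = 7L)
  bags <- lapply(1:3, function(i) toy_bag(K = 4L, D = 4L, seed = i,
                                          label = i %% 2L))
  labels <- vapply(bags, `[[`, integer(1L), "label")
  wgt <- wsimil:::class_weights(labels)
  loss_of <- function(p) {
    caches <- lapply(bags, function(b) wsimil:::attmil_bag_forward(b$features, p))
    Z <- do.call(rbind, lapply(caches, `[[`, "hsum"))
    mu <- colMeans(Z); v <- colMeans(sweep(Z, 2, mu)^2)
    Xh <- sweep(sweep(Z, 2, mu), 2, sqrt(v + 1e-5), "/")
    Y <- sweep(sweep(Xh, 2, p$bn_gamma, "*"), 2, p$bn_beta, "+")
    P <- wsimil:::softmax_rows(sweep(Y %*% p$Wc, 2, p$bc, "+"))
    wv <- wgt[as.character(labels)]
    sum(wv * -log(P[cbind(1:3, labels + 1L)])) / sum(wv)
  }
  # analytic gradient via the internal batch backward
  caches <- lapply(bags, function(b) wsimil:::attmil_bag_forward(b$features, params))
  Z <- do.call(rbind, lapply(caches, `[[`, "hsum"))
  B <- 3L
  mu <- colMeans(Z); v <- colMeans(sweep(Z, 2, mu)^2)
  invstd <- 1 / sqrt(v + 1e-5)
  Xh <- sweep(sweep(Z, 2, mu), 2, invstd, "*")
  Y <- sweep(sweep(Xh, 2, params$bn_gamma, "*"), 2, params$bn_beta, "+")
  P <- wsimil:::softmax_rows(sweep(Y %*% params$Wc, 2, params$bc, "+"))
  wv <- wgt[as.character(labels)]
  dlog <- P; dlog[cbind(1:3, labels + 1L)] <- dlog[cbind(1:3, labels + 1L)] - 1
  dlog <- dlog * (wv / sum(wv))
  grads <- wsimil:::zero_grads(params)
  grads$Wc <- crossprod(Y, dlog); grads$bc <- colSums(dlog)
  dY <- dlog %*% t(params$Wc)
  grads$bn_gamma <- colSums(dY * Xh); grads$bn_beta <- colSums(dY)
  dXh <- sweep(dY, 2, params$bn_gamma, "*")
  s1 <- colSums(dXh); s2 <- colSums(dXh * Xh)
  dZ <- sweep(B * dXh, 2, s1, "-") - sweep(Xh, 2, s2, "*")
  dZ <- sweep(dZ, 2, invstd / B, "*")
  for (i in 1:3) {
    grads <- wsimil:::attmil_bag_backward(caches[[i]], dZ[i, ], params, grads)
  }
  h <- 1e-5
  for (nm in c("W1", "V", "w", "Wc", "bn_gamma")) {
    idx <- seq_len(min(4L, length(params[[nm]])))
    for (j in idx) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + h; up <- loss_of(pp)
      pp[[nm]][j] <- pp[[nm]][j] - 2 * h; dn <- loss_of(pp)
      expect_equal(grads[[nm]][j], (up - dn) / (2 * h), tolerance = 1e-5)
    }
  }
})

test_that("one-cycle schedule hits the documented endpoints", {
  cfg <- attmil_train_config()
  expect_equal(one_cycle_lr(0, cfg), 1e-4 / 25)      # 4e-6 at epoch 0
  expect_equal(one_cycle_lr(8, cfg), 1e-4)           # lr_max at epoch 8
  expect_equal(one_cycle_lr(32, cfg), 1e-4 / 10000)
  expect_equal(one_cycle_beta1(0, cfg), 0.95)
  expect_equal(one_cycle_beta1(8, cfg), 0.85)
  expect_equal(one_cycle_beta1(32, cfg), 0.95)
  # monotone rise then fall
  rise <- vapply(seq(0, 8, 0.5), one_cycle_lr, 0, cfg = cfg)
  fall <- vapply(seq(8, 32, 0.5), one_cycle_lr, 0, cfg = cfg)
  expect_true(all(diff(rise) > 0))
  expect_true(all(diff(fall) < 0))
})

test_that("training decreases the loss and refuses degenerate labels", {
  bags <- make_mil_bags(mil_sim_config(n_pos = 12L, n_neg = 12L,
                                       k_total = 16L, dim = 8L, seed = 21L))
  cfg <- attmil_train_config(batch_size = 8L, seed = 3L)
  fit <- train_attmil(bags, cfg)
  first8 <- fit$log$train_loss[1:8]
  expect_lt(mean(first8[6:8]), mean(first8[1:3]))
  expect_s3_class(fit, "attmil_fit")
  # single-class training set errors out
  ones <- Filter(function(b) b$label == 1L, bags)
  expect_error(train_attmil(ones, cfg), "class")
})
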