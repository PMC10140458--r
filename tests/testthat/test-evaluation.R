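test_that("stratified folds balance classes and honor the seed", {
  # 50 + 50 patients: every fold gets exactly 10 + 10
  ids <- sprintf("p%03d", 1:100)
  labs <- rep(c(1L, 0L), each = 50L)
  sp <- make_stratified_folds(ids, labs, k = 5L, seed = 4L)
  for (f in 0:4) {
    in_fold <- names(sp$fold)[sp$fold == f]
    expect_identical(sum(labs[match(in_fold, ids)] == 1L), 10L)
    expect_identical(sum(labs[match(in_fold, ids)] == 0L), 10L)
  }
  # pigeonhole: 13 positives over 5 folds -> 2 or 3 per fold
  ids2 <- sprintf("q%03d", 1:100)
  labs2 <- rep(c(1L, 0L), c(13L, 87L))
  sp2 <- make_stratified_folds(ids2, labs2, k = 5L, seed = 1L)
  pos_per_fold <- vapply(0:4, function(f) {
    sum(labs2[match(names(sp2$fold)[sp2$fold == f], ids2)] == 1L)
  }, 0L)
  expect_true(all(pos_per_fold %in% c(2L, 3L)))
  # determinism and seed sensitivity
  expect_identical(make_stratified_folds(ids, labs, seed = 4L)$fold, sp$fold)
  expect_false(identical(make_stratified_folds(ids, labs, seed = 5L)$fold,
                         sp$fold))
  # validation patients come from the training portion only
  s0 <- sp$splits[[1L]]
  expect_length(intersect(s0$val_ids, s0$test_ids), 0L)
  expect_length(intersect(s0$train_ids, s0$val_ids), 0L)
  # too-small class
  expect_error(make_stratified_folds(ids[1:10], c(1L, rep(0L, 9L))),
               "per class")
})

test_that("AUROC is the rank statistic with half-credit ties", {
  perfect <- data.frame(label = c(1L, 1L, 0L, 0L),
                        score = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(auroc(perfect), 1)
  mixed <- data.frame(label = c(1L, 0L, 1L, 0L),
                      score = c(0.9, 0.8, 0.7, 0.6))
  expect_equal(auroc(mixed), 0.75)
  ties <- data.frame(label = c(1L, 0L, 1L, 0L), score = rep(0.5, 4L))
  expect_equal(auroc(ties), 0.5)
  expect_error(auroc(data.frame(label = c(1L, 1L), score = c(0.1, 0.2))),
               "one class")
})

test_that("AUROC equals the exhaustive pairwise oracle on random tables", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(4:50, 1L)
    lab <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))
    sc <- round(runif(n), sample(c(1L, 2L, 8L), 1L))  # induce ties sometimes
    tb <- data.frame(label = lab, score = sc)
    expect_equal(auroc(tb), auroc_pairwise(lab, sc), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  set.seed(12)
  for (i in 1:5) {
    lab <- c(1L, 0L, sample(0:1, 30L, replace = TRUE))
    sc <- runif(32L)
    tb <- data.frame(label = lab, score = sc)
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auroc(tb), ref, tolerance = 1e-12)
  }
})

test_that("AUPRC follows the step convention and class inversion", {
  perfect <- data.frame(label = c(1L, 1L, 0L, 0L),
                        score = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(auprc(perfect, "pos"), 1)
  expect_equal(auprc(perfect, "neg"), 1)
  set.seed(9)
  for (i in 1:10) {
    n <- sample(4:12, 1L)
    lab <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))
    sc <- round(runif(n), 2L)
    tb <- data.frame(label = lab, score = sc)
    expect_equal(auprc(tb, "pos"), auprc_sweep(lab, sc), tolerance = 1e-12)
    expect_equal(auprc(tb, "neg"), auprc_sweep(1L - lab, 1 - sc),
                 tolerance = 1e-12)
  }
  # under random scores AUPRC approaches the prevalence
  tb <- make_score_table(400L, 1600L, auc_target = 0.5, seed = 3L)
  expect_lt(abs(auprc(tb, "pos") - 0.2), 0.05)
  expect_error(auprc(data.frame(label = c(0L, 0L), score = c(0.1, 0.2)),
                     "pos"), "absent")
})

test_that("replicate summaries use the normal-approximation CI", {
  s <- summarize_replicates(c(0.9, 0.9, 0.9, 0.9, 1.0))
  expect_equal(s$mean, 0.92)
  expect_equal(s$ci_half_width, 0.0392, tolerance = 0.0005)
  expect_equal(summarize_replicates(rep(0.7, 5L))$ci_half_width, 0)
  expect_equal(summarize_replicates(c(1.0, 0.9, 0.9, 0.9, 0.9))$mean, 0.92)
  expect_error(summarize_replicates(0.5), "2 replicates")
})

test_that("confusion counts and threshold metrics compose correctly", {
  tb <- data.frame(label = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
                   score = c(0.9, 0.6, 0.4, 0.7, 0.5, 0.3, 0.2, 0.5, 0.8, 0.1))
  c0 <- confusion_at_threshold(tb, 0)
  expect_identical(c(c0$FN, c0$TN), c(0L, 0L))
  chigh <- confusion_at_threshold(tb, 1)
  expect_identical(c(chigh$TP, chigh$FP), c(0L, 0L))
  # exhaustive enumeration oracle at 0.5 (score >= t is positive)
  c5 <- confusion_at_threshold(tb, 0.5)
  expect_identical(c(c5$TP, c5$FP, c5$FN, c5$TN), c(3L, 3L, 1L, 3L))
  # sweep composition: sensitivity non-increasing, specificity non-decreasing
  ths <- seq(0, 1, by = 0.05)
  m <- vapply(ths, function(t) {
    metrics_from_confusion(confusion_at_threshold(tb, t))[1:2]
  }, numeric(2L))
  expect_true(all(diff(m[1L, ]) <= 1e-12))
  expect_true(all(diff(m[2L, ]) >= -1e-12))
})

test_that("confusion metrics reproduce the screening worked example", {
  m <- metrics_from_confusion(list(TP = 236L, FP = 639L, FN = 9L, TN = 890L))
  expect_equal(round(100 * m[["sensitivity"]], 1), 96.3)
  expect_equal(round(100 * m[["specificity"]], 1), 58.2)
  expect_equal(round(100 * m[["ppv"]], 1), 27.0)
  expect_equal(round(100 * m[["npv"]], 1), 99.0)
  expect_equal(metrics_from_confusion(list(TP = 10L, FP = 0L, FN = 0L,
                                           TN = 5L))[["sensitivity"]], 1)
  expect_true(is.na(metrics_from_confusion(list(TP = 0L, FP = 0L, FN = 2L,
                                                TN = 5L))[["ppv"]]))
})

test_that("the 95% in-domain sensitivity threshold averages model cutoffs", {
  one <- data.frame(label = c(1L, 1L, 1L, 0L),
                    score = c(0.9, 0.8, 0.7, 0.5))
  # all three positives must be captured -> threshold 0.7
  expect_equal(in_domain_sensitivity_threshold(list(one)), 0.7)
  five <- lapply(c(0.1, 0.2, 0.3, 0.2, 0.25), function(t) {
    data.frame(label = 1L, score = t)
  })
  expect_equal(in_domain_sensitivity_threshold(five), 0.21)
  expect_error(in_domain_sensitivity_threshold(
    list(data.frame(label = 0L, score = 0.5))), "no positives")
})

test_that("external deployment yields per-model replicates and score means", {
  bags <- make_mil_bags(mil_sim_config(n_pos = 5L, n_neg = 5L, k_total = 8L,
                                       dim = 6L, seed = 13L))
  cfg <- attmil_config(input_dim = 6L, embed_dim = 8L, attn_hidden = 4L)
  fits <- lapply(1:5, function(s) {
    structure(list(params = init_attmil_params(cfg, seed = s)),
              class = "attmil_fit")
  })
  out <- external_deploy(fits, bags)
  expect_length(out$per_model, 5L)
  sc <- vapply(out$per_model, `[[`, numeric(10L), "score")
  expect_equal(out$averaged$score, rowMeans(sc), tolerance = 1e-12)
  # identical models collapse to any single table
  same <- external_deploy(fits[c(1L, 1L, 1L)], bags)
  expect_equal(same$averaged$score, same$per_model[[1L]]$score,
               tolerance = 1e-12)
})

test_that("ANOVA on replicate AUROCs behaves like the F-test it is", {
  base <- c(0.91, 0.92, 0.90, 0.93, 0.915)
  expect_gt(anova_auroc(list(base, base)), 0.99)
  g1 <- 0.9 + c(-2, -1, 0, 1, 2) * 1e-3
  g2 <- 0.7 + c(2, -2, 1, -1, 0) * 1e-3
  expect_lt(anova_auroc(list(g1, g2)), 0.001)
  # two-group ANOVA p equals the squared-t (pooled) p
  p_t <- stats::t.test(g1, g2, var.equal = TRUE)$p.value
  expect_equal(anova_auroc(list(g1, g2)), p_t, tolerance = 1e-10)
})

test_that("odds ratios follow ad/bc with optional zero-cell correction", {
  expect_equal(odds_ratio_2x2(9, 1, 5, 5), 9)
  expect_equal(odds_ratio_2x2(5, 5, 5, 5), 1)
  expect_equal(odds_ratio_2x2(5, 0, 5, 5, correction = TRUE),
               (5.5 * 5.5) / (0.5 * 5.5))
  expect_error(odds_ratio_2x2(5, 0, 5, 5), "correction")
})

test_that("score histograms use fixed 0.05 bins and conserve counts", {
  tb <- data.frame(label = rep(c(0L, 1L), each = 6L),
                   score = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
                             0.02, 0.11, 0.99, 1.0, 0.5, 0.55))
  h <- score_distributions(tb)
  neg <- h[h$label == 0L, ]
  expect_identical(sum(neg$count > 0L), 1L)       # all negatives in one bin
  expect_identical(sum(h$count), 12L)
  pos <- h[h$label == 1L, ]
  # hand-binned oracle for the positives (bins indexed to dodge 0.05 float
  # accumulation in the edge sequence)
  cnt <- function(lo) pos$count[which.min(abs(pos$bin_lo - lo))]
  expect_identical(cnt(0.00), 1L)
  expect_identical(cnt(0.10), 1L)
  expect_identical(cnt(0.95), 2L)  # 0.99 and 1.0
  expect_identical(cnt(0.50), 1L)
  expect_identical(cnt(0.55), 1L)
  expect_equal(sum(h$freq[h$label == 1L]), 1)
})
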