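#' Stratified patient-level cross-validation folds
#'
#' Patients are partitioned into `k` folds stratified by label (per-fold
#' class counts differ from exact proportionality by at most one patient).
#' Within each fold's training portion, a validation subset (`val_frac`,
#' default 25%) is split off at random — stratified as well — for
#' overfitting monitoring; validation patients never come from the test
#' fold.
#'
#' @param patients Character patient ids.
#' @param labels 0/1 labels aligned with `patients`.
#' @param k Number of folds.
#' @param val_frac Fraction of the training portion used for validation.
#' @param seed Integer seed; the split is deterministic given it.
#' @return A `cv_split`: `fold` (named integer vector, 0-based fold index
#'   per patient) and `splits` (per fold: `train_ids`, `val_ids`,
#'   `test_ids`).
#' @export
make_stratified_folds <- function(patients, labels, k = 5L, val_frac = 0.25,
                                  seed = 1L) {
  stopifnot(length(patients) == length(labels), !anyDuplicated(patients))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (min(n_pos, n_neg) < k) {
    stop("need at least k = ", k, " patients per class", call. = FALSE)
  }
  with_seed(seed, {
    fold <- stats::setNames(integer(length(patients)), patients)
    for (cl in c(0L, 1L)) {
      ids <- sample(patients[labels == cl])
      fold[ids] <- (seq_along(ids) - 1L) %% k
    }
    splits <- lapply(seq_len(k) - 1L, function(f) {
      test_ids <- names(fold)[fold == f]
      rest <- names(fold)[fold != f]
      rest_lab <- labels[match(rest, patients)]
      val_ids <- unlist(lapply(c(0L, 1L), function(cl) {
        ids <- sample(rest[rest_lab == cl])
        ids[seq_len(round(val_frac * length(ids)))]
      }), use.names = FALSE)
      list(train_ids = setdiff(rest, val_ids), val_ids = val_ids,
           test_ids = test_ids)
    })
    structure(list(fold = fold, k = k, splits = splits), class = "cv_split")
  })
}

check_score_table <- function(table) {
  stopifnot(all(c("label", "score") %in% names(table)))
  stopifnot(all(table$label %in% c(0L, 1L)), all(is.finite(table$score)))
  table
}

#' Area under the ROC curve
#'
#' Rank-based AUROC (the Mann-Whitney statistic): ties between a positive
#' and a negative score count one half.
#'
#' @param table Score table with columns `label` (0/1) and `score`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(table) {
  check_score_table(table)
  n1 <- sum(table$label == 1L); n0 <- sum(table$label == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: only one class present", call. = FALSE)
  }
  r <- rank(table$score)
  (sum(r[table$label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation: thresholds sweep the distinct scores from high to
#' low and the area is `sum_i (R_i - R_{i-1}) * P_i` (the average-precision
#' convention, no linear interpolation between operating points). For the
#' negative class the labels are inverted and scores replaced by
#' `1 - score`.
#'
#' @param table Score table (`label`, `score`).
#' @param positive_class `"pos"` scores the positive class as is; `"neg"`
#'   inverts labels and scores.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(table, positive_class = c("pos", "neg")) {
  check_score_table(table)
  positive_class <- match.arg(positive_class)
  lab <- table$label; sc <- table$score
  if (positive_class == "neg") {
    lab <- 1L - lab; sc <- 1 - sc
  }
  if (sum(lab == 1L) == 0L) {
    stop("AUPRC undefined: requested class absent", call. = FALSE)
  }
  o <- order(sc, decreasing = TRUE)
  lab <- lab[o]; sc <- sc[o]
  tp <- cumsum(lab == 1L); fp <- cumsum(lab == 0L)
  last <- !duplicated(sc, fromLast = TRUE)   # one point per distinct score
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(lab == 1L)
  sum(diff(c(0, rec)) * prec)
}

#' Summarize replicate metric values as mean and 95% CI
#'
#' Normal-approximation confidence interval: half-width
#' `1.96 * sd / sqrt(n)` with the sample standard deviation.
#'
#' @param values Numeric replicate values (n >= 2; typically the five
#'   cross-validation folds).
#' @param metric Metric name carried in the result.
#' @return A `metric_summary`: `metric`, `values`, `mean`, `ci_half_width`.
#' @export
summarize_replicates <- function(values, metric = "AUROC") {
  if (length(values) < 2L) stop("need at least 2 replicates", call. = FALSE)
  structure(list(metric = metric, values = values, mean = mean(values),
                 ci_half_width = 1.96 * stats::sd(values) / sqrt(length(values))),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("%s: %.3f +/- %.3f (n = %d)\n", x$metric, x$mean,
              x$ci_half_width, length(x$values)))
  invisible(x)
}

#' Confusion counts at a threshold
#'
#' A patient is predicted positive when `score >= t` (ties go to the
#' positive side).
#'
#' @param table Score table (`label`, `score`).
#' @param t Threshold in \[0, 1\].
#' @return A `confusion_counts` list: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_at_threshold <- function(table, t) {
  check_score_table(table)
  stopifnot(t >= 0, t <= 1)
  pred <- table$score >= t
  structure(list(TP = sum(pred & table$label == 1L),
                 FP = sum(pred & table$label == 0L),
                 FN = sum(!pred & table$label == 1L),
                 TN = sum(!pred & table$label == 0L)),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive
#' value TP/(TP+FP), negative predictive value TN/(TN+FN). A metric with a
#' zero denominator is `NA` (undefined), never 0.
#'
#' @param c A `confusion_counts` or a list with `TP`, `FP`, `FN`, `TN`.
#' @return Named numeric vector (proportions in \[0, 1\]).
#' @export
metrics_from_confusion <- function(c) {
  stopifnot(all(c(c$TP, c$FP, c$FN, c$TN) >= 0))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe(c$TP, c$TP + c$FN),
    specificity = safe(c$TN, c$TN + c$FP),
    ppv = safe(c$TP, c$TP + c$FP),
    npv = safe(c$TN, c$TN + c$FN))
}

#' Threshold achieving a target in-domain sensitivity
#'
#' For each model's internal test-set score table, the largest threshold
#' whose sensitivity is at least `target_sens` — the
#' `ceiling(target_sens * P)`-th largest positive score. The returned value
#' is the arithmetic mean over models, matching the protocol of averaging
#' each cross-validation model's own 95% sensitivity threshold.
#'
#' @param per_model_tables List of score tables, one per model.
#' @param target_sens Target sensitivity (default 0.95).
#' @return Scalar threshold.
#' @export
in_domain_sensitivity_threshold <- function(per_model_tables,
                                            target_sens = 0.95) {
  ths <- vapply(per_model_tables, function(tb) {
    check_score_table(tb)
    pos <- sort(tb$score[tb$label == 1L], decreasing = TRUE)
    if (length(pos) == 0L) {
      stop("a model's table has no positives; threshold undefined",
           call. = FALSE)
    }
    pos[ceiling(target_sens * length(pos))]
  }, 0)
  mean(ths)
}

#' Deploy cross-validation models on an external cohort
#'
#' Scores every external bag with each of the models (giving the AUROC
#' replicates) and additionally returns the averaged-score table (mean of
#' the per-model scores per patient) used for threshold statistics.
#'
#' @param fits List of trained models (`attmil_fit`s).
#' @param external_bags List of [feature_bag()]s; patients missing a bag
#'   are skipped with a warning by the caller that assembles the list.
#' @param cohort Cohort tag.
#' @return List with `per_model` (list of score tables) and `averaged`
#'   (one score table, `model_id = "averaged"`).
#' @export
external_deploy <- function(fits, external_bags, cohort = "external") {
  per_model <- lapply(seq_along(fits), function(i) {
    predict_bags(fits[[i]], external_bags,
                 model_id = sprintf("fold%d", i - 1L), cohort = cohort)
  })
  avg <- per_model[[1L]]
  avg$score <- rowMeans(do.call(cbind, lapply(per_model, `[[`, "score")))
  avg$model_id <- "averaged"
  list(per_model = per_model, averaged = avg)
}

#' One-way ANOVA on replicate AUROCs
#'
#' Fixed-effects one-way analysis of variance across model groups (equal
#' variances assumed); for two groups the F statistic equals the squared
#' pooled t statistic.
#'
#' @param groups List of numeric vectors of replicate AUROCs (>= 2 groups,
#'   each n >= 2).
#' @return The ANOVA p value.
#' @export
anova_auroc <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::var, 0) == 0) &&
      stats::var(vapply(groups, mean, 0)) == 0) {
    stop("all groups constant and identical: ANOVA undefined", call. = FALSE)
  }
  stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
}

#' Odds ratio of a 2x2 table
#'
#' `(a * d) / (b * c)`. With `correction = TRUE` and any zero cell, 0.5 is
#' added to every cell (Haldane-Anscombe) before the ratio is formed.
#'
#' @param a,b,c,d Nonnegative counts.
#' @param correction Apply the 0.5 continuity correction on zero cells.
#' @return Scalar odds ratio.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, correction = FALSE) {
  stopifnot(all(c(a, b, c, d) >= 0))
  if (any(c(a, b, c, d) == 0)) {
    if (!correction) {
      if (b * c == 0) {
        stop("odds ratio undefined with zero cells; set correction = TRUE",
             call. = FALSE)
      }
    } else {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
  }
  (a * d) / (b * c)
}

#' Binned prediction-score distributions per cohort and class
#'
#' Fixed bin edges 0, 0.05, ..., 1 (scores of exactly 1 fall in the last
#' bin); counts and within-group normalized frequencies per cohort x class,
#' the raw material of domain-shift plots.
#'
#' @param internal,external Score tables (`label`, `score`); `external`
#'   may be `NULL`.
#' @return Data frame with `cohort`, `label`, `bin_lo`, `bin_hi`, `count`,
#'   `freq`.
#' @export
score_distributions <- function(internal, external = NULL) {
  edges <- seq(0, 1, by = 0.05)
  one <- function(tb, tag) {
    check_score_table(tb)
    do.call(rbind, lapply(c(0L, 1L), function(cl) {
      sc <- tb$score[tb$label == cl]
      if (length(sc) == 0L) return(NULL)
      bin <- pmin(findInterval(sc, edges, rightmost.closed = TRUE), 20L)
      cnt <- tabulate(bin, nbins = 20L)
      data.frame(cohort = tag, label = cl, bin_lo = edges[-21L],
                 bin_hi = edges[-1L], count = cnt, freq = cnt / sum(cnt))
    }))
  }
  out <- one(internal, "internal")
  if (!is.null(external)) out <- rbind(out, one(external, "external"))
  out
}
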