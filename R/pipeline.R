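#' Describe one experiment
#'
#' A declarative record of one row of the experimental design matrix:
#' target, algorithm, encoder, stain normalization and seed. Carried into
#' every report for provenance.
#'
#' @param target Biomarker name (free text, e.g. "MSI").
#' @param algorithm One of `"attmil"`, `"multi-input"`, `"clinical-only"`,
#'   `"inpt"`.
#' @param encoder_name Encoder tag recorded in the report.
#' @param normalization `"macenko"` or `"none"` (recorded for provenance;
#'   normalization itself happens at tile preprocessing).
#' @param seed Master seed of the experiment.
#' @export
experiment_spec <- function(target = "synthetic", algorithm = "attmil",
                            encoder_name = "sim", normalization = "none",
                            seed = 1L) {
  algorithm <- match.arg(algorithm,
                         c("attmil", "multi-input", "clinical-only", "inpt"))
  structure(list(target = target, algorithm = algorithm,
                 encoder_name = encoder_name, normalization = normalization,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

# Assemble per-algorithm bags for one fold given the fitted clinical encoder.
build_fold_bags <- function(bags, spec, clinical = NULL, clin_enc = NULL) {
  if (spec$algorithm == "attmil" || is.null(clinical)) return(bags)
  lapply(bags, function(b) {
    rec <- clinical[clinical$PATIENT == b$patient_id, , drop = FALSE]
    v <- if (nrow(rec) == 1L) encode_clinical(rec, clin_enc) else rep(0, 4L)
    b2 <- attach_clinical(b, v)
    if (spec$algorithm == "clinical-only") b2 <- zero_image_features(b2)
    b2
  })
}

#' Internal cross-validated experiment
#'
#' Trains one attention-MIL model per stratified fold, scores each fold's
#' held-out patients, and summarizes AUROC, AUPRC (positive and negative
#' class) as mean +/- 95% CI over the five replicates — one row of the
#' results table. For `"multi-input"` the clinical 4-vector (fitted on each
#' fold's training patients only) is appended to every tile; for
#' `"clinical-only"` the image block is additionally zeroed.
#'
#' @param bags Labeled [feature_bag()]s, one per patient.
#' @param spec An [experiment_spec()].
#' @param clinical Optional clinical table (see [fit_clinical_encoder()]);
#'   required for multi-input / clinical-only.
#' @param k Folds.
#' @param train_cfg An [attmil_train_config()]; its seed is re-derived per
#'   fold from the experiment seed.
#' @return A `cv_report`: `spec`, `report` (one-row data frame),
#'   `replicates`, `scores` (pooled held-out score table), `fits` (5
#'   models), `split`, `threshold_sens95`, `provenance`.
#' @export
run_internal_cv <- function(bags, spec = experiment_spec(), clinical = NULL,
                            k = 5L, train_cfg = attmil_train_config()) {
  if (spec$algorithm == "inpt") {
    stop("run_internal_cv orchestrates bag-level models; train tile-level ",
         "baselines with train_inpt()", call. = FALSE)
  }
  if (spec$algorithm %in% c("multi-input", "clinical-only") &&
      is.null(clinical)) {
    stop("algorithm '", spec$algorithm, "' needs a clinical table",
         call. = FALSE)
  }
  ids <- vapply(bags, `[[`, "", "patient_id")
  labels <- vapply(bags, `[[`, integer(1L), "label")
  names(bags) <- ids
  split <- make_stratified_folds(ids, labels, k = k,
                                 seed = derive_seed(spec$seed, "folds"))
  fits <- vector("list", k)
  fold_tables <- vector("list", k)
  for (f in seq_len(k)) {
    sp <- split$splits[[f]]
    clin_enc <- if (!is.null(clinical)) {
      fit_clinical_encoder(clinical, sp$train_ids)
    }
    tr <- build_fold_bags(bags[sp$train_ids], spec, clinical, clin_enc)
    va <- build_fold_bags(bags[sp$val_ids], spec, clinical, clin_enc)
    te <- build_fold_bags(bags[sp$test_ids], spec, clinical, clin_enc)
    cfg <- train_cfg
    cfg$seed <- derive_seed(spec$seed, paste0("fold", f))
    fit <- train_attmil(tr, cfg, val_bags = va)
    fit$clinical_encoder <- clin_enc
    fits[[f]] <- fit
    fold_tables[[f]] <- predict_bags(fit, te,
                                     model_id = sprintf("fold%d", f - 1L),
                                     cohort = "internal")
  }
  scores <- do.call(rbind, fold_tables)
  reps <- data.frame(
    fold = seq_len(k) - 1L,
    auroc = vapply(fold_tables, auroc, 0),
    auprc_pos = vapply(fold_tables, auprc, 0, positive_class = "pos"),
    auprc_neg = vapply(fold_tables, auprc, 0, positive_class = "neg"))
  s <- function(v) summarize_replicates(v)
  report <- data.frame(
    target = spec$target, algorithm = spec$algorithm,
    encoder = spec$encoder_name, normalization = spec$normalization,
    auroc_mean = s(reps$auroc)$mean, auroc_ci = s(reps$auroc)$ci_half_width,
    auprc_pos_mean = s(reps$auprc_pos)$mean,
    auprc_pos_ci = s(reps$auprc_pos)$ci_half_width,
    auprc_neg_mean = s(reps$auprc_neg)$mean,
    auprc_neg_ci = s(reps$auprc_neg)$ci_half_width,
    stringsAsFactors = FALSE)
  thr95 <- in_domain_sensitivity_threshold(fold_tables)
  structure(list(spec = spec, report = report, replicates = reps,
                 scores = scores, fits = fits, split = split,
                 threshold_sens95 = thr95,
                 provenance = list(seed = spec$seed,
                                   input_hash = content_hash(lapply(bags, `[[`, "features")),
                                   n_patients = length(bags))),
            class = "cv_report")
}

#' External validation of a cross-validated experiment
#'
#' Deploys the fold models of a [run_internal_cv()] result on an external
#' cohort: per-model AUROC replicates (mean +/- CI) plus threshold
#' statistics (0.25 / 0.5 / 0.75 and the stored 95% in-domain sensitivity
#' threshold) computed on the averaged-score table.
#'
#' @param cv A `cv_report`.
#' @param external_bags Labeled bags of the external cohort. Multi-input
#'   and clinical-only experiments need `clinical` for the external
#'   patients; each fold model reuses its own training-fold clinical
#'   encoder.
#' @param clinical Optional external clinical table.
#' @param thresholds Fixed thresholds to report.
#' @return List with `summary` (AUROC mean/CI data frame), `replicates`,
#'   `thresholds` (per-threshold metric data frame), `averaged` score
#'   table, `normalization`.
#' @export
run_external_validation <- function(cv, external_bags, clinical = NULL,
                                    thresholds = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(cv, "cv_report"))
  have <- !vapply(external_bags, function(b) is.null(b$label), TRUE)
  if (!all(have)) {
    warning(sum(!have), " external patients lack labels; skipped",
            call. = FALSE)
    external_bags <- external_bags[have]
  }
  per_model <- lapply(seq_along(cv$fits), function(i) {
    bb <- build_fold_bags(external_bags, cv$spec, clinical,
                          cv$fits[[i]]$clinical_encoder)
    predict_bags(cv$fits[[i]], bb, model_id = sprintf("fold%d", i - 1L),
                 cohort = "external")
  })
  avg <- per_model[[1L]]
  avg$score <- rowMeans(do.call(cbind, lapply(per_model, `[[`, "score")))
  avg$model_id <- "averaged"
  reps <- vapply(per_model, auroc, 0)
  thr <- c(thresholds, sens95 = cv$threshold_sens95)
  thr_rows <- do.call(rbind, lapply(seq_along(thr), function(i) {
    m <- metrics_from_confusion(confusion_at_threshold(avg, thr[[i]]))
    data.frame(threshold = thr[[i]],
               kind = if (i > length(thresholds)) "sens95" else "fixed",
               t(m))
  }))
  sm <- summarize_replicates(reps)
  list(summary = data.frame(target = cv$spec$target,
                            algorithm = cv$spec$algorithm,
                            auroc_mean = sm$mean, auroc_ci = sm$ci_half_width),
       replicates = reps, thresholds = thr_rows, averaged = avg,
       normalization = cv$spec$normalization,
       provenance = list(seed = cv$spec$seed,
                         input_hash = content_hash(lapply(external_bags, `[[`, "features"))))
}

#' Write a cross-validation report to CSV and JSON
#'
#' @param cv A `cv_report`.
#' @param dir Output directory.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cv$report, file.path(dir, "report.csv"), row.names = FALSE)
  utils::write.csv(cv$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  jsonlite::write_json(list(spec = unclass(cv$spec), report = cv$report,
                            replicates = cv$replicates,
                            threshold_sens95 = cv$threshold_sens95,
                            provenance = cv$provenance),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
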