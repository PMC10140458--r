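#' Configuration for the witness-tile MIL simulator
#'
#' The generator emulates the weak-label structure of whole-slide biomarker
#' prediction: each patient contributes a bag of tile feature vectors and a
#' single binary label, but only a fraction of tiles in positive bags (the
#' "witness" tiles) actually carries the class signal. Negative-bag tiles are
#' standard normal in `dim` dimensions; in positive bags, `ceiling(witness_fraction
#' * k_total)` tiles are mean-shifted by `effect_size` along one seeded unit
#' direction.
#'
#' The defaults are the desk-scale study conditions used throughout the test
#' suite: D = 64 features, K = 64 tiles per bag, witness fraction 0.1, effect
#' size 3, 100 + 100 patients.
#'
#' @param n_pos,n_neg Patients per class.
#' @param k_total Tiles per bag.
#' @param dim Feature dimension D.
#' @param witness_fraction Fraction of tiles in a positive bag carrying
#'   signal, in (0, 1].
#' @param effect_size Mean shift of witness tiles along the signal direction.
#' @param noise_sd Isotropic noise standard deviation.
#' @param seed Integer seed; all randomness is a pure function of it.
#' @param direction_seed Seed of the signal direction. Defaults to `seed`,
#'   so one call defines one population; pin it across calls to draw
#'   independent cohorts (e.g. train and external validation) that share
#'   the same witness direction.
#' @return An object of class `mil_sim_config`.
#' @export
mil_sim_config <- function(n_pos = 100L, n_neg = 100L, k_total = 64L,
                           dim = 64L, witness_fraction = 0.1,
                           effect_size = 3, noise_sd = 1, seed = 1L,
                           direction_seed = seed) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, k_total >= 1L, dim >= 1L,
            witness_fraction > 0, witness_fraction <= 1, noise_sd >= 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 k_total = as.integer(k_total), dim = as.integer(dim),
                 witness_fraction = witness_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 direction_seed = as.integer(direction_seed)),
            class = "mil_sim_config")
}

#' Simulate MIL feature bags with witness-tile structure
#'
#' @param cfg A [mil_sim_config()].
#' @return A list of [feature_bag()] objects. Each bag carries its binary
#'   label and a logical `witness` vector marking the signal tiles (all
#'   `FALSE` for negative bags), used by attention-localization tests.
#' @export
make_mil_bags <- function(cfg) {
  stopifnot(inherits(cfg, "mil_sim_config"))
  u <- with_seed(cfg$direction_seed, {
    u <- rnorm(cfg$dim)
    u / sqrt(sum(u^2))
  })
  with_seed(cfg$seed, {
    n <- cfg$n_pos + cfg$n_neg
    labels <- rep(c(1L, 0L), c(cfg$n_pos, cfg$n_neg))
    n_wit <- ceiling(cfg$witness_fraction * cfg$k_total)
    lapply(seq_len(n), function(i) {
      X <- matrix(rnorm(cfg$k_total * cfg$dim, sd = cfg$noise_sd),
                  cfg$k_total, cfg$dim)
      wit <- rep(FALSE, cfg$k_total)
      if (labels[i] == 1L) {
        idx <- sample.int(cfg$k_total, n_wit)
        X[idx, ] <- X[idx, ] + rep(cfg$effect_size * u, each = n_wit)
        wit[idx] <- TRUE
      }
      pid <- sprintf("P%03d", i)
      coords <- cbind(grid_row = seq_len(cfg$k_total) - 1L,
                      grid_col = rep(0L, cfg$k_total))
      bag <- feature_bag(patient_id = pid, slide_id = pid, features = X,
                         tile_coords = coords, label = labels[i])
      bag$witness <- wit
      bag
    })
  })
}

#' Configuration for the clinical-covariate simulator
#'
#' Emulates covariates associated with a binary biomarker label the way
#' sidedness, organ, sex and age relate to microsatellite instability in
#' colorectal cohorts. Binary covariates are drawn from label-conditional
#' Bernoulli distributions with the configured log-odds shifts; age is
#' normal with a label-dependent mean shift.
#'
#' @param log_odds Named numeric vector with entries `sex`, `sidedness`,
#'   `organ`: additive log-odds of the "1" level (male / right / rectum) for
#'   positive-label patients. Baseline probabilities are 0.6 / 0.35 / 0.3.
#' @param age_shift_years Mean age difference (years) of positive patients;
#'   baseline mean 65, sd 10.
#' @param missing_rate Independent missingness probability per field.
#' @param seed Integer seed.
#' @export
clinical_sim_config <- function(log_odds = c(sex = 0, sidedness = 2, organ = 2),
                                age_shift_years = 0, missing_rate = 0,
                                seed = 1L) {
  stopifnot(all(is.finite(log_odds)), missing_rate >= 0, missing_rate < 1)
  lo <- c(sex = 0, sidedness = 0, organ = 0)
  lo[names(log_odds)] <- log_odds
  structure(list(log_odds = lo, age_shift_years = age_shift_years,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "clinical_sim_config")
}

#' Simulate a clinical covariate table
#'
#' @param labels Integer 0/1 labels, one per patient.
#' @param cfg A [clinical_sim_config()].
#' @param patient_ids Optional ids; defaults to `P001`, `P002`, ...
#' @return A data frame with columns `PATIENT`, `SEX` ("female"/"male"),
#'   `AGE`, `SIDEDNESS` ("left"/"right"), `ORGAN` ("colon"/"rectum");
#'   `NA` marks missing values.
#' @export
make_clinical <- function(labels, cfg = clinical_sim_config(),
                          patient_ids = sprintf("P%03d", seq_along(labels))) {
  stopifnot(inherits(cfg, "clinical_sim_config"), all(labels %in% c(0L, 1L)))
  with_seed(cfg$seed, {
    n <- length(labels)
    base <- c(sex = 0.60, sidedness = 0.35, organ = 0.30)
    draw <- function(field, lev0, lev1) {
      p <- stats::plogis(stats::qlogis(base[[field]]) +
                           cfg$log_odds[[field]] * labels)
      ifelse(stats::runif(n) < p, lev1, lev0)
    }
    sex <- draw("sex", "female", "male")
    side <- draw("sidedness", "left", "right")
    organ <- draw("organ", "colon", "rectum")
    age <- stats::rnorm(n, 65 + cfg$age_shift_years * labels, 10)
    age <- round(pmax(age, 18))
    if (cfg$missing_rate > 0) {
      blank <- function(x) {
        x[stats::runif(n) < cfg$missing_rate] <- NA
        x
      }
      sex <- blank(sex); side <- blank(side)
      organ <- blank(organ); age <- blank(age)
    }
    data.frame(PATIENT = patient_ids, SEX = sex, AGE = age,
               SIDEDNESS = side, ORGAN = organ, stringsAsFactors = FALSE)
  })
}

#' Simulate a score table with a requested AUROC
#'
#' Scores are drawn from the binormal model: negatives from N(0, 1),
#' positives from N(delta, 1) with `delta = sqrt(2) * qnorm(auc_target)`, so
#' the population AUROC is exactly `auc_target` (`pnorm(delta / sqrt(2))`).
#' The latent values are mapped to (0, 1) through the logistic function,
#' which is monotone and therefore AUROC-preserving. `auc_target = 1` is
#' handled by capping the separation at 6 standard deviations.
#'
#' @param n_pos,n_neg Patients per class.
#' @param auc_target Requested AUROC in \[0.5, 1\].
#' @param seed Integer seed.
#' @param model_id,cohort Tags copied into the table.
#' @return A score table data frame (`patient_id`, `label`, `score`,
#'   `model_id`, `cohort`).
#' @export
make_score_table <- function(n_pos, n_neg, auc_target, seed = 1L,
                             model_id = "sim", cohort = "sim") {
  stopifnot(auc_target >= 0.5, auc_target <= 1)
  delta <- min(sqrt(2) * stats::qnorm(auc_target), 6)
  with_seed(seed, {
    z <- c(stats::rnorm(n_pos, delta, 1), stats::rnorm(n_neg, 0, 1))
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n_pos + n_neg)),
      label = rep(c(1L, 0L), c(n_pos, n_neg)),
      score = stats::plogis(z),
      model_id = model_id, cohort = cohort,
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic two-stain tile from the stain mixing model
#'
#' Draws per-pixel hematoxylin/eosin concentrations and renders the tile
#' through the Beer-Lambert model `I = 256 * 10^(-(c1 s1 + c2 s2)) - 1`
#' with unit stain vectors, the exact generative model that Macenko
#' normalization inverts. Mixing fractions follow a Beta(0.5, 0.5) (mass
#' near the pure stains, so the percentile angle estimator can see them)
#' and total stain magnitudes are uniform on `mag`, high enough that pure
#' pixels stay above the optical-density floor in every channel.
#'
#' @param px_edge Tile edge length in pixels.
#' @param stain_matrix 3 x 2 matrix of stain vectors (columns are
#'   normalized internally); default: typical hematoxylin/eosin vectors.
#' @param mag Range of the per-pixel total stain magnitude.
#' @param pure_frac Fraction of pixels per stain that are exactly pure
#'   (hematoxylin-only nuclei, eosin-only stroma).
#' @param seed Integer seed.
#' @return List with `pixels` (RGB array 0..255), `concentrations`
#'   (n x 2), and `stain_matrix` (unit columns) — the ground truth.
#' @export
make_he_tile <- function(px_edge = 64L,
                         stain_matrix = cbind(c(0.65, 0.70, 0.29),
                                              c(0.21, 0.95, 0.15)),
                         mag = c(1.1, 2), pure_frac = 0.1, seed = 1L) {
  S <- apply(stain_matrix, 2L, function(v) v / sqrt(sum(v^2)))
  with_seed(seed, {
    n <- px_edge^2
    t <- stats::rbeta(n, 0.5, 0.5)
    n_pure <- round(pure_frac * n)
    if (n_pure > 0) {
      t[seq_len(n_pure)] <- 1
      t[seq_len(n_pure) + n_pure] <- 0
    }
    m <- stats::runif(n, mag[1L], mag[2L])
    conc <- cbind(m * t, m * (1 - t))
    OD <- conc %*% t(S)
    px <- array(pmin(pmax(round(256 * 10^(-OD) - 1), 0), 255),
                c(px_edge, px_edge, 3L))
    list(pixels = px, concentrations = conc, stain_matrix = S)
  })
}

#' Generate a synthetic slide raster with a known tissue mask
#'
#' Produces a white-background RGB raster with pink/purple textured
#' elliptical "tissue" blobs (speckled with dark nucleus-like dots so tiles
#' contain edges), optional saturated pen strokes, and optional
#' Gaussian-blurred patches. The returned mask marks tissue pixels and is
#' the ground truth for tile-QC recall/false-positive tests.
#'
#' @param width,height Raster size in pixels.
#' @param mpp Microns per pixel.
#' @param n_blobs Number of tissue blobs.
#' @param coverage Approximate fraction of the raster covered by tissue.
#' @param pen_marks,blur_patches Add artifacts.
#' @param seed Integer seed.
#' @return A list with `slide` (a [slide_raster()]) and `mask`
#'   (height x width logical matrix of tissue pixels).
#' @export
make_synthetic_slide <- function(width = 1024L, height = 768L, mpp = 1,
                                 n_blobs = 6L, coverage = 0.3,
                                 pen_marks = FALSE, blur_patches = FALSE,
                                 seed = 1L) {
  with_seed(seed, {
    h <- as.integer(height); w <- as.integer(width)
    px <- array(255, dim = c(h, w, 3L))
    mask <- matrix(FALSE, h, w)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    if (n_blobs > 0L) {
      # split the requested coverage across blobs; area pi*a*b
      area_per <- coverage * h * w / n_blobs
      for (b in seq_len(n_blobs)) {
        ar <- stats::runif(1, 0.6, 1.6)                      # aspect ratio
        a <- sqrt(area_per * ar / pi); bb <- area_per / (pi * a)
        cx <- stats::runif(1, a, w - a); cy <- stats::runif(1, bb, h - bb)
        th <- stats::runif(1, 0, pi)
        xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
        yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
        inside <- (xr / a)^2 + (yr / bb)^2 <= 1
        mask <- mask | inside
        # eosin-pink base with mild texture
        n_in <- sum(inside)
        if (n_in > 0) {
          tex <- stats::rnorm(n_in, 0, 8)
          px[, , 1L][inside] <- pmin(pmax(225 + tex, 0), 255)
          px[, , 2L][inside] <- pmin(pmax(160 + tex, 0), 255)
          px[, , 3L][inside] <- pmin(pmax(190 + tex, 0), 255)
          # hematoxylin-dark nuclei speckles: ~1.5% of blob pixels dilated
          idx <- which(inside)
          nuc <- sample(idx, max(1L, round(0.015 * n_in)))
          for (d in c(0L, 1L, h, h + 1L)) {   # 2x2 dots
            j <- nuc + d
            j <- j[j >= 1L & j <= h * w]
            px[, , 1L][j] <- 90; px[, , 2L][j] <- 60; px[, , 3L][j] <- 130
          }
        }
      }
    }
    if (pen_marks) {
      # a thick saturated green stroke across the slide
      x0 <- stats::runif(1, 0.1, 0.9) * w
      slope <- stats::runif(1, -0.5, 0.5)
      dist <- abs((xs - x0) * slope - (ys - h / 2)) / sqrt(slope^2 + 1)
      stroke <- dist < 6
      px[, , 1L][stroke] <- 20; px[, , 2L][stroke] <- 160; px[, , 3L][stroke] <- 40
    }
    if (blur_patches) {
      pw <- round(w / 5); ph <- round(h / 5)
      x1 <- sample.int(w - pw, 1L); y1 <- sample.int(h - ph, 1L)
      patch <- px[y1:(y1 + ph - 1L), x1:(x1 + pw - 1L), , drop = FALSE]
      blurred <- from_ebimage(EBImage::gblur(as_ebimage(patch), sigma = 4))
      px[y1:(y1 + ph - 1L), x1:(x1 + pw - 1L), ] <- blurred
    }
    slide <- slide_raster(slide_id = sprintf("SYN%06d", seed),
                          pixels = round(px), mpp = mpp)
    list(slide = slide, mask = mask)
  })
}
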