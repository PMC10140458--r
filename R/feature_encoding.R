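#' Define a tile encoder
#'
#' An encoder maps a prepared 224 x 224 x 3 tile array (see
#' [prepare_model_input()]) to a fixed-length feature vector. Encoders are
#' pluggable and frozen: the MIL head never trains them. Two reference
#' encoders ship with the package: [encoder_channel_mean()] (D = 3, the
#' per-channel means — handy for arithmetic oracles) and
#' [encoder_random_projection()] (seeded Gaussian projection of a pooled
#' thumbnail — a stand-in for a frozen pretrained network).
#'
#' @param name Encoder name (stored in bag metadata).
#' @param dim Output dimension D.
#' @param apply Function taking one prepared array, returning a D-vector of
#'   finite values.
#' @export
encoder_spec <- function(name, dim, apply) {
  stopifnot(is.character(name), dim >= 1L, is.function(apply))
  structure(list(name = name, dim = as.integer(dim), apply = apply),
            class = "encoder_spec")
}

#' @rdname encoder_spec
#' @export
encoder_channel_mean <- function() {
  encoder_spec("channel-mean", 3L,
               function(x) c(mean(x[, , 1L]), mean(x[, , 2L]), mean(x[, , 3L])))
}

#' @rdname encoder_spec
#' @param dim Output dimension.
#' @param pool_px Thumbnail edge length average-pooled before projection.
#' @param seed Seed for the fixed projection matrix.
#' @export
encoder_random_projection <- function(dim = 64L, pool_px = 16L, seed = 7L) {
  p <- pool_px^2 * 3L
  W <- with_seed(seed, matrix(stats::rnorm(p * dim, sd = 1 / sqrt(p)), p, dim))
  encoder_spec(sprintf("random-projection-%d", dim), dim, function(x) {
    th <- avg_pool_to(x, pool_px)
    as.vector(crossprod(matrix(as.vector(th), ncol = 1L), W))
  })
}

# Block average-pool an H x W x 3 array to out_px x out_px x 3.
avg_pool_to <- function(x, out_px) {
  h <- dim(x)[1L]
  idx <- ceiling(seq_len(h) / (h / out_px))
  out <- array(0, c(out_px, out_px, 3L))
  for (c in 1:3) {
    out[, , c] <- t(vapply(split(seq_len(h), idx), function(rr) {
      col <- vapply(split(seq_len(dim(x)[2L]),
                          ceiling(seq_len(dim(x)[2L]) / (dim(x)[2L] / out_px))),
                    function(cc) mean(x[rr, cc, c]), 0)
      col
    }, numeric(out_px)))
  }
  out
}

#' Construct a feature bag
#'
#' The per-patient container for MIL: a K x D matrix of tile feature
#' vectors, the tile grid coordinates aligned row-for-row, and an optional
#' binary label (0 = wild-type/MSS, 1 = mutated/MSI).
#'
#' @param patient_id,slide_id Identifiers.
#' @param features K x D numeric matrix, all values finite.
#' @param tile_coords K x 2 matrix of (grid_row, grid_col).
#' @param label Optional 0/1 label.
#' @export
feature_bag <- function(patient_id, slide_id, features, tile_coords,
                        label = NULL) {
  features <- as.matrix(features)
  tile_coords <- as.matrix(tile_coords)
  stopifnot(nrow(features) >= 1L, nrow(features) == nrow(tile_coords),
            all(is.finite(features)))
  if (!is.null(label)) stopifnot(label %in% c(0L, 1L))
  structure(list(patient_id = as.character(patient_id),
                 slide_id = as.character(slide_id),
                 features = features, tile_coords = tile_coords,
                 label = if (is.null(label)) NULL else as.integer(label),
                 n_image_cols = ncol(features)),
            class = "feature_bag")
}

#' Encode a slide's tiles into a feature bag
#'
#' @param tiles List of prepared tile arrays (or `tile_record`s, prepared on
#'   the fly), all QC-passed.
#' @param encoder An [encoder_spec()].
#' @param patient_id,slide_id,label Bag metadata.
#' @param tile_coords Optional K x 2 coordinates; taken from `tile_record`s
#'   when available.
#' @export
encode_slide <- function(tiles, encoder, patient_id, slide_id = patient_id,
                         label = NULL, tile_coords = NULL) {
  stopifnot(inherits(encoder, "encoder_spec"))
  if (length(tiles) == 0L) {
    stop("slide ", slide_id, " has zero QC-passed tiles; cannot build a bag",
         call. = FALSE)
  }
  if (is.null(tile_coords) && inherits(tiles[[1L]], "tile_record")) {
    tile_coords <- t(vapply(tiles, function(t) c(t$grid_row, t$grid_col),
                            integer(2L)))
  }
  arrays <- lapply(tiles, function(t) {
    if (inherits(t, "tile_record")) prepare_model_input(t) else t
  })
  feats <- t(vapply(arrays, function(a) {
    v <- encoder$apply(a)
    stopifnot(length(v) == encoder$dim, all(is.finite(v)))
    v
  }, numeric(encoder$dim)))
  if (is.null(tile_coords)) {
    tile_coords <- cbind(seq_along(tiles) - 1L, 0L)
  }
  bag <- feature_bag(patient_id, slide_id, feats, tile_coords, label)
  attr(bag, "encoder_name") <- encoder$name
  bag
}

#' Fit the clinical covariate encoder on training-fold patients
#'
#' Learns, per encoded dimension (sex: female = 0 / male = 1; sidedness:
#' left = 0 / right = 1; organ: colon = 0 / rectum = 1; age in years), the
#' training-fold mean used for imputation and the mean/sd used for
#' zero-centering and scaling. Statistics come exclusively from
#' `training_ids` — never from validation or test patients. Standardization
#' uses the population (n-denominator) standard deviation; a constant field
#' (sd = 0) or an all-missing field is encoded as constant 0 with a warning.
#'
#' @param records Clinical data frame with columns `PATIENT`, `SEX`, `AGE`,
#'   `SIDEDNESS`, `ORGAN` (`NA` = missing).
#' @param training_ids Patient ids of the training fold.
#' @return An object of class `clinical_encoder`.
#' @export
fit_clinical_encoder <- function(records, training_ids) {
  stopifnot(length(training_ids) >= 1L)
  tr <- records[records$PATIENT %in% training_ids, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no training records found", call. = FALSE)
  raw <- clinical_raw_matrix(tr)
  fit_dim <- function(x, nm) {
    obs <- x[!is.na(x)]
    if (length(obs) == 0L) {
      warning("clinical field ", nm, " entirely missing; encoded as 0",
              call. = FALSE)
      return(list(impute = 0, center = 0, scale = 1, drop = TRUE))
    }
    imp <- mean(obs)
    filled <- ifelse(is.na(x), imp, x)
    mu <- mean(filled)
    sd_pop <- sqrt(mean((filled - mu)^2))
    if (sd_pop == 0) {
      warning("clinical field ", nm, " constant in training fold; encoded as 0",
              call. = FALSE)
      return(list(impute = imp, center = mu, scale = 1, drop = TRUE))
    }
    list(impute = imp, center = mu, scale = sd_pop, drop = FALSE)
  }
  stats <- Map(fit_dim, asplit(raw, 2L), colnames(raw))
  structure(list(stats = stats, fields = colnames(raw)),
            class = "clinical_encoder")
}

# sex/sidedness/organ as 0/1, age numeric; NA preserved.
clinical_raw_matrix <- function(records) {
  lev01 <- function(x, one) {
    out <- rep(NA_real_, length(x))
    out[!is.na(x)] <- as.numeric(x[!is.na(x)] == one)
    out
  }
  cbind(sex = lev01(records$SEX, "male"),
        sidedness = lev01(records$SIDEDNESS, "right"),
        organ = lev01(records$ORGAN, "rectum"),
        age = suppressWarnings(as.numeric(records$AGE)))
}

#' Encode one clinical record as a 4-vector
#'
#' Missing fields are mean-imputed with the training-fold mean, then all
#' four dimensions are zero-centered and scaled by the training-fold
#' statistics, so a fully missing record encodes to the zero vector.
#' Unknown categorical levels are treated as missing.
#'
#' @param record One-row clinical data frame (columns as in
#'   [fit_clinical_encoder()]).
#' @param enc A fitted `clinical_encoder`.
#' @return Numeric 4-vector (sex, sidedness, organ, age).
#' @export
encode_clinical <- function(record, enc) {
  stopifnot(inherits(enc, "clinical_encoder"))
  raw <- clinical_raw_matrix(record)[1L, ]
  out <- vapply(seq_along(raw), function(i) {
    s <- enc$stats[[i]]
    if (isTRUE(s$drop)) return(0)
    x <- raw[i]
    if (is.na(x)) x <- s$impute
    (x - s$center) / s$scale
  }, 0)
  names(out) <- enc$fields
  out
}

#' Append a clinical vector to every tile row of a bag
#'
#' @param bag A [feature_bag()] of width D.
#' @param clin Length-4 clinical vector from [encode_clinical()].
#' @return A bag of width D + 4; the image column count is recorded so that
#'   [zero_image_features()] knows where the image block ends.
#' @export
attach_clinical <- function(bag, clin) {
  stopifnot(inherits(bag, "feature_bag"))
  d_img <- bag$n_image_cols
  bag$features <- cbind(bag$features,
                        matrix(rep(clin, each = nrow(bag$features)),
                               nrow(bag$features), length(clin)))
  bag$n_image_cols <- d_img
  bag
}

#' Zero out the image feature block of a bag
#'
#' The clinical-data-only ablation: with the image columns set to zero the
#' downstream MIL model can only use the appended clinical dimensions, so
#' its scores are independent of the image encoder.
#'
#' @param bag A bag with clinical columns attached.
#' @export
zero_image_features <- function(bag) {
  stopifnot(inherits(bag, "feature_bag"))
  if (ncol(bag$features) <= bag$n_image_cols) {
    stop("bag has no clinical columns attached", call. = FALSE)
  }
  bag$features[, seq_len(bag$n_image_cols)] <- 0
  bag
}

#' Randomly subsample a bag to at most k tiles
#'
#' Uniform sampling without replacement, used once per training epoch; bags
#' with at most `k` tiles are used whole.
#'
#' @param bag A [feature_bag()].
#' @param k Maximum tiles (512 in the reference protocol).
#' @param seed Optional seed for reproducible selection.
#' @export
sample_bag <- function(bag, k = 512L, seed = NULL) {
  stopifnot(inherits(bag, "feature_bag"), k >= 1L)
  n <- nrow(bag$features)
  if (n <= k) return(bag)
  idx <- with_seed(seed, sample.int(n, k))
  bag$features <- bag$features[idx, , drop = FALSE]
  bag$tile_coords <- bag$tile_coords[idx, , drop = FALSE]
  if (!is.null(bag$witness)) bag$witness <- bag$witness[idx]
  bag
}

#' Write / read a feature bag container
#'
#' One file per slide holding the K x D feature matrix, the K x 2 integer
#' coordinates and the bag attributes (patient id, label, encoder name,
#' dimension). The round trip is lossless.
#'
#' @param bag A [feature_bag()].
#' @param path Destination file (conventionally `.bag.rds`).
#' @export
write_feature_bag <- function(bag, path) {
  stopifnot(inherits(bag, "feature_bag"))
  payload <- list(format = "wsimil-bag", version = 1L,
                  feats = bag$features,
                  coords = bag$tile_coords,
                  patient_id = bag$patient_id, slide_id = bag$slide_id,
                  label = bag$label, witness = bag$witness,
                  n_image_cols = bag$n_image_cols,
                  encoder_name = attr(bag, "encoder_name") %||% NA_character_,
                  dim = ncol(bag$features))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_feature_bag
#' @export
read_feature_bag <- function(path) {
  p <- readRDS(path)
  if (!identical(p$format, "wsimil-bag")) {
    stop(path, " is not a feature-bag container", call. = FALSE)
  }
  bag <- feature_bag(p$patient_id, p$slide_id, p$feats, p$coords, p$label)
  bag$witness <- p$witness
  bag$n_image_cols <- p$n_image_cols
  attr(bag, "encoder_name") <- p$encoder_name
  bag
}
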