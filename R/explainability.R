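#' Normalized attention heatmap on the tile grid
#'
#' Places per-tile attention on the slide's (grid_row, grid_col) raster and
#' min-max normalizes it per slide: `(a - min) / (max - min)`, so the
#' displayed range is exactly \[0, 1\]. Grid positions without a tissue tile
#' are `NA`. With fewer than two distinct attention values the
#' normalization is degenerate and all values are set to 0 with a warning.
#'
#' @param prediction A `bag_prediction` from [forward_bag()] (or a numeric
#'   attention vector).
#' @param coords K x 2 matrix of (grid_row, grid_col); defaults to the
#'   prediction's coordinates.
#' @return A `heatmap_grid`: matrix with attribute `channel = "attention"`.
#' @export
attention_heatmap <- function(prediction, coords = NULL) {
  a <- if (inherits(prediction, "bag_prediction")) prediction$attention
       else prediction
  if (is.null(coords) && inherits(prediction, "bag_prediction")) {
    coords <- prediction$tile_coords
  }
  stopifnot(length(a) == nrow(coords))
  rng <- range(a)
  if (diff(rng) < .Machine$double.eps) {
    warning("attention constant across tiles; normalized map set to 0",
            call. = FALSE)
    a_norm <- rep(0, length(a))
  } else {
    a_norm <- (a - rng[1L]) / (rng[2L] - rng[1L])
  }
  place_on_grid(a_norm, coords, "attention")
}

#' Per-tile prediction heatmap
#'
#' Raw (unnormalized) positive-class tile probabilities placed on the grid
#' — the spatial "MSI-ness"/"BRAF-ness" map.
#'
#' @param tile_scores Length-K vector of probabilities in \[0, 1\].
#' @param coords K x 2 matrix of (grid_row, grid_col).
#' @export
prediction_heatmap <- function(tile_scores, coords) {
  stopifnot(length(tile_scores) == nrow(coords),
            all(tile_scores >= 0 & tile_scores <= 1))
  place_on_grid(tile_scores, coords, "prediction")
}

place_on_grid <- function(values, coords, channel) {
  nr <- max(coords[, 1L]) + 1L; nc <- max(coords[, 2L]) + 1L
  g <- matrix(NA_real_, nr, nc)
  g[cbind(coords[, 1L] + 1L, coords[, 2L] + 1L)] <- values
  structure(g, channel = channel, class = c("heatmap_grid", "matrix", "array"))
}

#' Render a heatmap grid to a PNG file
#'
#' Colormap and missing-tile color are presentation choices, not part of
#' the heatmap contract.
#'
#' @param grid A `heatmap_grid`.
#' @param path Output PNG path.
#' @param scale_px Pixels per grid cell.
#' @export
write_heatmap_png <- function(grid, path, scale_px = 16L) {
  pal <- grDevices::hcl.colors(256L, "viridis")
  idx <- pmin(pmax(round(unclass(grid) * 255) + 1L, 1L), 256L)
  col <- matrix("#FFFFFF", nrow(grid), ncol(grid))
  col[!is.na(idx)] <- pal[idx[!is.na(idx)]]
  rgb <- grDevices::col2rgb(col) / 255
  img <- array(0, c(nrow(grid), ncol(grid), 3L))
  for (c in 1:3) img[, , c] <- matrix(rgb[c, ], nrow(grid), ncol(grid))
  big <- img[rep(seq_len(nrow(grid)), each = scale_px),
             rep(seq_len(ncol(grid)), each = scale_px), , drop = FALSE]
  png::writePNG(big, path)
  invisible(path)
}

#' Select the top-scoring tiles for gallery display
#'
#' Patients are ranked by their overall bag score; within each of the top
#' `n_patients`, tiles are ranked by the product of the tile's attention
#' and the tile's classification score. Tiers cut the ranking at
#' `ceiling(tier * K)` tiles (a tier given as an integer >= 1 is an
#' absolute count, e.g. top-1). Ties are broken deterministically by
#' (product descending, grid_row, grid_col), so the selection is invariant
#' to the input order.
#'
#' @param predictions List of `bag_prediction`s with `tile_scores`
#'   computed (see [forward_bag()] with `tile_scores = TRUE`).
#' @param tiers Numeric tiers: integers >= 1 are absolute counts, fractions
#'   in (0, 1) are percentiles. Default: top-1, top 5%, top 10%.
#' @param n_patients Number of highest-scoring patients to include.
#' @return Data frame with `patient_id`, `patient_rank`, `tier`, `rank`,
#'   `grid_row`, `grid_col`, `attention`, `tile_score`, `product`.
#' @export
select_top_tiles <- function(predictions, tiers = c(1, 0.05, 0.10),
                             n_patients = 3L) {
  stopifnot(length(predictions) >= 1L)
  scores <- vapply(predictions, `[[`, 0, "score")
  top_pat <- order(-scores)[seq_len(min(n_patients, length(predictions)))]
  out <- list()
  for (pr in seq_along(top_pat)) {
    p <- predictions[[top_pat[pr]]]
    if (is.null(p$tile_scores)) {
      stop("predictions must carry tile_scores", call. = FALSE)
    }
    prod <- p$attention * p$tile_scores
    ord <- order(-prod, p$tile_coords[, 1L], p$tile_coords[, 2L])
    K <- length(prod)
    for (tier in tiers) {
      n_tier <- if (tier >= 1) as.integer(tier) else ceiling(tier * K)
      if (n_tier > K) {
        warning("tier ", tier, " truncated to bag size ", K, call. = FALSE)
        n_tier <- K
      }
      sel <- ord[seq_len(n_tier)]
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p$patient_id, patient_rank = pr, tier = tier,
        rank = seq_len(n_tier),
        grid_row = p$tile_coords[sel, 1L], grid_col = p$tile_coords[sel, 2L],
        attention = p$attention[sel], tile_score = p$tile_scores[sel],
        product = prod[sel], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Grad-CAM saliency map for a tile-level convolutional classifier
#'
#' Gradient-weighted class activation mapping: the gradients of the
#' target-class logit with respect to the designated convolutional feature
#' layer are averaged spatially into channel weights, the rectified
#' weighted activation sum is upsampled bilinearly to the tile size and
#' min-max normalized to \[0, 1\]. Only models with spatial feature maps
#' support this; the attention-MIL head works on precomputed feature
#' vectors and is refused unless its encoder is itself a differentiable
#' tile model.
#'
#' @param tile A raw RGB array (0..255) or `tile_record`.
#' @param fit An `inpt_fit` whose backbone exposes feature maps.
#' @param target_class 0 or 1.
#' @return List with `map` (tile-sized matrix in \[0, 1\]), `weights`
#'   (per-channel), and `degenerate` (TRUE when the map was constant).
#' @export
grad_cam <- function(tile, fit, target_class = 1L) {
  stopifnot(inherits(fit, "inpt_fit"), target_class %in% c(0L, 1L))
  bb <- fit$backbone
  if (!isTRUE(bb$has_feature_maps)) {
    stop("model has no spatial feature maps; Grad-CAM unsupported",
         call. = FALSE)
  }
  px <- if (inherits(tile, "tile_record")) tile$pixels else tile
  x <- prepare_model_input(px, out_px = bb$input_px)
  fw <- bb$forward(fit$params, x)
  # gradient of the target-class softmax score through the logits; for a
  # two-class head this follows the discriminative (logit-difference)
  # direction rather than one raw logit's weights
  p <- softmax_vec(fw$logits)
  onehot <- c(0, 0); onehot[target_class + 1L] <- 1
  dlogits <- p[target_class + 1L] * (onehot - p)
  dfeat <- bb$backward(fit$params, fw$cache, dlogits,
                       to_features_only = TRUE)$dfeat
  wts <- apply(dfeat, 3L, mean)
  A <- fw$feature_maps
  cam <- matrix(0, dim(A)[1L], dim(A)[2L])
  for (c in seq_len(dim(A)[3L])) cam <- cam + wts[c] * A[, , c]
  cam <- pmax(cam, 0)
  rng <- range(cam)
  degenerate <- diff(rng) < .Machine$double.eps
  if (degenerate) {
    warning("Grad-CAM map is constant (degenerate)", call. = FALSE)
    cam <- matrix(0, dim(A)[1L], dim(A)[2L])
  } else {
    cam <- (cam - rng[1L]) / (rng[2L] - rng[1L])
  }
  up <- EBImage::resize(EBImage::Image(t(cam)), w = ncol(px), h = nrow(px))
  list(map = t(EBImage::imageData(up)), weights = wts,
       degenerate = degenerate)
}
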