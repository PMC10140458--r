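#' Construct a slide raster
#'
#' A plain in-memory stand-in for a whole-slide image: an 8-bit RGB raster
#' plus its physical resolution in microns per pixel. Pyramidal formats are
#' out of scope; any reader that can produce an RGB array at a known mpp can
#' feed the same contract.
#'
#' @param slide_id Character identifier.
#' @param pixels height x width x 3 numeric array with values in \[0, 255\].
#' @param mpp Microns per pixel (> 0).
#' @export
slide_raster <- function(slide_id, pixels, mpp) {
  stopifnot_rgb(pixels, "slide pixels")
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0) {
    stop("mpp must be a single positive number", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(slide_id = as.character(slide_id), pixels = pixels,
                 mpp = mpp),
            class = "slide_raster")
}

#' Read a PNG or TIFF raster as a slide
#'
#' @param path Image file (.png/.tif/.tiff).
#' @param mpp Microns per pixel of the raster.
#' @param slide_id Defaults to the file name without extension.
#' @export
read_slide <- function(path, mpp,
                       slide_id = tools::file_path_sans_ext(basename(path))) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  slide_raster(slide_id, round(img * 255), mpp)
}

tile_record <- function(slide_id, grid_row, grid_col, origin_x, origin_y,
                        edge_px_source, pixels) {
  structure(list(slide_id = slide_id, grid_row = as.integer(grid_row),
                 grid_col = as.integer(grid_col),
                 origin_x = as.integer(origin_x),
                 origin_y = as.integer(origin_y),
                 edge_px_source = as.integer(edge_px_source),
                 pixels = pixels),
            class = "tile_record")
}

#' Tessellate a slide into tiles of fixed physical edge length
#'
#' Cuts the raster into a regular non-overlapping grid whose step in source
#' pixels is `round(tile_um / mpp)` (256 µm by default), discards partial
#' tiles at the right/bottom edges, and resamples each tile to
#' `tile_px` x `tile_px` by bilinear interpolation. Coordinates are 0-based
#' with origin at the top-left corner; a tile occupies the half-open pixel
#' interval `[origin, origin + edge_px_source)`.
#'
#' @param slide A [slide_raster()].
#' @param tile_um Physical tile edge length in microns.
#' @param tile_px Output tile edge length in pixels.
#' @return A list of `tile_record` objects (possibly empty when the slide is
#'   smaller than one tile).
#' @export
tessellate <- function(slide, tile_um = 256, tile_px = 512L) {
  stopifnot(inherits(slide, "slide_raster"))
  step <- round(tile_um / slide$mpp)
  if (step < 1) stop("tile_um / mpp must be at least one pixel", call. = FALSE)
  h <- dim(slide$pixels)[1L]; w <- dim(slide$pixels)[2L]
  n_rows <- floor(h / step); n_cols <- floor(w / step)
  if (n_rows < 1L || n_cols < 1L) return(list())
  out <- vector("list", n_rows * n_cols)
  i <- 0L
  for (r in seq_len(n_rows) - 1L) {
    for (cc in seq_len(n_cols) - 1L) {
      oy <- r * step; ox <- cc * step
      sub <- slide$pixels[(oy + 1L):(oy + step), (ox + 1L):(ox + step), ,
                          drop = FALSE]
      if (step != tile_px) {
        sub <- from_ebimage(EBImage::resize(as_ebimage(sub), w = tile_px,
                                            h = tile_px))
        sub <- pmin(pmax(sub, 0), 255)
      }
      i <- i + 1L
      out[[i]] <- tile_record(slide$slide_id, r, cc, ox, oy, step, sub)
    }
  }
  out
}

# Canny edge detection returning a logical edge mask.
# Gaussian smoothing at `sigma`, Sobel gradients, non-maximum suppression,
# hysteresis with thresholds at the 10th/90th percentile of the nonzero
# gradient magnitudes (weak edges kept only in components touching strong
# ones, 8-connectivity).
canny_edges <- function(gray, sigma = 1, q_low = 0.10, q_high = 0.90) {
  h <- nrow(gray); w <- ncol(gray)
  img <- EBImage::gblur(EBImage::Image(t(gray) / 255), sigma = sigma)
  sm <- t(EBImage::imageData(img)) * 255
  # Sobel gradients via replicate-padded shifts
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- sm
  p[1L, ] <- p[2L, ]; p[h + 2L, ] <- p[h + 1L, ]
  p[, 1L] <- p[, 2L]; p[, w + 2L] <- p[, w + 1L]
  shp <- function(dy, dx) p[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
  gx <- (shp(-1L, 1L) + 2 * shp(0L, 1L) + shp(1L, 1L)) -
    (shp(-1L, -1L) + 2 * shp(0L, -1L) + shp(1L, -1L))
  gy <- (shp(1L, -1L) + 2 * shp(1L, 0L) + shp(1L, 1L)) -
    (shp(-1L, -1L) + 2 * shp(-1L, 0L) + shp(-1L, 1L))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) < 1e-6) return(matrix(FALSE, h, w))
  hi <- stats::quantile(mag[mag > 0], q_high, names = FALSE)
  lo <- stats::quantile(mag[mag > 0], q_low, names = FALSE)
  hi <- max(hi, 1e-6); lo <- min(lo, hi)
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  pad <- matrix(0, h + 2L, w + 2L); pad[2:(h + 1L), 2:(w + 1L)] <- mag
  sh <- function(dy, dx) pad[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  s0 <- sector == 0; n1[s0] <- sh(0L, 1L)[s0];  n2[s0] <- sh(0L, -1L)[s0]
  s1 <- sector == 1; n1[s1] <- sh(-1L, 1L)[s1]; n2[s1] <- sh(1L, -1L)[s1]
  s2 <- sector == 2; n1[s2] <- sh(-1L, 0L)[s2]; n2[s2] <- sh(1L, 0L)[s2]
  s3 <- sector == 3; n1[s3] <- sh(-1L, -1L)[s3]; n2[s3] <- sh(1L, 1L)[s3]
  peak <- mag >= n1 & mag >= n2
  strong <- peak & mag >= hi
  weak <- peak & mag >= lo
  if (!any(strong)) return(matrix(FALSE, h, w))
  lab <- EBImage::bwlabel(EBImage::Image(t(weak)))
  labm <- t(EBImage::imageData(lab))
  keep <- unique(labm[strong])
  keep <- keep[keep > 0]
  matrix(labm %in% keep, h, w) & weak
}

# Count of connected edge objects (8-connectivity) in an edge mask.
count_edge_objects <- function(edges) {
  if (!any(edges)) return(0L)
  max(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(edges)))))
}

#' Tissue quality control for a tile
#'
#' Applies the two tissue-detection rules used for tile selection: the sum
#' of the per-channel median brightness must be below 660 (rejects white
#' background), and the tile must contain at least four edge objects
#' (connected components of Canny edge pixels, 8-connectivity; rejects
#' homogeneous non-tissue regions). The Canny detector runs on the luma
#' grayscale at sigma = 1 with hysteresis thresholds at the 10th/90th
#' percentile of the gradient magnitude.
#'
#' @param tile A `tile_record` or a height x width x 3 RGB array (0..255).
#' @param brightness_max Brightness-sum threshold (default 660).
#' @param min_edges Minimum edge-object count (default 4).
#' @return A list of class `qc_result`: `brightness_sum`, `edge_count`,
#'   `blur_score`, `passed_tissue`, `passed_blur`.
#' @export
qc_tissue <- function(tile, brightness_max = 660, min_edges = 4L) {
  px <- if (inherits(tile, "tile_record")) tile$pixels else tile
  stopifnot_rgb(px, "tile")
  brightness <- stats::median(px[, , 1L]) + stats::median(px[, , 2L]) +
    stats::median(px[, , 3L])
  edges <- canny_edges(to_gray(px))
  n_edges <- count_edge_objects(edges)
  blur <- blur_score(px)
  structure(list(brightness_sum = brightness, edge_count = n_edges,
                 blur_score = blur,
                 passed_tissue = brightness < brightness_max &&
                   n_edges >= min_edges,
                 passed_blur = blur >= 80),
            class = "qc_result")
}

#' Variance-of-Laplacian blur score
#'
#' Convolves the luma grayscale tile with the 3x3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` (replicate padding at the borders) and
#' returns the variance of the response. Sharp texture gives high scores;
#' a constant tile scores exactly 0. Scores below 80 flag a tile as blurry
#' or homogeneous — flagging only, never an exclusion criterion.
#'
#' @param tile A `tile_record` or RGB array (0..255).
#' @return Nonnegative scalar.
#' @export
blur_score <- function(tile) {
  px <- if (inherits(tile, "tile_record")) tile$pixels else tile
  g <- if (length(dim(px)) == 3L) to_gray(px) else px
  h <- nrow(g); w <- ncol(g)
  # replicate-pad by one pixel, then 4-neighbour sum minus 4x centre
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- g
  p[1L, ] <- p[2L, ]; p[h + 2L, ] <- p[h + 1L, ]
  p[, 1L] <- p[, 2L]; p[, w + 2L] <- p[, w + 1L]
  lap <- p[1:h, 2:(w + 1L)] + p[3:(h + 2L), 2:(w + 1L)] +
    p[2:(h + 1L), 1:w] + p[2:(h + 1L), 3:(w + 2L)] - 4 * g
  stats::var(as.vector(lap))
}

# Optical density of 8-bit intensities: OD = -log10((I + 1) / 256).
od_transform <- function(px) -log10((px + 1) / 256)

od_inverse <- function(od) 256 * 10^(-od) - 1

# Vectorized nonnegative least squares against a 3x2 stain matrix:
# closed form for two variables (solve unconstrained, clamp to axes).
nnls_conc <- function(S, OD) {
  G <- crossprod(S)            # 2x2
  B <- OD %*% S                # n x 2, rhs S^T od
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  c1 <- (G[2, 2] * B[, 1] - G[1, 2] * B[, 2]) / det
  c2 <- (G[1, 1] * B[, 2] - G[1, 2] * B[, 1]) / det
  bad <- c1 < 0 | c2 < 0
  if (any(bad)) {
    a1 <- pmax(B[bad, 1] / G[1, 1], 0)     # c2 = 0 solution
    a2 <- pmax(B[bad, 2] / G[2, 2], 0)     # c1 = 0 solution
    r1 <- rowSums(OD[bad, , drop = FALSE]^2) - 2 * a1 * B[bad, 1] +
      a1^2 * G[1, 1]
    r2 <- rowSums(OD[bad, , drop = FALSE]^2) - 2 * a2 * B[bad, 2] +
      a2^2 * G[2, 2]
    use1 <- r1 <= r2
    c1[bad] <- ifelse(use1, a1, 0)
    c2[bad] <- ifelse(use1, 0, a2)
  }
  cbind(c1, c2)
}

# Fit the Macenko stain model to a pixel cloud. Returns stain matrix (3x2,
# unit columns, hematoxylin first) and the 99th-percentile concentrations.
fit_stain_core <- function(px, beta = 0.15, alpha = 0.01, conc_q = 0.99,
                           min_pixels = 50L) {
  OD <- od_transform(matrix(px, ncol = 3L))
  keep <- rowSums(OD < beta) == 0
  ODk <- OD[keep, , drop = FALSE]
  if (nrow(ODk) < min_pixels) {
    stop("degenerate stain reference: fewer than ", min_pixels,
         " pixels above the optical-density floor", call. = FALSE)
  }
  e <- eigen(stats::cov(ODk), symmetric = TRUE)
  basis <- e$vectors[, 1:2, drop = FALSE]    # plane of top-2 components
  proj <- ODk %*% basis
  # orient basis so projections are mostly positive (keeps the angle
  # distribution away from the atan2 branch cut)
  flip <- colMeans(proj) < 0
  basis[, flip] <- -basis[, flip]
  proj[, flip] <- -proj[, flip]
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha, 1 - alpha), names = FALSE)
  v1 <- basis %*% c(cos(q[1]), sin(q[1]))
  v2 <- basis %*% c(cos(q[2]), sin(q[2]))
  fix <- function(v) {                       # nonnegative OD orientation
    if (sum(v) < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  v1 <- fix(v1); v2 <- fix(v2)
  collapsed <- abs(sum(v1 * v2)) > cos(2 * pi / 180)
  # hematoxylin first: larger blue-channel OD component
  S <- if (v1[3] >= v2[3]) cbind(v1, v2) else cbind(v2, v1)
  colnames(S) <- c("hematoxylin", "eosin")
  conc <- nnls_conc(S, ODk)
  maxc <- pmax(apply(conc, 2L, stats::quantile, probs = conc_q), 1e-6)
  list(stain_matrix = S, max_concentrations = maxc, collapsed = collapsed)
}

#' Fit a Macenko stain reference from a reference tile
#'
#' Estimates the hematoxylin/eosin stain vectors from the optical-density
#' distribution of the tile: pixels with any channel below the OD floor
#' (beta = 0.15) are discarded, the remaining OD cloud is projected on the
#' plane of its top two principal directions, and the stain vectors are
#' taken at the 1st/99th percentile angles within that plane, oriented to
#' nonnegative OD, unit norm, hematoxylin first (larger blue-channel
#' component). Robust maximum concentrations are the 99th percentile of
#' per-pixel nonnegative-least-squares concentrations.
#'
#' @param reference_tile A `tile_record` or RGB array (0..255).
#' @param beta Optical-density floor.
#' @param alpha Angle percentile (alpha and 1 - alpha).
#' @param conc_q Concentration percentile.
#' @param min_pixels Minimum above-floor pixel count.
#' @return An object of class `stain_reference` with `stain_matrix` (3x2)
#'   and `max_concentrations` (length-2). If the two stain directions
#'   collapse within 2 degrees (single-stain input) the result is flagged
#'   via a warning and the `collapsed` field.
#' @export
fit_stain_reference <- function(reference_tile, beta = 0.15, alpha = 0.01,
                                conc_q = 0.99, min_pixels = 50L) {
  px <- if (inherits(reference_tile, "tile_record")) reference_tile$pixels
        else reference_tile
  stopifnot_rgb(px, "reference tile")
  fit <- fit_stain_core(px, beta, alpha, conc_q, min_pixels)
  if (fit$collapsed) {
    warning("stain directions collapsed toward a single stain", call. = FALSE)
  }
  structure(fit, class = "stain_reference")
}

#' Macenko color normalization of a tile against a reference
#'
#' Estimates the tile's own stain matrix and robust maximum concentrations
#' (same procedure as [fit_stain_reference()]), rescales each pixel's stain
#' concentrations by `ref$max_concentrations / tile_max_concentrations`, and
#' reconstructs the image through the reference stain matrix. Output is
#' clipped to \[0, 255\] and rounded. A degenerate tile (too few pixels above
#' the OD floor, e.g. pure background) is returned unchanged with a warning
#' and attribute `macenko_skipped = TRUE`.
#'
#' @param tile A `tile_record` or RGB array.
#' @param ref A `stain_reference`.
#' @inheritParams fit_stain_reference
#' @return Same type as `tile`, with normalized pixels.
#' @export
macenko_normalize <- function(tile, ref, beta = 0.15, alpha = 0.01,
                              conc_q = 0.99, min_pixels = 50L) {
  stopifnot(inherits(ref, "stain_reference"))
  px <- if (inherits(tile, "tile_record")) tile$pixels else tile
  stopifnot_rgb(px, "tile")
  fit <- tryCatch(fit_stain_core(px, beta, alpha, conc_q, min_pixels),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("tile has no stain signal; returned unnormalized", call. = FALSE)
    attr(tile, "macenko_skipped") <- TRUE
    return(tile)
  }
  d <- dim(px)
  OD <- od_transform(matrix(px, ncol = 3L))
  conc <- nnls_conc(fit$stain_matrix, OD)
  conc <- conc * rep(ref$max_concentrations / fit$max_concentrations,
                     each = nrow(conc))
  out <- od_inverse(conc %*% t(ref$stain_matrix))
  out <- array(pmin(pmax(round(out), 0), 255), dim = d)
  if (inherits(tile, "tile_record")) {
    tile$pixels <- out
    tile
  } else out
}

#' Prepare a tile array for a convolutional encoder
#'
#' Bilinear resize to `out_px` (224 by default), rescale to \[0, 1\], and
#' per-channel standardization with the ImageNet RGB statistics
#' mean = (0.485, 0.456, 0.406), sd = (0.229, 0.224, 0.225).
#'
#' @param tile A `tile_record` or RGB array (0..255).
#' @param out_px Output edge length in pixels.
#' @return An `out_px` x `out_px` x 3 numeric array.
#' @export
prepare_model_input <- function(tile, out_px = 224L) {
  px <- if (inherits(tile, "tile_record")) tile$pixels else tile
  stopifnot_rgb(px, "tile")
  if (nrow(px) != out_px || ncol(px) != out_px) {
    px <- from_ebimage(EBImage::resize(as_ebimage(px), w = out_px, h = out_px))
    px <- pmin(pmax(px, 0), 255)
  }
  x <- px / 255
  mean <- c(0.485, 0.456, 0.406); sd <- c(0.229, 0.224, 0.225)
  for (c in 1:3) x[, , c] <- (x[, , c] - mean[c]) / sd[c]
  x
}

#' Read a slide manifest
#'
#' @param path CSV with columns `PATIENT`, `FILENAME`, `MPP`, `TARGET`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("PATIENT", "FILENAME", "MPP", "TARGET")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m
}

#' Tessellate, QC and optionally normalize one slide to disk
#'
#' Writes QC-passed tiles as PNG files named `<slide>_<row>_<col>.png` and
#' returns (and writes) a per-tile QC table.
#'
#' @param slide A [slide_raster()].
#' @param out_dir Output directory for tiles and `<slide>_tiles.csv`.
#' @param ref Optional `stain_reference` for Macenko normalization.
#' @param tile_um,tile_px Passed to [tessellate()].
#' @return Invisibly, the QC data frame (one row per tile, all tiles).
#' @export
process_slide <- function(slide, out_dir, ref = NULL, tile_um = 256,
                          tile_px = 512L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tiles <- tessellate(slide, tile_um = tile_um, tile_px = tile_px)
  rows <- lapply(tiles, function(t) {
    qc <- qc_tissue(t)
    if (qc$passed_tissue) {
      out <- if (!is.null(ref)) macenko_normalize(t, ref) else t
      png::writePNG(out$pixels / 255,
                    file.path(out_dir, sprintf("%s_%d_%d.png", t$slide_id,
                                               t$grid_row, t$grid_col)))
    }
    data.frame(slide_id = t$slide_id, grid_row = t$grid_row,
               grid_col = t$grid_col, origin_x = t$origin_x,
               origin_y = t$origin_y, brightness_sum = qc$brightness_sum,
               edge_count = qc$edge_count, blur_score = qc$blur_score,
               passed_tissue = qc$passed_tissue,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(df)) {
    utils::write.csv(df, file.path(out_dir,
                                   paste0(slide$slide_id, "_tiles.csv")),
                     row.names = FALSE)
  }
  invisible(df)
}
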