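#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG state. If `seed` is NULL the current
# stream is used (and advanced); otherwise the global stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed and a stream label, staying well
# inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# RGB (H x W x 3, 0..255) <-> EBImage Image (x = width, y = height, 0..1)
as_ebimage <- function(px) {
  EBImage::Image(aperm(px, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

from_ebimage <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) d <- array(d, dim = c(dim(d), 1L))
  aperm(d, c(2L, 1L, 3L)) * 255
}

# Luma grayscale on the 0..255 scale.
to_gray <- function(px) {
  0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
}

stopifnot_rgb <- function(px, what = "image") {
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3L] != 3L) {
    stop(what, " must be a height x width x 3 RGB array", call. = FALSE)
  }
  invisible(px)
}

# Content hash for provenance records: md5 of the serialized object.
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
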