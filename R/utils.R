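# internal helpers shared across modules

# EBImage operators return Image objects; downstream code works on plain
# matrices throughout.
as_mat <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  x
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(as_mat(img))
  as_mat(EBImage::gblur(as_mat(img), sigma = sigma, boundary = "replicate"))
}

# validate an image raster: finite, non-negative, >= 1x1
assert_image <- function(img, arg = "img") {
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must be a matrix with at least one row and column", arg))
  }
  if (!all(is.finite(img)) || any(img < 0)) {
    stop(sprintf("`%s` must contain finite, non-negative values", arg))
  }
  invisible(img)
}

quantile_pair <- function(img, q_low, q_high) {
  stats::quantile(img, c(q_low, q_high), names = FALSE, type = 7)
}
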