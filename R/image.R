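# Scene images are plain numeric arrays H x W x 3 on the 8-bit scale
# (0..255, not clipped internally). PNG is the interchange format: it is
# lossless, which is mandatory for generated color references.

#' Read a scene image
#'
#' @param path PNG file path.
#' @return Numeric H x W x 3 array on the 0-255 scale.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Write a scene image
#'
#' Values are clipped to [0, 255] at export only.
#'
#' @param img Numeric H x W x 3 array, 0-255 scale.
#' @param path Output PNG path.
#' @export
write_image <- function(img, path) {
  png::writePNG(clip255(img) / 255, path)
  invisible(path)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Rec.601 relative luminance on the 8-bit scale; `rgb` is length-3 or n x 3
rgb_luminance <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3L)
  as.numeric(rgb %*% c(0.299, 0.587, 0.114))
}

# grayscale H x W matrix from an H x W x 3 array
img_luminance <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# Otsu threshold on a numeric matrix (0-255 scale)
otsu_threshold <- function(g) {
  h <- tabulate(pmin(pmax(as.integer(g) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L
}

# bilinear sampling of img at (x, y) pixel-center coordinates (0-based,
# x = column); points outside the image return `fill`
bilinear_sample <- function(img, x, y, fill = 255) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- matrix(fill, length(x), 3L)
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  for (ch in 1:3) {
    plane <- img[, , ch]
    idx <- function(yy, xx) plane[cbind(yy + 1L, xx + 1L)]
    v <- (1 - fx[ok]) * (1 - fy[ok]) * idx(y0[ok], x0[ok]) +
      fx[ok] * (1 - fy[ok]) * idx(y0[ok], x1[ok]) +
      (1 - fx[ok]) * fy[ok] * idx(y1[ok], x0[ok]) +
      fx[ok] * fy[ok] * idx(y1[ok], x1[ok])
    col <- out[, ch]
    col[ok] <- v
    out[, ch] <- col
  }
  out
}
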