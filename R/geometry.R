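# Planar projective geometry: homography estimation (normalized DLT) and
# image warping by inverse mapping with bilinear resampling.
# Points are (x, y) pixel coordinates, x = column, 0-based.

#' Fit a projective homography from point correspondences
#'
#' Normalized direct linear transform; with exactly four points the map is
#' exact, with more it is least-squares.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) points, n >= 4.
#' @return 3 x 3 homography matrix H with \code{dst ~ H \%*\% (src, 1)}.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) >= 4L, nrow(src) == nrow(dst), ncol(src) == 2L)
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- rbind(c(s, 0, -s * ctr[1L]), c(0, s, -s * ctr[2L]), c(0, 0, 1))
    list(p = cbind(p[, 1L] * s - s * ctr[1L], p[, 2L] * s - s * ctr[2L]), T = T)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1L]; y <- ns$p[i, 2L]
    u <- nd$p[i, 1L]; v <- nd$p[i, 2L]
    A[2L * i - 1L, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2L * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9L]
  H <- solve(nd$T) %*% matrix(h, 3L, 3L, byrow = TRUE) %*% ns$T
  if (abs(H[3L, 3L]) < 1e-12)
    stop("degenerate homography (near-singular normalization)")
  H / H[3L, 3L]
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography.
#' @param pts n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  p <- cbind(pts, 1) %*% t(H)
  w <- p[, 3L]
  if (any(abs(w) < 1e-12)) stop("point maps to infinity under homography")
  cbind(p[, 1L] / w, p[, 2L] / w)
}

# warp `img` into an out_h x out_w canvas where H maps source pixel (x,y)
# to output pixel (x,y); inverse mapping + bilinear interpolation
warp_image <- function(img, H, out_w, out_h, fill = 255) {
  Hi <- solve(H)
  det3 <- det(H)
  if (!is.finite(det3) || abs(det3) < 1e-10)
    stop("degenerate homography (determinant ~ 0)")
  grid_x <- rep(0:(out_w - 1L), each = out_h)
  grid_y <- rep(0:(out_h - 1L), times = out_w)
  srcp <- apply_homography(Hi, cbind(grid_x, grid_y))
  vals <- bilinear_sample(img, srcp[, 1L], srcp[, 2L], fill = fill)
  out <- array(0, c(out_h, out_w, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(vals[, ch], out_h, out_w)
  out
}
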