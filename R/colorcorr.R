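# Thin-plate-spline color correction.
#
# The captured palette colors c_i (under the unknown illuminant and device)
# and their reference values r_i (the palette as defined under the 6500 K
# reference condition) are interpolation pairs for three scalar maps
# f_k : R^3 -> R, one per output channel:
#
#   f_k(c) = a0_k + a_k . c + sum_i w_ik phi(||c - c_i||)
#
# solved per channel from the block system
#
#   [ K + lambda I   P ] [ w ]   [ y ]
#   [     P^T        0 ] [ a ] = [ 0 ],   K_ij = phi(||c_i - c_j||),
#
# with P_i = (1, c_i^T). At lambda = 0 the map interpolates the pairs
# exactly; lambda > 0 trades fidelity at the control points for smoothness.
# The side conditions P^T w = 0 make the radial part orthogonal to the
# affine part. Colors are raw 8-bit sRGB values, not linearized.

tps_kernel <- function(r, kernel = c("r2logr", "r")) {
  kernel <- match.arg(kernel)
  if (kernel == "r") return(r)
  out <- numeric(length(r))
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos])
  out
}

pair_matrices <- function(pairs) {
  if (is.data.frame(pairs)) {
    cap_cols <- intersect(c("captured_R", "captured_G", "captured_B"),
                          names(pairs))
    ref_cols <- intersect(c("reference_R", "reference_G", "reference_B"),
                          names(pairs))
    if (length(cap_cols) == 3L && length(ref_cols) == 3L)
      return(list(captured = as.matrix(pairs[, cap_cols]),
                  reference = as.matrix(pairs[, ref_cols])))
  }
  if (is.list(pairs) && !is.null(pairs$captured) && !is.null(pairs$reference))
    return(list(captured = as.matrix(pairs$captured),
                reference = as.matrix(pairs$reference)))
  stop("pairs must have captured and reference colors ",
       "(list(captured=, reference=) or a patch-measurement data frame)")
}

#' Fit a thin-plate-spline color-correction map
#'
#' @param pairs Captured/reference color pairs: either
#'   \code{list(captured = n x 3, reference = n x 3)} or the data frame
#'   returned by \code{\link{sample_palette_patches}}.
#' @param lambda Regularization, >= 0. Default 0: exact interpolation at
#'   the control points.
#' @param kernel Radial basis: \code{"r2logr"} (classical thin-plate,
#'   phi(r) = r^2 log r, phi(0) = 0) or the polyharmonic \code{"r"}.
#' @return A \code{tps_map} with elements \code{control_points} (n x 3),
#'   \code{weights} (n x 3, one column per output channel), \code{affine}
#'   (4 x 3: intercept + linear part per channel), \code{kernel},
#'   \code{lambda}.
#' @export
fit_tps_map <- function(pairs, lambda = 0, kernel = c("r2logr", "r")) {
  kernel <- match.arg(kernel)
  pm <- pair_matrices(pairs)
  cap <- pm$captured; ref <- pm$reference
  n <- nrow(cap)
  if (n < 8L) stop("need at least 8 color pairs to fit a TPS map, got ", n)
  stopifnot(lambda >= 0, nrow(ref) == n)
  D <- as.matrix(stats::dist(cap))
  K <- matrix(tps_kernel(as.numeric(D), kernel), n, n)
  P <- cbind(1, cap)
  if (qr(P)$rank < 4L)
    stop("degenerate control points: captured colors are coplanar/collinear ",
         "in RGB space")
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4L, 4L)))
  B <- rbind(ref, matrix(0, 4L, 3L))
  sol <- tryCatch({
    s <- solve(A, B)
    s + solve(A, B - A %*% s)  # one iterative-refinement step
  }, error = function(e)
    stop("rank-deficient TPS system: ", conditionMessage(e)))
  structure(list(control_points = unname(cap),
                 weights = unname(sol[seq_len(n), , drop = FALSE]),
                 affine = unname(sol[(n + 1L):(n + 4L), , drop = FALSE]),
                 kernel = kernel, lambda = lambda),
            class = "tps_map")
}

#' Apply a fitted color-correction map
#'
#' Evaluates the three channel maps at arbitrary colors. Output is not
#' clipped; clip at export with \code{\link{clip255}} if needed.
#'
#' @param map A \code{tps_map}.
#' @param colors n x 3 matrix (or length-3 vector) of 8-bit colors.
#' @return n x 3 matrix of corrected colors.
#' @export
apply_map <- function(map, colors) {
  stopifnot(inherits(map, "tps_map"))
  if (is.null(dim(colors))) colors <- matrix(colors, ncol = 3L)
  colors <- as.matrix(colors)
  cp <- map$control_points
  # cross-distances query x control, computed by explicit differencing
  # (the |a|^2 + |b|^2 - 2ab expansion cancels catastrophically near
  # control points, which matters for the linear kernel)
  U <- matrix(0, nrow(colors), nrow(cp))
  for (i in seq_len(nrow(cp))) {
    d <- sqrt((colors[, 1L] - cp[i, 1L])^2 +
                (colors[, 2L] - cp[i, 2L])^2 +
                (colors[, 3L] - cp[i, 3L])^2)
    U[, i] <- tps_kernel(d, map$kernel)
  }
  U %*% map$weights + cbind(1, colors) %*% map$affine
}

#' @export
predict.tps_map <- function(object, newdata, ...) apply_map(object, newdata)

#' @export
print.tps_map <- function(x, ...) {
  cat(sprintf("TPS color map: %d control points, kernel %s, lambda %g\n",
              nrow(x$control_points), x$kernel, x$lambda))
  invisible(x)
}

#' Root-mean-square correction residual
#'
#' RMSE between corrected captured colors and their references, channels
#' pooled; a quality gate for a capture (large residuals mean the palette
#' sampling or the illumination model is off).
#'
#' @inheritParams fit_tps_map
#' @param map A \code{tps_map}.
#' @return Scalar RMSE on the 8-bit scale.
#' @export
correction_residual <- function(map, pairs) {
  pm <- pair_matrices(pairs)
  if (nrow(pm$captured) == 0L) stop("empty pair list")
  pred <- apply_map(map, pm$captured)
  sqrt(mean((pred - pm$reference)^2))
}

#' Diagonal white-balance baseline
#'
#' Per-channel (von Kries) gains fitted on the white patch only; the
#' simple color-constancy baseline that the TPS map is expected to beat
#' whenever the capture distortion is not a pure diagonal gain.
#'
#' @inheritParams fit_tps_map
#' @param white_id Palette id of the white patch (default \code{"white"});
#'   if absent, the pair with the brightest reference is used.
#' @param ids Optional character vector of entry ids aligned with the
#'   pairs (taken from the data frame's \code{entry_id} if present).
#' @return Function mapping n x 3 colors to white-balanced colors.
#' @export
fit_white_balance <- function(pairs, white_id = "white", ids = NULL) {
  pm <- pair_matrices(pairs)
  if (is.null(ids) && is.data.frame(pairs) && "entry_id" %in% names(pairs))
    ids <- pairs$entry_id
  k <- if (!is.null(ids) && white_id %in% ids) which(ids == white_id)[1L]
       else which.max(rgb_luminance(pm$reference))
  gains <- pm$reference[k, ] / pmax(pm$captured[k, ], 1e-6)
  function(colors) {
    if (is.null(dim(colors))) colors <- matrix(colors, ncol = 3L)
    sweep(as.matrix(colors), 2L, gains, "*")
  }
}

#' Serialize / restore a TPS map
#'
#' JSON round-trip for reproducible re-application of a fitted map.
#'
#' @param map A \code{tps_map}.
#' @param path JSON file path.
#' @export
tps_to_json <- function(map, path) {
  stopifnot(inherits(map, "tps_map"))
  jsonlite::write_json(list(
    control_points = map$control_points, weights = map$weights,
    affine = map$affine, kernel = map$kernel, lambda = map$lambda),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tps_to_json
#' @export
tps_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(control_points = as.matrix(obj$control_points),
                 weights = as.matrix(obj$weights),
                 affine = as.matrix(obj$affine),
                 kernel = obj$kernel, lambda = obj$lambda),
            class = "tps_map")
}
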