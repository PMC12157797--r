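# Assay-hardware localization in the canonical frame: template matching
# for the strip ink pad (multi-scale normalized cross-correlation, the
# pluggable stand-in for an appearance-based cascade detector) and
# contour analysis for the dark-bordered cuvette face.

roi_box <- function(x, y, w, h, score = 1, kind = "strip_pad") {
  structure(list(x = as.integer(round(x)), y = as.integer(round(y)),
                 w = as.integer(round(w)), h = as.integer(round(h)),
                 score = score, kind = kind), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("ROI [%s]: x=%d y=%d w=%d h=%d score=%.3f\n",
              x$kind, x$x, x$y, x$w, x$h, x$score))
  invisible(x)
}

check_box_inside <- function(box, img) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  if (box$x < 0 || box$y < 0 || box$x + box$w > w || box$y + box$h > h)
    stop("ROI box extends outside the image")
  invisible(TRUE)
}

#' Default strip-pad template
#'
#' Grayscale structural template of the strip ink pad: a darker square
#' pad centered on the lighter strip background. Normalized correlation
#' is invariant to intensity gain/offset, so the template encodes shape,
#' not the (concentration-dependent) pad color.
#'
#' @param pad_px Pad side, pixels (default 44, the layout pad size).
#' @param border_px Strip background margin around the pad.
#' @return Square grayscale matrix.
#' @export
default_pad_template <- function(pad_px = 44L, border_px = 6L) {
  side <- pad_px + 2L * border_px
  tpl <- matrix(230, side, side)
  tpl[(border_px + 1L):(border_px + pad_px),
      (border_px + 1L):(border_px + pad_px)] <- 100
  tpl
}

# fast NCC of template over image via FFT convolution (EBImage::filter2);
# returns matrix of correlation at each center position (NA near borders)
ncc_map <- function(gray, tpl) {
  th <- nrow(tpl); tw <- ncol(tpl)
  n <- th * tw
  tz <- tpl - mean(tpl)
  tsd <- sqrt(sum(tz^2))
  if (tsd < 1e-9) stop("template has zero variance")
  # filter2 computes correlation with the kernel centered; odd dims needed
  if (th %% 2L == 0L) { tz <- rbind(tz, 0); }
  if (tw %% 2L == 0L) { tz <- cbind(tz, 0); }
  kones <- matrix(0, nrow(tz), ncol(tz))
  kones[seq_len(th), seq_len(tw)] <- 1
  num <- EBImage::imageData(EBImage::filter2(gray, tz, boundary = "replicate"))
  s1 <- EBImage::imageData(EBImage::filter2(gray, kones, boundary = "replicate"))
  s2 <- EBImage::imageData(EBImage::filter2(gray^2, kones, boundary = "replicate"))
  denom <- sqrt(pmax(s2 - s1^2 / n, 0)) * tsd
  out <- ifelse(denom > 1e-9, num / denom, 0)
  # invalidate positions where the template sticks out
  hh <- nrow(gray); ww <- ncol(gray)
  half_h <- th %/% 2L; half_w <- tw %/% 2L
  mask <- matrix(NA_real_, hh, ww)
  rr <- (half_h + 1L):(hh - (th - half_h) + 1L)
  cc <- (half_w + 1L):(ww - (tw - half_w) + 1L)
  mask[rr, cc] <- 1
  out * mask
}

#' Detect the strip ink pad by multi-scale template matching
#'
#' Multi-scale normalized cross-correlation of a pad template over the
#' hardware search window; the best-scoring match wins. The detector has
#' the same contract (box + confidence) as an appearance-based cascade
#' and can be swapped for one.
#'
#' @param canonical Canonical-frame image.
#' @param template Grayscale template matrix (default
#'   \code{\link{default_pad_template}}).
#' @param search_window List (x, y, w, h) in canonical pixels; default
#'   the layout hardware window.
#' @param threshold Minimum acceptable correlation in [0, 1], default 0.5.
#' @param scales Template scale factors tried (default 0.75-1.5).
#' @param layout Canonical layout (for the default search window).
#' @return An \code{roi_box} with \code{kind = "strip_pad"}, score = best
#'   correlation. The box covers the pad (the template's inner square).
#' @export
detect_strip_pad <- function(canonical, template = default_pad_template(),
                             search_window = NULL, threshold = 0.5,
                             scales = c(0.75, 1, 1.25, 1.5),
                             layout = default_layout()) {
  if (is.null(search_window)) search_window <- layout$search_window
  sw <- search_window
  gray <- img_luminance(canonical)
  win <- gray[(sw$y + 1L):(sw$y + sw$h), (sw$x + 1L):(sw$x + sw$w)]
  best <- list(score = -Inf)
  for (s in scales) {
    tpl <- if (abs(s - 1) < 1e-9) template else
      EBImage::imageData(EBImage::resize(EBImage::Image(template),
                                         w = max(4L, round(nrow(template) * s))))
    if (nrow(tpl) > nrow(win) || ncol(tpl) > ncol(win)) next
    cc <- ncc_map(win, tpl)
    sc <- suppressWarnings(max(cc, na.rm = TRUE))
    if (is.finite(sc) && sc > best$score) {
      at <- which(cc == sc, arr.ind = TRUE)[1L, ]
      best <- list(score = sc, row = at[1L], col = at[2L],
                   th = nrow(tpl), tw = ncol(tpl), scale = s)
    }
  }
  score <- max(0, min(1, best$score))
  if (!is.finite(best$score) || score < threshold)
    stop(sprintf(
      "strip pad not found: best correlation %.3f below threshold %.2f",
      max(0, best$score), threshold))
  # box of the matched template, converted back to full-image coordinates
  x0 <- sw$x + best$col - 1L - best$tw %/% 2L
  y0 <- sw$y + best$row - 1L - best$th %/% 2L
  # shrink to the pad (inner square) proportionally to the template design
  frac <- 44 / 56  # pad/template side ratio of the default template
  mx <- round(best$tw * (1 - frac) / 2)
  my <- round(best$th * (1 - frac) / 2)
  box <- roi_box(x0 + mx, y0 + my, best$tw - 2L * mx, best$th - 2L * my,
                 score = score, kind = "strip_pad")
  check_box_inside(box, canonical)
  box
}

#' Detect the cuvette face by contour analysis
#'
#' Thresholds the search window, labels connected dark components, fills
#' their interiors and keeps rectangles (fill ratio >= 0.85) whose aspect
#' ratio is within tolerance of the expected cuvette face aspect and
#' whose area is in range; the largest conforming rectangle wins. The
#' dark-painted cuvette border is what makes this robust.
#'
#' @param canonical Canonical-frame image.
#' @param expected_aspect Width/height of the visible face (default 3.0,
#'   a 3.3 cm x 1.1 cm face).
#' @param aspect_tol Relative tolerance (default 0.25).
#' @param area_range Acceptable bounding-box area in px^2.
#' @param search_window,layout As in \code{\link{detect_strip_pad}}.
#' @return An \code{roi_box}, \code{kind = "cuvette_outer"}.
#' @export
detect_cuvette <- function(canonical, expected_aspect = 3, aspect_tol = 0.25,
                           area_range = c(2000, 60000),
                           search_window = NULL, layout = default_layout()) {
  if (is.null(search_window)) search_window <- layout$search_window
  sw <- search_window
  gray <- img_luminance(canonical)
  win <- gray[(sw$y + 1L):(sw$y + sw$h), (sw$x + 1L):(sw$x + sw$w)]
  th <- otsu_threshold(win)
  dark <- floor(win) <= th  # otsu thresholds integer luminance bins
  if (!any(dark) || all(dark))
    stop("no cuvette candidate: search window has no dark pixels")
  lab <- EBImage::bwlabel(EBImage::Image(dark * 1))
  filled <- EBImage::fillHull(lab)
  labs <- setdiff(unique(as.integer(EBImage::imageData(lab))), 0L)
  rejections <- character(0)
  best <- NULL
  for (l in labs) {
    px <- which(EBImage::imageData(filled) == l, arr.ind = TRUE)
    y0 <- min(px[, 1L]); y1 <- max(px[, 1L])
    x0 <- min(px[, 2L]); x1 <- max(px[, 2L])
    w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
    area <- w * h
    fill_ratio <- nrow(px) / area
    aspect <- max(w, h) / min(w, h)
    reason <- NULL
    if (area < area_range[1L] || area > area_range[2L])
      reason <- sprintf("area %d outside [%d, %d]", area,
                        as.integer(area_range[1L]), as.integer(area_range[2L]))
    else if (fill_ratio < 0.85)
      reason <- sprintf("fill ratio %.2f < 0.85 (not a rectangle)", fill_ratio)
    else if (abs(aspect - expected_aspect) > aspect_tol * expected_aspect)
      reason <- sprintf("aspect %.2f outside %.2f +/- %.0f%%", aspect,
                        expected_aspect, 100 * aspect_tol)
    if (!is.null(reason)) {
      rejections <- c(rejections, sprintf("component %d (%dx%d): %s",
                                          l, w, h, reason))
      next
    }
    if (is.null(best) || area > best$w * best$h)
      best <- roi_box(sw$x + x0 - 1L, sw$y + y0 - 1L, w, h,
                      score = fill_ratio, kind = "cuvette_outer")
  }
  if (is.null(best))
    stop("no cuvette candidate passed the contour filters:\n  ",
         paste(rejections, collapse = "\n  "))
  check_box_inside(best, canonical)
  best
}

#' Shrink a cuvette box to its centered inner ROI
#'
#' The measurement ROI is a centered box about \code{shrink} times
#' smaller per axis (so ~shrink^2 in area; 25x for the default shrink of
#' 5), keeping the measurement away from the dark border and meniscus.
#'
#' @param outer An \code{roi_box}.
#' @param shrink Per-axis shrink factor > 1 (default 5).
#' @return An \code{roi_box}, \code{kind = "cuvette_inner"}.
#' @export
shrink_to_inner_roi <- function(outer, shrink = 5) {
  stopifnot(inherits(outer, "roi_box"), shrink > 1)
  w2 <- max(1L, as.integer(round(outer$w / shrink)))
  h2 <- max(1L, as.integer(round(outer$h / shrink)))
  kind <- if (identical(outer$kind, "cuvette_outer")) "cuvette_inner"
          else outer$kind
  roi_box(outer$x + round((outer$w - w2) / 2),
          outer$y + round((outer$h - h2) / 2),
          w2, h2, score = outer$score, kind = kind)
}

#' Measure the mean color of an ROI
#'
#' Per-channel mean and (population) standard deviation over the box.
#'
#' @param canonical Image array.
#' @param box An \code{roi_box} inside the image.
#' @return List with \code{mean_rgb}, \code{std_rgb},
#'   \code{pixel_count}, \code{box}.
#' @export
measure_roi <- function(canonical, box) {
  check_box_inside(box, canonical)
  block <- canonical[(box$y + 1L):(box$y + box$h),
                     (box$x + 1L):(box$x + box$w), , drop = FALSE]
  n <- box$w * box$h
  mean_rgb <- vapply(1:3, function(ch) mean(block[, , ch]), double(1))
  std_rgb <- vapply(1:3, function(ch) {
    v <- block[, , ch]
    sqrt(mean((v - mean(v))^2))
  }, double(1))
  list(mean_rgb = mean_rgb, std_rgb = std_rgb, pixel_count = n, box = box)
}
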