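# Scene understanding: locate the QR symbol in a photograph via its
# finder patterns, estimate the projective map to module coordinates,
# decode the payload, rectify the scene to the canonical frame and sample
# the embedded palette patches.
#
# Finder detection follows the classic run-length approach: scan rows for
# dark/light runs in the 1:1:3:1:1 finder ratio, confirm candidates with
# a vertical scan, cluster, and pick the triple of centers with the most
# consistent module size and a right-angle geometry. The homography is
# fitted on the three finder centers plus the bottom-right alignment
# pattern (refined by local template search), which keeps the grid
# sampling accurate under projective distortion.

# candidate finder centers from 1:1:3:1:1 run scanning
find_finder_centers <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  cand <- list()
  for (r in seq_len(h)) {
    runs <- rle(bin[r, ])
    if (length(runs$lengths) < 5L) next
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_len(length(runs$lengths) - 4L)) {
      if (!runs$values[k]) next  # must start dark
      L <- runs$lengths[k:(k + 4L)]
      unit <- sum(L) / 7
      if (unit < 1.5) next
      ok <- abs(L[1L] - unit) < 0.75 * unit && abs(L[2L] - unit) < 0.75 * unit &&
        abs(L[3L] - 3 * unit) < 1.2 * unit && abs(L[4L] - unit) < 0.75 * unit &&
        abs(L[5L] - unit) < 0.75 * unit
      if (!ok) next
      cx <- starts[k + 2L] + runs$lengths[k + 2L] / 2 - 0.5
      # vertical confirmation through the candidate center
      col <- bin[, round(cx) + 0L]
      vruns <- rle(col)
      vends <- cumsum(vruns$lengths)
      vstarts <- vends - vruns$lengths + 1L
      seg <- which(vstarts <= r & vends >= r)
      if (length(seg) != 1L || !vruns$values[seg] ||
          seg < 3L || seg > length(vruns$lengths) - 2L) next
      VL <- vruns$lengths[(seg - 2L):(seg + 2L)]
      vunit <- sum(VL) / 7
      vok <- abs(VL[3L] - 3 * vunit) < 1.2 * vunit &&
        abs(VL[2L] - vunit) < 0.75 * vunit && abs(VL[4L] - vunit) < 0.75 * vunit
      if (!vok) next
      cy <- vstarts[seg] + vruns$lengths[seg] / 2 - 0.5
      cand[[length(cand) + 1L]] <- c(cx = cx, cy = cy, unit = (unit + vunit) / 2)
    }
  }
  if (length(cand) == 0L) return(matrix(numeric(0), ncol = 3L))
  m <- do.call(rbind, cand)
  # cluster by proximity (< 2 units)
  centers <- list()
  used <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (used[i]) next
    grp <- which(!used & abs(m[, 1L] - m[i, 1L]) < 2 * m[i, 3L] &
                   abs(m[, 2L] - m[i, 2L]) < 2 * m[i, 3L])
    used[grp] <- TRUE
    centers[[length(centers) + 1L]] <-
      c(colMeans(m[grp, , drop = FALSE]), hits = length(grp))
  }
  cm <- do.call(rbind, centers)
  cm[cm[, 4L] >= 2, , drop = FALSE]
}

# candidate finder triples: right angle at one vertex, equal arms,
# consistent module size; ranked by module-size consistency then area,
# so the caller can fall back if the best-ranked triple fails to decode
pick_finder_triples <- function(centers) {
  n <- nrow(centers)
  if (n < 3L) return(list())
  out <- list()
  combos <- utils::combn(n, 3L)
  for (k in seq_len(ncol(combos))) {
    tri <- centers[combos[, k], , drop = FALSE]
    for (tl in 1:3) {
      others <- setdiff(1:3, tl)
      v1 <- tri[others[1L], 1:2] - tri[tl, 1:2]
      v2 <- tri[others[2L], 1:2] - tri[tl, 1:2]
      a <- sqrt(sum(v1^2)); b <- sqrt(sum(v2^2))
      if (a < 1e-6 || b < 1e-6) next
      cosang <- sum(v1 * v2) / (a * b)
      if (abs(cosang) > 0.35) next            # ~70-110 degrees
      if (abs(a - b) > 0.25 * max(a, b)) next # equal arms
      us <- tri[, 3L]
      spread <- (max(us) - min(us)) / mean(us)
      if (spread > 0.5) next
      cross <- v1[1L] * v2[2L] - v1[2L] * v2[1L]
      tr <- if (cross > 0) others[1L] else others[2L]
      bl <- if (cross > 0) others[2L] else others[1L]
      out[[length(out) + 1L]] <- list(
        TL = tri[tl, ], TR = tri[tr, ], BL = tri[bl, ],
        spread = spread, area = abs(cross))
    }
  }
  if (length(out) == 0L) return(out)
  ord <- order(vapply(out, function(t) t$spread, double(1)) -
                 1e-9 * vapply(out, function(t) t$area, double(1)))
  out[ord]
}

# refine the bottom-right alignment-pattern center by template search
refine_alignment <- function(gray, guess, module_px) {
  pat <- matrix(1, 5L, 5L)
  pat[2:4, 2:4] <- 0
  pat[3L, 3L] <- 1
  ms <- max(2L, round(module_px))
  tpl <- kronecker(pat, matrix(1, ms, ms))
  tpl <- (1 - tpl) * 255  # 1=dark -> low luminance
  th <- nrow(tpl)
  half <- th %/% 2L
  search <- round(2.5 * ms)
  h <- nrow(gray); w <- ncol(gray)
  tz <- tpl - mean(tpl)
  tden <- sqrt(sum(tz^2))
  best <- NULL; best_s <- -Inf
  for (dy in seq(-search, search, by = 2L)) for (dx in seq(-search, search, by = 2L)) {
    cx <- round(guess[1L]) + dx; cy <- round(guess[2L]) + dy
    x0 <- cx - half; y0 <- cy - half
    if (x0 < 0 || y0 < 0 || x0 + th > w || y0 + th > h) next
    patch <- gray[(y0 + 1L):(y0 + th), (x0 + 1L):(x0 + th)]
    pz <- patch - mean(patch)
    den <- sqrt(sum(pz^2)) * tden
    if (den < 1e-9) next
    s <- sum(pz * tz) / den
    if (s > best_s) { best_s <- s; best <- c(cx, cy) }
  }
  if (is.null(best) || best_s < 0.4) return(NULL)
  # refine at single-pixel resolution around the coarse optimum
  coarse <- best
  for (dy in -2:2) for (dx in -2:2) {
    cx <- coarse[1L] + dx; cy <- coarse[2L] + dy
    x0 <- cx - half; y0 <- cy - half
    if (x0 < 0 || y0 < 0 || x0 + th > w || y0 + th > h) next
    patch <- gray[(y0 + 1L):(y0 + th), (x0 + 1L):(x0 + th)]
    pz <- patch - mean(patch)
    den <- sqrt(sum(pz^2)) * tden
    if (den < 1e-9) next
    s <- sum(pz * tz) / den
    if (s > best_s) { best_s <- s; best <- c(cx, cy) }
  }
  best
}

#' Locate and decode the QR symbol in a scene
#'
#' Finds the finder patterns, fits the module-to-image homography,
#' samples the module grid, and decodes the payload (tolerating module
#' errors up to the symbol's Reed-Solomon budget, so embedded color
#' patches and illuminant shifts do not break decoding).
#'
#' @param scene H x W x 3 image array (0-255) or a PNG path.
#' @return A \code{qr_detection}: list with \code{corners} (4 x 2, TL,
#'   TR, BR, BL, image pixels), \code{payload}, \code{qr_id},
#'   \code{version}, \code{homography} (3 x 3 mapping image pixels to
#'   module coordinates), \code{module_homography} (its inverse),
#'   \code{module_px} (estimated pixels per module),
#'   \code{n_corrected}.
#' @export
locate_and_decode <- function(scene) {
  if (is.character(scene)) scene <- read_image(scene)
  stopifnot(length(dim(scene)) == 3L, dim(scene)[3L] == 3L,
            dim(scene)[1L] >= 64L, dim(scene)[2L] >= 64L)
  gray <- img_luminance(scene)
  th <- otsu_threshold(gray)
  bin <- gray < th
  centers <- find_finder_centers(bin)
  triples <- pick_finder_triples(centers)
  if (length(triples) == 0L)
    stop("no decodable QR symbol found (", nrow(centers),
         " finder candidates)")

  attempt <- function(triple) {
    ms <- mean(c(triple$TL[3L], triple$TR[3L], triple$BL[3L]))
    D <- (sqrt(sum((triple$TR[1:2] - triple$TL[1:2])^2)) +
            sqrt(sum((triple$BL[1:2] - triple$TL[1:2])^2))) / 2
    version <- max(1L, min(qr_max_version, round((D / ms + 7 - 17) / 4)))
    side <- qr_side(version)

    mod_pts <- rbind(c(3.5, 3.5), c(side - 3.5, 3.5), c(3.5, side - 3.5))
    img_pts <- rbind(triple$TL[1:2], triple$TR[1:2], triple$BL[1:2])

    # affine estimate from the three finder centers
    A <- cbind(mod_pts, 1)
    ax <- solve(A, img_pts[, 1L])
    ay <- solve(A, img_pts[, 2L])
    affine_map <- function(p) cbind(cbind(p, 1) %*% ax, cbind(p, 1) %*% ay)

    H <- NULL
    if (version >= 2L) {
      guess <- affine_map(matrix(c(side - 6.5, side - 6.5), 1L))
      al <- refine_alignment(gray, as.numeric(guess), ms)
      if (!is.null(al)) {
        H <- fit_homography(rbind(mod_pts, c(side - 6.5, side - 6.5)),
                            rbind(img_pts, al))
      }
    }
    if (is.null(H)) {
      # fall back to the affine map (exact for version 1 / mild distortion)
      br <- affine_map(matrix(c(side - 3.5, side - 3.5), 1L))
      H <- fit_homography(rbind(mod_pts, c(side - 3.5, side - 3.5)),
                          rbind(img_pts, br))
    }

    # sample module centers, threshold, decode
    grid <- expand.grid(x = (0:(side - 1L)) + 0.5, y = (0:(side - 1L)) + 0.5)
    pix <- apply_homography(H, as.matrix(grid))
    vals <- bilinear_sample(scene, pix[, 1L], pix[, 2L])
    lum <- rgb_luminance(vals)
    sth <- otsu_threshold(matrix(lum, ncol = 1L))
    # expand.grid varies x fastest, so the filled matrix indexes
    # (col, row): transpose to module (row, col) order
    bits <- t(matrix(as.integer(floor(lum) <= sth), side, side))
    dec <- decode_matrix(bits)
    list(dec = dec, H = H, ms = ms,
         side = qr_side(dec$version), version = dec$version)
  }

  res <- NULL
  last_err <- NULL
  for (triple in triples[seq_len(min(5L, length(triples)))]) {
    res <- tryCatch(attempt(triple), error = function(e) {
      last_err <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) break
  }
  if (is.null(res))
    stop("no decodable QR symbol found (grid sampled but undecodable: ",
         last_err, ")")
  dec <- res$dec; H <- res$H; ms <- res$ms
  version <- res$version; side <- res$side

  corners_mod <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  corners <- apply_homography(H, corners_mod)
  rownames(corners) <- c("TL", "TR", "BR", "BL")
  structure(list(
    corners = corners,
    payload = dec$payload,
    qr_id = sub("^[^#]*#?", "", dec$payload),
    version = version,
    ec_level = dec$ec_level,
    homography = solve(H),
    module_homography = H,
    module_px = ms,
    n_corrected = dec$n_corrected
  ), class = "qr_detection")
}

#' @export
print.qr_detection <- function(x, ...) {
  cat(sprintf("QR detection: version %d-%s, payload '%s', ~%.1f px/module\n",
              x$version, x$ec_level, x$payload, x$module_px))
  invisible(x)
}

#' Rectify a scene to the canonical frame
#'
#' Warps the photograph into the canonical canvas in which the QR symbol
#' occupies its fixed layout square and the assay hardware window lies at
#' a fixed region to its right. Resampling is bilinear.
#'
#' @param scene Image array or PNG path.
#' @param det Detection from \code{\link{locate_and_decode}}.
#' @param layout Canonical layout (see \code{\link{default_layout}}).
#' @return Canonical-frame image array (layout canvas size).
#' @export
rectify_to_canonical <- function(scene, det, layout = default_layout()) {
  if (is.character(scene)) scene <- read_image(scene)
  stopifnot(inherits(det, "qr_detection"))
  mp <- layout$qr$module_px
  # canvas pixel -> module coordinate (affine), then module -> image
  A <- rbind(c(1 / mp, 0, -layout$qr$x / mp),
             c(0, 1 / mp, -layout$qr$y / mp),
             c(0, 0, 1))
  H_canvas2img <- det$module_homography %*% A
  if (abs(det(H_canvas2img)) < 1e-10) stop("degenerate homography")
  warp_image(scene, solve(H_canvas2img), layout$canvas_w, layout$canvas_h)
}

#' Sample the palette patches in a canonical frame
#'
#' Measures the captured color of every embedded reference patch as the
#' mean over the central 50 percent of its module square (avoiding
#' warp/demosaicing bleed at module borders).
#'
#' @param canonical Canonical-frame image from
#'   \code{\link{rectify_to_canonical}}.
#' @param spec The \code{color_qr} whose id matches the detection.
#' @param layout Canonical layout.
#' @param central_frac Side fraction of the module square to average
#'   (default 0.5).
#' @return Data frame: \code{entry_id}, captured_R/G/B, reference_R/G/B,
#'   \code{pixel_count}.
#' @export
sample_palette_patches <- function(canonical, spec,
                                   layout = default_layout(),
                                   central_frac = 0.5) {
  stopifnot(inherits(spec, "color_qr"))
  mp <- layout$qr$module_px
  inner <- max(1L, floor(mp * central_frac))
  margin <- (mp - inner) %/% 2L
  n <- nrow(spec$placements)
  out <- data.frame(entry_id = spec$palette$id,
                    captured_R = numeric(n), captured_G = numeric(n),
                    captured_B = numeric(n),
                    reference_R = spec$palette$R,
                    reference_G = spec$palette$G,
                    reference_B = spec$palette$B,
                    pixel_count = rep(inner^2, n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    r <- spec$placements[k, 1L]; c <- spec$placements[k, 2L]
    y0 <- layout$qr$y + r * mp + margin
    x0 <- layout$qr$x + c * mp + margin
    block <- canonical[(y0 + 1L):(y0 + inner), (x0 + 1L):(x0 + inner), ,
                       drop = FALSE]
    out[k, c("captured_R", "captured_G", "captured_B")] <-
      c(mean(block[, , 1L]), mean(block[, , 2L]), mean(block[, , 3L]))
  }
  out
}
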