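# Back-compatible Color QR codes: a standard-decodable symbol whose
# selected data modules are replaced by colorimetric reference patches.
#
# Back-compatibility rests on one rule: a patch may only sit on a module
# whose binary value matches the patch's luminance class (Rec.601 luminance
# vs. the mid-gray threshold 128), so grayscale binarization of the colored
# symbol reproduces the black/white module matrix cell for cell.

#' Read a color palette from JSON
#'
#' Schema: \code{[{"id": "...", "rgb": [r, g, b]}, ...]} with 8-bit
#' components. The rgb values are the patch colors under the reference
#' condition (6500 K illuminant).
#'
#' @param path JSON file.
#' @return Data frame with columns \code{id}, \code{R}, \code{G}, \code{B}.
#' @export
read_palette <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  pal <- data.frame(
    id = vapply(raw, function(e) as.character(e$id), character(1)),
    R = vapply(raw, function(e) as.numeric(e$rgb[[1L]]), double(1)),
    G = vapply(raw, function(e) as.numeric(e$rgb[[2L]]), double(1)),
    B = vapply(raw, function(e) as.numeric(e$rgb[[3L]]), double(1)),
    stringsAsFactors = FALSE)
  validate_palette(pal)
}

#' @rdname read_palette
#' @param palette Palette data frame.
#' @export
write_palette <- function(palette, path) {
  palette <- validate_palette(palette)
  entries <- lapply(seq_len(nrow(palette)), function(i) {
    list(id = palette$id[i],
         rgb = c(palette$R[i], palette$G[i], palette$B[i]))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_palette <- function(palette) {
  stopifnot(is.data.frame(palette),
            all(c("id", "R", "G", "B") %in% names(palette)))
  rgb <- as.matrix(palette[, c("R", "G", "B")])
  if (any(rgb < 0 | rgb > 255))
    stop("palette rgb components must lie in [0, 255]")
  if (anyDuplicated(palette$id))
    stop("palette entry ids must be unique")
  palette
}

#' Built-in reference palettes
#'
#' Two 24-entry palettes shipped with the package: \code{"btb"} spans the
#' yellow-green-blue ramp of a bromothymol-blue strip plus neutral and
#' primary anchors; \code{"dpd"} spans the white-to-pink DPD ramp with the
#' same anchors. The numeric values are package constants chosen to cover
#' the dye gamut; they are configurable, not measured ground truth.
#'
#' @param chemistry \code{"btb"} or \code{"dpd"}.
#' @return Palette data frame (see \code{\link{read_palette}}).
#' @export
default_palette <- function(chemistry = c("btb", "dpd")) {
  chemistry <- match.arg(chemistry)
  path <- system.file("extdata", paste0("palette_", chemistry, ".json"),
                      package = "colorqr")
  if (!nzchar(path))
    stop("built-in palette not found; is the package installed?")
  read_palette(path)
}

# luminance class of a color: TRUE = light (binarizes to a light module)
luminance_is_light <- function(rgb) rgb_luminance(rgb) >= 128

#' Choose module placements for palette patches
#'
#' Greedy row-major scan of the data region (never finder, timing,
#' alignment or format modules): each palette entry takes the first free
#' module whose binary value matches the entry's luminance class.
#'
#' @param m A \code{qr_matrix} from \code{\link{encode_payload}}.
#' @param palette Palette data frame.
#' @return Integer n x 2 matrix of 0-based (row, col) placements.
#' @export
choose_placements <- function(m, palette) {
  palette <- validate_palette(palette)
  fmask <- attr(m, "fmask")
  side <- nrow(m)
  light <- luminance_is_light(as.matrix(palette[, c("R", "G", "B")]))
  used <- matrix(FALSE, side, side)
  placements <- matrix(NA_integer_, nrow(palette), 2L)
  for (k in seq_len(nrow(palette))) {
    want_dark <- !light[k]
    found <- FALSE
    for (r in seq_len(side)) {
      for (c in seq_len(side)) {
        if (fmask[r, c] || used[r, c]) next
        if ((m[r, c] == 1L) == want_dark) {
          placements[k, ] <- c(r - 1L, c - 1L)
          used[r, c] <- TRUE
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found)
      stop("no free ", if (want_dark) "dark" else "light",
           " module left for palette entry '", palette$id[k], "'")
  }
  placements
}

#' Embed a color palette into a QR module matrix
#'
#' Produces a colored module matrix whose grayscale binarization equals the
#' input black/white matrix, so any standard decoder still reads the
#' payload.
#'
#' @param m A \code{qr_matrix}.
#' @param palette Palette data frame.
#' @param placements Integer n x 2 matrix of 0-based (row, col) module
#'   coordinates, one row per palette entry, or \code{NULL} to choose them
#'   with \code{\link{choose_placements}}.
#' @return A \code{color_qr_matrix}: side x side x 3 array of 8-bit colors
#'   with attributes \code{placement_index} (data frame id/row/col),
#'   \code{matrix} (the underlying \code{qr_matrix}).
#' @export
embed_palette <- function(m, palette, placements = NULL) {
  stopifnot(inherits(m, "qr_matrix"))
  palette <- validate_palette(palette)
  if (is.null(placements)) placements <- choose_placements(m, palette)
  placements <- matrix(as.integer(placements), ncol = 2L)
  if (nrow(placements) != nrow(palette))
    stop("need exactly one placement per palette entry (",
         nrow(placements), " vs ", nrow(palette), ")")
  side <- nrow(m)
  fmask <- attr(m, "fmask")
  if (nrow(palette) > 0L) {
    if (any(placements < 0L) || any(placements >= side))
      stop("placement outside the symbol")
    if (anyDuplicated(placements) > 0L)
      stop("duplicate placements")
    onf <- fmask[cbind(placements[, 1L] + 1L, placements[, 2L] + 1L)]
    if (any(onf))
      stop("placement on a function pattern for entry '",
           palette$id[which(onf)[1L]], "' at (",
           placements[which(onf)[1L], 1L], ",",
           placements[which(onf)[1L], 2L], ")")
  }
  colored <- array(0, c(side, side, 3L))
  for (ch in 1:3) colored[, , ch] <- (1 - unclass(m)) * 255
  for (k in seq_len(nrow(palette))) {
    r <- placements[k, 1L] + 1L; c <- placements[k, 2L] + 1L
    rgb <- as.numeric(palette[k, c("R", "G", "B")])
    if (luminance_is_light(rgb) != (m[r, c] == 0L))
      stop("luminance conflict: entry '", palette$id[k], "' (luminance ",
           round(rgb_luminance(rgb), 1), ") on a ",
           if (m[r, c] == 1L) "dark" else "light", " module at (",
           r - 1L, ",", c - 1L, ")")
    colored[r, c, ] <- rgb
  }
  structure(colored, class = "color_qr_matrix",
            placement_index = data.frame(
              id = palette$id,
              row = placements[, 1L], col = placements[, 2L],
              stringsAsFactors = FALSE),
            matrix = m)
}

#' Render a (color) module matrix as an image
#'
#' @param colored A \code{color_qr_matrix} (or a plain \code{qr_matrix},
#'   rendered black/white).
#' @param module_px Pixels per module, >= 1.
#' @param quiet_zone Quiet-zone width in modules (rendered white).
#' @return H x W x 3 image array, 0-255.
#' @export
render_symbol <- function(colored, module_px = 8L, quiet_zone = 4L) {
  stopifnot(module_px >= 1L, quiet_zone >= 0L)
  if (inherits(colored, "qr_matrix")) {
    side <- nrow(colored)
    arr <- array(0, c(side, side, 3L))
    for (ch in 1:3) arr[, , ch] <- (1 - unclass(colored)) * 255
    colored <- arr
  }
  side <- dim(colored)[1L]
  out_side <- (side + 2L * quiet_zone) * module_px
  img <- array(255, c(out_side, out_side, 3L))
  ones <- matrix(1, module_px, module_px)
  off <- quiet_zone * module_px
  for (ch in 1:3) {
    img[(off + 1L):(off + side * module_px),
        (off + 1L):(off + side * module_px), ch] <-
      kronecker(colored[, , ch], ones)
  }
  img
}

#' Build a complete Color QR specification
#'
#' Convenience constructor tying together payload encoding, palette
#' placement and rendering geometry.
#'
#' @inheritParams encode_payload
#' @param palette Palette data frame (default: built-in \code{"btb"}).
#' @param placements Optional explicit placements (see
#'   \code{\link{embed_palette}}).
#' @param module_px,quiet_zone Rendering geometry.
#' @return A \code{color_qr} object: list with \code{payload},
#'   \code{qr_id} (fragment after '#'), \code{version}, \code{ec_level},
#'   \code{palette}, \code{placements}, \code{matrix}, \code{colored},
#'   \code{module_px}, \code{quiet_zone}.
#' @export
color_qr_spec <- function(payload, version = 3L, ec_level = "Q",
                          palette = default_palette("btb"),
                          placements = NULL, module_px = 8L,
                          quiet_zone = 4L) {
  m <- encode_payload(payload, version, ec_level)
  colored <- embed_palette(m, palette, placements)
  pi <- attr(colored, "placement_index")
  structure(list(
    payload = payload,
    qr_id = sub("^[^#]*#?", "", payload),
    version = as.integer(version),
    ec_level = ec_level,
    palette = palette,
    placements = as.matrix(pi[, c("row", "col")]),
    matrix = m,
    colored = colored,
    module_px = as.integer(module_px),
    quiet_zone = as.integer(quiet_zone)
  ), class = "color_qr")
}

#' @export
print.color_qr <- function(x, ...) {
  cat(sprintf("Color QR: version %d-%s, %d palette patches, id '%s'\n",
              x$version, x$ec_level, nrow(x$palette), x$qr_id))
  invisible(x)
}

#' @export
plot.color_qr <- function(x, ...) {
  img <- render_symbol(x$colored, x$module_px, x$quiet_zone)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(clip255(img) / 255),
                        0, 0, 1, 1, interpolate = FALSE)
  invisible(x)
}

# binarize a rendered symbol image back to a module matrix by block means
# (threshold 128 on Rec.601 luminance), for back-compatibility checks
symbol_bits_from_image <- function(img, side, module_px, quiet_zone,
                                   threshold = 128) {
  g <- img_luminance(img)
  off <- quiet_zone * module_px
  bits <- matrix(0L, side, side)
  for (r in seq_len(side)) for (c in seq_len(side)) {
    block <- g[(off + (r - 1L) * module_px + 1L):(off + r * module_px),
               (off + (c - 1L) * module_px + 1L):(off + c * module_px)]
    bits[r, c] <- as.integer(mean(block) < threshold)
  }
  bits
}
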