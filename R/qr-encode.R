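# QR model-2 encoder (byte mode, versions 1-10, EC levels L/M/Q/H).
#
# The symbol is represented as a `qr_matrix`: an integer side x side matrix
# with 1 = dark, 0 = light, and attributes version, ec_level, mask, payload
# and the function-module mask. Coordinates are 0-based (row, col) from the
# top-left; matrix subscripts are of course 1-based.

# function patterns + reserved areas; data cells are NA
qr_template <- function(version) {
  side <- qr_side(version)
  m <- matrix(NA_integer_, side, side)
  fmask <- matrix(FALSE, side, side)

  put_finder <- function(r0, c0) {
    for (dr in 0:6) for (dc in 0:6) {
      d <- max(abs(dr - 3L), abs(dc - 3L))
      m[r0 + dr + 1L, c0 + dc + 1L] <<- if (d == 2L) 0L else 1L
    }
    # separator: one light module ring clipped to the symbol
    rr <- max(r0 - 1L, 0L):min(r0 + 7L, side - 1L)
    cc <- max(c0 - 1L, 0L):min(c0 + 7L, side - 1L)
    for (r in rr) for (c in cc)
      if (is.na(m[r + 1L, c + 1L])) m[r + 1L, c + 1L] <<- 0L
    fmask[rr + 1L, cc + 1L] <<- TRUE
  }
  put_finder(0L, 0L)
  put_finder(0L, side - 7L)
  put_finder(side - 7L, 0L)

  # timing patterns
  tc <- 8:(side - 9L)
  m[7L, tc + 1L] <- as.integer(tc %% 2L == 0L)
  m[tc + 1L, 7L] <- as.integer(tc %% 2L == 0L)
  fmask[7L, tc + 1L] <- TRUE
  fmask[tc + 1L, 7L] <- TRUE

  # alignment patterns
  ac <- qr_alignment_centers(version)
  if (nrow(ac) > 0L) for (k in seq_len(nrow(ac))) {
    r <- ac[k, 1L]; c <- ac[k, 2L]
    for (dr in -2:2) for (dc in -2:2) {
      d <- max(abs(dr), abs(dc))
      m[r + dr + 1L, c + dc + 1L] <- if (d == 1L) 0L else 1L
    }
    fmask[r + (-2:2) + 1L, c + (-2:2) + 1L] <- TRUE
  }

  # format information areas (filled later, reserved now) + dark module
  fpos <- qr_format_positions(side)
  idx <- rbind(fpos$copy1, fpos$copy2)
  fmask[cbind(idx[, 1L] + 1L, idx[, 2L] + 1L)] <- TRUE
  m[cbind(idx[, 1L] + 1L, idx[, 2L] + 1L)] <- 0L
  m[side - 8L + 1L, 9L] <- 1L   # dark module (row side-8, col 8)
  fmask[side - 8L + 1L, 9L] <- TRUE

  # version information areas (v >= 7)
  if (version >= 7L) {
    bits <- bch_18_6(version)
    for (i in 0:17) {
      b <- bitwAnd(bitwShiftR(bits, i), 1L)
      r <- i %/% 3L; c <- side - 11L + i %% 3L
      m[r + 1L, c + 1L] <- b
      m[c + 1L, r + 1L] <- b
      fmask[r + 1L, c + 1L] <- TRUE
      fmask[c + 1L, r + 1L] <- TRUE
    }
  }

  list(m = m, fmask = fmask)
}

# 0-based coordinates of the two 15-bit format-information copies.
# Row i of each matrix holds the position of bit i (i = 0 is the LSB).
qr_format_positions <- function(side) {
  copy1 <- matrix(0L, 15L, 2L)
  copy2 <- matrix(0L, 15L, 2L)
  for (i in 0:14) {
    # copy 1: the column-8 run (skips the timing row at 6, ends bottom-left)
    if (i < 6L) copy1[i + 1L, ] <- c(i, 8L)
    else if (i < 8L) copy1[i + 1L, ] <- c(i + 1L, 8L)
    else copy1[i + 1L, ] <- c(side - 15L + i, 8L)
    # copy 2: the row-8 run (right arm, then col 7, then cols 5..0)
    if (i < 8L) copy2[i + 1L, ] <- c(8L, side - 1L - i)
    else if (i < 9L) copy2[i + 1L, ] <- c(8L, 7L)
    else copy2[i + 1L, ] <- c(8L, 14L - i)
  }
  list(copy1 = copy1, copy2 = copy2)
}

# data-module visiting order (0-based coords), the standard zig-zag
qr_data_coords <- function(version) {
  side <- qr_side(version)
  free <- is.na(qr_template(version)$m)  # data cells
  coords <- matrix(0L, sum(free), 2L)
  k <- 0L
  row <- side - 1L
  inc <- -1L
  col <- side - 1L
  while (col > 0L) {
    if (col == 6L) col <- 5L
    repeat {
      for (c in c(col, col - 1L)) {
        if (free[row + 1L, c + 1L]) {
          k <- k + 1L
          coords[k, ] <- c(row, c)
        }
      }
      row <- row + inc
      if (row < 0L || row >= side) {
        row <- row - inc
        inc <- -inc
        break
      }
    }
    col <- col - 2L
  }
  coords[seq_len(k), , drop = FALSE]
}

# payload -> interleaved codeword bytes
qr_encode_codewords <- function(payload_bytes, version, ec_level) {
  spec <- qr_ec_spec(version, ec_level)
  n_data <- sum(spec$blocks)
  count_bits <- if (version <= 9L) 8L else 16L
  need <- 4L + count_bits + 8L * length(payload_bytes)
  if (need > 8L * n_data)
    stop(sprintf(
      "payload of %d bytes exceeds byte-mode capacity %d of version %d-%s",
      length(payload_bytes), qr_byte_capacity(version, ec_level),
      version, ec_level))

  push_bits <- function(acc, value, n) {
    c(acc, as.integer(bitwAnd(bitwShiftR(value, (n - 1L):0L), 1L)))
  }
  bits <- integer(0)
  bits <- push_bits(bits, 4L, 4L)  # byte mode 0100
  bits <- push_bits(bits, length(payload_bytes), count_bits)
  for (b in payload_bytes) bits <- push_bits(bits, as.integer(b), 8L)
  bits <- c(bits, integer(min(4L, 8L * n_data - length(bits))))  # terminator
  if (length(bits) %% 8L != 0L) bits <- c(bits, integer(8L - length(bits) %% 8L))
  data_cw <- as.integer(colSums(matrix(bits, 8L) * bitwShiftL(1L, 7:0)))
  pad <- c(236L, 17L)
  i <- 0L
  while (length(data_cw) < n_data) {
    data_cw <- c(data_cw, pad[i %% 2L + 1L])
    i <- i + 1L
  }

  # split into blocks, compute EC per block
  gen <- rs_generator_poly(spec$ec)
  offs <- cumsum(c(0L, spec$blocks))
  blocks <- lapply(seq_along(spec$blocks), function(b) {
    msg <- data_cw[(offs[b] + 1L):offs[b + 1L]]
    list(data = msg, ec = rs_encode_block(msg, gen, spec$ec))
  })

  # interleave data then EC
  max_d <- max(spec$blocks)
  inter <- integer(0)
  for (i in seq_len(max_d))
    for (b in blocks) if (i <= length(b$data)) inter <- c(inter, b$data[i])
  for (i in seq_len(spec$ec))
    for (b in blocks) inter <- c(inter, b$ec[i])
  inter
}

rs_encode_block <- function(msg, gen, n_ec) {
  rem <- c(msg, integer(n_ec))
  for (i in seq_along(msg)) {
    coef <- rem[i]
    if (coef == 0L) next
    idx <- i:(i + length(gen) - 1L)
    rem[idx] <- bitwXor(rem[idx], gf_mul(rep(coef, length(gen)), gen))
  }
  rem[(length(msg) + 1L):(length(msg) + n_ec)]
}

# mask-evaluation penalties, standard rules N1-N4
qr_mask_penalty <- function(m) {
  side <- nrow(m)
  pen <- 0L
  run_pen <- function(v) {
    r <- rle(v)
    sum(ifelse(r$lengths >= 5L, 3L + (r$lengths - 5L), 0L))
  }
  for (i in seq_len(side)) pen <- pen + run_pen(m[i, ]) + run_pen(m[, i])
  # N2: 2x2 blocks of one color
  a <- m[-side, -side]; b <- m[-side, -1]; c <- m[-1, -side]; d <- m[-1, -1]
  pen <- pen + 3L * sum(a == b & a == c & a == d)
  # N3: finder-like 1:1:3:1:1 pattern with 4-module light flank
  p1 <- c(1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L)
  p2 <- rev(p1)
  scan <- function(v) {
    n <- length(v); hits <- 0L
    if (n < 11L) return(0L)
    for (s in 1:(n - 10L)) {
      w <- v[s:(s + 10L)]
      if (all(w == p1) || all(w == p2)) hits <- hits + 1L
    }
    hits
  }
  n3 <- 0L
  for (i in seq_len(side)) n3 <- n3 + scan(m[i, ]) + scan(m[, i])
  pen <- pen + 40L * n3
  # N4: dark-module proportion
  dark_pct <- 100 * sum(m) / (side * side)
  pen + 10L * (abs(dark_pct - 50) %/% 5)
}

#' Encode a payload as a QR module matrix
#'
#' Builds the final (masked) module matrix of a standard-conforming QR
#' symbol in byte mode. Version 3 gives the 29 x 29 matrix used for the
#' chlorine-assay reference charts; the side length is always
#' \code{17 + 4 * version}.
#'
#' @param payload Character scalar to encode (typically a URL with a
#'   fragment identifier, e.g. \code{"http://diesmar.com/#n87RXv6i3"}).
#' @param version QR symbol version, 1-10. Default 3.
#' @param ec_level Error-correction level, one of \code{"L","M","Q","H"}.
#'   Default \code{"Q"}: the highest level whose byte-mode capacity (32
#'   characters at version 3) still holds a typical URL + identifier.
#' @param mask Mask pattern 0-7, or \code{NULL} (default) to select the
#'   mask with the lowest standard penalty score.
#' @return A \code{qr_matrix}: integer matrix (1 = dark, 0 = light) with
#'   attributes \code{version}, \code{ec_level}, \code{mask},
#'   \code{payload} and \code{fmask} (function-module positions).
#' @examples
#' m <- encode_payload("http://diesmar.com/#AdDk", version = 3, ec_level = "H")
#' dim(m)  # 29 x 29
#' @export
encode_payload <- function(payload, version = 3L, ec_level = "Q", mask = NULL) {
  stopifnot(is.character(payload), length(payload) == 1L)
  version <- as.integer(version)
  ec_level <- match.arg(ec_level, c("L", "M", "Q", "H"))
  bytes <- utf8ToInt(enc2utf8(payload))
  if (any(bytes > 255L)) bytes <- as.integer(charToRaw(enc2utf8(payload)))

  cw <- qr_encode_codewords(bytes, version, ec_level)
  tmpl <- qr_template(version)
  side <- qr_side(version)
  coords <- qr_data_coords(version)
  nbits <- nrow(coords)
  bitstream <- integer(nbits)
  cw_bits <- as.integer(bitwAnd(
    bitwShiftR(rep(cw, each = 8L), rep(7:0, length(cw))), 1L))
  bitstream[seq_len(min(nbits, length(cw_bits)))] <-
    cw_bits[seq_len(min(nbits, length(cw_bits)))]

  build <- function(msk) {
    m <- tmpl$m
    flip <- qr_mask_fun(msk)(coords[, 1L], coords[, 2L])
    m[cbind(coords[, 1L] + 1L, coords[, 2L] + 1L)] <-
      bitwXor(bitstream, as.integer(flip))
    fb <- qr_format_bits(ec_level, msk)
    fpos <- qr_format_positions(side)
    bits <- bitwAnd(bitwShiftR(fb, 0:14), 1L)
    m[cbind(fpos$copy1[, 1L] + 1L, fpos$copy1[, 2L] + 1L)] <- bits
    m[cbind(fpos$copy2[, 1L] + 1L, fpos$copy2[, 2L] + 1L)] <- bits
    m
  }

  if (is.null(mask)) {
    pens <- vapply(0:7, function(k) qr_mask_penalty(build(k)), double(1))
    mask <- which.min(pens) - 1L
  }
  m <- build(mask)
  structure(m, class = "qr_matrix", version = version, ec_level = ec_level,
            mask = as.integer(mask), payload = payload, fmask = tmpl$fmask)
}

#' @export
print.qr_matrix <- function(x, ...) {
  cat(sprintf("QR symbol: version %d-%s (%dx%d), mask %d\n",
              attr(x, "version"), attr(x, "ec_level"),
              nrow(x), ncol(x), attr(x, "mask")))
  cat(sprintf("payload: %s\n", attr(x, "payload")))
  invisible(x)
}
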