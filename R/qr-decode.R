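# QR symbol decoder: from a binary module matrix back to the payload.
#
# Deliberately written as an independent code path from the encoder: the
# format information is recovered by nearest-codeword search over the full
# 32-entry BCH codebook, and each Reed-Solomon block is checked by syndrome
# computation with Berlekamp-Massey error location when the capture
# flipped modules (e.g. borderline color patches under a strong illuminant).

rs_syndromes <- function(cw, n_ec) {
  vapply(0:(n_ec - 1L), function(j) gf_poly_eval(cw, gf_pow(2L, j)), integer(1))
}

# Berlekamp-Massey: error-locator polynomial (ascending powers, [1] = const)
rs_error_locator <- function(synd) {
  C <- c(1L, integer(length(synd)))
  B <- C
  L <- 0L; m <- 1L; b <- 1L
  for (n in seq_along(synd) - 1L) {
    d <- synd[n + 1L]
    if (L > 0L) for (i in 1:L)
      d <- bitwXor(d, gf_mul(C[i + 1L], synd[n - i + 1L]))
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= n) {
      T <- C
      coef <- gf_mul(d, gf_inv(b))
      shifted <- c(integer(m), gf_mul(rep(coef, length(B)), B))
      length(shifted) <- length(C)
      shifted[is.na(shifted)] <- 0L
      C <- bitwXor(C, shifted)
      L <- n + 1L - L
      B <- T; b <- d; m <- 1L
    } else {
      coef <- gf_mul(d, gf_inv(b))
      shifted <- c(integer(m), gf_mul(rep(coef, length(B)), B))
      length(shifted) <- length(C)
      shifted[is.na(shifted)] <- 0L
      C <- bitwXor(C, shifted)
      m <- m + 1L
    }
  }
  list(lambda = C[1:(L + 1L)], n_errors = L)
}

# Gaussian elimination over GF(256)
gf_solve <- function(A, y) {
  n <- nrow(A)
  M <- cbind(A, y)
  for (col in seq_len(n)) {
    piv <- which(M[col:n, col] != 0L)
    if (length(piv) == 0L) stop("singular GF(256) system")
    piv <- piv[1L] + col - 1L
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    M[col, ] <- gf_mul(M[col, ], rep(gf_inv(M[col, col]), ncol(M)))
    for (r in seq_len(n)) {
      if (r != col && M[r, col] != 0L)
        M[r, ] <- bitwXor(M[r, ], gf_mul(rep(M[r, col], ncol(M)), M[col, ]))
    }
  }
  M[, n + 1L]
}

# correct one RS block in place; returns list(cw, n_corrected) or stops
rs_correct_block <- function(cw, n_ec) {
  synd <- rs_syndromes(cw, n_ec)
  if (all(synd == 0L)) return(list(cw = cw, n_corrected = 0L))
  loc <- rs_error_locator(synd)
  if (loc$n_errors == 0L || loc$n_errors > n_ec %/% 2L)
    stop("uncorrectable Reed-Solomon block (too many module errors)")
  N <- length(cw)
  # Chien search over byte positions: error at index i <=> lambda(X^-1)=0
  # with X = alpha^(N-1-i)
  pos <- integer(0)
  for (i in 0:(N - 1L)) {
    xinv <- gf_pow(2L, (255L - (N - 1L - i)) %% 255L)
    acc <- 0L; xp <- 1L
    for (k in seq_along(loc$lambda)) {
      acc <- bitwXor(acc, gf_mul(loc$lambda[k], xp))
      xp <- gf_mul(xp, xinv)
    }
    if (acc == 0L) pos <- c(pos, i)
  }
  if (length(pos) != loc$n_errors)
    stop("uncorrectable Reed-Solomon block (locator root mismatch)")
  # magnitudes from the syndrome equations S_j = sum_k e_k X_k^j
  X <- vapply(pos, function(i) gf_pow(2L, N - 1L - i), integer(1))
  t <- length(pos)
  A <- matrix(0L, t, t)
  for (j in seq_len(t)) for (k in seq_len(t))
    A[j, k] <- gf_pow(X[k], j - 1L)
  e <- gf_solve(A, synd[seq_len(t)])
  cw[pos + 1L] <- bitwXor(cw[pos + 1L], e)
  if (!all(rs_syndromes(cw, n_ec) == 0L))
    stop("uncorrectable Reed-Solomon block (correction failed)")
  list(cw = cw, n_corrected = t)
}

# read the 15 format bits at the given positions and match the codebook
qr_read_format <- function(m, side) {
  fpos <- qr_format_positions(side)
  book <- qr_format_codebook()
  best <- NULL; best_d <- Inf
  for (copy in list(fpos$copy1, fpos$copy2)) {
    bits <- m[cbind(copy[, 1L] + 1L, copy[, 2L] + 1L)]
    word <- sum(bitwShiftL(as.integer(bits), 0:14))
    d <- vapply(book$bits, function(b) {
      x <- bitwXor(b, word)
      sum(bitwAnd(bitwShiftR(x, 0:14), 1L))
    }, integer(1))
    if (min(d) < best_d) {
      best_d <- min(d)
      best <- book[which.min(d), ]
    }
  }
  if (best_d > 3L) stop("format information unreadable (distance ", best_d, ")")
  list(ec_level = best$ec, mask = best$mask)
}

#' Decode a QR module matrix
#'
#' Recovers the payload from a binary (1 = dark) module matrix, e.g. one
#' sampled from a photograph or from a rendered symbol. Handles any mask
#' and error-correction level and corrects byte errors up to the
#' Reed-Solomon budget of the symbol.
#'
#' @param m Integer or logical side x side matrix, 1/TRUE = dark.
#' @return List with \code{payload}, \code{version}, \code{ec_level},
#'   \code{mask} and \code{n_corrected} (RS byte corrections applied).
#' @export
decode_matrix <- function(m) {
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  side <- nrow(m)
  if (side != ncol(m) || (side - 17L) %% 4L != 0L)
    stop("not a QR module matrix: side ", side)
  version <- (side - 17L) %/% 4L
  if (version > qr_max_version)
    stop("unsupported QR version ", version)

  fmt <- qr_read_format(m, side)
  spec <- qr_ec_spec(version, fmt$ec_level)
  coords <- qr_data_coords(version)
  bits <- m[cbind(coords[, 1L] + 1L, coords[, 2L] + 1L)]
  flip <- qr_mask_fun(fmt$mask)(coords[, 1L], coords[, 2L])
  bits <- bitwXor(as.integer(bits), as.integer(flip))

  n_cw <- qr_total_codewords(version)
  bits <- bits[seq_len(8L * n_cw)]
  cw <- as.integer(colSums(matrix(bits, 8L) * bitwShiftL(1L, 7:0)))

  # de-interleave
  nb <- length(spec$blocks)
  data_cw <- vector("list", nb)
  ec_cw <- vector("list", nb)
  k <- 0L
  for (i in seq_len(max(spec$blocks))) for (b in seq_len(nb)) {
    if (i <= spec$blocks[b]) {
      k <- k + 1L
      data_cw[[b]] <- c(data_cw[[b]], cw[k])
    }
  }
  for (i in seq_len(spec$ec)) for (b in seq_len(nb)) {
    k <- k + 1L
    ec_cw[[b]] <- c(ec_cw[[b]], cw[k])
  }

  n_corrected <- 0L
  data_bytes <- integer(0)
  for (b in seq_len(nb)) {
    fixed <- rs_correct_block(c(data_cw[[b]], ec_cw[[b]]), spec$ec)
    n_corrected <- n_corrected + fixed$n_corrected
    data_bytes <- c(data_bytes, fixed$cw[seq_len(spec$blocks[b])])
  }

  # parse byte-mode segment
  stream <- as.integer(bitwAnd(
    bitwShiftR(rep(data_bytes, each = 8L), rep(7:0, length(data_bytes))), 1L))
  take <- function(n) {
    v <- stream[seq_len(n)]
    stream <<- stream[-seq_len(n)]
    sum(bitwShiftL(v, (n - 1L):0L))
  }
  mode <- take(4L)
  if (mode == 0L) return(list(payload = "", version = version,
                              ec_level = fmt$ec_level, mask = fmt$mask,
                              n_corrected = n_corrected))
  if (mode != 4L) stop("unsupported QR mode indicator ", mode,
                       " (only byte mode is supported)")
  count <- take(if (version <= 9L) 8L else 16L)
  bytes <- vapply(seq_len(count), function(i) take(8L), double(1))
  payload <- rawToChar(as.raw(bytes))
  Encoding(payload) <- "UTF-8"
  if (!validUTF8(payload)) Encoding(payload) <- "latin1"
  list(payload = payload, version = version, ec_level = fmt$ec_level,
       mask = fmt$mask, n_corrected = n_corrected)
}
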