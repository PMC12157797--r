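# Constant tables for QR model-2 symbols, versions 1-10, byte mode.
# All indices in this file are 0-based module coordinates (row, col) from the
# top-left corner, matching image row-major order.

# GF(256) arithmetic, primitive polynomial x^8+x^4+x^3+x^2+1 (0x11D)
.gf <- local({
  exp <- integer(512L)
  log <- integer(256L)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 0x11DL)
  }
  exp[256:510] <- exp[1:255]  # wraparound so exp[(a+b) mod 255] is a lookup
  list(exp = exp, log = log)
})

gf_mul <- function(a, b) {
  out <- integer(length(a) * 0 + max(length(a), length(b)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- .gf$exp[(.gf$log[a[nz] + 1L] + .gf$log[b[nz] + 1L]) %% 255L + 1L]
  out
}

gf_pow <- function(base, e) {
  if (base == 0L) return(0L)
  .gf$exp[(.gf$log[base + 1L] * e) %% 255L + 1L]
}

gf_inv <- function(a) {
  if (any(a == 0L)) stop("GF(256) division by zero")
  .gf$exp[(255L - .gf$log[a + 1L]) %% 255L + 1L]
}

# polynomial ops; polynomials are integer vectors, highest-degree term first
gf_poly_mul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    prod <- gf_mul(rep(p[i], length(q)), q)
    idx <- i:(i + length(q) - 1L)
    out[idx] <- bitwXor(out[idx], prod)
  }
  out
}

gf_poly_eval <- function(p, x) {
  # Horner
  y <- 0L
  for (coef in p) y <- bitwXor(gf_mul(y, x), coef)
  y
}

# Reed-Solomon generator polynomial with roots alpha^0 .. alpha^(n-1)
rs_generator_poly <- function(n) {
  g <- 1L
  for (i in 0:(n - 1L)) g <- gf_poly_mul(g, c(1L, gf_pow(2L, i)))
  g
}

# Error-correction block structure per (version, level).
# Each entry: ec = EC codewords per block; blocks = data codeword counts.
.qr_ec_blocks <- list(
  `1` = list(L = list(ec =  7L, blocks = c(19L)),
             M = list(ec = 10L, blocks = c(16L)),
             Q = list(ec = 13L, blocks = c(13L)),
             H = list(ec = 17L, blocks = c(9L))),
  `2` = list(L = list(ec = 10L, blocks = c(34L)),
             M = list(ec = 16L, blocks = c(28L)),
             Q = list(ec = 22L, blocks = c(22L)),
             H = list(ec = 28L, blocks = c(16L))),
  `3` = list(L = list(ec = 15L, blocks = c(55L)),
             M = list(ec = 26L, blocks = c(44L)),
             Q = list(ec = 18L, blocks = c(17L, 17L)),
             H = list(ec = 22L, blocks = c(13L, 13L))),
  `4` = list(L = list(ec = 20L, blocks = c(80L)),
             M = list(ec = 18L, blocks = c(32L, 32L)),
             Q = list(ec = 26L, blocks = c(24L, 24L)),
             H = list(ec = 16L, blocks = c(9L, 9L, 9L, 9L))),
  `5` = list(L = list(ec = 26L, blocks = c(108L)),
             M = list(ec = 24L, blocks = c(43L, 43L)),
             Q = list(ec = 18L, blocks = c(15L, 15L, 16L, 16L)),
             H = list(ec = 22L, blocks = c(11L, 11L, 12L, 12L))),
  `6` = list(L = list(ec = 18L, blocks = c(68L, 68L)),
             M = list(ec = 16L, blocks = c(27L, 27L, 27L, 27L)),
             Q = list(ec = 24L, blocks = c(19L, 19L, 19L, 19L)),
             H = list(ec = 28L, blocks = c(15L, 15L, 15L, 15L))),
  `7` = list(L = list(ec = 20L, blocks = c(78L, 78L)),
             M = list(ec = 18L, blocks = c(31L, 31L, 31L, 31L)),
             Q = list(ec = 18L, blocks = c(14L, 14L, 15L, 15L, 15L, 15L)),
             H = list(ec = 26L, blocks = c(13L, 13L, 13L, 13L, 14L))),
  `8` = list(L = list(ec = 24L, blocks = c(97L, 97L)),
             M = list(ec = 22L, blocks = c(38L, 38L, 39L, 39L)),
             Q = list(ec = 22L, blocks = c(18L, 18L, 18L, 18L, 19L, 19L)),
             H = list(ec = 26L, blocks = c(14L, 14L, 14L, 14L, 15L, 15L))),
  `9` = list(L = list(ec = 30L, blocks = c(116L, 116L)),
             M = list(ec = 22L, blocks = c(36L, 36L, 36L, 37L, 37L)),
             Q = list(ec = 20L, blocks = c(16L, 16L, 16L, 16L, 17L, 17L, 17L, 17L)),
             H = list(ec = 24L, blocks = c(12L, 12L, 12L, 12L, 13L, 13L, 13L, 13L))),
  `10` = list(L = list(ec = 18L, blocks = c(68L, 68L, 69L, 69L)),
              M = list(ec = 26L, blocks = c(43L, 43L, 43L, 43L, 44L)),
              Q = list(ec = 24L, blocks = c(19L, 19L, 19L, 19L, 19L, 19L, 20L, 20L)),
              H = list(ec = 28L, blocks = c(15L, 15L, 15L, 15L, 15L, 15L, 16L, 16L)))
)

qr_max_version <- 10L

qr_ec_spec <- function(version, ec_level) {
  v <- as.character(version)
  if (is.null(.qr_ec_blocks[[v]]))
    stop("unsupported QR version ", version, " (supported: 1-", qr_max_version, ")")
  .qr_ec_blocks[[v]][[ec_level]]
}

# remainder bits left over after the last codeword, per version
qr_remainder_bits <- function(version) {
  if (version == 1L) 0L else if (version <= 6L) 7L else 0L
}

qr_side <- function(version) 17L + 4L * as.integer(version)

# alignment pattern center coordinates per version
.qr_align_pos <- list(
  `1` = integer(0), `2` = c(6L, 18L), `3` = c(6L, 22L), `4` = c(6L, 26L),
  `5` = c(6L, 30L), `6` = c(6L, 34L), `7` = c(6L, 22L, 38L),
  `8` = c(6L, 24L, 42L), `9` = c(6L, 26L, 46L), `10` = c(6L, 28L, 50L)
)

qr_alignment_centers <- function(version) {
  pos <- .qr_align_pos[[as.character(version)]]
  if (length(pos) == 0L) return(matrix(integer(0), ncol = 2L))
  side <- qr_side(version)
  grid <- expand.grid(row = pos, col = pos)
  # drop the three combinations that collide with finder patterns
  keep <- !((grid$row == 6L & grid$col == 6L) |
              (grid$row == 6L & grid$col == side - 7L) |
              (grid$row == side - 7L & grid$col == 6L))
  as.matrix(grid[keep, c("row", "col"), drop = FALSE])
}

# format information: 5 data bits (ec<<3 | mask) + BCH(15,5), masked
.qr_ec_bits <- c(L = 1L, M = 0L, Q = 3L, H = 2L)

bch_15_5 <- function(data5) {
  g <- 0x537L  # x^10+x^8+x^5+x^4+x^2+x+1
  d <- bitwShiftL(data5, 10L)
  for (bit in 14:10) {
    if (bitwAnd(d, bitwShiftL(1L, bit)) != 0L)
      d <- bitwXor(d, bitwShiftL(g, bit - 10L))
  }
  bitwXor(bitwOr(bitwShiftL(data5, 10L), d), 0x5412L)
}

qr_format_bits <- function(ec_level, mask) {
  bch_15_5(bitwOr(bitwShiftL(.qr_ec_bits[[ec_level]], 3L), mask))
}

# all 32 valid format codewords, for nearest-codeword decoding
qr_format_codebook <- function() {
  ec <- rep(c("L", "M", "Q", "H"), each = 8L)
  mask <- rep(0:7, times = 4L)
  data.frame(ec = ec, mask = mask,
             bits = vapply(seq_along(ec),
                           function(i) qr_format_bits(ec[i], mask[i]), integer(1)))
}

# version information (v >= 7): 6 data bits + BCH(18,6)
bch_18_6 <- function(version) {
  g <- 0x1F25L  # x^12+x^11+x^10+x^9+x^8+x^5+x^2+1
  d <- bitwShiftL(version, 12L)
  for (bit in 17:12) {
    if (bitwAnd(d, bitwShiftL(1L, bit)) != 0L)
      d <- bitwXor(d, bitwShiftL(g, bit - 12L))
  }
  bitwOr(bitwShiftL(version, 12L), d)
}

# total codewords in the symbol (data + EC), from the block table
qr_total_codewords <- function(version) {
  s <- .qr_ec_blocks[[as.character(version)]][["L"]]
  sum(s$blocks) + s$ec * length(s$blocks)
}

# byte-mode character capacity
qr_byte_capacity <- function(version, ec_level) {
  s <- qr_ec_spec(version, ec_level)
  data_bits <- 8L * sum(s$blocks)
  count_bits <- if (version <= 9L) 8L else 16L
  (data_bits - 4L - count_bits) %/% 8L
}

# mask predicates, 0-based (i = row, j = col); TRUE means flip the data bit
qr_mask_fun <- function(mask) {
  switch(as.character(mask),
    "0" = function(i, j) (i + j) %% 2L == 0L,
    "1" = function(i, j) i %% 2L == 0L,
    "2" = function(i, j) j %% 3L == 0L,
    "3" = function(i, j) (i + j) %% 3L == 0L,
    "4" = function(i, j) (i %/% 2L + j %/% 3L) %% 2L == 0L,
    "5" = function(i, j) (i * j) %% 2L + (i * j) %% 3L == 0L,
    "6" = function(i, j) ((i * j) %% 2L + (i * j) %% 3L) %% 2L == 0L,
    "7" = function(i, j) ((i * j) %% 3L + (i + j) %% 2L) %% 2L == 0L,
    stop("mask must be 0-7"))
}
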