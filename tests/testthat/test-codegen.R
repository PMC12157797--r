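# Color QR generation: symbol geometry, payload round trips,
# palette embedding and back-compatibility.

test_that("symbol side length follows the version law", {
  expect_equal(dim(encode_payload(short_payload, 3, "H")), c(29L, 29L))
  expect_equal(nrow(encode_payload("x", 1, "L")), 21L)
  for (v in 1:10)
    expect_equal(nrow(encode_payload("ab", v, "M")), 17L + 4L * v)
})

test_that("module accounting matches the symbol capacity tables", {
  # non-function modules must hold exactly the interleaved codewords plus
  # the version's remainder bits; this pins the EC block tables to the
  # symbol geometry
  for (v in 1:10) {
    n_data_modules <- nrow(colorqr:::qr_data_coords(v))
    expect_equal(n_data_modules,
                 8L * colorqr:::qr_total_codewords(v) +
                   colorqr:::qr_remainder_bits(v))
  }
})

test_that("capacity errors name version, EC level and payload length", {
  err <- expect_error(encode_payload(paper_payload, 3, "H"))
  expect_match(conditionMessage(err), "29 bytes")
  expect_match(conditionMessage(err), "version 3-H")
})

test_that("payloads round-trip through an independent decode path", {
  set.seed(101)
  for (i in 1:50) {
    v <- sample(1:10, 1)
    ec <- sample(c("L", "M", "Q", "H"), 1)
    n <- sample(1:min(qr_byte_capacity(v, ec), 60), 1)
    p <- paste(sample(c(letters, LETTERS, 0:9, "/", ":", "#", "."), n,
                      replace = TRUE), collapse = "")
    dec <- decode_matrix(encode_payload(p, v, ec))
    expect_identical(dec$payload, p)
    expect_identical(dec$ec_level, ec)
  }
})

test_that("decoding corrects flipped modules within the RS budget", {
  set.seed(7)
  m <- encode_payload(paper_payload, 3, "Q")
  mm <- unclass(m)
  tmpl <- colorqr:::qr_template(3)
  free <- which(!tmpl$fmask & is.na(tmpl$m))
  flip <- sample(free, 10)
  mm[flip] <- 1L - mm[flip]
  dec <- decode_matrix(mm)
  expect_identical(dec$payload, paper_payload)
  expect_gt(dec$n_corrected, 0L)
})

test_that("empty palette embedding is a no-op", {
  m <- encode_payload(short_payload, 3, "H")
  empty <- data.frame(id = character(0), R = numeric(0), G = numeric(0),
                      B = numeric(0))
  colored <- embed_palette(m, empty, matrix(integer(0), ncol = 2L))
  bw <- array(0, c(29, 29, 3))
  for (ch in 1:3) bw[, , ch] <- (1 - unclass(m)) * 255
  expect_equal(unclass(colored), bw, ignore_attr = TRUE)
})

test_that("grayscale binarization of a colored render reproduces the matrix", {
  img <- render_symbol(btb_spec$colored, module_px = 8, quiet_zone = 4)
  bits <- colorqr:::symbol_bits_from_image(img, 29, 8, 4)
  expect_identical(bits, matrix(as.integer(btb_spec$matrix), 29, 29))
})

test_that("colored renders still decode to the payload", {
  for (spec in list(btb_spec, dpd_spec)) {
    img <- render_symbol(spec$colored, 8, 4)
    bits <- colorqr:::symbol_bits_from_image(img, 29, 8, 4)
    expect_identical(decode_matrix(bits)$payload, spec$payload)
  }
})

test_that("randomized palettes keep symbols back-compatible", {
  # the seeded property behind the design: color embedding never breaks
  # binarization nor decoding
  set.seed(202)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    pal <- data.frame(id = paste0("p", 1:n),
                      R = sample(0:255, n, TRUE),
                      G = sample(0:255, n, TRUE),
                      B = sample(0:255, n, TRUE))
    p <- paste0("http://diesmar.com/#", paste(sample(letters, 8, TRUE),
                                              collapse = ""))
    spec <- color_qr_spec(p, palette = pal)
    img <- render_symbol(spec$colored, 4, 4)
    bits <- colorqr:::symbol_bits_from_image(img, 29, 4, 4)
    expect_identical(bits, matrix(as.integer(spec$matrix), 29, 29))
    expect_identical(decode_matrix(bits)$payload, p)
  }
})

test_that("placement validation rejects bad placements", {
  m <- encode_payload(short_payload, 3, "H")
  pal <- data.frame(id = "white", R = 255, G = 255, B = 255)
  # (0, 0) is inside the top-left finder pattern
  expect_error(embed_palette(m, pal, matrix(c(0L, 0L), 1)),
               "function pattern")
  # a light color on a dark module is a luminance conflict
  dark_mods <- which(unclass(m) == 1L & !attr(m, "fmask"), arr.ind = TRUE)
  dm <- dark_mods[1, ] - 1L
  expect_error(embed_palette(m, pal, matrix(dm, 1)), "luminance conflict")
})

test_that("rendered geometry and patch pixels are exact", {
  img <- render_symbol(btb_spec$colored, module_px = 10, quiet_zone = 4)
  expect_equal(dim(img), c(370, 370, 3))
  # center pixel of each palette placement equals its reference color
  for (k in seq_len(nrow(btb_spec$palette))) {
    r <- btb_spec$placements[k, 1]; c <- btb_spec$placements[k, 2]
    px <- img[(4 + r) * 10 + 5, (4 + c) * 10 + 5, ]
    expect_equal(as.numeric(px),
                 as.numeric(btb_spec$palette[k, c("R", "G", "B")]))
  }
  # module_px = 1: pixel grid equals cell grid plus quiet zone
  img1 <- render_symbol(btb_spec$colored, 1, 2)
  expect_equal(dim(img1), c(33, 33, 3))
})

test_that("palette JSON round-trips", {
  pal <- default_palette("dpd")
  path <- tempfile(fileext = ".json")
  write_palette(pal, path)
  expect_equal(read_palette(path), pal)
})
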