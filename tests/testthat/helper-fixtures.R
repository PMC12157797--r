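# Shared fixtures, built once per test run.

paper_payload <- "http://diesmar.com/#n87RXv6i3"
short_payload <- "http://diesmar.com/#AdDk"

btb_spec <- color_qr_spec(paper_payload, palette = default_palette("btb"))
dpd_spec <- color_qr_spec(paper_payload, palette = default_palette("dpd"))

# the scene-formation color transform of the generator, recomputed
# independently of render_scene for held-out oracle checks
distort_colors <- function(colors, cct, gamma = FALSE) {
  g <- illuminant_gains(cct)
  g <- g / max(g)
  out <- sweep(as.matrix(colors), 2L, g, "*")
  out <- pmin(pmax(out, 0), 255)
  if (gamma) out <- 255 * (out / 255)^(1 / 2.2)
  out
}

# random colors inside the palette's convex hull (mixtures of entries)
hull_colors <- function(palette, n, seed = 1) {
  set.seed(seed)
  P <- as.matrix(palette[, c("R", "G", "B")])
  t(vapply(seq_len(n), function(i) {
    w <- stats::runif(nrow(P))
    as.numeric(colSums(P * (w / sum(w))))
  }, double(3)))
}

# synthetic BTB feature table straight from the response model (no imaging)
btb_feature_table <- function(C, sigma = 0, seed = 1) {
  set.seed(seed)
  params <- default_response_params("btb", noise_sigma = sigma)
  rgb <- btb_response(C, params)
  fv <- do.call(rbind, lapply(seq_len(nrow(rgb)),
                              function(i) extract_features(rgb[i, ])))
  fv$concentration_ppm <- C
  fv
}
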