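# Synthetic scene and sample generator.
#
# Emulates the acquisition conditions of the assay photographs: dye
# response vs. concentration, illuminant color temperature (Planckian,
# 2500-6500 K), perspective distortion from hand-held capture, and sensor
# noise. Every scene carries complete ground truth so each pipeline stage
# can be tested against known answers.

#' Default dye response parameters
#'
#' BTB (strip): the red channel decays exponentially with concentration,
#' calibrated so that the inverse map is the log-linear line
#' C = m ln(R) + b with m = -0.64 ppm per ln-intensity and b = 3.3 ppm;
#' green and blue decay linearly. DPD (cuvette): log-linear decays of the
#' green and blue channels with red held high, producing the pink ramp.
#' The channel constants other than (m, b) are package conventions chosen
#' to reproduce the qualitative feature trends; they are configurable and
#' carry no claim of being measured values.
#'
#' @param chemistry \code{"btb"} or \code{"dpd"}.
#' @param noise_sigma Gaussian channel noise, 8-bit units (default 2).
#' @return List of response parameters.
#' @export
default_response_params <- function(chemistry = c("btb", "dpd"),
                                    noise_sigma = 2) {
  chemistry <- match.arg(chemistry)
  stopifnot(noise_sigma >= 0)
  if (chemistry == "btb") {
    list(chemistry = "btb", m = -0.64, b = 3.3,
         G0 = 200, gG = 25, B0 = 150, gB = 10,
         noise_sigma = noise_sigma,
         valid_range = c(0.2, 0.9))
  } else {
    list(chemistry = "dpd", lnG0 = log(230), gG = 0.35,
         lnB0 = log(235), gB = 0.25, R_level = 230,
         noise_sigma = noise_sigma,
         valid_range = c(0.2, 1.1))
  }
}

#' BTB strip pad color response
#'
#' R = exp((b - C)/|m|), G = G0 - gG C, B = B0 - gB C, each clipped to
#' [0, 255], plus Gaussian noise of sd \code{params$noise_sigma} drawn from
#' the current RNG state (seed with \code{set.seed}).
#'
#' @param C Concentration(s), ppm, >= 0.
#' @param params See \code{\link{default_response_params}}.
#' @return n x 3 matrix of 8-bit RGB colors.
#' @export
btb_response <- function(C, params = default_response_params("btb")) {
  if (any(C < 0)) stop("concentration must be non-negative")
  base <- cbind(
    R = exp((params$b - C) / abs(params$m)),
    G = params$G0 - params$gG * C,
    B = params$B0 - params$gB * C)
  add_channel_noise(clip255(base), params$noise_sigma)
}

#' DPD cuvette color response
#'
#' ln G and ln B decrease linearly in concentration while R stays at
#' \code{R_level}, giving the white-to-pink ramp of the DPD reaction.
#'
#' @inheritParams btb_response
#' @export
dpd_response <- function(C, params = default_response_params("dpd")) {
  if (any(C < 0)) stop("concentration must be non-negative")
  base <- cbind(
    R = rep(params$R_level, length(C)),
    G = exp(params$lnG0 - params$gG * C),
    B = exp(params$lnB0 - params$gB * C))
  add_channel_noise(clip255(base), params$noise_sigma)
}

add_channel_noise <- function(base, sigma) {
  if (sigma > 0)
    base <- base + matrix(stats::rnorm(length(base), 0, sigma), nrow(base))
  clip255(base)
}

#' Diagonal illuminant gains for a correlated color temperature
#'
#' Von Kries gains of a Planckian radiator at the given CCT, relative to
#' the 6500 K reference condition under which the palette references are
#' defined, with the green gain normalized to 1 (so gains(6500 K) is
#' exactly (1, 1, 1)). The chromaticity comes from the standard cubic
#' polynomial approximation of the Planckian locus in CIE 1931 (x, y),
#' converted to linear sRGB; since scene pixels live on the
#' gamma-encoded 8-bit scale, the linear-light ratio is raised to 1/2.2
#' so the gains express the illuminant's effect on encoded values.
#'
#' @param cct Correlated color temperature in kelvin, in [1000, 12000].
#' @return Length-3 gain vector (R, G, B).
#' @export
illuminant_gains <- function(cct) {
  stopifnot(length(cct) == 1L)
  if (cct < 1000 || cct > 12000)
    stop("cct must be in [1000, 12000] K, got ", cct)
  w <- (planck_rgb(cct) / planck_rgb(6500))^(1 / 2.2)
  w / w[2L]
}

# linear-sRGB white of a Planckian radiator (cubic locus approximation)
planck_rgb <- function(T) {
  t3 <- 1e9 / T^3; t2 <- 1e6 / T^2; t1 <- 1e3 / T
  x <- if (T <= 4000)
    -0.2661239 * t3 - 0.2343589 * t2 + 0.8776956 * t1 + 0.179910
  else
    -3.0258469 * t3 + 2.1070379 * t2 + 0.2226347 * t1 + 0.240390
  y <- if (T <= 2222)
    -1.1063814 * x^3 - 1.34811020 * x^2 + 2.18555832 * x - 0.20219683
  else if (T <= 4000)
    -0.9549476 * x^3 - 1.37418593 * x^2 + 2.09137015 * x - 0.16748867
  else
    3.0817580 * x^3 - 5.87338670 * x^2 + 3.75112997 * x - 0.37001483
  X <- x / y; Y <- 1; Z <- (1 - x - y) / y
  rgb <- c(3.2406 * X - 1.5372 * Y - 0.4986 * Z,
           -0.9689 * X + 1.8758 * Y + 0.0415 * Z,
           0.0557 * X - 0.2040 * Y + 1.0570 * Z)
  pmax(rgb, 1e-6)
}

#' Default canonical scene layout
#'
#' Canvas geometry of the canonical frame: the QR symbol occupies a fixed
#' square at the left and the assay hardware search window lies to its
#' right (the placement that minimizes projective deformation of the
#' assay region).
#'
#' @return Nested list: canvas size, QR placement (top-left pixel of the
#'   symbol, module pixels), hardware search window, strip/pad and cuvette
#'   rectangles (all 0-based pixel coordinates, x = column).
#' @export
default_layout <- function() {
  list(
    canvas_w = 560L, canvas_h = 340L,
    qr = list(x = 40L, y = 54L, module_px = 8L),
    search_window = list(x = 300L, y = 30L, w = 250L, h = 290L),
    strip = list(x = 380L, y = 50L, w = 56L, h = 240L, gray = 230),
    pad = list(x = 386L, y = 148L, w = 44L, h = 44L),
    cuvette = list(x = 320L, y = 140L, w = 180L, h = 60L, border = 6L,
                   dark = 25)
  )
}

rect_overlap <- function(a, b) {
  !(a$x + a$w <= b$x || b$x + b$w <= a$x ||
      a$y + a$h <= b$y || b$y + b$h <= a$y)
}

#' Render a synthetic assay scene
#'
#' Draws the Color QR code and the assay hardware (strip pad or
#' dark-bordered cuvette) on a white canvas at the layout positions,
#' applies diagonal illuminant gains (optionally followed by a 2.2 camera
#' gamma), warps the canvas with a projective transform whose corners are
#' jittered by up to \code{warp_jitter} of the canvas size, and adds
#' Gaussian sensor noise. Identical seeds give byte-identical scenes.
#'
#' @param spec A \code{color_qr} from \code{\link{color_qr_spec}}.
#' @param chemistry \code{"btb"} or \code{"dpd"}.
#' @param C Free-chlorine concentration, ppm.
#' @param layout See \code{\link{default_layout}}.
#' @param cct Illuminant correlated color temperature, K.
#' @param warp_jitter Corner jitter as a fraction of the canvas size
#'   (0 = axis-aligned placement).
#' @param noise_sigma Sensor noise sd, 8-bit units.
#' @param gamma If \code{TRUE}, apply a 2.2 encoding gamma after the
#'   gains (a per-channel non-linearity that diagonal white balance
#'   cannot undo).
#' @param seed Integer seed controlling every random draw in the scene.
#' @param params Response parameters; default
#'   \code{default_response_params(chemistry, noise_sigma = 0)} (the pad
#'   base color is deterministic; scene noise plays the sensor role).
#' @return A \code{synthetic_scene}: list with \code{image} (H x W x 3)
#'   and \code{truth} (concentration, class_label, homography canvas ->
#'   image, pad/cuvette box, illuminant, gains, seed).
#' @export
render_scene <- function(spec, chemistry = c("btb", "dpd"), C,
                         layout = default_layout(), cct = 6500,
                         warp_jitter = 0, noise_sigma = 0, gamma = FALSE,
                         seed = 1L,
                         params = default_response_params(chemistry,
                                                          noise_sigma = 0)) {
  chemistry <- match.arg(chemistry)
  stopifnot(inherits(spec, "color_qr"), C >= 0, warp_jitter >= 0)
  set.seed(as.integer(seed))

  qr_img <- render_symbol(spec$colored, layout$qr$module_px, quiet_zone = 0L)
  qr_rect <- list(x = layout$qr$x, y = layout$qr$y,
                  w = dim(qr_img)[2L], h = dim(qr_img)[1L])
  assay_rect <- if (chemistry == "btb") layout$strip else layout$cuvette
  if (rect_overlap(qr_rect, assay_rect))
    stop("layout overlap: QR symbol and assay hardware rectangles collide")

  w <- layout$canvas_w; h <- layout$canvas_h
  canvas <- array(255, c(h, w, 3L))
  canvas[(qr_rect$y + 1L):(qr_rect$y + qr_rect$h),
         (qr_rect$x + 1L):(qr_rect$x + qr_rect$w), ] <- qr_img

  fill_rect <- function(img, r, rgb) {
    for (ch in 1:3)
      img[(r$y + 1L):(r$y + r$h), (r$x + 1L):(r$x + r$w), ch] <- rgb[ch]
    img
  }
  color <- as.numeric(
    if (chemistry == "btb") btb_response(C, params) else dpd_response(C, params))
  if (chemistry == "btb") {
    s <- layout$strip
    canvas <- fill_rect(canvas, s, rep(s$gray, 3L))
    canvas <- fill_rect(canvas, layout$pad, color)
    truth_box <- layout$pad
  } else {
    cv <- layout$cuvette
    canvas <- fill_rect(canvas, cv, rep(cv$dark, 3L))
    inner <- list(x = cv$x + cv$border, y = cv$y + cv$border,
                  w = cv$w - 2L * cv$border, h = cv$h - 2L * cv$border)
    canvas <- fill_rect(canvas, inner, color)
    truth_box <- cv
  }

  # exposure-normalized von Kries gains: dividing by the largest gain
  # emulates camera auto-exposure, so a warm illuminant shifts chromaticity
  # without saturating bright patches
  gains <- illuminant_gains(cct) / max(illuminant_gains(cct))
  for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] * gains[ch]
  canvas <- clip255(canvas)
  if (isTRUE(gamma)) canvas <- 255 * (canvas / 255)^(1 / 2.2)

  src <- cbind(c(0, w - 1, w - 1, 0), c(0, 0, h - 1, h - 1))
  jit <- warp_jitter * min(w, h)
  dst <- src + matrix(stats::runif(8L, -jit, jit), 4L, 2L)
  H <- fit_homography(src, dst)
  img <- if (warp_jitter > 0) warp_image(canvas, H, w, h, fill = 255) else canvas
  if (warp_jitter == 0) H <- diag(3)

  if (noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sigma), dim(img))
  img <- clip255(img)

  structure(list(
    image = img,
    truth = list(concentration = C,
                 class_label = relabel_concentration(C, class_bounds(chemistry)),
                 homography = H,
                 box = truth_box,
                 illuminant_cct = cct,
                 gains = gains,
                 gamma = isTRUE(gamma),
                 noise_sigma = noise_sigma,
                 chemistry = chemistry,
                 payload = spec$payload,
                 seed = as.integer(seed)),
    spec = spec, layout = layout
  ), class = "synthetic_scene")
}

#' Draw response samples without rendering scenes
#'
#' Samples concentrations and evaluates the dye response model with
#' channel noise; the light-weight route to calibration-style tables
#' (concentration + RGB) when no imaging is involved.
#'
#' @param n Number of samples.
#' @param chemistry \code{"btb"} or \code{"dpd"}.
#' @param range Concentration interval to sample uniformly; default the
#'   chemistry's acceptable (medium) class interval.
#' @param params Response parameters (noise included here).
#' @param seed RNG seed.
#' @return Data frame with columns \code{concentration_ppm}, \code{R},
#'   \code{G}, \code{B}.
#' @export
sample_responses <- function(n, chemistry = c("btb", "dpd"),
                             range = NULL,
                             params = default_response_params(chemistry),
                             seed = 1L) {
  chemistry <- match.arg(chemistry)
  if (is.null(range)) range <- params$valid_range
  set.seed(as.integer(seed))
  C <- stats::runif(n, range[1L], range[2L])
  rgb <- if (chemistry == "btb") btb_response(C, params)
         else dpd_response(C, params)
  data.frame(concentration_ppm = C, R = rgb[, 1L], G = rgb[, 2L],
             B = rgb[, 3L])
}

#' Stratified concentration sampler
#'
#' Returns a sampler function drawing equal thirds from the three
#' chlorine classes, spanning 0-\code{max_c} ppm.
#'
#' @param bounds Class bounds (see \code{\link{class_bounds}}).
#' @param max_c Upper concentration, ppm (default 8.4, the top of the
#'   diluted measurement range).
#' @param min_c Lower concentration for the low class.
#' @return Function \code{f(n)} returning n concentrations.
#' @export
sampler_stratified <- function(bounds, max_c = 8.4, min_c = 0.02) {
  force(bounds)
  function(n) {
    cls <- rep_len(1:3, n)
    lo <- c(min_c, bounds$low_max, bounds$high_min)[cls]
    hi <- c(bounds$low_max, bounds$high_min, max_c)[cls]
    stats::runif(n, lo, hi)
  }
}

#' Generate a labelled synthetic dataset on disk
#'
#' Renders scenes across the illuminant grid, writes one PNG per scene, a
#' ground-truth CSV matching the training-table schema, and a sidecar
#' JSON with every generation parameter.
#'
#' @param n Number of scenes, >= 1.
#' @param chemistry \code{"btb"} or \code{"dpd"}.
#' @param dir Output directory (created if missing).
#' @param spec Color QR spec; default one built on the built-in palette.
#' @param concentration_sampler Function \code{f(n)}; default stratified
#'   over the three classes up to 8.4 ppm.
#' @param cct_grid Illuminant grid, cycled over scenes; default
#'   2500-6500 K in 500 K steps.
#' @param warp_jitter,noise_sigma,gamma Scene rendering controls.
#' @param layout Canonical layout.
#' @param seed Master seed; scene i uses seed \code{seed * 10000 + i}.
#' @return Invisibly, the truth data frame (with \code{image_path}).
#' @export
generate_dataset <- function(n, chemistry = c("btb", "dpd"), dir,
                             spec = NULL,
                             concentration_sampler = NULL,
                             cct_grid = seq(2500, 6500, by = 500),
                             warp_jitter = 0.02, noise_sigma = 2,
                             gamma = FALSE, layout = default_layout(),
                             seed = 1L) {
  chemistry <- match.arg(chemistry)
  stopifnot(n >= 1L)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  if (is.null(spec))
    spec <- color_qr_spec("http://diesmar.com/#n87RXv6i3",
                          palette = default_palette(chemistry))
  bounds <- class_bounds(chemistry)
  if (is.null(concentration_sampler))
    concentration_sampler <- sampler_stratified(bounds)
  set.seed(as.integer(seed))
  C <- concentration_sampler(n)
  cct <- rep_len(cct_grid, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- render_scene(spec, chemistry, C[i], layout = layout,
                       cct = cct[i], warp_jitter = warp_jitter,
                       noise_sigma = noise_sigma, gamma = gamma,
                       seed = as.integer(seed) * 10000L + i)
    path <- file.path(dir, sprintf("scene_%04d.png", i))
    ok <- tryCatch(write_image(sc$image, path), error = function(e)
      stop("failed writing ", path, ": ", conditionMessage(e)))
    rows[[i]] <- data.frame(
      image_path = path, chemistry = chemistry,
      concentration_ppm = C[i],
      class_label = sc$truth$class_label,
      illuminant_K = cct[i], flash = "no", device = "synthetic",
      seed = sc$truth$seed, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    n = n, chemistry = chemistry, cct_grid = cct_grid,
    warp_jitter = warp_jitter, noise_sigma = noise_sigma, gamma = gamma,
    seed = seed, payload = spec$payload,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(truth)
}
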