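# End-to-end readout: photo -> detection -> rectification -> color
# correction -> ROI -> features -> chlorine class and ppm estimate.

#' Analyze one assay scene
#'
#' Runs the full readout pipeline on a photograph: locates and decodes
#' the Color QR, rectifies to the canonical frame, samples the embedded
#' palette, fits the thin-plate-spline correction, finds the assay ROI
#' (pad or cuvette inner square), extracts corrected features, and, if a
#' calibration model is supplied, classifies and estimates ppm.
#'
#' @param scene Image array or PNG path.
#' @param spec The \code{color_qr} the scene contains.
#' @param chemistry \code{"btb"} or \code{"dpd"}.
#' @param model Optional \code{chlorine_calibration}.
#' @param layout Canonical layout.
#' @param lambda TPS regularization (default 0).
#' @param shrink Cuvette inner-ROI shrink (default 5).
#' @return List with \code{detection}, \code{patches}, \code{map} (TPS),
#'   \code{residual} (palette RMSE after correction), \code{roi} (box +
#'   measurement), \code{features}, and \code{measurement} (when a model
#'   was given).
#' @export
analyze_scene <- function(scene, spec, chemistry = c("btb", "dpd"),
                          model = NULL, layout = default_layout(),
                          lambda = 0, shrink = 5) {
  chemistry <- match.arg(chemistry)
  if (is.character(scene)) scene <- read_image(scene)
  det <- locate_and_decode(scene)
  if (nzchar(spec$qr_id) && !identical(det$qr_id, spec$qr_id))
    stop("layout for id unknown: decoded '", det$qr_id,
         "' but spec is '", spec$qr_id, "'")
  canonical <- rectify_to_canonical(scene, det, layout)
  patches <- sample_palette_patches(canonical, spec, layout)
  map <- fit_tps_map(patches, lambda = lambda)
  residual <- correction_residual(map, patches)

  if (chemistry == "btb") {
    box <- detect_strip_pad(canonical, layout = layout)
    # measure the central pad region, away from warp bleed at the rim
    meas <- measure_roi(canonical, shrink_to_inner_roi(box, 1.5))
  } else {
    outer <- detect_cuvette(canonical, layout = layout)
    box <- shrink_to_inner_roi(outer, shrink)
    meas <- measure_roi(canonical, box)
  }
  fv <- extract_features(meas, map)

  out <- list(detection = det, patches = patches, map = map,
              residual = residual, roi = list(box = box, measurement = meas),
              features = fv)
  if (!is.null(model)) {
    out$measurement <- predict_concentration(
      fv, model, provenance = list(qr_id = det$qr_id,
                                   corrected_modules = det$n_corrected))
  }
  out
}

#' Build a feature table from a synthetic dataset
#'
#' Runs the measurement pipeline over rendered scenes and returns one
#' feature row per scene joined with its ground truth; the table feeds
#' \code{\link{train_calibration}}.
#'
#' @param truth Data frame from \code{\link{generate_dataset}} (or a path
#'   to its \code{truth.csv}).
#' @param spec The \code{color_qr} used to render the scenes.
#' @param layout Canonical layout.
#' @param quiet Suppress per-scene failure messages.
#' @return Data frame: features (R, G, B, H, L, S, Rc) +
#'   \code{concentration_ppm}, \code{class_label}, \code{illuminant_K},
#'   \code{image_path}, \code{residual}. Scenes whose pipeline fails are
#'   dropped (reported unless \code{quiet}).
#' @export
build_feature_table <- function(truth, spec, layout = default_layout(),
                                quiet = FALSE) {
  if (is.character(truth)) truth <- utils::read.csv(truth)
  chemistry <- as.character(truth$chemistry[1L])
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    res <- tryCatch(
      analyze_scene(truth$image_path[i], spec, chemistry, layout = layout),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (!quiet)
        message("scene ", truth$image_path[i], " failed: ",
                conditionMessage(res))
      next
    }
    rows[[i]] <- cbind(res$features,
                       data.frame(concentration_ppm = truth$concentration_ppm[i],
                                  class_label = truth$class_label[i],
                                  illuminant_K = truth$illuminant_K[i],
                                  image_path = truth$image_path[i],
                                  residual = res$residual,
                                  stringsAsFactors = FALSE))
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
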