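# Colorimetric models: feature extraction, 3-class chlorine classifier,
# and per-chemistry calibration regressions.
#
# BTB strips use all six features (R, G, B, H, L, S) for classification
# and the log of the corrected red channel, ln(Rc), for the medium-range
# regression C = m ln(Rc) + b. DPD cuvettes carry their signal in the
# green and blue channels (the reaction is a pink ramp, so red barely
# moves): classification uses (G, B) and the regression predictor is the
# first principal component of (ln G, ln B).

#' Chlorine class bounds
#'
#' Manufacturer-defined class intervals: low < 0.2 ppm for both tests;
#' the acceptable range ends at 0.9 ppm (BTB strip) or 1.1 ppm (DPD
#' cuvette), above which chlorine is in excess. Intervals are half-open
#' (low: C < low_max; acceptable: low_max <= C < high_min; excess:
#' C >= high_min) so labels are deterministic at the boundaries.
#'
#' @param chemistry \code{"btb"} or \code{"dpd"}.
#' @return List with \code{low_max}, \code{high_min}, \code{labels}.
#' @export
class_bounds <- function(chemistry = c("btb", "dpd")) {
  chemistry <- match.arg(chemistry)
  b <- list(low_max = 0.2,
            high_min = if (chemistry == "btb") 0.9 else 1.1,
            labels = c("low", "acceptable", "excess"))
  stopifnot(0 < b$low_max, b$low_max < b$high_min)
  b
}

#' Relabel concentrations by class bounds
#'
#' @param C Concentrations, ppm.
#' @param bounds From \code{\link{class_bounds}}.
#' @return Factor with levels low / acceptable / excess.
#' @export
relabel_concentration <- function(C, bounds) {
  lab <- ifelse(C < bounds$low_max, "low",
                ifelse(C < bounds$high_min, "acceptable", "excess"))
  factor(lab, levels = bounds$labels)
}

#' Convert RGB to HLS
#'
#' Standard hexcone model: H in degrees [0, 360) (0 when S = 0), L and S
#' in [0, 1]. Vectorized over rows.
#'
#' @param rgb Length-3 vector or n x 3 matrix, components in [0, 255].
#' @return n x 3 matrix with columns \code{H}, \code{L}, \code{S}.
#' @export
rgb_to_hls <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3L)
  if (any(rgb < 0 | rgb > 255))
    stop("rgb components must be in [0, 255]")
  v <- rgb / 255
  mx <- pmax(v[, 1L], v[, 2L], v[, 3L])
  mn <- pmin(v[, 1L], v[, 2L], v[, 3L])
  L <- (mx + mn) / 2
  d <- mx - mn
  S <- ifelse(d == 0, 0, d / (1 - abs(2 * L - 1)))
  H <- numeric(nrow(v))
  r <- v[, 1L]; g <- v[, 2L]; b <- v[, 3L]
  i <- d > 0 & mx == r
  H[i] <- 60 * (((g[i] - b[i]) / d[i]) %% 6)
  i <- d > 0 & mx == g & mx != r
  H[i] <- 60 * ((b[i] - r[i]) / d[i] + 2)
  i <- d > 0 & mx == b & mx != r & mx != g
  H[i] <- 60 * ((r[i] - g[i]) / d[i] + 4)
  cbind(H = H %% 360, L = L, S = S)
}

#' Extract the colorimetric feature vector of an ROI
#'
#' Applies the color-correction map to the ROI's mean color
#' (mean-then-correct), then derives the HLS triple from the corrected
#' color. \code{Rc} is the corrected red channel, the BTB regression
#' predictor.
#'
#' @param m An ROI measurement (list with \code{mean_rgb}) from
#'   \code{\link{measure_roi}}, or a bare RGB triple.
#' @param map A fitted \code{tps_map}, or \code{NULL} for no correction.
#' @return One-row data frame with columns R, G, B, H, L, S, Rc.
#' @export
extract_features <- function(m, map = NULL) {
  rgb <- if (is.list(m) && !is.null(m$mean_rgb)) m$mean_rgb else m
  rgb <- matrix(as.numeric(rgb), ncol = 3L)
  if (!is.null(map)) rgb <- apply_map(map, rgb)
  rgb <- clip255(rgb)  # features live on the 8-bit scale
  hls <- rgb_to_hls(rgb)
  data.frame(R = rgb[, 1L], G = rgb[, 2L], B = rgb[, 3L],
             H = hls[, 1L], L = hls[, 2L], S = hls[, 3L],
             Rc = rgb[, 1L])
}

feature_names_for <- function(chemistry) {
  if (chemistry == "btb") c("R", "G", "B", "H", "L", "S") else c("G", "B")
}

# stratified 80/20 split; returns logical "in training set"
stratified_split <- function(labels, split_seed, train_frac = 0.8) {
  set.seed(as.integer(split_seed))
  train <- logical(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_tr <- max(1L, round(train_frac * length(idx)))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Train the 3-class chlorine classifier
#'
#' Relabels concentrations by the class bounds, performs a stratified
#' 80/20 train/test split, standardizes the chemistry's feature subset
#' (zero mean, unit variance on the training set) and fits an RBF SVM
#' (cost 1, bandwidth 1/d on standardized features).
#'
#' @param table Data frame with the feature columns (R, G, B, H, L, S for
#'   BTB; G, B for DPD) and \code{concentration_ppm}.
#' @param chemistry \code{"btb"} or \code{"dpd"}.
#' @param bounds Class bounds; default those of the chemistry.
#' @param split_seed Seed of the stratified split (default 42).
#' @return A \code{chlorine_calibration} object (classifier part; attach
#'   the regression block with \code{\link{train_calibration}} or the
#'   \code{fit_regression_*} functions). Contains the scaler, the SVM,
#'   split indices and logged train/test accuracies.
#' @export
train_classifier <- function(table, chemistry = c("btb", "dpd"),
                             bounds = NULL, split_seed = 42L) {
  chemistry <- match.arg(chemistry)
  if (is.null(bounds)) bounds <- class_bounds(chemistry)
  feats <- feature_names_for(chemistry)
  missing_cols <- setdiff(c(feats, "concentration_ppm"), names(table))
  if (length(missing_cols) > 0L)
    stop("training table lacks columns: ", paste(missing_cols, collapse = ", "))
  y <- relabel_concentration(table$concentration_ppm, bounds)
  counts <- table(y)
  if (any(counts < 3L))
    stop("missing or underpopulated class after relabeling: ",
         paste(names(counts)[counts < 3L], collapse = ", "),
         " (need >= 3 rows per class)")
  X <- as.matrix(table[, feats])
  train <- stratified_split(y, split_seed)
  mu <- colMeans(X[train, , drop = FALSE])
  sdev <- apply(X[train, , drop = FALSE], 2L, stats::sd)
  if (any(sdev <= 0))
    stop("degenerate feature(s) with zero variance: ",
         paste(feats[sdev <= 0], collapse = ", "))
  Z <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  d <- length(feats)
  fit <- e1071::svm(x = Z[train, , drop = FALSE], y = y[train],
                    kernel = "radial", cost = 1, gamma = 1 / d,
                    scale = FALSE)
  acc <- function(idx) {
    if (!any(idx)) return(NA_real_)
    mean(stats::predict(fit, Z[idx, , drop = FALSE]) == y[idx])
  }
  structure(list(
    chemistry = chemistry,
    feature_names = feats,
    scaler = list(mean = mu, scale = sdev),
    classifier = fit,
    svm_params = list(kernel = "radial", cost = 1, gamma = 1 / d),
    bounds = bounds,
    split_seed = as.integer(split_seed),
    split_train = train,
    train_accuracy = acc(train),
    test_accuracy = acc(!train),
    regression = NULL
  ), class = "chlorine_calibration")
}

#' Classify a feature vector
#'
#' @param fv Feature-vector data frame (from
#'   \code{\link{extract_features}}) or anything with the model's feature
#'   columns.
#' @param model A \code{chlorine_calibration}.
#' @return Factor label: low / acceptable / excess.
#' @export
classify <- function(fv, model) {
  stopifnot(inherits(model, "chlorine_calibration"))
  miss <- setdiff(model$feature_names, names(fv))
  if (length(miss) > 0L)
    stop("feature-name mismatch; missing: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(fv)[, model$feature_names, drop = FALSE])
  Z <- sweep(sweep(X, 2L, model$scaler$mean), 2L, model$scaler$scale, "/")
  stats::predict(model$classifier, Z)
}

#' BTB medium-range calibration line
#'
#' Ordinary least squares of concentration on ln(Rc) over medium-range
#' samples: C = m ln(Rc) + b, with R squared and 95 percent confidence /
#' prediction intervals.
#'
#' @param rows Data frame with columns \code{Rc} (corrected red channel,
#'   > 0) and \code{concentration_ppm}.
#' @return List with \code{m} (slope, ppm per ln-intensity), \code{b}
#'   (intercept, ppm), \code{r_squared}, \code{coef_ci} (95 percent CI on
#'   both coefficients), \code{fit} (the lm object, used for prediction
#'   intervals) and \code{n}.
#' @export
fit_regression_btb <- function(rows) {
  stopifnot(all(c("Rc", "concentration_ppm") %in% names(rows)))
  if (nrow(rows) < 5L) stop("need >= 5 medium-range pairs, got ", nrow(rows))
  if (any(rows$Rc <= 0)) stop("non-positive Rc value; ln(Rc) undefined")
  x <- log(rows$Rc)
  if (stats::sd(x) < 1e-12)
    stop("rank-deficient design: all ln(Rc) values identical")
  fit <- stats::lm(concentration_ppm ~ x,
                   data = data.frame(concentration_ppm = rows$concentration_ppm,
                                     x = x))
  list(m = unname(stats::coef(fit)[2L]),
       b = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       coef_ci = stats::confint(fit, level = 0.95),
       fit = fit,
       n = nrow(rows),
       predictor = "ln(Rc)")
}

#' DPD medium-range calibration (PCA on ln G, ln B)
#'
#' First principal component of the centered (ln G, ln B) cloud, sign
#' fixed so the component increases with concentration, then OLS of
#' concentration on that component.
#'
#' @param rows Data frame with columns \code{G}, \code{B} (> 0) and
#'   \code{concentration_ppm}.
#' @return List with \code{pca_loadings}, \code{pc_mean}, \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{explained_variance},
#'   \code{fit}, \code{n}.
#' @export
fit_regression_dpd <- function(rows) {
  stopifnot(all(c("G", "B", "concentration_ppm") %in% names(rows)))
  if (nrow(rows) < 5L) stop("need >= 5 medium-range rows, got ", nrow(rows))
  if (any(rows$G <= 0 | rows$B <= 0))
    stop("non-positive G/B channel value; logarithm undefined")
  M <- cbind(lnG = log(rows$G), lnB = log(rows$B))
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, 1L]
  score <- pc$x[, 1L]
  if (stats::cor(score, rows$concentration_ppm) < 0) {
    load <- -load
    score <- -score
  }
  fit <- stats::lm(C ~ s, data = data.frame(C = rows$concentration_ppm,
                                            s = score))
  list(pca_loadings = load,
       pc_mean = pc$center,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       explained_variance = pc$sdev[1L]^2 / sum(pc$sdev^2),
       fit = fit,
       n = nrow(rows))
}

#' Fit the full calibration model (classifier + regression)
#'
#' Convenience fitter: trains the 3-class SVM and attaches the
#' chemistry's medium-range regression block fitted on the training-split
#' rows whose true concentration lies in the acceptable interval.
#'
#' @inheritParams train_classifier
#' @return A complete \code{chlorine_calibration}.
#' @export
train_calibration <- function(table, chemistry = c("btb", "dpd"),
                              bounds = NULL, split_seed = 42L) {
  chemistry <- match.arg(chemistry)
  model <- train_classifier(table, chemistry, bounds, split_seed)
  medium <- table$concentration_ppm >= model$bounds$low_max &
    table$concentration_ppm < model$bounds$high_min
  rows <- table[medium & model$split_train, , drop = FALSE]
  model$regression <- if (chemistry == "btb") {
    if (!"Rc" %in% names(rows)) rows$Rc <- rows$R
    fit_regression_btb(rows)
  } else {
    fit_regression_dpd(rows)
  }
  model
}

#' Predict a chlorine measurement from a feature vector
#'
#' Classifies first; a ppm estimate is produced only for samples
#' classified acceptable (the regressions are calibrated in the medium
#' range only). Regression outputs outside the acceptable interval are
#' clipped to it and flagged, recording the hazard of regressing a
#' misclassified sample.
#'
#' @param fv Feature-vector data frame.
#' @param model A \code{chlorine_calibration} with a regression block.
#' @param provenance Optional list (qr_id, timestamps, config) carried
#'   into the measurement.
#' @return A \code{chlorine_measurement}: list with \code{class_label},
#'   \code{ppm} (NULL unless acceptable), \code{ppm_interval} (95
#'   percent prediction interval when available), \code{out_of_range}
#'   flag, \code{features}, \code{provenance}.
#' @export
predict_concentration <- function(fv, model, provenance = NULL) {
  stopifnot(inherits(model, "chlorine_calibration"))
  label <- classify(fv, model)
  ppm <- NULL; interval <- NULL; oob <- FALSE
  if (as.character(label) == "acceptable") {
    if (is.null(model$regression))
      stop("calibration model has no regression block; use train_calibration()")
    rg <- model$regression
    if (model$chemistry == "btb") {
      rc <- fv$Rc[1L]
      if (is.null(rc)) rc <- fv$R[1L]
      if (rc <= 0) stop("non-positive Rc; ln undefined")
      ppm <- rg$m * log(rc) + rg$b
      if (!is.null(rg$fit)) {
        pr <- stats::predict(rg$fit, newdata = data.frame(x = log(rc)),
                             interval = "prediction", level = 0.95)
        interval <- c(pr[1L, "lwr"], pr[1L, "upr"])
      }
    } else {
      if (fv$G[1L] <= 0 || fv$B[1L] <= 0)
        stop("non-positive channel; ln undefined")
      s <- sum(rg$pca_loadings * (c(log(fv$G[1L]), log(fv$B[1L])) - rg$pc_mean))
      ppm <- rg$slope * s + rg$intercept
      if (!is.null(rg$fit)) {
        pr <- stats::predict(rg$fit, newdata = data.frame(s = s),
                             interval = "prediction", level = 0.95)
        interval <- c(pr[1L, "lwr"], pr[1L, "upr"])
      }
    }
    if (ppm < model$bounds$low_max || ppm > model$bounds$high_min) {
      ppm <- min(max(ppm, model$bounds$low_max), model$bounds$high_min)
      oob <- TRUE
    }
  }
  structure(list(class_label = label, ppm = ppm, ppm_interval = interval,
                 out_of_range = oob, features = fv,
                 provenance = provenance),
            class = "chlorine_measurement")
}

#' @export
print.chlorine_measurement <- function(x, ...) {
  cat("Free-chlorine measurement\n")
  cat("  class:", as.character(x$class_label), "\n")
  if (!is.null(x$ppm))
    cat(sprintf("  estimate: %.3f ppm (95%% PI %.3f-%.3f)%s\n", x$ppm,
                x$ppm_interval[1L], x$ppm_interval[2L],
                if (x$out_of_range) " [clipped: regression out of range]" else ""))
  invisible(x)
}

#' @export
print.chlorine_calibration <- function(x, ...) {
  cat(sprintf("Chlorine calibration (%s): features %s\n", x$chemistry,
              paste(x$feature_names, collapse = ",")))
  cat(sprintf("  classes low < %.1f <= acceptable < %.1f <= excess (ppm)\n",
              x$bounds$low_max, x$bounds$high_min))
  cat(sprintf("  SVM accuracy: train %.3f, held-out %.3f\n",
              x$train_accuracy, x$test_accuracy))
  if (!is.null(x$regression)) {
    if (x$chemistry == "btb")
      cat(sprintf("  regression: C = %.3f ln(Rc) + %.3f  (R2 %.3f, n %d)\n",
                  x$regression$m, x$regression$b, x$regression$r_squared,
                  x$regression$n))
    else
      cat(sprintf("  regression: C = %.3f PC1 + %.3f  (R2 %.3f, n %d)\n",
                  x$regression$slope, x$regression$intercept,
                  x$regression$r_squared, x$regression$n))
  }
  invisible(x)
}

#' @export
summary.chlorine_calibration <- function(object, ...) {
  print(object)
  if (!is.null(object$regression) && !is.null(object$regression$fit)) {
    cat("\nRegression details:\n")
    print(summary(object$regression$fit))
  }
  invisible(object)
}

#' @export
coef.chlorine_calibration <- function(object, ...) {
  rg <- object$regression
  if (is.null(rg)) return(NULL)
  if (object$chemistry == "btb") c(slope = rg$m, intercept = rg$b)
  else c(slope = rg$slope, intercept = rg$intercept)
}

#' @export
predict.chlorine_calibration <- function(object, newdata, ...) {
  if (nrow(as.data.frame(newdata)) == 1L)
    return(predict_concentration(newdata, object))
  lapply(seq_len(nrow(newdata)),
         function(i) predict_concentration(newdata[i, , drop = FALSE], object))
}
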