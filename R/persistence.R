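# Calibration-model persistence as JSON: language-neutral and diffable.
# The SVM is stored as its support coefficients and reconstructed with an
# explicit one-vs-one RBF decision function, so a saved model predicts
# without the original fit object.

svm_export <- function(fit) {
  list(SV = unname(as.matrix(fit$SV)),
       coefs = unname(as.matrix(fit$coefs)),
       rho = as.numeric(fit$rho),
       nSV = as.integer(fit$nSV),
       labels = as.integer(fit$labels),
       levels = fit$levels,
       gamma = fit$gamma)
}

# one-vs-one voting over the k(k-1)/2 libsvm binary machines
svm_decision_predict <- function(sv, Z) {
  Z <- as.matrix(Z)
  k <- length(sv$nSV)
  start <- cumsum(c(0L, sv$nSV))
  # RBF kernel between query rows and all SVs
  d2 <- outer(rowSums(Z^2), rowSums(sv$SV^2), "+") - 2 * Z %*% t(sv$SV)
  K <- exp(-sv$gamma * pmax(d2, 0))
  votes <- matrix(0L, nrow(Z), k)
  p <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    p <- p + 1L
    idx_i <- (start[i] + 1L):start[i + 1L]
    idx_j <- (start[j] + 1L):start[j + 1L]
    dec <- K[, idx_i, drop = FALSE] %*% sv$coefs[idx_i, j - 1L] +
      K[, idx_j, drop = FALSE] %*% sv$coefs[idx_j, i] - sv$rho[p]
    win <- ifelse(dec > 0, i, j)
    votes[cbind(seq_len(nrow(Z)), win)] <- votes[cbind(seq_len(nrow(Z)), win)] + 1L
  }
  internal <- max.col(votes, ties.method = "first")
  factor(sv$levels[sv$labels[internal]], levels = sv$levels)
}

#' Save / load a calibration model as JSON
#'
#' Stores the scaler, SVM support coefficients, regression block, class
#' bounds and split seed. A loaded model classifies through an explicit
#' one-vs-one RBF decision function and regresses through the stored
#' coefficients; prediction intervals (which need the full least-squares
#' fit) are not available from a loaded model.
#'
#' @param model A \code{chlorine_calibration}.
#' @param path JSON file path.
#' @export
calibration_to_json <- function(model, path) {
  stopifnot(inherits(model, "chlorine_calibration"))
  rg <- model$regression
  rg_out <- if (is.null(rg)) NULL else {
    keep <- setdiff(names(rg), c("fit", "coef_ci"))
    rg[keep]
  }
  jsonlite::write_json(list(
    chemistry = model$chemistry,
    feature_names = model$feature_names,
    scaler = list(mean = as.numeric(model$scaler$mean),
                  scale = as.numeric(model$scaler$scale)),
    svm = svm_export(model$classifier),
    svm_params = model$svm_params,
    bounds = model$bounds[c("low_max", "high_min", "labels")],
    split_seed = model$split_seed,
    regression = rg_out
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_to_json
#' @return \code{calibration_from_json} returns a
#'   \code{chlorine_calibration} whose classifier is the reconstructed
#'   decision function.
#' @export
calibration_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  sv <- list(SV = as.matrix(obj$svm$SV), coefs = as.matrix(obj$svm$coefs),
             rho = as.numeric(obj$svm$rho), nSV = as.integer(obj$svm$nSV),
             labels = as.integer(obj$svm$labels), levels = obj$svm$levels,
             gamma = obj$svm$gamma)
  classifier <- structure(list(sv = sv), class = "colorqr_svm")
  rg <- obj$regression
  if (!is.null(rg) && !is.null(rg$pca_loadings)) {
    rg$pca_loadings <- stats::setNames(as.numeric(rg$pca_loadings),
                                       c("lnG", "lnB"))
    rg$pc_mean <- stats::setNames(as.numeric(rg$pc_mean), c("lnG", "lnB"))
  }
  structure(list(
    chemistry = obj$chemistry,
    feature_names = obj$feature_names,
    scaler = list(mean = stats::setNames(as.numeric(obj$scaler$mean),
                                         obj$feature_names),
                  scale = stats::setNames(as.numeric(obj$scaler$scale),
                                          obj$feature_names)),
    classifier = classifier,
    svm_params = obj$svm_params,
    bounds = list(low_max = obj$bounds$low_max,
                  high_min = obj$bounds$high_min,
                  labels = obj$bounds$labels),
    split_seed = obj$split_seed,
    split_train = NULL,
    train_accuracy = NA_real_, test_accuracy = NA_real_,
    regression = rg
  ), class = "chlorine_calibration")
}

#' @export
predict.colorqr_svm <- function(object, newdata, ...) {
  svm_decision_predict(object$sv, newdata)
}
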