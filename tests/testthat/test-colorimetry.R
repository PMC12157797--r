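# Feature extraction, classification and calibration regressions.

test_that("RGB to HLS matches the hexcone closed forms", {
  expect_equal(as.numeric(rgb_to_hls(c(255, 0, 0))), c(0, 0.5, 1))
  expect_equal(as.numeric(rgb_to_hls(c(0, 0, 255))), c(240, 0.5, 1))
  gray <- rgb_to_hls(c(128, 128, 128))
  expect_equal(as.numeric(gray), c(0, 128 / 255, 0), tolerance = 1e-9)
  expect_error(rgb_to_hls(c(-1, 0, 0)), "0, 255")
  # gray inputs always give S = 0 and H = 0
  g <- rgb_to_hls(cbind(0:255, 0:255, 0:255))
  expect_true(all(g[, "S"] == 0) && all(g[, "H"] == 0))
})

test_that("feature extraction composes correction and HLS", {
  fv <- extract_features(c(200, 50, 50))
  expect_equal(fv$R, 200)
  expect_equal(fv$Rc, 200)
  expect_equal(as.numeric(fv[, c("H", "L", "S")]),
               as.numeric(rgb_to_hls(c(200, 50, 50))))
  expect_equal(extract_features(c(90, 90, 90))$S, 0)
  # with an identity map the features are unchanged
  pairs <- list(captured = as.matrix(default_palette("btb")[, c("R", "G", "B")]),
                reference = as.matrix(default_palette("btb")[, c("R", "G", "B")]))
  map <- fit_tps_map(pairs)
  expect_equal(as.numeric(extract_features(c(120, 80, 60), map)[, 1:3]),
               c(120, 80, 60), tolerance = 1e-6)
})

test_that("classifier separates noiseless classes and logs accuracies", {
  C <- rep(c(0.1, 0.5, 2.0), each = 10)
  tab <- btb_feature_table(C, sigma = 0)
  model <- train_classifier(tab, "btb")
  expect_equal(model$test_accuracy, 1)
  expect_true(model$train_accuracy >= 0.95)
  # standardized training features have mean 0, sd 1
  X <- as.matrix(tab[model$split_train, model$feature_names])
  Z <- sweep(sweep(X, 2, model$scaler$mean), 2, model$scaler$scale, "/")
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
})

test_that("permuted labels drop held-out accuracy to chance", {
  set.seed(55)
  C <- rep(c(0.1, 0.5, 2.0), each = 20)
  tab <- btb_feature_table(C, sigma = 2, seed = 56)
  tab$concentration_ppm <- sample(tab$concentration_ppm)
  model <- train_classifier(tab, "btb")
  # 12 held-out samples; chance = 1/3, binomial 99% envelope
  expect_lt(model$test_accuracy, 1 / 3 + 3 * sqrt((1 / 3) * (2 / 3) / 12))
})

test_that("degenerate training tables are rejected", {
  C <- rep(0.5, 30)  # single class
  tab <- btb_feature_table(C, sigma = 1)
  expect_error(train_classifier(tab, "btb"), "class")
  C <- rep(c(0.1, 0.5, 2.0), each = 5)
  tab2 <- btb_feature_table(C, sigma = 0)
  tab2$H <- 0  # zero-variance feature
  expect_error(train_classifier(tab2, "btb"), "zero variance")
})

test_that("classification assigns the generator's labels", {
  C <- rep(c(0.05, 0.1, 0.4, 0.6, 1.5, 2.5), each = 5)
  tab <- btb_feature_table(C, sigma = 1, seed = 57)
  model <- train_classifier(tab, "btb")
  fv_low <- btb_feature_table(0.05, sigma = 0)
  fv_mid <- btb_feature_table(0.5, sigma = 0)
  expect_identical(as.character(classify(fv_low, model)), "low")
  expect_identical(as.character(classify(fv_mid, model)), "acceptable")
  expect_error(classify(data.frame(R = 1), model), "feature-name mismatch")
})

test_that("BTB regression recovers the generator line exactly when noiseless", {
  set.seed(58)
  C <- runif(40, 0.2, 0.9)
  params <- default_response_params("btb", noise_sigma = 0)
  rows <- data.frame(Rc = btb_response(C, params)[, "R"],
                     concentration_ppm = C)
  fit <- suppressWarnings(fit_regression_btb(rows))  # exact fit by design
  expect_equal(fit$m, -0.64, tolerance = 1e-6)
  expect_equal(fit$b, 3.3, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)
})

test_that("BTB regression is accurate under channel noise", {
  rows <- sample_responses(100, "btb", seed = 1)
  names(rows)[names(rows) == "R"] <- "Rc"
  fit <- fit_regression_btb(rows)
  expect_lt(abs(fit$m - (-0.64)), 0.05)
  expect_lt(abs(fit$b - 3.3), 0.2)
})

test_that("BTB regression rejects degenerate or invalid designs", {
  rows <- data.frame(Rc = rep(80, 6), concentration_ppm = rep(0.5, 6))
  expect_error(fit_regression_btb(rows), "rank")
  expect_error(fit_regression_btb(data.frame(Rc = c(-1, 2, 3, 4, 5),
                                             concentration_ppm = 1:5)),
               "non-positive")
  expect_error(fit_regression_btb(data.frame(Rc = 1:3,
                                             concentration_ppm = 1:3)),
               ">= 5")
})

test_that("DPD regression matches the closed-form 2x2 PCA oracle", {
  set.seed(59)
  C <- runif(60, 0.2, 1.1)
  params <- default_response_params("dpd", noise_sigma = 2)
  rgb <- dpd_response(C, params)
  rows <- data.frame(G = rgb[, "G"], B = rgb[, "B"], concentration_ppm = C)
  fit <- fit_regression_dpd(rows)
  # oracle: closed-form eigenvector of the 2x2 covariance of (lnG, lnB)
  M <- cbind(log(rows$G), log(rows$B))
  S <- stats::cov(M)
  tr <- S[1, 1] + S[2, 2]
  disc <- sqrt((S[1, 1] - S[2, 2])^2 + 4 * S[1, 2]^2)
  l1 <- (tr + disc) / 2
  v <- c(S[1, 2], l1 - S[1, 1])
  v <- v / sqrt(sum(v^2))
  cosang <- abs(sum(v * fit$pca_loadings))
  expect_equal(cosang, 1, tolerance = 1e-9)
  expect_gt(fit$r_squared, 0.9)
  # loadings are sign-fixed so the component increases with C
  score <- as.numeric((M - matrix(fit$pc_mean, nrow(M), 2, byrow = TRUE)) %*%
                        fit$pca_loadings)
  expect_gt(stats::cor(score, C), 0)
})

test_that("collinear log-channels give a perfect DPD fit", {
  C <- seq(0.25, 1.05, length.out = 20)
  rows <- data.frame(G = exp(5.4 - 0.35 * C), B = exp(5.45 - 0.25 * C),
                     concentration_ppm = C)
  fit <- suppressWarnings(fit_regression_dpd(rows))  # exact fit by design
  expect_gt(fit$explained_variance, 1 - 1e-12)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_error(fit_regression_dpd(data.frame(G = c(0, 1, 2, 3, 4),
                                             B = 1:5,
                                             concentration_ppm = 1:5)),
               "non-positive")
})

test_that("predict_concentration honours the class gate and inverts the line", {
  C <- rep(c(0.05, 0.1, 0.3, 0.5, 0.7, 1.5, 2.5), each = 6)
  tab <- btb_feature_table(C, sigma = 1, seed = 60)
  model <- train_calibration(tab, "btb")
  rg <- model$regression
  # feature whose Rc inverts to exactly 0.5 ppm under the fitted line
  rc_half <- exp((0.5 - rg$b) / rg$m)
  fv <- extract_features(c(rc_half, 185, 145))
  m <- predict_concentration(fv, model)
  expect_identical(as.character(m$class_label), "acceptable")
  expect_equal(m$ppm, 0.5, tolerance = 1e-6)
  expect_length(m$ppm_interval, 2)
  expect_true(m$ppm_interval[1] < 0.5 && m$ppm_interval[2] > 0.5)
  # low and excess classes carry no ppm estimate
  m_low <- predict_concentration(btb_feature_table(0.05, 0), model)
  expect_identical(as.character(m_low$class_label), "low")
  expect_null(m_low$ppm)
  m_hi <- predict_concentration(btb_feature_table(2.5, 0), model)
  expect_identical(as.character(m_hi$class_label), "excess")
  expect_null(m_hi$ppm)
})

test_that("predicted ppm decreases monotonically in Rc in the medium range", {
  C <- rep(c(0.05, 0.3, 0.5, 0.7, 1.5), each = 8)
  tab <- btb_feature_table(C, sigma = 1, seed = 61)
  model <- train_calibration(tab, "btb")
  expect_lt(model$regression$m, 0)
  rcs <- seq(45, 120, by = 5)
  ppms <- vapply(rcs, function(rc) {
    model$regression$m * log(rc) + model$regression$b
  }, double(1))
  expect_true(all(diff(ppms) < 0))
})

test_that("calibration JSON round trip reproduces classifier and regression", {
  C <- rep(c(0.1, 0.5, 2.0), each = 12)
  tab <- btb_feature_table(C, sigma = 2, seed = 62)
  model <- train_calibration(tab, "btb")
  path <- tempfile(fileext = ".json")
  calibration_to_json(model, path)
  loaded <- calibration_from_json(path)
  # predictions agree with the e1071 object on fresh noisy features
  probe <- btb_feature_table(rep(c(0.08, 0.45, 1.8), each = 10), sigma = 3,
                             seed = 63)
  expect_identical(as.character(classify(probe, loaded)),
                   as.character(classify(probe, model)))
  expect_equal(coef(loaded), coef(model), tolerance = 1e-12)
  # ppm estimates agree (no intervals from a loaded model)
  fv <- btb_feature_table(0.5, 0)
  expect_equal(predict_concentration(fv, loaded)$ppm,
               predict_concentration(fv, model)$ppm, tolerance = 1e-9)
})
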