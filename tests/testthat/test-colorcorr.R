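# Thin-plate-spline color correction: interpolation contract, oracle
# equivalence with a dense solve, affine recovery, and superiority over
# diagonal white balance on non-linear distortions.

identity_pairs <- function(n = 24, seed = 5) {
  set.seed(seed)
  cols <- cbind(runif(n, 0, 255), runif(n, 0, 255), runif(n, 0, 255))
  list(captured = cols, reference = cols)
}

test_that("identity pairs give the identity map everywhere", {
  pairs <- identity_pairs()
  map <- fit_tps_map(pairs, lambda = 0)
  set.seed(6)
  probe <- cbind(runif(100, 0, 255), runif(100, 0, 255), runif(100, 0, 255))
  expect_lt(max(abs(apply_map(map, probe) - probe)), 1e-6)
  expect_lt(max(abs(apply_map(map, pairs$captured) - pairs$reference)), 1e-6)
})

test_that("lambda = 0 interpolates the control points for any pairs", {
  set.seed(11)
  cap <- cbind(runif(20, 0, 255), runif(20, 0, 255), runif(20, 0, 255))
  ref <- cbind(runif(20, 0, 255), runif(20, 0, 255), runif(20, 0, 255))
  for (kern in c("r2logr", "r")) {
    map <- fit_tps_map(list(captured = cap, reference = ref), 0, kern)
    expect_lt(max(abs(apply_map(map, cap) - ref)), 1e-6)
    expect_lt(correction_residual(map, list(captured = cap, reference = ref)),
              1e-6)
  }
})

test_that("side conditions hold: weights orthogonal to the affine space", {
  set.seed(12)
  cap <- cbind(runif(30, 0, 255), runif(30, 0, 255), runif(30, 0, 255))
  ref <- cap + cbind(rnorm(30, 0, 10), rnorm(30, 0, 10), rnorm(30, 0, 10))
  for (lam in c(0, 1)) {
    map <- fit_tps_map(list(captured = cap, reference = ref), lam)
    expect_lt(max(abs(colSums(map$weights))), 1e-8)
    expect_lt(max(abs(t(cap) %*% map$weights)), 1e-6)
  }
})

test_that("solution matches a brute-force dense solve", {
  # independent oracle: assemble and solve the same block system with a
  # generic least-squares solver (qr.solve), entry by entry
  set.seed(13)
  for (n in c(8, 20, 50)) {
    cap <- cbind(runif(n, 0, 255), runif(n, 0, 255), runif(n, 0, 255))
    ref <- cbind(runif(n, 0, 255), runif(n, 0, 255), runif(n, 0, 255))
    lam <- 0.5
    map <- fit_tps_map(list(captured = cap, reference = ref), lam)
    K <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      r <- sqrt(sum((cap[i, ] - cap[j, ])^2))
      K[i, j] <- if (r > 0) r^2 * log(r) else 0
    }
    A <- rbind(cbind(K + lam * diag(n), cbind(1, cap)),
               cbind(t(cbind(1, cap)), matrix(0, 4, 4)))
    for (ch in 1:3) {
      sol <- qr.solve(A, c(ref[, ch], rep(0, 4)))
      expect_lt(max(abs(sol[1:n] - map$weights[, ch])), 1e-8)
      expect_lt(max(abs(sol[(n + 1):(n + 4)] - map$affine[, ch])), 1e-8)
    }
  }
})

test_that("an affine color distortion is inverted exactly inside the hull", {
  set.seed(14)
  M <- matrix(rnorm(9, 0, 0.2), 3, 3) + diag(3)
  tvec <- runif(3, -10, 10)
  ref <- as.matrix(default_palette("btb")[, c("R", "G", "B")])
  cap <- ref %*% t(M) + matrix(tvec, nrow(ref), 3, byrow = TRUE)
  map <- fit_tps_map(list(captured = cap, reference = ref))
  probe_ref <- hull_colors(default_palette("btb"), 50, seed = 15)
  probe_cap <- probe_ref %*% t(M) + matrix(tvec, 50, 3, byrow = TRUE)
  # oracle: the explicit affine inverse
  inverse <- (probe_cap - matrix(tvec, 50, 3, byrow = TRUE)) %*% t(solve(M))
  expect_lt(max(abs(apply_map(map, probe_cap) - inverse)), 0.5)
  expect_lt(max(abs(apply_map(map, probe_cap) - probe_ref)), 0.5)
})

test_that("residual is non-decreasing in lambda", {
  set.seed(16)
  cap <- cbind(runif(24, 0, 255), runif(24, 0, 255), runif(24, 0, 255))
  ref <- cap + matrix(rnorm(72, 0, 15), 24, 3)
  pairs <- list(captured = cap, reference = ref)
  res <- vapply(c(0, 0.1, 1, 10),
                function(l) correction_residual(fit_tps_map(pairs, l), pairs),
                double(1))
  expect_true(all(diff(res) >= -1e-9))
  expect_lt(res[1], 1e-6)
})

test_that("degenerate and undersized inputs are rejected", {
  set.seed(17)
  cap <- cbind(runif(6, 0, 255), runif(6, 0, 255), runif(6, 0, 255))
  expect_error(fit_tps_map(list(captured = cap, reference = cap)),
               "at least 8")
  # collinear captured colors are rank-deficient in the affine block
  t1 <- seq(0, 1, length.out = 10)
  line <- cbind(10 + 200 * t1, 20 + 100 * t1, 30 + 50 * t1)
  expect_error(fit_tps_map(list(captured = line, reference = line)),
               "degenerate|rank")
  expect_error(correction_residual(fit_tps_map(identity_pairs()),
                                   list(captured = matrix(0, 0, 3),
                                        reference = matrix(0, 0, 3))),
               "empty")
})

test_that("TPS beats white balance on gamma-distorted illuminants", {
  pal <- default_palette("btb")
  ref <- as.matrix(pal[, c("R", "G", "B")])
  cap <- distort_colors(ref, cct = 3000, gamma = TRUE)
  pairs <- list(captured = cap, reference = ref)
  map <- fit_tps_map(pairs)
  wb <- fit_white_balance(pairs, ids = pal$id)
  probe_ref <- hull_colors(pal, 80, seed = 18)
  probe_cap <- distort_colors(probe_ref, cct = 3000, gamma = TRUE)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  e_raw <- rmse(probe_cap, probe_ref)
  e_tps <- rmse(apply_map(map, probe_cap), probe_ref)
  e_wb <- rmse(wb(probe_cap), probe_ref)
  expect_lt(e_tps, e_raw / 10)
  expect_lt(e_tps, e_wb)
})

test_that("maps serialize to JSON and back without changing predictions", {
  pairs <- identity_pairs(12, seed = 19)
  pairs$reference <- pairs$reference + 5
  map <- fit_tps_map(pairs, lambda = 0.2)
  path <- tempfile(fileext = ".json")
  tps_to_json(map, path)
  map2 <- tps_from_json(path)
  probe <- hull_colors(default_palette("btb"), 20, seed = 20)
  expect_equal(apply_map(map2, probe), apply_map(map, probe),
               tolerance = 1e-12)
})
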