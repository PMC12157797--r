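# Synthetic generator: dye response models, illuminant gains, scene
# determinism and dataset generation.

test_that("BTB response follows the inverse calibration line", {
  params <- default_response_params("btb", noise_sigma = 0)
  # construction: C with (b - C)/|m| = ln(128) gives R = 128 exactly
  C128 <- params$b - abs(params$m) * log(128)
  expect_equal(unname(btb_response(C128, params)[1, "R"]), 128,
               tolerance = 1e-9)
  # direct arithmetic from the calibration coefficients
  expect_equal(unname(btb_response(0.5, params)[1, "R"]),
               exp((3.3 - 0.5) / 0.64), tolerance = 1e-9)
  r <- btb_response(c(0.2, 0.5, 0.9), params)[, "R"]
  expect_true(all(diff(r) < 0))
  expect_error(btb_response(-1, params), "non-negative")
})

test_that("DPD response is a pink ramp decaying in G and B", {
  params <- default_response_params("dpd", noise_sigma = 0)
  C <- seq(0, 3, by = 0.25)
  rgb <- dpd_response(C, params)
  expect_true(all(diff(rgb[, "G"]) < 0))
  expect_true(all(diff(rgb[, "B"]) < 0))
  # zero-analyte limit is near-neutral
  expect_equal(unname(rgb[1, "G"]), exp(params$lnG0), tolerance = 1e-9)
  expect_true(max(rgb[1, ]) - min(rgb[1, ]) < 15)
  # the developed color at C = 2 sits in the magenta/pink hue sector
  h <- rgb_to_hls(dpd_response(2, params))[1, "H"]
  expect_true(h >= 280 || h < 20)
  expect_error(dpd_response(-0.1, params), "non-negative")
})

test_that("illuminant gains behave like a Planckian sweep", {
  expect_equal(illuminant_gains(6500), c(1, 1, 1), tolerance = 0.05)
  g2500 <- illuminant_gains(2500)
  expect_gt(g2500[1], 1)
  expect_lt(g2500[3], 1)
  expect_gt(g2500[1], g2500[3])
  # smoothness across the sweep (including the 4000 K branch boundary)
  for (t in c(2000, 3000, 3999, 4000, 5000, 6000, 8000))
    expect_lt(max(abs(illuminant_gains(t) - illuminant_gains(t + 1))), 1e-2)
  expect_error(illuminant_gains(500), "1000")
  expect_error(illuminant_gains(15000), "12000")
})

test_that("identical seeds give byte-identical scenes", {
  a <- render_scene(btb_spec, "btb", 0.5, cct = 3500, warp_jitter = 0.03,
                    noise_sigma = 3, seed = 99)
  b <- render_scene(btb_spec, "btb", 0.5, cct = 3500, warp_jitter = 0.03,
                    noise_sigma = 3, seed = 99)
  expect_identical(a$image, b$image)
  c <- render_scene(btb_spec, "btb", 0.5, cct = 3500, warp_jitter = 0.03,
                    noise_sigma = 3, seed = 100)
  expect_false(identical(a$image, c$image))
})

test_that("generator and analyzer agree at identity conditions", {
  params <- default_response_params("btb", noise_sigma = 0)
  for (C in c(0.1, 0.5, 1.4)) {
    sc <- render_scene(btb_spec, "btb", C, cct = 6500, warp_jitter = 0,
                       noise_sigma = 0, seed = 1)
    res <- analyze_scene(sc$image, btb_spec, "btb")
    expect_lt(max(abs(as.numeric(res$features[, c("R", "G", "B")]) -
                        as.numeric(btb_response(C, params)))), 1)
    # palette extraction is exact under identity conditions
    expect_lt(max(abs(as.matrix(res$patches[, 2:4]) -
                        as.matrix(res$patches[, 5:7]))), 1e-9)
  }
})

test_that("scene ground truth is consistent with the class bounds", {
  for (C in c(0.05, 0.2, 0.5, 0.9, 3)) {
    sc <- render_scene(btb_spec, "btb", C, seed = 2)
    expect_identical(as.character(sc$truth$class_label),
                     as.character(relabel_concentration(C, class_bounds("btb"))))
  }
})

test_that("layout overlap is rejected", {
  bad <- default_layout()
  bad$strip$x <- 60L
  expect_error(render_scene(btb_spec, "btb", 0.5, layout = bad, seed = 1),
               "overlap")
})

test_that("generate_dataset writes labelled scenes with valid truth", {
  dir <- file.path(tempdir(), "colorqr-ds-test")
  on.exit(unlink(dir, recursive = TRUE))
  truth <- generate_dataset(9, "btb", dir, spec = btb_spec,
                            cct_grid = seq(2500, 6500, by = 500),
                            warp_jitter = 0, noise_sigma = 1, seed = 3)
  expect_equal(nrow(truth), 9)
  expect_length(list.files(dir, pattern = "\\.png$"), 9)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "params.json")))
  expect_setequal(truth$illuminant_K, seq(2500, 6500, by = 500))
  # truth labels equal relabeling of concentrations by the class bounds
  expect_identical(as.character(truth$class_label),
                   as.character(relabel_concentration(truth$concentration_ppm,
                                                      class_bounds("btb"))))
  # stratified sampler: 30 draws give >= 9 per class
  set.seed(4)
  C30 <- sampler_stratified(class_bounds("btb"))(30)
  expect_true(all(table(relabel_concentration(C30, class_bounds("btb"))) >= 9))
})

test_that("response samples honour the requested range and seed", {
  s1 <- sample_responses(50, "btb", seed = 21)
  s2 <- sample_responses(50, "btb", seed = 21)
  expect_identical(s1, s2)
  rng <- default_response_params("btb")$valid_range
  expect_true(all(s1$concentration_ppm >= rng[1] &
                    s1$concentration_ppm <= rng[2]))
})
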