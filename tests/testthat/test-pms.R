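test_that("the average boundary line reproduces straight borders exactly", {
  u <- seq(0, 60, by = 1)
  v <- 0.25 * u - 3
  b <- curve_from_points(rep(0, length(u)), u, u = u, v = v)
  fit <- fit_average_boundary(b, knot_spacing = 15)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(compute_pms(fit)$pms, 0, tolerance = 1e-8)
})

test_that("the spline is too stiff to follow wavelength-8 oscillation", {
  u <- 0:159
  v <- 2 * sin(2 * pi * u / 8)
  b <- curve_from_points(rep(0, 160), u, u = u, v = v)
  fit <- fit_average_boundary(b, knot_spacing = 40)
  rms <- sqrt(mean(fit$residuals^2))
  expect_equal(rms, 2 / sqrt(2), tolerance = 0.1)
  expect_equal(fit$knots_used, 3)
})

test_that("the least-squares fit matches an independent QR solve", {
  set.seed(7)
  u <- sort(runif(80, 0, 100))
  v <- sin(u / 5) + rnorm(80, sd = 0.3)
  b <- curve_from_points(rep(0, 80), u, u = u, v = v)
  fit <- fit_average_boundary(b, knot_spacing = 25)
  # oracle: normal equations on the same uniform-interior-knot cubic basis
  all_knots <- c(rep(min(u), 4), fit$basis_knots, rep(max(u), 4))
  basis <- splines::splineDesign(all_knots, u, ord = 4)
  beta <- qr.solve(basis, v)
  oracle_res <- v - drop(basis %*% beta)
  expect_equal(fit$residuals, oracle_res, tolerance = 1e-8)
})

test_that("knot count degrades gracefully when points are scarce", {
  u <- seq(0, 22, by = 2)  # 12 points
  v <- rnorm(12)
  b <- curve_from_points(rep(0, 12), u, u = u, v = v)
  fit <- fit_average_boundary(b, knot_spacing = 2)
  expect_lt(fit$knots_used, 10)
  expect_equal(length(fit$residuals), 12)
})

test_that("a too-short border fails the baseline fit with a clear message", {
  u <- 0:19
  b <- curve_from_points(rep(0, 20), u, u = u, v = rnorm(20))
  expect_error(fit_average_boundary(b, knot_spacing = 15), "too short for baseline")
})

test_that("pms is the root mean square of the residuals", {
  u <- 0:39
  b <- curve_from_points(rep(0, 40), u, u = u, v = rep(0, 40))
  fit <- fit_average_boundary(b, knot_spacing = 10)
  fit$residuals <- c(1, -1, 1, -1)
  expect_equal(compute_pms(fit)$pms, 1)
  fit$residuals <- rep(0, 4)
  expect_equal(compute_pms(fit)$pms, 0)
})

test_that("score_roi on a flat noise-free phantom stays under the quantization floor", {
  ph <- test_phantom(rms = 0, seed = 1, noise = 0)
  r <- score_roi(ph$image, centered_roi(ph$image, 40, 40, "tumor"))
  expect_lte(r$pms, 0.35)
  expect_equal(r$roi_label, "tumor")
  expect_match(r$params_fingerprint, "^[0-9a-f]+$")
})

test_that("a 4x rougher phantom scores strictly higher than a smooth one", {
  smooth <- test_phantom(rms = 0.5, seed = 12)
  rough <- test_phantom(rms = 2.0, seed = 12)
  roi <- centered_roi(smooth$image, 40, 40)
  expect_gt(score_roi(rough$image, roi)$pms, score_roi(smooth$image, roi)$pms)
})

test_that("pipeline failures surface with the failing stage attached", {
  flat <- gray_image(matrix(50, 64, 64))
  err <- tryCatch(score_roi(flat, roi_box(10, 10, 40, 40)),
                  error = function(e) e)
  expect_match(conditionMessage(err), "^canny_edges: ")
  expect_error(score_roi(flat, roi_box(40, 40, 40, 40)), "^crop: ")
})

test_that("classification calls low scores cancer and ties healthy", {
  expect_equal(classify_pms(c(0.50, 1.27, 0.6855), threshold = 0.6855),
               c("cancer", "healthy", "healthy"))
  expect_error(classify_pms(0.5, threshold = 0), "positive")
  expect_error(classify_pms(-1), "non-negative")
})

test_that("score_cohort returns one paired row per patient", {
  tpl_s <- phantom_spec(shape = c(64, 64), perturbation_rms = 0.4,
                        blur_sigma = 0.3, noise_sigma = 2)
  tpl_r <- phantom_spec(shape = c(64, 64), perturbation_rms = 1.5,
                        blur_sigma = 0.3, noise_sigma = 2)
  coh <- make_cohort(4, tpl_s, tpl_r, seed = 5)
  scored <- score_cohort(coh, roi_shape = c(48, 48))
  expect_equal(nrow(scored), 4)
  expect_true(all(scored$pms_healthy > scored$pms_tumor))
})

test_that("score_manifest flags failing rows and scores the rest", {
  tpl <- phantom_spec(shape = c(48, 48), perturbation_rms = 0.8, band = c(4, 8),
                      blur_sigma = 0.3, noise_sigma = 2)
  coh <- make_cohort(3, tpl, tpl, seed = 9)
  dir <- withr::local_tempdir()
  man <- load_manifest(write_cohort(coh, dir))
  # sabotage one image with a constant frame
  write_image(gray_image(matrix(5, 48, 96)), man$image_path[2])
  out <- score_manifest(man)
  expect_equal(nrow(out), 3)
  expect_true(is.na(out$pms_tumor[2]))
  expect_match(out$error[2], "canny_edges")
  expect_true(all(!is.na(out$pms_tumor[c(1, 3)])))
})

test_that("tidy methods return one-row tibbles with the score fields", {
  ph <- test_phantom(rms = 0.8, seed = 2)
  r <- score_roi(ph$image, centered_roi(ph$image, 40, 40, "healthy"))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("roi_label", "pms", "pms_mm", "n_points", "knots_used",
                     "params_fingerprint"))
})
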