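test_that("zero-amplitude phantom has an exactly flat border", {
  ph <- make_phantom(phantom_spec(shape = c(64, 64), perturbation_rms = 0,
                                  blur_sigma = 0.3, noise_sigma = 0, seed = 1))
  expect_identical(ph$truth$true_rms, 0)
  # border points lie exactly on the base line through the image center
  expect_true(all(abs(ph$truth$border_points$row - 31.5) < 1e-12))
})

test_that("equal spec and seed reproduce the phantom bit for bit", {
  sp <- phantom_spec(shape = c(48, 48), perturbation_rms = 1.5, seed = 99)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth, b$truth)
})

test_that("phantom generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(make_phantom(phantom_spec(seed = 7)))
  expect_identical(runif(1), r1)
})

test_that("realized border RMS calibrates to the requested amplitude", {
  # border 40x the max wavelength: realized RMS within 5% of the request
  for (seed in 1:5) {
    ph <- make_phantom(phantom_spec(shape = c(32, 128), perturbation_rms = 1.5,
                                    band = c(2, 3), blur_sigma = 0.3,
                                    noise_sigma = 0, seed = seed))
    expect_gt(ph$truth$true_rms, 1.425)
    expect_lt(ph$truth$true_rms, 1.575)
  }
})

test_that("truth is computed before degradation and ignores blur and noise", {
  base <- phantom_spec(shape = c(64, 64), perturbation_rms = 2, seed = 5,
                       blur_sigma = 0.3, noise_sigma = 0)
  degraded <- base
  degraded$blur_sigma <- 2
  degraded$noise_sigma <- 8
  a <- make_phantom(base)
  b <- make_phantom(degraded)
  expect_identical(a$truth, b$truth)
})

test_that("infeasible band errors with the minimum border length", {
  sp <- phantom_spec(shape = c(16, 16), perturbation_rms = 1, band = c(10, 40))
  expect_error(make_phantom(sp), "minimum border length")
})

test_that("phantom intensities interpolate the two phase levels", {
  ph <- make_phantom(phantom_spec(shape = c(64, 64), perturbation_rms = 0,
                                  blur_sigma = 0, noise_sigma = 0, seed = 1))
  px <- unclass(ph$image)
  expect_true(all(px >= 20 - 1e-9 & px <= 110 + 1e-9))
  expect_true(any(px == 20) && any(px == 110))
})

test_that("a cohort pairs one phantom per arm per patient, reproducibly", {
  tpl <- phantom_spec(shape = c(32, 32), perturbation_rms = 0.5, band = c(3, 6))
  coh <- make_cohort(8, tpl, tpl, seed = 11)
  expect_equal(nrow(coh), 8)
  expect_equal(length(coh$phantom_tumor), 8)
  expect_equal(length(coh$phantom_healthy), 8)
  expect_false(any(duplicated(c(coh$seed_tumor, coh$seed_healthy))))
  # regenerating a single pair from its recorded seeds matches the cohort
  sp <- tpl
  sp$seed <- coh$seed_healthy[3]
  expect_identical(unclass(make_phantom(sp)$image),
                   unclass(coh$phantom_healthy[[3]]$image))
  expect_error(make_cohort(1, tpl, tpl), "at least 2")
})

test_that("identical templates give symmetric paired roughness", {
  tpl <- phantom_spec(shape = c(32, 96), perturbation_rms = 1, band = c(4, 8))
  coh <- make_cohort(10, tpl, tpl, seed = 3)
  d <- coh$true_rms_tumor - coh$true_rms_healthy
  # realized-RMS rescaling pins both arms at the requested amplitude, so the
  # paired differences vanish even though the borders themselves differ
  expect_true(all(abs(d) < 1e-9))
  expect_false(identical(unclass(coh$phantom_tumor[[1]]$image),
                         unclass(coh$phantom_healthy[[1]]$image)))
})

test_that("a 3x rougher template yields close to 3x the realized RMS", {
  smooth <- phantom_spec(shape = c(48, 160), perturbation_rms = 0.5, band = c(4, 8))
  rough <- phantom_spec(shape = c(48, 160), perturbation_rms = 1.5, band = c(4, 8))
  coh <- make_cohort(10, smooth, rough, seed = 21)
  ratio <- mean(coh$true_rms_healthy) / mean(coh$true_rms_tumor)
  expect_gt(ratio, 2.85)
  expect_lt(ratio, 3.15)
})

test_that("spec validation rejects out-of-contract phantoms", {
  expect_error(phantom_spec(shape = c(8, 64)), "16")
  expect_error(phantom_spec(perturbation_rms = -1), "non-negative")
  expect_error(phantom_spec(band = c(1, 8)), "min >= 2")
  expect_error(phantom_spec(contrast = c(50, 50)), "distinct")
  expect_error(phantom_spec(base_curve = list(type = "arc")), "radius")
})

test_that("arc phantoms put the border through the image center", {
  ph <- make_phantom(phantom_spec(shape = c(64, 64),
                                  base_curve = list(type = "arc", radius = 200),
                                  perturbation_rms = 0, blur_sigma = 0.3,
                                  noise_sigma = 0, seed = 2))
  bp <- ph$truth$border_points
  mid <- bp[which.min(abs(bp$u)), ]
  expect_lt(abs(mid$row - 31.5), 0.3)
  expect_lt(abs(mid$col - 31.5), 0.3)
})

test_that("a written cohort round-trips through the manifest loader", {
  tpl_s <- phantom_spec(shape = c(48, 48), perturbation_rms = 0.4, band = c(4, 8))
  tpl_r <- phantom_spec(shape = c(48, 48), perturbation_rms = 1.2, band = c(4, 8))
  coh <- make_cohort(3, tpl_s, tpl_r, seed = 8)
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(coh, dir)
  man <- load_manifest(manifest_path)
  expect_equal(nrow(man), 3)
  expect_equal(man$true_rms_tumor, coh$true_rms_tumor)
  img <- load_image(man$image_path[1])
  expect_equal(dim(img), c(48, 96))
  # tumor ROI crops the left half, healthy the right
  expect_lt(man$roi_tumor[[1]]$left + man$roi_tumor[[1]]$width, 49)
  expect_gte(man$roi_healthy[[1]]$left, 48)
})
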