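test_that("phantom generation is deterministic and honours identity transforms", {
  sp <- phantom_spec(seed = 99, image_size = 256, n_vessels = 6)
  ph1 <- make_phantom(sp)
  ph2 <- make_phantom(sp)
  expect_identical(ph1$images, ph2$images)
  expect_identical(ph1$landmarks, ph2$landmarks)

  # identity transforms: src landmarks equal dst landmarks in every pair
  for (lp in ph1$landmarks) {
    expect_equal(lp$x_src, lp$x_dst)
    expect_equal(lp$y_src, lp$y_dst)
  }
  # written twice, files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_phantom(sp, dir = d1)
  make_phantom(sp, dir = d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("phantom images are valid rasters and the spec validates its FC", {
  ph <- demo_phantom(seed = 2, render = TRUE, image_size = 256)
  for (img in ph$images) {
    expect_identical(dim(img), c(256L, 256L))
    expect_true(all(img >= 0 & img <= 1))
    expect_gt(stats::sd(img), 0)   # vessels actually rendered
  }
  expect_error(phantom_spec(image_size = 256, true_fc = c(300, 10)),
               "inside the image")
})

test_that("generated files pass the interchange-format validators", {
  dir <- withr::local_tempdir()
  sp <- phantom_spec(seed = 11, image_size = 256,
                     transforms = demo_transforms())
  ph <- make_phantom(sp, dir = dir, render = FALSE)
  for (fr in c("oct_h", "oct_v", "maia")) {
    lp <- read_landmark_csv(file.path(dir, paste0("landmarks_", fr, ".csv")))
    expect_s3_class(lp, "landmark_pairs")
    expect_identical(attr(lp, "src_frame"), fr)
  }
  expect_s3_class(read_scanline_csv(file.path(dir, "scanline_h.csv"))[[1]],
                  "scan_line")
  exam <- make_fixation_exam(fixation_cloud_spec(n_samples = 100, seed = 1),
                             ph$truth$true_fc, ph$ruler,
                             transform = sp$transforms$maia)
  write_fixation_csv(exam, file.path(dir, "fixation.csv"))
  expect_s3_class(read_fixation_csv(file.path(dir, "fixation.csv")),
                  "fixation_exam")
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$true_fc, sp$true_fc)
})

test_that("registered scan lines recover the true foveal center to < 0.5 px", {
  for (seed in c(3, 17, 51)) {
    ph <- demo_phantom(seed = seed)
    fc <- intersect_scanlines(ph$scanlines$h, ph$scanlines$v,
                              estimate_transform(ph$landmarks$oct_h),
                              estimate_transform(ph$landmarks$oct_v))
    expect_lt(sqrt(sum((fc$position - ph$truth$true_fc)^2)), 0.5)
  }
})

test_that("tiny-spread clouds recover the programmed offset as DFC", {
  spec <- fixation_cloud_spec(n_samples = 500, sigma = c(0.01, 0.01),
                              center_offset_from_fc = c(1000, 0),
                              drift = 0, seed = 4)
  ph <- demo_phantom(seed = 4)
  exam <- make_fixation_exam(spec, ph$truth$true_fc, ph$ruler,
                             transform = ph$truth$transforms$maia)
  m <- eye_metrics(exam, ph$truth$true_fc, ph$ruler,
                   transform = ph$truth$transforms$maia)
  expect_equal(m$dfc, 1000, tolerance = 2e-3)
  # +x is nasal-right on OD; y is on-axis up to sampling noise
  expect_match(m$quadrant, "nasal")
})

test_that("without drift the PRLi-PRLf separation vanishes with n", {
  # fixed 40 s exam so the PRLi window sample count grows with n
  d_at <- function(n) {
    spec <- fixation_cloud_spec(n_samples = n, rate = n / 40, drift = 0,
                                seed = 8)
    exam <- make_fixation_exam(spec, c(400, 400), scale_ruler(23, 200))
    dprl(compute_prl_pair(exam))
  }
  expect_lt(d_at(8000), d_at(150))
  expect_lt(d_at(8000), 25)
})

test_that("the closed-form cloud BCEA matches measurement when drift is off", {
  spec <- fixation_cloud_spec(n_samples = 20000, drift = 0, rho = 0.3,
                              sigma = c(1.2, 0.8), seed = 10)
  exam <- make_fixation_exam(spec, c(400, 400), scale_ruler(23, 200))
  expect_equal(as.numeric(bcea(exam, 0.95)),
               attr(exam, "truth")$bcea_deg2, tolerance = 0.05)
})

test_that("full-pipeline parameter recovery holds over 50 random specs", {
  set.seed(2026)
  n_specs <- 50
  err_px <- numeric(n_specs)
  class_ok <- logical(n_specs)
  for (i in seq_len(n_specs)) {
    sp <- random_phantom_spec(seed = 1000 + i)
    ph <- make_phantom(sp, render = FALSE)
    # programmed conditions sampled away from the 75% class boundary:
    # tight (sigma 0.35 deg -> stable) or loose (sigma 2.6 deg -> unstable)
    tight <- runif(1) < 0.5
    cl <- fixation_cloud_spec(
      n_samples = 1000,
      center_offset_from_fc = runif(2, -1500, 1500),
      sigma = if (tight) c(0.35, 0.35) else c(2.6, 2.6),
      rho = runif(1, -0.5, 0.5),
      drift = runif(1, 0, 100),
      seed = 2000 + i)
    res <- recover_metrics(ph, cl)
    truth <- attr(res$exam, "truth")
    err_px[i] <- abs(res$metrics$dfc - truth$dfc_um) /
      ph$ruler$microns_per_pixel
    class_ok[i] <- res$metrics$stability ==
      (if (tight) "stable" else "unstable")
  }
  expect_lt(median(err_px), 1)
  expect_gte(mean(class_ok), 0.95)
})
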