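const_exam <- function(n, x, y, eye = "OD", rate = 25, ...) {
  fixation_exam(t = (seq_len(n) - 1) / rate, x = rep(x, n), y = rep(y, n),
                eye = eye, ...)
}

test_that("PRL pair is the cluster centroid of the initial window and the full exam", {
  e <- const_exam(40, 1, 2)
  pair <- compute_prl_pair(e)
  expect_equal(pair$prl_initial, c(1, 2))
  expect_equal(pair$prl_final, c(1, 2))

  # 250 early samples around (0,0), 250 late around (2,0): brute-force means
  set.seed(3)
  x <- c(rnorm(250, 0, 0.1), rnorm(250, 2, 0.1))
  y <- rnorm(500, 0, 0.1)
  t <- seq(0, 19.96, by = 0.04)
  e2 <- fixation_exam(t, x, y, eye = "OD")
  pair2 <- compute_prl_pair(e2, initial_window = 10)
  init <- t <= 10
  expect_equal(pair2$prl_initial, c(mean(x[init]), mean(y[init])))
  expect_equal(pair2$prl_final, c(mean(x), mean(y)))
  expect_equal(pair2$prl_initial[1], 0, tolerance = 0.05)
  expect_equal(pair2$prl_final[1], 1, tolerance = 0.05)

  single <- fixation_exam(0, 0.7, -0.3, eye = "OS")
  p1 <- compute_prl_pair(single)
  expect_equal(p1$prl_initial, c(0.7, -0.3))
  expect_equal(p1$prl_final, c(0.7, -0.3))

  late <- fixation_exam(c(20, 21), c(0, 0), c(0, 0), eye = "OD")
  expect_error(compute_prl_pair(late), "initial.*window")

  med <- compute_prl_pair(e2, center = "median")
  expect_equal(med$prl_final, c(median(x), median(y)))
})

test_that("DFC is the ruler-scaled Euclidean distance between FC and PRLf", {
  r <- scale_ruler(23, 200)
  expect_equal(dfc(c(10, 10), c(10, 10), r), 0)
  expect_equal(dfc(c(0, 0), c(23, 0), r), 200)
  expect_equal(dfc(c(0, 0), c(69, 92), r), 1000)   # 23 * (3,4,5) triple
  # symmetric in its two points
  set.seed(6)
  for (i in 1:5) {
    a <- runif(2, 0, 100); b <- runif(2, 0, 100)
    expect_equal(dfc(a, b, r), dfc(b, a, r))
  }
})

test_that("DFC and DPRL are invariant under a rigid motion of all points", {
  r <- scale_ruler(23, 200)
  set.seed(61)
  for (i in 1:8) {
    a <- runif(2, 0, 100); b <- runif(2, 0, 100)
    tf <- similarity_transform(1, runif(1, -pi, pi), runif(2, -50, 50))
    expect_equal(dfc(apply_transform(tf, a), apply_transform(tf, b), r),
                 dfc(a, b, r), tolerance = 1e-9)
  }
})

test_that("DPRL converts the PRLi-PRLf separation with the proper scale", {
  e <- const_exam(20, 1, 1)
  expect_equal(dprl(compute_prl_pair(e)), 0)

  # 1 degree apart in degree space -> 288 um at the default degree scale
  t <- seq(0, 39.96, by = 0.04)
  x <- ifelse(t <= 10, 0, 4 / 3)   # full-exam mean is 1 deg right of PRLi
  e2 <- fixation_exam(t, x, rep(0, length(t)), eye = "OD")
  pair <- compute_prl_pair(e2)
  expect_equal(sqrt(sum((pair$prl_final - pair$prl_initial)^2)), 1,
               tolerance = 0.005)
  expect_lt(abs(dprl(pair) - 288), 2)

  # programmed drift is recovered from a synthetic exam
  spec <- fixation_cloud_spec(n_samples = 10000, drift = 150,
                              center_offset_from_fc = c(500, 0), seed = 14)
  exam <- make_fixation_exam(spec, c(400, 400), scale_ruler(23, 200))
  pair_deg <- compute_prl_pair(exam)
  expect_lt(abs(dprl(pair_deg) - 150), 40)

  expect_error(dprl(compute_prl_pair(e), scale_ruler(23, 200)),
               "degree_scale")
})

test_that("longitudinal PRLf change is the triangle's third side", {
  r <- scale_ruler(20, 200)   # 10 um per px
  expect_equal(dfc_change(c(5, 5), c(5, 5), r), 0)
  # follow-up PRLf 40 px = 400 um from baseline, independent of the FC
  expect_equal(dfc_change(c(10, 10), c(50, 10), r), 400)
  # collinear FC / PRLf(t0) / PRLf(t1): change equals |DFC1 - DFC0|
  fc <- c(0, 0); p0 <- c(30, 0); p1 <- c(70, 0)
  expect_equal(dfc_change(p0, p1, r),
               abs(dfc(fc, p1, r) - dfc(fc, p0, r)))
  # triangle inequality in randomized trials
  set.seed(9)
  for (i in 1:20) {
    fc <- runif(2, 0, 200); p0 <- runif(2, 0, 200); p1 <- runif(2, 0, 200)
    expect_lte(dfc_change(p0, p1, r),
               dfc(fc, p0, r) + dfc(fc, p1, r) + 1e-9)
  }
})

test_that("quadrant labels follow laterality on a superior-up raster", {
  fc <- c(100, 100)
  expect_identical(quadrant(fc, c(90, 90), "OD"), "superotemporal")
  expect_identical(quadrant(fc, c(90, 90), "OS"), "superonasal")
  expect_identical(quadrant(fc, c(110, 90), "OD"), "superonasal")
  expect_identical(quadrant(fc, c(90, 110), "OD"), "inferotemporal")
  expect_identical(quadrant(fc, c(110, 110), "OD"), "inferonasal")
  expect_identical(quadrant(fc, c(110, 110), "OS"), "inferotemporal")
  expect_identical(quadrant(fc, fc, "OD"), "on_axis")
  expect_identical(quadrant(fc, c(100, 42), "OD"), "on_axis")
  expect_identical(quadrant(fc, c(100 + 1e-12, 42), "OD"), "on_axis")
  expect_error(quadrant(fc, c(90, 90), "left"), "OD.*OS|eye")
})

test_that("BCEA matches the closed form and degenerates to zero", {
  e0 <- const_exam(10, 1, 2)
  b0 <- bcea(e0)
  expect_equal(as.numeric(b0), 0)
  expect_true(attr(b0, "degenerate"))

  # perfectly correlated cloud collapses the sqrt(1 - r^2) term
  x <- seq(0, 1, length.out = 50)
  e1 <- fixation_exam(t = seq_along(x), x = x, y = 2 * x, eye = "OD")
  expect_equal(as.numeric(bcea(e1)), 0, tolerance = 1e-12)

  expect_error(bcea(const_exam(2, 0, 0)), "at least 3")
  expect_error(bcea(const_exam(10, 0, 0), coverage = 1), "in \\(0, 1\\)")
})

test_that("BCEA of a large normal cloud matches 5.991*pi and contains ~95% of points", {
  set.seed(2024)
  n <- 100000
  xy <- MASS::mvrnorm(n, c(0, 0), diag(2))
  e <- fixation_exam(t = seq_len(n) - 1, x = xy[, 1], y = xy[, 2],
                     eye = "OD")
  area <- as.numeric(bcea(e, 0.95))
  expect_equal(area, qchisq(0.95, 2) * pi, tolerance = 0.02)
  expect_equal(area, 18.82, tolerance = 0.02)

  # Monte-Carlo containment: the fitted 95% ellipse holds ~95% of samples
  mu <- colMeans(xy)
  S <- stats::cov(xy)
  d2 <- stats::mahalanobis(xy, mu, S)
  inside <- mean(d2 <= qchisq(0.95, 2))
  expect_equal(inside, 0.95, tolerance = 0.01 / 0.95)
})

test_that("BCEA is rigid-invariant and scales quadratically", {
  set.seed(77)
  xy <- MASS::mvrnorm(400, c(1, -2), matrix(c(1, 0.4, 0.4, 0.8), 2))
  e <- fixation_exam(t = 1:400, x = xy[, 1], y = xy[, 2], eye = "OD")
  base <- as.numeric(bcea(e))
  for (i in 1:5) {
    tf <- similarity_transform(1, runif(1, -pi, pi), runif(2, -3, 3))
    m <- apply_transform(tf, xy)
    er <- fixation_exam(t = 1:400, x = m[, 1], y = m[, 2], eye = "OD")
    expect_equal(as.numeric(bcea(er)), base, tolerance = 1e-9)
  }
  es <- fixation_exam(t = 1:400, x = 3 * xy[, 1], y = 3 * xy[, 2],
                      eye = "OD")
  expect_equal(as.numeric(bcea(es)), 9 * base, tolerance = 1e-9)
})

test_that("P1/P2 are inclusive percentages and monotone in the radius", {
  e <- const_exam(10, 0.5, 0.5)
  expect_equal(unname(p1_p2(e, c(0.5, 0.5))), c(100, 100))

  # hand count: distances 0.5, 1.5, 1.5, 3 from the reference
  e2 <- fixation_exam(t = 1:4, x = c(0.5, 1.5, 0, 3), y = c(0, 0, 1.5, 0),
                      eye = "OD")
  expect_equal(unname(p1_p2(e2, c(0, 0))), c(25, 75))

  # boundary: points exactly on the 1-degree circle count towards P1
  e3 <- fixation_exam(t = 1:4, x = c(1, -1, 0, 0), y = c(0, 0, 1, -1),
                      eye = "OD")
  expect_equal(unname(p1_p2(e3, c(0, 0))), c(100, 100))

  set.seed(15)
  xy <- MASS::mvrnorm(300, c(0, 0), diag(2))
  e4 <- fixation_exam(t = 1:300, x = xy[, 1], y = xy[, 2], eye = "OD")
  radii <- sort(runif(6, 0.2, 4))
  pcts <- vapply(radii, function(r)
    p1_p2(e4, c(0, 0), radii = c(r, r))[["p1"]], numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("stability classes apply strict 75% rules", {
  expect_identical(stability_class(80, 90), "stable")
  expect_identical(stability_class(70, 80), "relatively_unstable")
  expect_identical(stability_class(50, 70), "unstable")
  # boundary: exactly 75% is NOT 'more than 75%'
  expect_identical(stability_class(75, 75), "unstable")
  expect_identical(stability_class(75, 80), "relatively_unstable")
  expect_identical(stability_class(75 + 1e-9, 80), "stable")
  expect_error(stability_class(80, 70), "p1 must not exceed p2")
})

test_that("exam validity applies the inclusive 15% fixation-loss criterion", {
  mk <- function(fl) const_exam(5, 0, 0, fixation_loss_pct = fl)
  expect_true(exam_valid(mk(15)))
  expect_false(exam_valid(mk(15.1)))
  expect_true(exam_valid(mk(0)))
  expect_error(exam_valid(const_exam(5, 0, 0)), "no fixation_loss_pct")
})

test_that("eye_metrics assembles a coherent per-eye record", {
  ph <- demo_phantom(seed = 5)
  res <- recover_metrics(ph, fixation_cloud_spec(n_samples = 1500,
                                                 seed = 5))
  m <- res$metrics
  truth <- attr(res$exam, "truth")
  mpp <- ph$ruler$microns_per_pixel
  expect_equal(m$dfc, truth$dfc_um, tolerance = 3 * mpp / truth$dfc_um)
  expect_identical(m$quadrant, "superotemporal")
  expect_identical(m$stability, stability_class(m$p1, m$p2))
  expect_true(m$p1 <= m$p2)
  expect_true(m$valid_exam)
  expect_s3_class(summary(m), "data.frame")
  expect_output(print(m), "DFC")
})
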