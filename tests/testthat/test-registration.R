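make_pairs <- function(tf, src, noise_sd = 0) {
  dst <- apply_transform(tf, src)
  if (noise_sd > 0)
    dst <- dst + matrix(rnorm(length(dst), 0, noise_sd), ncol = 2)
  landmark_pairs(src, dst, tf$src_frame, tf$dst_frame)
}

test_that("identity landmark pairs recover the identity transform", {
  src <- cbind(c(0, 100, 0, 100), c(0, 0, 100, 100))
  tf <- estimate_transform(landmark_pairs(src, src))
  expect_equal(tf$scale, 1, tolerance = 1e-12)
  expect_equal(tf$rotation, 0, tolerance = 1e-12)
  expect_equal(unname(tf$translation), c(0, 0), tolerance = 1e-12)
  expect_equal(tf$rms_residual, 0, tolerance = 1e-12)
})

test_that("similarity estimation is exact on noise-free pairs across the parameter range", {
  set.seed(42)
  for (i in 1:25) {
    truth <- random_similarity()
    src <- matrix(runif(12, 0, 600), ncol = 2)
    est <- estimate_transform(make_pairs(truth, src))
    expect_equal(est$scale, truth$scale, tolerance = 1e-9)
    expect_equal(est$rotation, truth$rotation, tolerance = 1e-9)
    expect_equal(unname(est$translation), unname(truth$translation),
                 tolerance = 1e-9)
    expect_lt(est$rms_residual, 1e-9)
  }
})

test_that("known similarity (s=1.15, 7 deg, t=(12,-5)) is recovered to 1e-9 from 6 points", {
  truth <- similarity_transform(1.15, 7 * pi / 180, c(12, -5))
  set.seed(1)
  src <- matrix(runif(12, 0, 400), ncol = 2)
  est <- estimate_transform(make_pairs(truth, src))
  expect_equal(est$scale, 1.15, tolerance = 1e-9)
  expect_equal(est$rotation, 7 * pi / 180, tolerance = 1e-9)
  expect_equal(unname(est$translation), c(12, -5), tolerance = 1e-9)
})

test_that("parameter error shrinks with more noisy landmarks", {
  truth <- similarity_transform(1.1, 0.2, c(20, -30))
  err_at <- function(n, reps = 40) {
    mean(vapply(seq_len(reps), function(i) {
      src <- matrix(runif(2 * n, 0, 500), ncol = 2)
      est <- estimate_transform(make_pairs(truth, src, noise_sd = 0.5))
      sqrt(sum((est$translation - truth$translation)^2))
    }, numeric(1)))
  }
  set.seed(99)
  e10 <- err_at(10)
  e90 <- err_at(90)
  expect_lt(e90, e10)          # consistency
  expect_lt(e90 / e10, 0.70)   # roughly 1/sqrt(9) = 0.33, with MC slack
})

test_that("rms residual equals an independent brute-force recomputation", {
  set.seed(5)
  truth <- random_similarity()
  src <- matrix(runif(20, 0, 300), ncol = 2)
  pairs <- make_pairs(truth, src, noise_sd = 1)
  for (kind in c("similarity", "affine")) {
    est <- estimate_transform(pairs, kind)
    misfit <- vapply(seq_len(nrow(pairs)), function(i) {
      p <- apply_transform(est, c(pairs$x_src[i], pairs$y_src[i]))
      sum((p - c(pairs$x_dst[i], pairs$y_dst[i]))^2)
    }, numeric(1))
    expect_equal(est$rms_residual, sqrt(mean(misfit)), tolerance = 1e-12)
  }
})

test_that("estimate is invariant to landmark row order", {
  set.seed(8)
  truth <- random_similarity()
  src <- matrix(runif(16, 0, 300), ncol = 2)
  pairs <- make_pairs(truth, src, noise_sd = 0.8)
  perm <- sample(nrow(pairs))
  shuffled <- landmark_pairs(cbind(pairs$x_src, pairs$y_src)[perm, ],
                             cbind(pairs$x_dst, pairs$y_dst)[perm, ],
                             attr(pairs, "src_frame"),
                             attr(pairs, "dst_frame"))
  expect_equal(estimate_transform(pairs)$A, estimate_transform(shuffled)$A,
               tolerance = 1e-10)
})

test_that("affine estimation recovers a known affine map", {
  A <- matrix(c(1.1, 0.08, -0.05, 0.95, 12, -7), 2, 3)
  truth <- affine_transform(A)
  set.seed(2)
  src <- matrix(runif(16, 0, 300), ncol = 2)
  est <- estimate_transform(make_pairs(truth, src), kind = "affine")
  expect_equal(est$A, A, tolerance = 1e-9)
})

test_that("degenerate landmark configurations are rejected", {
  one <- landmark_pairs(rbind(c(0, 0), c(1, 1)), rbind(c(0, 0), c(1, 1)))
  expect_error(estimate_transform(one[1, ], "similarity"), "at least 2")
  expect_error(estimate_transform(one, "affine"), "at least 3")
  col3 <- landmark_pairs(cbind(0:2, 0:2), cbind(0:2, 0:2) + 1)
  expect_error(estimate_transform(col3, "affine"), "collinear")
  same <- landmark_pairs(rbind(c(5, 5), c(5, 5), c(5, 5)),
                         rbind(c(1, 2), c(3, 4), c(5, 6)))
  expect_error(estimate_transform(same), "zero spread")
})

test_that("apply_transform follows the y-down rotation convention", {
  expect_equal(apply_transform(identity_transform(), c(3, 4)), c(3, 4))
  tr <- similarity_transform(translation = c(5, 7))
  expect_equal(apply_transform(tr, c(0, 0)), c(5, 7))
  rot90 <- similarity_transform(rotation = pi / 2)
  expect_equal(apply_transform(rot90, c(1, 0)), c(0, 1), tolerance = 1e-12)
})

test_that("composition and inversion have exact sequential semantics", {
  i1 <- identity_transform("f")
  expect_equal(compose_transform(i1, i1)$A, i1$A)

  t1 <- similarity_transform(translation = c(1, 0), src_frame = "a",
                             dst_frame = "b")
  t2 <- similarity_transform(translation = c(0, 1), src_frame = "b",
                             dst_frame = "c")
  t12 <- compose_transform(t1, t2)
  expect_equal(unname(t12$translation), c(1, 1))
  expect_identical(t12$src_frame, "a")
  expect_identical(t12$dst_frame, "c")

  set.seed(21)
  for (i in 1:10) {
    A <- random_similarity("a", "b")
    B <- random_similarity("b", "c")
    p <- runif(2, -50, 50)
    expect_equal(apply_transform(compose_transform(A, B), p),
                 apply_transform(B, apply_transform(A, p)),
                 tolerance = 1e-9)
    rt <- compose_transform(A, invert_transform(A))
    expect_equal(rt$A, cbind(diag(2), c(0, 0)), tolerance = 1e-9)
  }

  expect_error(compose_transform(t2, t1), "frame mismatch.*'c'.*'a'")
})

test_that("overlay quality gate is inclusive at the ceiling", {
  tf <- estimate_transform(landmark_pairs(cbind(c(0, 10), c(0, 10)),
                                          cbind(c(0, 10), c(0, 10))))
  expect_identical(overlay_quality(tf, 2), "pass")          # rms 0
  tf$rms_residual <- 2
  expect_identical(overlay_quality(tf, 2), "pass")          # boundary
  tf$rms_residual <- 10
  expect_identical(overlay_quality(tf, 2), "fail")
})
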