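# Synthetic inputs for end-to-end validation: procedural vessel-tree
# phantom images under known inter-modality transforms, scan-line
# annotations crossing at a known foveal center, and bivariate-normal
# fixation clouds with programmed offset, spread, correlation and drift.
#
# Landmark tables are emitted analytically (exact under the true
# transforms), so tests of the measurement chain never depend on rendered
# pixel content; the images exist so a human can repeat the landmark picks.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic retinal phantom
#'
#' Describes one synthetic "eye": image geometry, a procedural vessel
#' tree, the true foveal center, the true transforms taking each acquired
#' modality frame (horizontal-scan OCT IR, vertical-scan OCT IR,
#' microperimetry SLO) into the common FAF frame, and the scale bar drawn
#' on the FAF image.
#'
#' @param image_size Side length of the square images in pixels
#'   (default 768).
#' @param n_vessels Number of vessel random walks (default 12).
#' @param seed Integer seed making the phantom deterministic.
#' @param true_fc Foveal center `(x, y)` in common-frame pixels; must lie
#'   inside the image. Default: image center.
#' @param transforms Named list with similarity `planar_transform`s
#'   `oct_h`, `oct_v`, `maia` mapping each modality frame into the common
#'   `"faf"` frame. Default: identity for all three.
#' @param scale_bar List `(pixels, microns)` of the FAF scale bar
#'   (default 23 px = 200 µm).
#' @param eye `"OD"` or `"OS"` (places the optic disc nasally).
#' @param n_landmarks Landmark correspondences emitted per modality pair
#'   (default 8).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 768, n_vessels = 12, seed = 1,
                         true_fc = NULL, transforms = NULL,
                         scale_bar = list(pixels = 23, microns = 200),
                         eye = "OD", n_landmarks = 8) {
  stopifnot(image_size >= 64, n_vessels >= 1, n_landmarks >= 3,
            eye %in% c("OD", "OS"))
  if (is.null(true_fc)) true_fc <- c(image_size / 2, image_size / 2)
  true_fc <- as.numeric(true_fc)
  if (length(true_fc) != 2L || any(!is.finite(true_fc)) ||
      any(true_fc < 0) || any(true_fc > image_size - 1))
    stop("phantom_spec: 'true_fc' must lie inside the image", call. = FALSE)
  if (is.null(transforms))
    transforms <- list(oct_h = similarity_transform(src_frame = "oct_h",
                                                    dst_frame = "faf"),
                       oct_v = similarity_transform(src_frame = "oct_v",
                                                    dst_frame = "faf"),
                       maia = similarity_transform(src_frame = "maia",
                                                   dst_frame = "faf"))
  stopifnot(all(c("oct_h", "oct_v", "maia") %in% names(transforms)),
            all(vapply(transforms, inherits, logical(1),
                       "planar_transform")))
  stopifnot(scale_bar$pixels > 0, scale_bar$microns > 0)
  structure(list(image_size = as.integer(image_size),
                 n_vessels = as.integer(n_vessels),
                 seed = as.integer(seed),
                 true_fc = true_fc,
                 transforms = transforms,
                 scale_bar = scale_bar,
                 eye = eye,
                 n_landmarks = as.integer(n_landmarks)),
            class = "phantom_spec")
}

# Random-walk vessel tree radiating from the optic disc; returns an n x 2
# matrix of polyline vertices (common frame) with NA rows separating
# vessels.
vessel_vertices <- function(size, n_vessels, disc) {
  steps <- max(60L, as.integer(size / 6))
  step_len <- size / steps * 2.2
  out <- vector("list", n_vessels)
  for (v in seq_len(n_vessels)) {
    heading <- stats::runif(1, 0, 2 * pi)
    pos <- disc + c(stats::rnorm(1, 0, size / 60),
                    stats::rnorm(1, 0, size / 60))
    pts <- matrix(NA_real_, steps, 2)
    for (s in seq_len(steps)) {
      heading <- heading + stats::rnorm(1, 0, 0.16)
      pos <- pos + step_len * c(cos(heading), sin(heading))
      if (any(pos < 2) || any(pos > size - 3)) break
      pts[s, ] <- pos
    }
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    out[[v]] <- rbind(pts, c(NA, NA))
  }
  do.call(rbind, out)
}

gaussian_kernel <- function(sigma = 1.2, radius = 3L) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

blur_separable <- function(img, k) {
  f <- function(m) {
    out <- stats::filter(m, k, sides = 2)
    out[is.na(out)] <- 0
    matrix(out, nrow(m), ncol(m))
  }
  t(f(t(f(img))))
}

# Render polyline vertices (x, y in 0-based px) into a [0, 1] grayscale
# matrix (rows = y) of side `size`.
render_vessel_image <- function(vertices, size) {
  seg_ok <- stats::complete.cases(vertices)
  # densify each consecutive in-vessel pair
  pts <- list(); pi_ <- 1L
  n <- nrow(vertices)
  for (i in seq_len(n - 1L)) {
    if (!seg_ok[i] || !seg_ok[i + 1L]) next
    a <- vertices[i, ]; b <- vertices[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    m <- max(2L, ceiling(len / 0.5))
    tt <- seq(0, 1, length.out = m)
    pts[[pi_]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    pi_ <- pi_ + 1L
  }
  if (length(pts) == 0L) return(matrix(0, size, size))
  p <- do.call(rbind, pts)
  ix <- round(p[, 1]) + 1L
  iy <- round(p[, 2]) + 1L
  keep <- ix >= 1L & ix <= size & iy >= 1L & iy <= size
  lin <- (ix[keep] - 1L) * size + iy[keep]
  tab <- tabulate(lin, nbins = size * size)
  img <- matrix(tab, size, size)  # column-major: [iy, ix], i.e. rows = y
  img[img > 0] <- 1
  img <- blur_separable(img, gaussian_kernel())
  img <- img / max(img, 1e-12)
  0.08 + 0.9 * pmin(img, 1)
}

#' Generate a synthetic phantom bundle
#'
#' Produces, deterministically for a given spec: one grayscale image per
#' modality (the same vessel tree seen through each modality's inverse
#' transform; the FAF image carries the scale bar), exact landmark
#' correspondence tables from each modality frame into the common frame,
#' and a horizontal plus a vertical scan-line annotation whose registered
#' intersection is exactly the true foveal center.
#'
#' @param spec A [phantom_spec()].
#' @param dir Optional directory; when given, PNG images, landmark and
#'   scan-line CSVs and a `ground_truth.json` are written there.
#' @param render Render pixel images (default TRUE). Landmarks and scan
#'   lines are analytic and do not require rendering.
#' @return A list with elements `images` (named list of matrices or
#'   `NULL`), `landmarks` (named list of [landmark_pairs()]: `oct_h`,
#'   `oct_v`, `maia`, each modality -> `"faf"`), `scanlines` (list `h`,
#'   `v` of [scan_line()]s in their own frames), `ruler` (the FAF
#'   [scale_ruler()]), and `truth` (true FC, transforms, target position
#'   in the MAIA frame, eye).
#' @export
make_phantom <- function(spec, dir = NULL, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$image_size
  fc <- spec$true_fc
  # optic disc sits nasally: image-right for OD, image-left for OS
  disc <- c(if (spec$eye == "OD") 0.86 * size else 0.14 * size, 0.52 * size)

  verts <- with_seed(spec$seed, vessel_vertices(size, spec$n_vessels, disc))
  good <- which(stats::complete.cases(verts))
  if (length(good) < spec$n_landmarks)
    stop("make_phantom: vessel tree too sparse for requested landmarks",
         call. = FALSE)
  sel <- good[round(seq(1, length(good), length.out = spec$n_landmarks))]
  lm_common <- verts[sel, , drop = FALSE]

  inv_tf <- lapply(spec$transforms, invert_transform)
  landmarks <- lapply(c(oct_h = "oct_h", oct_v = "oct_v", maia = "maia"),
                      function(fr) {
    src <- apply_transform(inv_tf[[fr]], lm_common)
    landmark_pairs(src, lm_common, src_frame = fr, dst_frame = "faf")
  })

  # scan lines constructed in their own acquisition frames, passing
  # exactly through the true FC once registered
  half <- 0.42 * size
  fc_h <- apply_transform(inv_tf$oct_h, fc)
  fc_v <- apply_transform(inv_tf$oct_v, fc)
  sl_h <- scan_line(fc_h - c(half, 0), fc_h + c(half, 0),
                    orientation = "horizontal", frame = "oct_h",
                    id = "transfoveal_h")
  sl_v <- scan_line(fc_v - c(0, half), fc_v + c(0, half),
                    orientation = "vertical", frame = "oct_v",
                    id = "transfoveal_v")

  ruler <- scale_ruler(spec$scale_bar$pixels, spec$scale_bar$microns)
  target_maia <- apply_transform(inv_tf$maia, fc)

  images <- NULL
  if (render) {
    images <- lapply(c(oct_h = "oct_h", oct_v = "oct_v",
                       maia = "maia", faf = "faf"), function(fr) {
      v <- verts
      ok <- stats::complete.cases(v)
      if (fr != "faf")
        v[ok, ] <- apply_transform(inv_tf[[fr]], v[ok, , drop = FALSE])
      img <- render_vessel_image(v, size)
      if (fr == "faf") {
        y0 <- size - 24L
        x0 <- 24L
        img[y0:(y0 + 2L), x0:(x0 + spec$scale_bar$pixels - 1L)] <- 1
      }
      img
    })
  }

  truth <- list(true_fc = fc, eye = spec$eye,
                target_maia = target_maia,
                microns_per_pixel = ruler$microns_per_pixel,
                transforms = spec$transforms)

  out <- list(images = images, landmarks = landmarks,
              scanlines = list(h = sl_h, v = sl_v),
              ruler = ruler, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (render)
      for (fr in names(images))
        png::writePNG(images[[fr]], file.path(dir, paste0(fr, ".png")))
    for (fr in names(landmarks))
      write_landmark_csv(landmarks[[fr]],
                         file.path(dir, paste0("landmarks_", fr, ".csv")))
    write_scanline_csv(sl_h, file.path(dir, "scanline_h.csv"))
    write_scanline_csv(sl_v, file.path(dir, "scanline_v.csv"))
    tf_json <- lapply(spec$transforms, function(x)
      list(kind = x$kind, scale = x$scale,
           rotation = x$rotation, translation = x$translation,
           src_frame = x$src_frame, dst_frame = x$dst_frame))
    jsonlite::write_json(
      list(true_fc = fc, eye = spec$eye, target_maia = target_maia,
           scale_bar = spec$scale_bar,
           microns_per_pixel = ruler$microns_per_pixel,
           transforms = tf_json),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Specification of a synthetic fixation cloud
#'
#' Parameters of a bivariate-normal gaze-sample stream: sampling cadence,
#' spread and correlation of the cloud in degrees, the programmed offset
#' of the cloud center from the foveal center (the true DFC vector, in
#' microns of the common frame), and a programmed drift (the expected
#' PRLi-to-PRLf separation, in microns).
#'
#' Defaults emulate one microperimetry fixation exam of an eye with
#' markedly eccentric, moderately unstable fixation: 2500 samples at
#' 25 Hz (100 s test), sigma 1 degree per axis, cloud center 1398 µm
#' superotemporal (OD) of the fovea, 750 µm drift.
#'
#' @param n_samples Number of gaze samples (default 2500).
#' @param rate Sampling rate in Hz (default 25).
#' @param center_offset_from_fc `(x, y)` offset of the cloud center from
#'   the foveal center, in µm along the common-frame raster axes
#'   (default `c(-989, -989)`, i.e. 1398 µm towards image up-left:
#'   superotemporal for OD).
#' @param sigma Per-axis standard deviations in degrees (default
#'   `c(1, 1)`).
#' @param rho Correlation of x and y gaze positions, `|rho| < 1`
#'   (default 0).
#' @param drift Programmed expected separation between PRLi and PRLf in
#'   µm (default 750); the mean gaze position moves linearly in time,
#'   scaled so the PRLi -> PRLf expectation has exactly this magnitude.
#' @param drift_angle Direction of the drift in radians in the common
#'   frame (default 0: towards image right).
#' @param fixation_loss_pct Fixation-loss percentage recorded in the exam
#'   metadata (default 5).
#' @param seed Integer seed.
#' @return An object of class `fixation_cloud_spec`.
#' @export
fixation_cloud_spec <- function(n_samples = 2500, rate = 25,
                                center_offset_from_fc = c(-989, -989),
                                sigma = c(1, 1), rho = 0, drift = 750,
                                drift_angle = 0, fixation_loss_pct = 5,
                                seed = 1) {
  stopifnot(n_samples >= 1, rate > 0, length(center_offset_from_fc) == 2L,
            all(is.finite(center_offset_from_fc)),
            length(sigma) == 2L, all(sigma > 0), abs(rho) < 1,
            drift >= 0, is.finite(drift_angle),
            fixation_loss_pct >= 0, fixation_loss_pct <= 100)
  structure(list(n_samples = as.integer(n_samples), rate = rate,
                 center_offset_from_fc = as.numeric(center_offset_from_fc),
                 sigma = as.numeric(sigma), rho = rho, drift = drift,
                 drift_angle = drift_angle,
                 fixation_loss_pct = fixation_loss_pct,
                 seed = as.integer(seed)),
            class = "fixation_cloud_spec")
}

#' Simulate a microperimetry fixation exam
#'
#' Draws gaze samples from a bivariate normal with the spec's moments,
#' centred (in expectation) on `fc + center_offset_from_fc` in the common
#' frame, with a linear drift such that the expected PRLi -> PRLf
#' separation equals the programmed drift. The fixation target is assumed
#' to sit on the anatomic foveal center (the stimulus grid is re-centred
#' on the fovea for eccentric fixators), so gaze degrees are relative to
#' the registered FC; the exam is expressed in degrees via the degree
#' scale and (if a MAIA -> common transform is given) the inverse of the
#' degree-axis mapping used by [fixation_to_frame()], making generation
#' and recovery exact inverses.
#'
#' @param spec A [fixation_cloud_spec()].
#' @param fc Foveal center in common-frame pixels.
#' @param ruler Common-frame [scale_ruler()].
#' @param deg_scale [degree_scale()].
#' @param transform Optional similarity transform MAIA -> common frame.
#' @param eye,subject_id,visit Exam metadata.
#' @return A [fixation_exam()] in degrees, with attribute `truth`: the
#'   programmed `dfc_um`, `dprl_um` and closed-form `bcea_deg2` at 95%
#'   coverage (`bcea_deg2` describes the sampling noise alone and matches
#'   the measured cloud only for `drift = 0`; drift widens the cloud).
#' @export
make_fixation_exam <- function(spec, fc, ruler, deg_scale = degree_scale(),
                               transform = NULL, eye = "OD",
                               subject_id = "synthetic",
                               visit = "baseline") {
  stopifnot(inherits(spec, "fixation_cloud_spec"),
            inherits(ruler, "scale_ruler"),
            inherits(deg_scale, "degree_scale"))
  fc <- as_point(fc, "fc")
  n <- spec$n_samples
  t <- (seq_len(n) - 1L) / spec$rate

  drift_vec <- spec$drift * c(cos(spec$drift_angle), sin(spec$drift_angle))
  init <- t <= 10
  if (!any(init)) init[1] <- TRUE
  denom <- mean(t) - mean(t[init])
  g <- if (spec$drift > 0 && denom > 0) (t - mean(t[init])) / denom
       else rep(0, n)

  # expected gaze path in common-frame microns, relative to the FC
  mu_um <- cbind(spec$center_offset_from_fc[1] + drift_vec[1] * g,
                 spec$center_offset_from_fc[2] + drift_vec[2] * g)

  theta <- if (!is.null(transform)) {
    stopifnot(inherits(transform, "planar_transform"),
              transform$kind == "similarity")
    transform$rotation
  } else 0
  ca <- cos(-theta); sa <- sin(-theta)
  mu_deg <- cbind(ca * mu_um[, 1] - sa * mu_um[, 2],
                  sa * mu_um[, 1] + ca * mu_um[, 2]) /
    deg_scale$microns_per_degree

  Sigma <- matrix(c(spec$sigma[1]^2,
                    spec$rho * spec$sigma[1] * spec$sigma[2],
                    spec$rho * spec$sigma[1] * spec$sigma[2],
                    spec$sigma[2]^2), 2, 2)
  noise <- with_seed(spec$seed, MASS::mvrnorm(n, c(0, 0), Sigma))
  if (n == 1L) noise <- matrix(noise, 1L, 2L)

  exam <- fixation_exam(t = t,
                        x = mu_deg[, 1] + noise[, 1],
                        y = mu_deg[, 2] + noise[, 2],
                        eye = eye, subject_id = subject_id, visit = visit,
                        fixation_loss_pct = spec$fixation_loss_pct,
                        test_duration = n / spec$rate)
  attr(exam, "truth") <- list(
    dfc_um = sqrt(sum((spec$center_offset_from_fc + drift_vec)^2)),
    dprl_um = spec$drift,
    bcea_deg2 = stats::qchisq(0.95, 2) * pi * spec$sigma[1] *
      spec$sigma[2] * sqrt(1 - spec$rho^2))
  exam
}
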