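# Fixation metrics: PRL positions, distance from the foveal center (DFC),
# distance between PRLs (DPRL), fixation quadrant, BCEA, P1/P2 and the
# derived stability class.

as_point <- function(p, what = "point") {
  if (is.list(p) && !is.null(p$position)) p <- p$position
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p)))
    stop(sprintf("%s must be a finite length-2 (x, y) coordinate", what),
         call. = FALSE)
  p
}

#' Initial and final preferred retinal locus of a fixation exam
#'
#' The initial PRL (PRLi) is the center of the cluster of fixation points
#' collected during the initial window of the exam (default: the first 10
#' seconds); the final PRL (PRLf) is the center of the full exam's cloud
#' and serves as the reference point for all stability metrics. The
#' cluster center is the arithmetic mean by default (matching the
#' second-moment basis of the BCEA); the coordinate-wise median is
#' available for robustness to transient excursions.
#'
#' @param exam A [fixation_exam()], or any data frame with columns
#'   `t`, `x`, `y`.
#' @param initial_window Length of the initial window in seconds
#'   (default 10); samples with `t <=` this bound define PRLi.
#' @param center `"mean"` (default) or `"median"`.
#' @return An object of class `prl_pair`: `prl_initial`, `prl_final`
#'   (length-2 `(x, y)`), `window_initial`, `units` (inherited from the
#'   exam, `"deg"` for raw exams).
#' @export
compute_prl_pair <- function(exam, initial_window = 10,
                             center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.data.frame(exam), all(c("t", "x", "y") %in% names(exam)))
  if (nrow(exam) < 1L)
    stop("compute_prl_pair: exam has no samples", call. = FALSE)
  if (!is.numeric(initial_window) || initial_window <= 0)
    stop("compute_prl_pair: 'initial_window' must be positive", call. = FALSE)
  init <- exam$t <= initial_window
  if (!any(init))
    stop(sprintf(
      "compute_prl_pair: no samples inside the initial %g s window",
      initial_window), call. = FALSE)
  ctr <- if (center == "mean") {
    function(ix) c(mean(exam$x[ix]), mean(exam$y[ix]))
  } else {
    function(ix) c(stats::median(exam$x[ix]), stats::median(exam$y[ix]))
  }
  units <- attr(exam, "units")
  structure(list(prl_initial = ctr(init),
                 prl_final = ctr(rep(TRUE, nrow(exam))),
                 window_initial = initial_window,
                 center = center,
                 units = if (is.null(units)) "deg" else units),
            class = "prl_pair")
}

#' @export
print.prl_pair <- function(x, ...) {
  cat(sprintf("PRL pair (%s, %s centers):\n", x$units, x$center))
  cat(sprintf("  PRLi (first %g s): (%.4g, %.4g)\n", x$window_initial,
              x$prl_initial[1], x$prl_initial[2]))
  cat(sprintf("  PRLf (full exam):  (%.4g, %.4g)\n",
              x$prl_final[1], x$prl_final[2]))
  invisible(x)
}

#' Map a fixation exam from visual degrees into an image frame
#'
#' Converts gaze samples (visual degrees relative to the fixation target,
#' raster y-down convention in memory) into pixel coordinates of an image
#' frame: degrees are scaled to microns with the degree scale, microns to
#' pixels with the common-frame ruler, and the degree axes are rotated by
#' the rotation of the (similarity) registration transform that carries
#' the fixation target into the common frame.
#'
#' @param exam A [fixation_exam()] in degrees.
#' @param target Fixation-target position `(x, y)` in pixels, in
#'   `transform`'s source frame (or directly in the common frame when
#'   `transform` is `NULL`).
#' @param ruler [scale_ruler()] of the common frame.
#' @param deg_scale [degree_scale()] converting degrees to microns.
#' @param transform Optional similarity `planar_transform` from the
#'   target's frame to the common frame.
#' @return A data frame of class `fixation_exam` with `x`, `y` in common
#'   frame pixels (`units` attribute `"px"`) and metadata preserved.
#' @export
fixation_to_frame <- function(exam, target, ruler,
                              deg_scale = degree_scale(),
                              transform = NULL) {
  stopifnot(inherits(exam, "fixation_exam"),
            inherits(ruler, "scale_ruler"),
            inherits(deg_scale, "degree_scale"))
  if (!identical(attr(exam, "units"), "deg"))
    stop("fixation_to_frame: exam is not in degrees", call. = FALSE)
  target <- as_point(target, "target")
  theta <- 0
  if (!is.null(transform)) {
    stopifnot(inherits(transform, "planar_transform"))
    if (transform$kind != "similarity")
      stop("fixation_to_frame: degree-axis mapping requires a similarity transform",
           call. = FALSE)
    theta <- transform$rotation
    target <- apply_transform(transform, target)
  }
  px_per_deg <- deg_scale$microns_per_degree / ruler$microns_per_pixel
  ca <- cos(theta); sa <- sin(theta)
  xr <- ca * exam$x - sa * exam$y
  yr <- sa * exam$x + ca * exam$y
  out <- exam
  out$x <- target[1] + xr * px_per_deg
  out$y <- target[2] + yr * px_per_deg
  attr(out, "units") <- "px"
  out
}

#' Distance from the foveal center (DFC)
#'
#' Euclidean distance, in microns, between the anatomic foveal center and
#' the final preferred retinal locus, both in the common image frame —
#' the shortest line between the two points, converted with the per-eye
#' ruler.
#'
#' @param fc A [intersect_scanlines()] result or a length-2 `(x, y)` point
#'   in common-frame pixels.
#' @param prl_final PRLf as a length-2 point in common-frame pixels, or a
#'   `prl_pair` in pixel units (its `prl_final` is used).
#' @param ruler [scale_ruler()] of the common frame.
#' @return DFC in microns (scalar, `>= 0`).
#' @export
dfc <- function(fc, prl_final, ruler) {
  stopifnot(inherits(ruler, "scale_ruler"))
  if (inherits(prl_final, "prl_pair")) {
    if (!identical(prl_final$units, "px"))
      stop("dfc: PRL pair is not in pixel units; map the exam into the common frame first",
           call. = FALSE)
    prl_final <- prl_final$prl_final
  }
  p_fc <- as_point(fc, "fc")
  p_prl <- as_point(prl_final, "prl_final")
  px_to_um(sqrt(sum((p_fc - p_prl)^2)), ruler)
}

#' Distance between the initial and final PRL (DPRL)
#'
#' Euclidean distance, in microns, between PRLi and PRLf — a point-to-point
#' proxy for fixation stability. Pairs in degree units are converted with
#' a [degree_scale()]; pairs already mapped to common-frame pixels with a
#' [scale_ruler()].
#'
#' @param pair A [compute_prl_pair()] result.
#' @param scale A [degree_scale()] (for degree-unit pairs) or
#'   [scale_ruler()] (for pixel-unit pairs).
#' @return DPRL in microns (scalar, `>= 0`).
#' @export
dprl <- function(pair, scale = degree_scale()) {
  stopifnot(inherits(pair, "prl_pair"))
  d <- sqrt(sum((pair$prl_final - pair$prl_initial)^2))
  if (identical(pair$units, "deg")) {
    if (!inherits(scale, "degree_scale"))
      stop("dprl: pair is in degrees; 'scale' must be a degree_scale",
           call. = FALSE)
    deg_to_um(d, scale)
  } else if (identical(pair$units, "px")) {
    if (!inherits(scale, "scale_ruler"))
      stop("dprl: pair is in pixels; 'scale' must be a scale_ruler",
           call. = FALSE)
    px_to_um(d, scale)
  } else {
    stop(sprintf("dprl: unsupported pair units '%s'", pair$units),
         call. = FALSE)
  }
}

#' Longitudinal change of fixation position between visits
#'
#' Euclidean distance, in microns, between the PRLf positions of two
#' visits registered to the same common frame. Together with the two DFC
#' segments this forms a triangle with the foveal center; the change is
#' its third side and is independent of the FC itself.
#'
#' @param prl_final_baseline,prl_final_followup PRLf positions (length-2
#'   `(x, y)`, common-frame pixels) at the two visits.
#' @param ruler [scale_ruler()] of the common frame.
#' @return Displacement in microns.
#' @export
dfc_change <- function(prl_final_baseline, prl_final_followup, ruler) {
  stopifnot(inherits(ruler, "scale_ruler"))
  p0 <- as_point(prl_final_baseline, "prl_final_baseline")
  p1 <- as_point(prl_final_followup, "prl_final_followup")
  px_to_um(sqrt(sum((p0 - p1)^2)), ruler)
}

#' Retinal quadrant of the preferred retinal locus
#'
#' Two perpendicular (axis-aligned) lines through the foveal center divide
#' the image into quadrants. On a standard fundus display (superior up),
#' raster y decreases towards superior retina; the nasal/temporal meaning
#' of image left/right depends on laterality: for OD (right eye) the optic
#' nerve — hence nasal retina — is on the image right and temporal on the
#' image left; for OS it is mirrored. A PRLf whose x or y coordinate ties
#' with the FC's (within `tol` pixels) is classified `on_axis`.
#'
#' @param fc Foveal center (`foveal_center` or length-2 point, px).
#' @param prl_final PRLf (length-2 point, px, same frame).
#' @param eye `"OD"` or `"OS"`.
#' @param tol Tie tolerance in pixels (default 1e-9).
#' @return One of `"superotemporal"`, `"superonasal"`,
#'   `"inferotemporal"`, `"inferonasal"`, `"on_axis"`.
#' @export
quadrant <- function(fc, prl_final, eye, tol = 1e-9) {
  if (missing(eye) || !is.character(eye) || length(eye) != 1L ||
      !(eye %in% c("OD", "OS")))
    stop("quadrant: 'eye' must be \"OD\" or \"OS\"", call. = FALSE)
  p_fc <- as_point(fc, "fc")
  p <- as_point(prl_final, "prl_final")
  dx <- p[1] - p_fc[1]
  dy <- p[2] - p_fc[2]
  if (abs(dx) <= tol || abs(dy) <= tol) return("on_axis")
  vert <- if (dy < 0) "supero" else "infero"
  # image-left is temporal retina for OD, nasal for OS
  horiz <- if (dx < 0) {
    if (eye == "OD") "temporal" else "nasal"
  } else {
    if (eye == "OD") "nasal" else "temporal"
  }
  paste0(vert, horiz)
}

#' Bivariate contour ellipse area (BCEA)
#'
#' Area, in squared degrees, of the ellipse that covers a stated fraction
#' of the fixation samples under a bivariate-normal model of the cloud:
#' `BCEA = chi2_quantile(coverage, df = 2) * pi * sx * sy * sqrt(1 - r^2)`
#' with `sx`, `sy` the sample standard deviations of the horizontal and
#' vertical eye positions and `r` their sample correlation. A degenerate
#' cloud (zero variance on an axis, or perfectly correlated) has area 0
#' and is flagged with attribute `degenerate`.
#'
#' @param exam A [fixation_exam()] in degrees (or any data frame with
#'   numeric `x`, `y` columns in degrees); at least 3 samples.
#' @param coverage Coverage probability in (0, 1); default 0.95 (0.63 is
#'   the other conventional choice).
#' @return BCEA in deg^2 (scalar `>= 0`), with attribute `degenerate`.
#' @export
bcea <- function(exam, coverage = 0.95) {
  stopifnot(is.data.frame(exam), all(c("x", "y") %in% names(exam)))
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage >= 1)
    stop("bcea: 'coverage' must be in (0, 1)", call. = FALSE)
  n <- nrow(exam)
  if (n < 3L)
    stop(sprintf("bcea: at least 3 samples required, got %d", n),
         call. = FALSE)
  sx <- stats::sd(exam$x)
  sy <- stats::sd(exam$y)
  if (sx == 0 || sy == 0)
    return(structure(0, degenerate = TRUE))
  r <- stats::cor(exam$x, exam$y)
  k <- stats::qchisq(coverage, df = 2)
  area <- k * pi * sx * sy * sqrt(max(0, 1 - r^2))
  structure(area, degenerate = (1 - r^2) <= 0)
}

#' Fraction of fixation samples within 1 and 2 degrees of PRLf
#'
#' P1 and P2 are the percentages of fixation points located within a
#' distance of 1 and 2 degrees of the reference point (the final PRL);
#' both radii are inclusive (a point exactly on the circle counts).
#'
#' @param exam A [fixation_exam()] in degrees (at least one sample).
#' @param prl_final Reference point `(x, y)` in degrees; defaults to the
#'   cloud's own PRLf (arithmetic mean).
#' @param radii Radii in degrees, nondecreasing (default `c(1, 2)`).
#' @return Named numeric vector `c(p1 = ..., p2 = ...)` of percentages.
#' @export
p1_p2 <- function(exam, prl_final = NULL, radii = c(1, 2)) {
  stopifnot(is.data.frame(exam), all(c("x", "y") %in% names(exam)))
  if (nrow(exam) < 1L)
    stop("p1_p2: exam has no samples", call. = FALSE)
  stopifnot(is.numeric(radii), length(radii) == 2L, all(radii > 0),
            radii[1] <= radii[2])
  if (is.null(prl_final))
    prl_final <- c(mean(exam$x), mean(exam$y))
  p <- as_point(prl_final, "prl_final")
  d <- sqrt((exam$x - p[1])^2 + (exam$y - p[2])^2)
  # inclusive boundary, with a hair of slack against sqrt round-off
  eps <- 1e-9
  c(p1 = 100 * mean(d <= radii[1] + eps),
    p2 = 100 * mean(d <= radii[2] + eps))
}

#' Fixation-stability class from P1 and P2
#'
#' Classification rule: fixation is `stable` if more than 75% of the
#' points fall within 1 degree of PRLf; `relatively_unstable` if not, but
#' more than 75% fall within 2 degrees; otherwise `unstable`. The
#' inequalities are strict, so p1 = p2 = 75 exactly classifies as
#' `unstable`.
#'
#' @param p1,p2 Percentages in `[0, 100]` with `p1 <= p2`.
#' @return `"stable"`, `"relatively_unstable"` or `"unstable"`.
#' @export
stability_class <- function(p1, p2) {
  stopifnot(is.numeric(p1), is.numeric(p2), length(p1) == 1L,
            length(p2) == 1L, is.finite(p1), is.finite(p2))
  if (p1 < 0 || p2 > 100)
    stop("stability_class: percentages must be in [0, 100]", call. = FALSE)
  if (p1 > p2)
    stop("stability_class: p1 must not exceed p2", call. = FALSE)
  if (p1 > 75) "stable"
  else if (p2 > 75) "relatively_unstable"
  else "unstable"
}

#' Exam validity from the fixation-loss criterion
#'
#' An exam is reliable iff its fixation-loss percentage does not exceed
#' 15% (inclusive); exams above the threshold are to be repeated.
#'
#' @param exam A [fixation_exam()] carrying `fixation_loss_pct` metadata.
#' @param max_loss_pct Threshold in percent (default 15).
#' @return Logical scalar.
#' @export
exam_valid <- function(exam, max_loss_pct = 15) {
  stopifnot(inherits(exam, "fixation_exam"))
  fl <- attr(exam, "fixation_loss_pct")
  if (is.null(fl) || is.na(fl))
    stop("exam_valid: exam has no fixation_loss_pct metadata", call. = FALSE)
  fl <= max_loss_pct
}

#' Full fixation-metric record for one eye and visit
#'
#' Convenience wrapper running the whole per-eye computation: maps the
#' exam into the common frame, computes the PRL pair, DFC, DPRL, quadrant,
#' BCEA, P1/P2, stability class and exam validity.
#'
#' @param exam A [fixation_exam()] in degrees.
#' @param fc Foveal center in common-frame pixels ([intersect_scanlines()]
#'   result or length-2 point).
#' @param ruler [scale_ruler()] of the common frame.
#' @param target Fixation-target position in pixels (in `transform`'s
#'   source frame); defaults to the foveal center itself when the target
#'   was positioned on the anatomic fovea.
#' @param transform Optional similarity transform from the target's frame
#'   to the common frame (see [fixation_to_frame()]).
#' @param deg_scale [degree_scale()].
#' @param initial_window PRLi window in seconds (default 10).
#' @param coverage BCEA coverage (default 0.95).
#' @param center PRL cluster-center estimator, `"mean"` or `"median"`.
#' @return An object of class `eye_metrics` with fields `dfc`, `dprl`
#'   (µm), `quadrant`, `bcea` (deg^2), `bcea_coverage`, `p1`, `p2`
#'   (percent), `stability`, `valid_exam`, plus `fc`, `prl_initial`,
#'   `prl_final` (common-frame px), `eye`, `subject_id`, `visit`.
#' @export
eye_metrics <- function(exam, fc, ruler, target = NULL, transform = NULL,
                        deg_scale = degree_scale(), initial_window = 10,
                        coverage = 0.95, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(inherits(exam, "fixation_exam"), inherits(ruler, "scale_ruler"))
  p_fc <- as_point(fc, "fc")
  if (is.null(target)) {
    if (!is.null(transform))
      target <- apply_transform(invert_transform(transform), p_fc)
    else
      target <- p_fc
  }
  eye <- attr(exam, "eye")
  exam_px <- fixation_to_frame(exam, target, ruler, deg_scale, transform)
  pair_px <- compute_prl_pair(exam_px, initial_window, center)
  pair_deg <- compute_prl_pair(exam, initial_window, center)
  pp <- p1_p2(exam, pair_deg$prl_final)
  b <- bcea(exam, coverage)
  structure(list(
    dfc = dfc(p_fc, pair_px$prl_final, ruler),
    dprl = dprl(pair_px, ruler),
    quadrant = quadrant(p_fc, pair_px$prl_final, eye),
    bcea = as.numeric(b),
    bcea_degenerate = isTRUE(attr(b, "degenerate")),
    bcea_coverage = coverage,
    p1 = unname(pp["p1"]),
    p2 = unname(pp["p2"]),
    stability = stability_class(pp["p1"], pp["p2"]),
    valid_exam = tryCatch(exam_valid(exam), error = function(e) NA),
    fc = p_fc,
    prl_initial = pair_px$prl_initial,
    prl_final = pair_px$prl_final,
    eye = eye,
    subject_id = attr(exam, "subject_id"),
    visit = attr(exam, "visit")),
    class = "eye_metrics")
}

#' @export
print.eye_metrics <- function(x, ...) {
  cat(sprintf("Eye metrics: subject %s, %s, visit %s\n",
              x$subject_id, x$eye, x$visit))
  cat(sprintf("  DFC  %8.4g um   (PRLf at (%.4g, %.4g) px, FC at (%.4g, %.4g) px)\n",
              x$dfc, x$prl_final[1], x$prl_final[2], x$fc[1], x$fc[2]))
  cat(sprintf("  DPRL %8.4g um   quadrant: %s\n", x$dprl, x$quadrant))
  cat(sprintf("  BCEA(%.2g) %.4g deg^2%s\n", x$bcea_coverage, x$bcea,
              if (x$bcea_degenerate) " [degenerate cloud]" else ""))
  cat(sprintf("  P1 %.3g%%, P2 %.3g%% -> %s fixation\n",
              x$p1, x$p2, gsub("_", " ", x$stability)))
  cat(sprintf("  exam %s\n",
              if (isTRUE(x$valid_exam)) "valid (fixation loss <= 15%)"
              else if (isFALSE(x$valid_exam)) "INVALID (fixation loss > 15%)"
              else "validity unknown"))
  invisible(x)
}

#' @export
summary.eye_metrics <- function(object, ...) {
  data.frame(subject_id = object$subject_id, eye = object$eye,
             visit = object$visit, dfc_um = object$dfc,
             dprl_um = object$dprl, quadrant = object$quadrant,
             bcea_deg2 = object$bcea, p1_pct = object$p1,
             p2_pct = object$p2, stability = object$stability,
             valid_exam = object$valid_exam,
             stringsAsFactors = FALSE)
}
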