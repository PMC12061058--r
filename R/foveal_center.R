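# Anatomic foveal center from registered transfoveal scan lines.
#
# The selected vertical and horizontal OCT B-scans are chords through the
# fovea; after both are registered into the common frame, the crossing of
# the two infinite lines through their endpoints defines the foveal center.

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

#' Locate the foveal center as the intersection of two scan lines
#'
#' Each scan line is transformed into the common frame by its registration
#' transform; the unique intersection of the two infinite lines through the
#' transformed endpoints is the foveal center (FC). The angular separation
#' between the lines is recorded: intersections from lines separated by
#' less than 60 deg (or more than 120 deg) are flagged unreliable, and
#' near-parallel lines (< `min_separation` deg) are a geometric error.
#'
#' @param line_a,line_b [scan_line()] annotations (order is irrelevant;
#'   conventionally the horizontal and vertical transfoveal scans).
#' @param transform_a,transform_b `planar_transform`s taking each line's
#'   frame into the common frame; `NULL` means the line is already in the
#'   common frame.
#' @param min_separation Angular separation (degrees) below which the
#'   lines are treated as parallel (default 5).
#' @param image_size Optional `c(width, height)` in pixels of the common
#'   frame. When given, an intersection farther than
#'   `max_distance_factor` x the image diagonal from BOTH segments is an
#'   out-of-frame error.
#' @param max_distance_factor Multiplier on the image diagonal for the
#'   out-of-frame check (default 1.5).
#' @return An object of class `foveal_center`: `position` (px, common
#'   frame), `angular_separation` (degrees, in (0, 180)), `reliable`
#'   (TRUE iff separation within [60, 120] deg), `source_scan_ids`,
#'   `frame`.
#' @examples
#' h <- scan_line(c(0, 100), c(200, 100), "horizontal", frame = "common")
#' v <- scan_line(c(50, 0), c(50, 200), "vertical", frame = "common")
#' intersect_scanlines(h, v)$position  # (50, 100)
#' @export
intersect_scanlines <- function(line_a, line_b,
                                transform_a = NULL, transform_b = NULL,
                                min_separation = 5,
                                image_size = NULL,
                                max_distance_factor = 1.5) {
  stopifnot(inherits(line_a, "scan_line"), inherits(line_b, "scan_line"))
  tx <- function(line, transform) {
    if (is.null(transform)) {
      list(p1 = line$p1, p2 = line$p2, frame = line$frame)
    } else {
      stopifnot(inherits(transform, "planar_transform"))
      if (!is.null(transform$src_frame) &&
          !identical(transform$src_frame, line$frame))
        stop(sprintf(
          "intersect_scanlines: line frame '%s' does not match transform source frame '%s'",
          line$frame, transform$src_frame), call. = FALSE)
      list(p1 = apply_transform(transform, line$p1),
           p2 = apply_transform(transform, line$p2),
           frame = if (is.null(transform$dst_frame)) line$frame
                   else transform$dst_frame)
    }
  }
  a <- tx(line_a, transform_a)
  b <- tx(line_b, transform_b)
  if (!identical(a$frame, b$frame))
    stop(sprintf(
      "intersect_scanlines: lines end up in different frames ('%s' vs '%s')",
      a$frame, b$frame), call. = FALSE)

  d1 <- a$p2 - a$p1
  d2 <- b$p2 - b$p1
  sep <- (atan2(d2[2], d2[1]) - atan2(d1[2], d1[1])) * 180 / pi
  sep <- sep %% 180
  if (min(sep, 180 - sep) < min_separation)
    stop(sprintf(
      "intersect_scanlines: lines are near-parallel (separation %.3g deg < %g deg)",
      min(sep, 180 - sep), min_separation), call. = FALSE)

  # solve a$p1 + t d1 = b$p1 + u d2
  M <- cbind(d1, -d2)
  tu <- solve(M, b$p1 - a$p1)
  fc <- a$p1 + tu[1] * d1

  if (!is.null(image_size)) {
    stopifnot(length(image_size) == 2L, all(image_size > 0))
    diag_px <- sqrt(sum(as.numeric(image_size)^2))
    da <- point_segment_distance(fc, a$p1, a$p2)
    db <- point_segment_distance(fc, b$p1, b$p2)
    if (da > max_distance_factor * diag_px &&
        db > max_distance_factor * diag_px)
      stop(sprintf(
        "intersect_scanlines: intersection is out of frame (%.3g px from both segments, limit %.3g px)",
        min(da, db), max_distance_factor * diag_px), call. = FALSE)
  }

  structure(list(position = unname(fc),
                 angular_separation = sep,
                 reliable = sep >= 60 && sep <= 120,
                 source_scan_ids = c(line_a$id, line_b$id),
                 frame = a$frame),
            class = "foveal_center")
}

#' @export
print.foveal_center <- function(x, ...) {
  cat(sprintf(
    "Foveal center: (%.4g, %.4g) px in frame '%s'\n", x$position[1],
    x$position[2], x$frame))
  cat(sprintf("  scan lines '%s' x '%s', separation %.4g deg%s\n",
              x$source_scan_ids[1], x$source_scan_ids[2],
              x$angular_separation,
              if (x$reliable) "" else " [WARNING: oblique crossing]"))
  invisible(x)
}
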