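# Open interchange formats: CSV with a '#'-prefixed metadata header for
# tabular inputs (fixation streams, landmark sets, scan-line annotations,
# paired grader measurements) and UTF-8 JSON for result records.
#
# Conventions, applied uniformly:
#   * image coordinates are 0-based pixels, origin top-left, x rightward,
#     y downward; sub-pixel positions are real-valued;
#   * fixation files store visual degrees centred on the exam's fixation
#     target, x positive rightward, y positive UPWARD on the displayed SLO;
#     the reader flips y so that in-memory tables use the raster (y-down)
#     convention everywhere, and the writer flips back.

fmt_num <- function(x) sprintf("%.17g", x)

write_meta_csv <- function(df, meta, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, as.character(meta[[k]])), con)
  is_num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[is_num] <- lapply(df[is_num], fmt_num)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_meta <- grepl("^#", lines)
  # metadata block is the leading run of '#' lines only
  lead <- cumprod(is_meta) == 1
  meta_lines <- lines[lead]
  body <- lines[!lead]
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  if (length(body) == 0L)
    stop(sprintf("'%s': no data rows after metadata header", path),
         call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(data = df, meta = meta)
}

meta_num <- function(meta, key, path, required = TRUE) {
  if (is.null(meta[[key]])) {
    if (required)
      stop(sprintf("'%s': missing metadata key '%s'", path, key),
           call. = FALSE)
    return(NA_real_)
  }
  v <- suppressWarnings(as.numeric(meta[[key]]))
  if (is.na(v))
    stop(sprintf("'%s': metadata key '%s' is not numeric", path, key),
         call. = FALSE)
  v
}

# ---------------------------------------------------------------------------
# Fixation exams

#' Construct a fixation exam (timestamped gaze samples)
#'
#' A fixation exam is the stream of gaze positions recorded by the
#' microperimeter while the patient fixates the target (nominally 25
#' samples per second). Positions are in visual degrees relative to the
#' fixation target; in memory, y follows the raster convention (positive
#' downward), matching the displayed SLO image.
#'
#' @param t Sample times in seconds, nondecreasing, `>= 0`.
#' @param x,y Gaze coordinates in degrees (y positive downward in memory).
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param subject_id,visit Identifier strings.
#' @param fixation_loss_pct Percentage of fixation losses reported for the
#'   exam, in `[0, 100]`; `NA` if unknown.
#' @param test_duration Total test duration in seconds; defaults to the
#'   last sample time.
#' @return A data frame of class `fixation_exam` with columns `t`, `x`,
#'   `y` and metadata in attributes (`eye`, `subject_id`, `visit`,
#'   `fixation_loss_pct`, `test_duration`, `units = "deg"`).
#' @export
fixation_exam <- function(t, x, y, eye, subject_id = "unknown",
                          visit = "baseline", fixation_loss_pct = NA_real_,
                          test_duration = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (n < 1L)
    stop("fixation_exam: at least one sample is required", call. = FALSE)
  if (length(x) != n || length(y) != n)
    stop("fixation_exam: t, x, y must have equal length", call. = FALSE)
  if (any(!is.finite(c(t, x, y))))
    stop("fixation_exam: non-finite sample values", call. = FALSE)
  if (any(t < 0))
    stop("fixation_exam: negative sample times", call. = FALSE)
  bad <- which(diff(t) < 0)
  if (length(bad) > 0L)
    stop(sprintf("fixation_exam: sample times decrease at row %d",
                 bad[1] + 1L), call. = FALSE)
  if (!is.character(eye) || length(eye) != 1L || !(eye %in% c("OD", "OS")))
    stop("fixation_exam: 'eye' must be \"OD\" or \"OS\"", call. = FALSE)
  if (!is.na(fixation_loss_pct) &&
      (fixation_loss_pct < 0 || fixation_loss_pct > 100))
    stop("fixation_exam: 'fixation_loss_pct' must be in [0, 100]",
         call. = FALSE)
  if (is.null(test_duration)) test_duration <- t[n]
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "eye") <- eye
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "visit") <- as.character(visit)
  attr(out, "fixation_loss_pct") <- as.numeric(fixation_loss_pct)
  attr(out, "test_duration") <- as.numeric(test_duration)
  attr(out, "units") <- "deg"
  class(out) <- c("fixation_exam", "data.frame")
  out
}

#' @export
print.fixation_exam <- function(x, ...) {
  cat(sprintf(
    "Fixation exam: %d samples over %.4g s (%s, subject %s, visit %s)\n",
    nrow(x), attr(x, "test_duration"), attr(x, "eye"),
    attr(x, "subject_id"), attr(x, "visit")))
  fl <- attr(x, "fixation_loss_pct")
  if (!is.na(fl)) cat(sprintf("  fixation loss %.3g%%\n", fl))
  invisible(x)
}

#' Write a fixation exam to CSV
#'
#' Columns `t,x,y`, preceded by a `#`-prefixed metadata header. On disk y
#' is positive upward (device convention); the y flip relative to the
#' in-memory raster convention is applied here and undone by
#' [read_fixation_csv()].
#'
#' @param exam A [fixation_exam()].
#' @param path Output file path.
#' @export
write_fixation_csv <- function(exam, path) {
  stopifnot(inherits(exam, "fixation_exam"))
  meta <- list(eye = attr(exam, "eye"),
               subject_id = attr(exam, "subject_id"),
               visit = attr(exam, "visit"),
               fixation_loss_pct = fmt_num(attr(exam, "fixation_loss_pct")),
               test_duration = fmt_num(attr(exam, "test_duration")))
  df <- data.frame(t = exam$t, x = exam$x, y = -exam$y)
  write_meta_csv(df, meta, path)
}

#' Read a fixation exam from CSV
#'
#' @param path File written by [write_fixation_csv()] (or conforming to
#'   the same layout).
#' @return A [fixation_exam()]; row order preserved, y flipped to the
#'   in-memory raster convention.
#' @export
read_fixation_csv <- function(path) {
  r <- read_meta_csv(path)
  for (col in c("t", "x", "y"))
    if (!(col %in% names(r$data)))
      stop(sprintf("'%s': missing required column '%s'", path, col),
           call. = FALSE)
  for (key in c("eye", "subject_id", "visit"))
    if (is.null(r$meta[[key]]))
      stop(sprintf("'%s': missing metadata key '%s'", path, key),
           call. = FALSE)
  fl <- meta_num(r$meta, "fixation_loss_pct", path, required = FALSE)
  td <- meta_num(r$meta, "test_duration", path, required = FALSE)
  t <- as.numeric(r$data$t)
  bad <- which(diff(t) < 0)
  if (length(bad) > 0L)
    stop(sprintf("'%s': sample times decrease at row %d", path, bad[1] + 1L),
         call. = FALSE)
  fixation_exam(t = t, x = as.numeric(r$data$x), y = -as.numeric(r$data$y),
                eye = r$meta$eye, subject_id = r$meta$subject_id,
                visit = r$meta$visit, fixation_loss_pct = fl,
                test_duration = if (is.na(td)) NULL else td)
}

# ---------------------------------------------------------------------------
# Landmark pairs

#' Construct a landmark correspondence table
#'
#' Matched positions (vessel bifurcations, optic nerve silhouette points)
#' clicked or generated in a source and a destination image frame; the
#' input to [estimate_transform()].
#'
#' @param src,dst n x 2 matrices (or data frames) of `(x, y)` pixel
#'   coordinates in the source and destination frames.
#' @param src_frame,dst_frame Frame names.
#' @return A data frame of class `landmark_pairs` with columns
#'   `x_src, y_src, x_dst, y_dst`.
#' @export
landmark_pairs <- function(src, dst, src_frame = "src", dst_frame = "dst") {
  src <- as_point_matrix(src); dst <- as_point_matrix(dst)
  if (nrow(src) != nrow(dst))
    stop("landmark_pairs: src and dst must have the same number of rows",
         call. = FALSE)
  if (nrow(src) < 2L)
    stop("landmark_pairs: at least 2 correspondences are required",
         call. = FALSE)
  out <- data.frame(x_src = src[, 1], y_src = src[, 2],
                    x_dst = dst[, 1], y_dst = dst[, 2])
  attr(out, "src_frame") <- as.character(src_frame)
  attr(out, "dst_frame") <- as.character(dst_frame)
  class(out) <- c("landmark_pairs", "data.frame")
  out
}

#' Write landmark pairs to CSV
#' @param pairs A [landmark_pairs()] table.
#' @param path Output file path.
#' @export
write_landmark_csv <- function(pairs, path) {
  stopifnot(inherits(pairs, "landmark_pairs"))
  meta <- list(src_frame = attr(pairs, "src_frame"),
               dst_frame = attr(pairs, "dst_frame"))
  write_meta_csv(as.data.frame(pairs), meta, path)
}

#' Read landmark pairs from CSV
#' @param path File with columns `x_src,y_src,x_dst,y_dst` and metadata
#'   keys `src_frame`, `dst_frame`.
#' @export
read_landmark_csv <- function(path) {
  r <- read_meta_csv(path)
  for (col in c("x_src", "y_src", "x_dst", "y_dst"))
    if (!(col %in% names(r$data)))
      stop(sprintf("'%s': missing required column '%s'", path, col),
           call. = FALSE)
  for (key in c("src_frame", "dst_frame"))
    if (is.null(r$meta[[key]]))
      stop(sprintf("'%s': missing metadata key '%s'", path, key),
           call. = FALSE)
  landmark_pairs(cbind(r$data$x_src, r$data$y_src),
                 cbind(r$data$x_dst, r$data$y_dst),
                 src_frame = r$meta$src_frame,
                 dst_frame = r$meta$dst_frame)
}

# ---------------------------------------------------------------------------
# Scan-line annotations

#' Construct a transfoveal scan-line annotation
#'
#' The en-face footprint of a selected OCT B-scan, given by its two
#' endpoints in a named image frame. The declared orientation must agree
#' with the endpoint geometry within an angular tolerance.
#'
#' @param p1,p2 Length-2 numeric endpoints `(x, y)` in pixels; must be
#'   distinct.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param frame Name of the image frame the endpoints live in.
#' @param id Optional scan identifier string.
#' @param angle_tol Maximum deviation, in degrees, of the segment from its
#'   declared orientation (default 15).
#' @return An object of class `scan_line`.
#' @export
scan_line <- function(p1, p2, orientation = c("horizontal", "vertical"),
                      frame = "oct", id = NULL, angle_tol = 15) {
  orientation <- match.arg(orientation)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  stopifnot(length(p1) == 2L, length(p2) == 2L,
            all(is.finite(c(p1, p2))))
  if (all(p1 == p2))
    stop("scan_line: endpoints must be distinct", call. = FALSE)
  d <- p2 - p1
  ang <- abs(atan2(d[2], d[1])) * 180 / pi       # in [0, 180]
  dev_h <- min(ang, 180 - ang)                   # deviation from horizontal
  dev_v <- abs(90 - ang)                         # deviation from vertical
  dev <- if (orientation == "horizontal") dev_h else dev_v
  if (dev > angle_tol)
    stop(sprintf(
      "scan_line: segment deviates %.3g deg from declared '%s' orientation (tolerance %g)",
      dev, orientation, angle_tol), call. = FALSE)
  structure(list(p1 = p1, p2 = p2, orientation = orientation,
                 frame = as.character(frame),
                 id = if (is.null(id)) orientation else as.character(id)),
            class = "scan_line")
}

#' @export
print.scan_line <- function(x, ...) {
  cat(sprintf("Scan line '%s' (%s, frame %s): (%.4g, %.4g) -- (%.4g, %.4g)\n",
              x$id, x$orientation, x$frame,
              x$p1[1], x$p1[2], x$p2[1], x$p2[2]))
  invisible(x)
}

#' Write scan-line annotations to CSV
#'
#' One row per line: `id,orientation,x1,y1,x2,y2`; the frame name goes in
#' the metadata header (all lines in one file share a frame).
#'
#' @param lines A `scan_line` or list of them, all in the same frame.
#' @param path Output file path.
#' @export
write_scanline_csv <- function(lines, path) {
  if (inherits(lines, "scan_line")) lines <- list(lines)
  stopifnot(length(lines) >= 1L,
            all(vapply(lines, inherits, logical(1), "scan_line")))
  frames <- unique(vapply(lines, `[[`, character(1), "frame"))
  if (length(frames) != 1L)
    stop("write_scanline_csv: all scan lines must share one frame",
         call. = FALSE)
  df <- do.call(rbind, lapply(lines, function(l)
    data.frame(id = l$id, orientation = l$orientation,
               x1 = l$p1[1], y1 = l$p1[2], x2 = l$p2[1], y2 = l$p2[2])))
  write_meta_csv(df, list(frame = frames), path)
}

#' Read scan-line annotations from CSV
#' @param path File written by [write_scanline_csv()].
#' @return A named list of `scan_line` objects (names are the ids).
#' @export
read_scanline_csv <- function(path) {
  r <- read_meta_csv(path)
  for (col in c("id", "orientation", "x1", "y1", "x2", "y2"))
    if (!(col %in% names(r$data)))
      stop(sprintf("'%s': missing required column '%s'", path, col),
           call. = FALSE)
  if (is.null(r$meta$frame))
    stop(sprintf("'%s': missing metadata key 'frame'", path), call. = FALSE)
  out <- lapply(seq_len(nrow(r$data)), function(i) {
    row <- r$data[i, ]
    scan_line(c(row$x1, row$y1), c(row$x2, row$y2),
              orientation = row$orientation, frame = r$meta$frame,
              id = row$id)
  })
  names(out) <- r$data$id
  out
}

# ---------------------------------------------------------------------------
# Paired grader measurements

#' Read paired grader measurements from CSV
#'
#' Columns `id,g1,g2`: one measurement of the same quantity (in µm) by two
#' independent graders per row. Input to [grader_agreement()].
#'
#' @param path CSV file path; `#`-prefixed comment lines are ignored.
#' @export
read_paired_csv <- function(path) {
  r <- read_meta_csv(path)
  for (col in c("id", "g1", "g2"))
    if (!(col %in% names(r$data)))
      stop(sprintf("'%s': missing required column '%s'", path, col),
           call. = FALSE)
  df <- data.frame(id = as.character(r$data$id),
                   g1 = as.numeric(r$data$g1),
                   g2 = as.numeric(r$data$g2))
  if (any(!is.finite(df$g1)) || any(!is.finite(df$g2)))
    stop(sprintf("'%s': non-finite measurement values", path), call. = FALSE)
  df
}

#' Bundled inter-grader DFC dataset
#'
#' Distance-from-foveal-center measurements (µm) of nine eyes, each graded
#' independently by two graders on the same registered images; the worked
#' example for [grader_agreement()].
#'
#' @return A data frame with columns `id`, `g1`, `g2`.
#' @export
dfc_grader_pairs <- function() {
  read_paired_csv(system.file("extdata", "dfc_grader_pairs.csv",
                              package = "fixtrack", mustWork = TRUE))
}

# ---------------------------------------------------------------------------
# Result records

#' Assemble a result record for one eye/visit
#'
#' Bundles the computed [eye_metrics()] with provenance (calibration,
#' transform parameters, input digests, software version) for JSON
#' serialization. Units are recorded explicitly. Records containing
#' non-finite numbers are refused.
#'
#' @param metrics An `eye_metrics` object.
#' @param ruler The [scale_ruler()] used.
#' @param transforms Optional named list of `planar_transform`s used.
#' @param inputs Optional named character vector/list of input file paths;
#'   stored with their md5 digests.
#' @return An object of class `result_record`.
#' @export
result_record <- function(metrics, ruler, transforms = NULL, inputs = NULL) {
  stopifnot(inherits(metrics, "eye_metrics"), inherits(ruler, "scale_ruler"))
  num <- unlist(metrics[c("dfc", "dprl", "bcea", "p1", "p2")])
  if (any(!is.finite(num)))
    stop("result_record: metrics contain non-finite values; refusing to serialize",
         call. = FALSE)
  tf <- NULL
  if (!is.null(transforms)) {
    stopifnot(all(vapply(transforms, inherits, logical(1),
                         "planar_transform")))
    tf <- lapply(transforms, function(x) list(
      kind = x$kind,
      coefficients = as.vector(t(x$A)),
      src_frame = x$src_frame, dst_frame = x$dst_frame,
      rms_residual = x$rms_residual, n_landmarks = x$n_landmarks))
  }
  digests <- NULL
  if (!is.null(inputs)) {
    inputs <- as.list(inputs)
    digests <- lapply(inputs, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
    names(digests) <- names(inputs)
  }
  structure(list(
    metrics = list(
      dfc = metrics$dfc, dprl = metrics$dprl,
      quadrant = metrics$quadrant, bcea = metrics$bcea,
      bcea_coverage = metrics$bcea_coverage,
      p1 = metrics$p1, p2 = metrics$p2,
      stability = metrics$stability, valid_exam = metrics$valid_exam,
      units = list(dfc = "um", dprl = "um", bcea = "deg2",
                   p1 = "percent", p2 = "percent")),
    eye = metrics$eye,
    subject_id = metrics$subject_id,
    visit = metrics$visit,
    foveal_center = list(x = metrics$fc[1], y = metrics$fc[2],
                         units = "px"),
    prl_final = list(x = metrics$prl_final[1], y = metrics$prl_final[2],
                     units = "px"),
    calibration = list(microns_per_pixel = ruler$microns_per_pixel,
                       source_bar_microns = ruler$source_bar_microns,
                       source_bar_pixels = ruler$source_bar_pixels),
    transforms = tf,
    inputs = digests,
    software = list(package = "fixtrack",
                    version = as.character(utils::packageVersion("fixtrack")))),
    class = "result_record")
}

#' Write a result record to JSON
#'
#' Full-precision UTF-8 JSON; read-back with [read_result_json()]
#' reproduces integers and strings exactly and reals to better than 1e-9
#' relative.
#'
#' @param record A [result_record()].
#' @param path Output file path.
#' @export
write_result_json <- function(record, path) {
  stopifnot(inherits(record, "result_record"))
  num <- unlist(record$metrics[c("dfc", "dprl", "bcea", "p1", "p2")])
  if (any(!is.finite(num)))
    stop("write_result_json: non-finite metric values; refusing to write",
         call. = FALSE)
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result record from JSON
#' @param path File written by [write_result_json()].
#' @export
read_result_json <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  structure(rec, class = "result_record")
}

#' @export
print.result_record <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Result record: subject %s, %s, visit %s\n",
              x$subject_id, x$eye, x$visit))
  cat(sprintf("  DFC %.4g um, DPRL %.4g um, quadrant %s\n",
              m$dfc, m$dprl, m$quadrant))
  cat(sprintf("  BCEA(%.2g) %.4g deg^2, P1 %.3g%%, P2 %.3g%%, %s, exam %s\n",
              m$bcea_coverage, m$bcea, m$p1, m$p2, m$stability,
              if (isTRUE(m$valid_exam)) "valid" else "invalid"))
  invisible(x)
}
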