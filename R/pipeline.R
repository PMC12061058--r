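# One-shot pipeline chaining registration -> foveal center -> calibration
# -> fixation metrics, from a declarative configuration.

read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

stage <- function(name, hint, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s\n  hint: %s",
                 name, conditionMessage(e), hint), call. = FALSE)
  })
}

cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run the full fixation-shift pipeline
#'
#' Chains the measurement steps for one eye/visit: estimate the
#' registration transforms from landmark files, register the transfoveal
#' scan lines and intersect them to locate the foveal center, build the
#' pixel-to-micron ruler from the scale bar, map the fixation exam into
#' the common frame and compute all fixation metrics. Optionally writes
#' the result record (JSON) and an overlay figure (FC cross, PRLf mark
#' and the DFC segment drawn on the common-frame image).
#'
#' @param config Named list, or path to a JSON/YAML file, with keys:
#'   \describe{
#'     \item{fixation}{path to the fixation CSV (required)}
#'     \item{landmarks_oct_h, landmarks_oct_v, landmarks_maia}{paths to
#'       landmark CSVs, each modality frame -> common frame (required)}
#'     \item{scanline_h, scanline_v}{paths to scan-line CSVs (required)}
#'     \item{bar_px, bar_um}{scale-bar length in pixels and microns
#'       (required; `bar_um` defaults to 200)}
#'     \item{target_x, target_y}{fixation-target position in MAIA-frame
#'       pixels; defaults to the foveal center mapped back into the MAIA
#'       frame}
#'     \item{microns_per_degree}{default 288}
#'     \item{bcea_coverage}{default 0.95}
#'     \item{max_rms}{registration quality ceiling in px, default 2}
#'     \item{transform_kind}{`"similarity"` (default) or `"affine"`}
#'     \item{out}{optional output path for the result JSON}
#'     \item{overlay}{optional output path for the overlay PNG}
#'     \item{image}{optional path to the common-frame image (used for the
#'       overlay and the out-of-frame check)}
#'   }
#' @return A [result_record()], invisibly also written to `config$out`
#'   when given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config))
  for (key in c("fixation", "landmarks_oct_h", "landmarks_oct_v",
                "landmarks_maia", "scanline_h", "scanline_v", "bar_px"))
    if (is.null(config[[key]]))
      stop(sprintf("run_pipeline: config key '%s' is required", key),
           call. = FALSE)

  kind <- cfg_get(config, "transform_kind", "similarity")
  max_rms <- cfg_get(config, "max_rms", 2)

  tf <- stage("register", "check the landmark CSV paths and contents", {
    tfs <- lapply(c(oct_h = "landmarks_oct_h", oct_v = "landmarks_oct_v",
                    maia = "landmarks_maia"), function(key) {
      p <- config[[key]]
      if (!file.exists(p))
        stop(sprintf("landmark file not found: '%s'", p), call. = FALSE)
      estimate_transform(read_landmark_csv(p), kind = kind)
    })
    for (nm in names(tfs))
      if (overlay_quality(tfs[[nm]], max_rms) == "fail")
        stop(sprintf(
          "registration '%s' rms residual %.3g px exceeds max_rms %.3g px",
          nm, tfs[[nm]]$rms_residual, max_rms), call. = FALSE)
    tfs
  })

  img <- NULL
  image_size <- NULL
  if (!is.null(config$image) && file.exists(config$image)) {
    img <- png::readPNG(config$image)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    image_size <- c(ncol(img), nrow(img))
  }

  fc <- stage("fc", "check the scan-line annotations and transforms", {
    sl_h <- read_scanline_csv(config$scanline_h)[[1]]
    sl_v <- read_scanline_csv(config$scanline_v)[[1]]
    intersect_scanlines(sl_h, sl_v, tf$oct_h, tf$oct_v,
                        image_size = image_size)
  })

  ruler <- stage("calibrate", "check bar_px/bar_um",
                 scale_ruler(config$bar_px, cfg_get(config, "bar_um", 200)))

  deg_scale <- degree_scale(cfg_get(config, "microns_per_degree", 288))

  rec <- stage("metrics", "check the fixation CSV and target position", {
    exam <- read_fixation_csv(config$fixation)
    target <- if (!is.null(config$target_x) && !is.null(config$target_y))
      c(config$target_x, config$target_y) else NULL
    m <- eye_metrics(exam, fc, ruler, target = target,
                     transform = tf$maia, deg_scale = deg_scale,
                     coverage = cfg_get(config, "bcea_coverage", 0.95))
    result_record(m, ruler, transforms = tf,
                  inputs = list(fixation = config$fixation))
  })

  if (!is.null(config$overlay) && !is.null(img))
    write_overlay_png(img, fc, rec, config$overlay)
  if (!is.null(config$out))
    write_result_json(rec, config$out)
  rec
}

# Overlay figure on the common-frame image: FC cross, PRLf mark, and the
# straight DFC segment between them.
write_overlay_png <- function(img, fc, record, path) {
  h <- nrow(img); w <- ncol(img)
  grDevices::png(path, width = w, height = h)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot(NA, xlim = c(0, w - 1), ylim = c(h - 1, 0),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(img, 0, h - 1, w - 1, 0)
  p_fc <- fc$position
  p_prl <- c(record$prl_final$x, record$prl_final$y)
  graphics::segments(p_fc[1], p_fc[2], p_prl[1], p_prl[2],
                     col = "white", lwd = 2)
  graphics::points(p_fc[1], p_fc[2], pch = 3, col = "green", cex = 2,
                   lwd = 2)
  graphics::points(p_prl[1], p_prl[2], pch = 4, col = "cyan", cex = 2,
                   lwd = 2)
  invisible(path)
}
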