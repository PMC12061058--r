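#' Pixel-to-micron ruler from an image scale bar
#'
#' Retinal image exports carry a scale bar of known physical length
#' (typically 200 µm). Measuring its length in pixels yields a per-eye
#' "custom ruler" that converts pixel distances on the final common frame
#' into microns.
#'
#' @param bar_pixels Length of the scale bar in pixels (> 0).
#' @param bar_microns Physical length of the scale bar in microns
#'   (default 200).
#' @return An object of class `scale_ruler` with fields
#'   `microns_per_pixel`, `source_bar_microns`, `source_bar_pixels`.
#' @examples
#' r <- scale_ruler(23, 200)
#' px_to_um(23, r)   # 200
#' px_to_um(115, r)  # 1000
#' @export
scale_ruler <- function(bar_pixels, bar_microns = 200) {
  if (!is.numeric(bar_pixels) || length(bar_pixels) != 1L ||
      !is.finite(bar_pixels) || bar_pixels <= 0)
    stop("scale_ruler: 'bar_pixels' must be a single finite positive number",
         call. = FALSE)
  if (!is.numeric(bar_microns) || length(bar_microns) != 1L ||
      !is.finite(bar_microns) || bar_microns <= 0)
    stop("scale_ruler: 'bar_microns' must be a single finite positive number",
         call. = FALSE)
  structure(
    list(microns_per_pixel = bar_microns / bar_pixels,
         source_bar_microns = bar_microns,
         source_bar_pixels = bar_pixels),
    class = "scale_ruler")
}

#' @export
print.scale_ruler <- function(x, ...) {
  cat(sprintf("Scale ruler: %.6g um/px (%g px scale bar = %g um)\n",
              x$microns_per_pixel, x$source_bar_pixels,
              x$source_bar_microns))
  invisible(x)
}

#' Convert a pixel distance to microns
#'
#' @param d Distance(s) in pixels, nonnegative.
#' @param ruler A [scale_ruler()].
#' @return Distance(s) in microns.
#' @export
px_to_um <- function(d, ruler) {
  stopifnot(inherits(ruler, "scale_ruler"))
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("px_to_um: 'd' must be finite numeric", call. = FALSE)
  if (any(d < 0))
    stop("px_to_um: negative pixel distance", call. = FALSE)
  d * ruler$microns_per_pixel
}

#' Convert a micron distance to pixels
#'
#' Inverse of [px_to_um()].
#' @inheritParams px_to_um
#' @export
um_to_px <- function(d, ruler) {
  stopifnot(inherits(ruler, "scale_ruler"))
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("um_to_px: 'd' must be finite numeric", call. = FALSE)
  if (any(d < 0))
    stop("um_to_px: negative distance", call. = FALSE)
  d / ruler$microns_per_pixel
}

#' Visual-degree to micron scale
#'
#' Fixation samples are recorded in visual degrees; distances on the retina
#' are reported in microns. The default 288 µm/degree is the emmetropic
#' schematic-eye approximation; it is configurable because the true factor
#' varies with axial length.
#'
#' @param microns_per_degree Conversion factor in µm per degree (> 0,
#'   default 288).
#' @return An object of class `degree_scale`.
#' @export
degree_scale <- function(microns_per_degree = 288) {
  if (!is.numeric(microns_per_degree) || length(microns_per_degree) != 1L ||
      !is.finite(microns_per_degree) || microns_per_degree <= 0)
    stop("degree_scale: 'microns_per_degree' must be a single finite positive number",
         call. = FALSE)
  structure(list(microns_per_degree = microns_per_degree),
            class = "degree_scale")
}

#' @export
print.degree_scale <- function(x, ...) {
  cat(sprintf("Degree scale: %g um/degree\n", x$microns_per_degree))
  invisible(x)
}

#' Convert degrees of visual angle to microns
#'
#' @param d Distance(s) in degrees, nonnegative.
#' @param scale A [degree_scale()].
#' @export
deg_to_um <- function(d, scale = degree_scale()) {
  stopifnot(inherits(scale, "degree_scale"))
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("deg_to_um: 'd' must be finite numeric", call. = FALSE)
  if (any(d < 0))
    stop("deg_to_um: negative distance", call. = FALSE)
  d * scale$microns_per_degree
}

#' Convert microns to degrees of visual angle
#'
#' Inverse of [deg_to_um()].
#' @inheritParams deg_to_um
#' @export
um_to_deg <- function(d, scale = degree_scale()) {
  stopifnot(inherits(scale, "degree_scale"))
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("um_to_deg: 'd' must be finite numeric", call. = FALSE)
  if (any(d < 0))
    stop("um_to_deg: negative distance", call. = FALSE)
  d / scale$microns_per_degree
}
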