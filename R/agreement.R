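# Inter-grader repeatability: per-grader summaries, Pearson correlation,
# and Bland-Altman bias with 95% limits of agreement.

#' Pearson product-moment correlation with validation
#'
#' @param x,y Numeric vectors of equal length `>= 3` with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("pearson_r: 'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop(sprintf("pearson_r: at least 3 observations required, got %d",
                 length(x)), call. = FALSE)
  if (any(!is.finite(c(x, y))))
    stop("pearson_r: non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r: correlation undefined for zero-variance input",
         call. = FALSE)
  stats::cor(x, y)
}

#' Inter-grader agreement summary (Pearson + Bland-Altman)
#'
#' For paired measurements of the same quantity by two graders: per-grader
#' mean, sample SD (n-1 denominator) and range; Pearson correlation; and
#' Bland-Altman bias (mean of grader2 - grader1 differences), SD of the
#' differences, and 95% limits of agreement at bias +/- 1.96 SD.
#'
#' @param pairs Data frame with columns `g1`, `g2` (and optionally `id`),
#'   e.g. from [read_paired_csv()] or [dfc_grader_pairs()]; at least 3
#'   rows.
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96, the
#'   conventional 95% limits).
#' @return An object of class `grader_agreement` with fields `n`,
#'   `mean_g1`, `sd_g1`, `range_g1`, `mean_g2`, `sd_g2`, `range_g2`,
#'   `pearson_r`, `bias`, `sd_diff`, `loa_low`, `loa_high`, and the input
#'   `data`.
#' @examples
#' summary_stats <- grader_agreement(dfc_grader_pairs())
#' summary_stats
#' @export
grader_agreement <- function(pairs, loa_multiplier = 1.96) {
  stopifnot(is.data.frame(pairs), all(c("g1", "g2") %in% names(pairs)))
  g1 <- as.numeric(pairs$g1); g2 <- as.numeric(pairs$g2)
  if (length(g1) < 3L)
    stop(sprintf("grader_agreement: at least 3 pairs required, got %d",
                 length(g1)), call. = FALSE)
  if (any(!is.finite(c(g1, g2))))
    stop("grader_agreement: non-finite measurements", call. = FALSE)
  d <- g2 - g1
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    n = length(g1),
    mean_g1 = mean(g1), sd_g1 = stats::sd(g1), range_g1 = range(g1),
    mean_g2 = mean(g2), sd_g2 = stats::sd(g2), range_g2 = range(g2),
    pearson_r = pearson_r(g1, g2),
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - loa_multiplier * sd_diff,
    loa_high = bias + loa_multiplier * sd_diff,
    loa_multiplier = loa_multiplier,
    data = data.frame(g1 = g1, g2 = g2)),
    class = "grader_agreement")
}

#' @export
print.grader_agreement <- function(x, ...) {
  cat(sprintf("Inter-grader agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  grader 1: mean %.4g um (range %.4g-%.4g, SD %.4g)\n",
              x$mean_g1, x$range_g1[1], x$range_g1[2], x$sd_g1))
  cat(sprintf("  grader 2: mean %.4g um (range %.4g-%.4g, SD %.4g)\n",
              x$mean_g2, x$range_g2[1], x$range_g2[2], x$sd_g2))
  cat(sprintf("  Pearson r = %.4g\n", x$pearson_r))
  cat(sprintf("  Bland-Altman: bias %.4g um (SD %.4g), %g%% LoA [%.4g, %.4g]\n",
              x$bias, x$sd_diff,
              round(100 * (2 * stats::pnorm(x$loa_multiplier) - 1)),
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot of grader agreement
#'
#' Differences (grader 2 - grader 1) against pair means, with the bias and
#' limits-of-agreement lines dashed.
#'
#' @param x A [grader_agreement()] result.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.grader_agreement <- function(x, ...) {
  m <- (x$data$g1 + x$data$g2) / 2
  d <- x$data$g2 - x$data$g1
  graphics::plot(m, d, pch = 19,
                 xlab = "Mean of graders (µm)",
                 ylab = "Difference, grader 2 - grader 1 (µm)",
                 ylim = range(c(d, x$loa_low, x$loa_high)), ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}
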