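# Landmark-based planar registration between en-face retinal image frames.
#
# Coordinates follow the raster convention: 0-based pixel indices, origin
# top-left, x rightward, y downward; sub-pixel positions are real-valued.
# A positive rotation angle therefore turns x towards +y (clockwise on the
# displayed image).

new_planar_transform <- function(kind, A, src_frame = NULL, dst_frame = NULL,
                                 rms_residual = 0, n_landmarks = NA_integer_) {
  stopifnot(kind %in% c("similarity", "affine"),
            is.matrix(A), nrow(A) == 2L, ncol(A) == 3L,
            all(is.finite(A)), is.finite(rms_residual), rms_residual >= 0)
  L <- A[, 1:2]
  if (abs(det(L)) <= 1e-9)
    stop("planar_transform: linear part is singular (|det| <= 1e-9)",
         call. = FALSE)
  out <- list(kind = kind, A = A,
              src_frame = src_frame, dst_frame = dst_frame,
              rms_residual = rms_residual, n_landmarks = n_landmarks)
  if (kind == "similarity") {
    # A similarity's linear part is s * R(theta); recover the parameters.
    a <- A[1, 1]; b <- A[2, 1]
    if (abs(A[1, 2] + b) > 1e-6 * max(1, abs(b)) + 1e-9 ||
        abs(A[2, 2] - a) > 1e-6 * max(1, abs(a)) + 1e-9)
      stop("planar_transform: matrix is not a similarity", call. = FALSE)
    s <- sqrt(a^2 + b^2)
    if (s <= 0) stop("planar_transform: similarity scale must be > 0",
                     call. = FALSE)
    out$scale <- s
    out$rotation <- atan2(b, a)
    out$translation <- A[, 3]
  }
  structure(out, class = "planar_transform")
}

#' Construct a similarity transform from its parameters
#'
#' @param scale Isotropic scale factor (> 0).
#' @param rotation Rotation angle in radians; positive turns +x towards +y
#'   (clockwise on a y-down raster).
#' @param translation Length-2 numeric, pixel translation.
#' @param src_frame,dst_frame Optional frame names used to check chaining.
#' @return A `planar_transform` of kind `"similarity"`.
#' @examples
#' Tr <- similarity_transform(rotation = pi / 2)
#' apply_transform(Tr, c(1, 0))  # (0, 1)
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0),
                                 src_frame = NULL, dst_frame = NULL) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            scale > 0, is.numeric(rotation), length(rotation) == 1L,
            is.finite(rotation), is.numeric(translation),
            length(translation) == 2L, all(is.finite(translation)))
  a <- scale * cos(rotation); b <- scale * sin(rotation)
  A <- matrix(c(a, b, -b, a, translation[1], translation[2]), 2, 3)
  new_planar_transform("similarity", A, src_frame, dst_frame)
}

#' Identity transform
#'
#' @param frame Optional frame name applied to both src and dst.
#' @export
identity_transform <- function(frame = NULL) {
  similarity_transform(src_frame = frame, dst_frame = frame)
}

#' Construct an affine transform from a 2x3 coefficient matrix
#'
#' @param A 2x3 numeric matrix `[L | t]` mapping `(x, y)` to
#'   `L %*% c(x, y) + t`.
#' @inheritParams similarity_transform
#' @export
affine_transform <- function(A, src_frame = NULL, dst_frame = NULL) {
  new_planar_transform("affine", A, src_frame, dst_frame)
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("Planar transform (%s)", x$kind))
  if (!is.null(x$src_frame) || !is.null(x$dst_frame))
    cat(sprintf(": %s -> %s",
                if (is.null(x$src_frame)) "?" else x$src_frame,
                if (is.null(x$dst_frame)) "?" else x$dst_frame))
  cat("\n")
  if (x$kind == "similarity")
    cat(sprintf("  scale %.6g, rotation %.4g deg, translation (%.4g, %.4g)\n",
                x$scale, x$rotation * 180 / pi,
                x$translation[1], x$translation[2]))
  else
    cat(sprintf("  [%.5g %.5g %.5g; %.5g %.5g %.5g]\n",
                x$A[1, 1], x$A[1, 2], x$A[1, 3],
                x$A[2, 1], x$A[2, 2], x$A[2, 3]))
  if (!is.na(x$n_landmarks))
    cat(sprintf("  fitted on %d landmarks, rms residual %.4g px\n",
                x$n_landmarks, x$rms_residual))
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, 1:2])
  if (is.null(dim(p))) {
    stopifnot(length(p) == 2L)
    p <- matrix(p, 1L, 2L)
  }
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 2L, all(is.finite(p)))
  p
}

#' Apply a planar transform to points
#'
#' @param transform A `planar_transform`.
#' @param points Length-2 numeric vector or an n x 2 matrix/data frame of
#'   `(x, y)` pixel coordinates.
#' @return Mapped coordinates in the same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "planar_transform"))
  vec <- is.null(dim(points)) && !is.data.frame(points)
  p <- as_point_matrix(points)
  out <- p %*% t(transform$A[, 1:2]) +
    matrix(transform$A[, 3], nrow(p), 2, byrow = TRUE)
  if (vec) c(out) else out
}

transform_matrix3 <- function(transform) {
  rbind(transform$A, c(0, 0, 1))
}

#' Compose two planar transforms
#'
#' `compose_transform(A, B)` is the map "apply `A`, then `B`", so that
#' `apply_transform(compose_transform(A, B), p)` equals
#' `apply_transform(B, apply_transform(A, p))`. If both transforms carry
#' frame names, `A$dst_frame` must equal `B$src_frame`.
#'
#' @param A,B `planar_transform` objects.
#' @return A `planar_transform`; kind is `"affine"` if either input is
#'   affine, otherwise `"similarity"`.
#' @export
compose_transform <- function(A, B) {
  stopifnot(inherits(A, "planar_transform"), inherits(B, "planar_transform"))
  if (!is.null(A$dst_frame) && !is.null(B$src_frame) &&
      !identical(A$dst_frame, B$src_frame))
    stop(sprintf(
      "compose_transform: frame mismatch: first transform ends in '%s' but second starts in '%s'",
      A$dst_frame, B$src_frame), call. = FALSE)
  M <- transform_matrix3(B) %*% transform_matrix3(A)
  kind <- if (A$kind == "affine" || B$kind == "affine") "affine" else "similarity"
  new_planar_transform(kind, M[1:2, , drop = FALSE],
                       src_frame = A$src_frame, dst_frame = B$dst_frame)
}

#' Invert a planar transform
#'
#' @param transform A `planar_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "planar_transform"))
  M <- solve(transform_matrix3(transform))
  new_planar_transform(transform$kind, M[1:2, , drop = FALSE],
                       src_frame = transform$dst_frame,
                       dst_frame = transform$src_frame)
}

#' Estimate a planar transform from landmark correspondences
#'
#' Least-squares estimation of the similarity (scale, rotation, translation;
#' 4 degrees of freedom) or affine (6 d.o.f.) map taking source landmarks to
#' destination landmarks. The similarity fit is the closed-form
#' orthogonal-Procrustes-with-scale solution, obtained by linear least
#' squares on the parametrization `(a, b, tx, ty)` with linear part
#' `[a -b; b a]`; it is exact (zero residual) on noise-free data and
#' deterministic.
#'
#' This computational step replaces the manual overlay of vessel and optic
#' nerve landmarks between image modalities.
#'
#' @param pairs A [landmark_pairs()] table (columns `x_src`, `y_src`,
#'   `x_dst`, `y_dst`), or any data frame with those columns.
#' @param kind `"similarity"` (default) or `"affine"`.
#' @return A `planar_transform` with `rms_residual` (root-mean-square
#'   post-fit landmark misfit in pixels) and `n_landmarks` filled in.
#' @examples
#' src <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
#' Tr0 <- similarity_transform(1.15, 7 * pi / 180, c(12, -5))
#' dst <- apply_transform(Tr0, src)
#' lp <- landmark_pairs(src, dst)
#' estimate_transform(lp)
#' @export
estimate_transform <- function(pairs, kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  req <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(req %in% names(pairs)))
    stop("estimate_transform: 'pairs' must have columns x_src, y_src, x_dst, y_dst",
         call. = FALSE)
  n <- nrow(pairs)
  need <- if (kind == "similarity") 2L else 3L
  if (n < need)
    stop(sprintf("estimate_transform: %s needs at least %d landmark pairs, got %d",
                 kind, need, n), call. = FALSE)
  xs <- as.numeric(pairs$x_src); ys <- as.numeric(pairs$y_src)
  xd <- as.numeric(pairs$x_dst); yd <- as.numeric(pairs$y_dst)
  if (any(!is.finite(c(xs, ys, xd, yd))))
    stop("estimate_transform: non-finite landmark coordinates", call. = FALSE)
  spread <- max(xs) - min(xs) + max(ys) - min(ys)
  if (spread <= .Machine$double.eps * max(1, abs(c(xs, ys))))
    stop("estimate_transform: source landmarks have zero spread (degenerate)",
         call. = FALSE)

  if (kind == "similarity") {
    # dst_x = a*x - b*y + tx ; dst_y = b*x + a*y + ty
    X <- rbind(cbind(xs, -ys, 1, 0), cbind(ys, xs, 0, 1))
    yv <- c(xd, yd)
    beta <- qr.coef(qr(X), yv)
    A <- matrix(c(beta[1], beta[2], -beta[2], beta[1], beta[3], beta[4]),
                2, 3)
    if (sqrt(beta[1]^2 + beta[2]^2) <= 1e-9)
      stop("estimate_transform: degenerate similarity fit (zero scale)",
           call. = FALSE)
  } else {
    D <- cbind(1, xs, ys)
    if (qr(D)$rank < 3L)
      stop("estimate_transform: source landmarks are collinear; affine fit is degenerate",
           call. = FALSE)
    cx <- qr.coef(qr(D), xd)
    cy <- qr.coef(qr(D), yd)
    A <- matrix(c(cx[2], cy[2], cx[3], cy[3], cx[1], cy[1]), 2, 3)
  }
  pred <- cbind(xs, ys) %*% t(A[, 1:2]) + matrix(A[, 3], n, 2, byrow = TRUE)
  rms <- sqrt(mean((pred[, 1] - xd)^2 + (pred[, 2] - yd)^2))
  new_planar_transform(kind, A,
                       src_frame = attr(pairs, "src_frame"),
                       dst_frame = attr(pairs, "dst_frame"),
                       rms_residual = rms, n_landmarks = n)
}

#' Check registration quality against an RMS residual ceiling
#'
#' Guards against poorly picked landmark correspondences before any
#' distance is measured on the registered frames.
#'
#' @param transform A fitted `planar_transform`.
#' @param max_rms Maximum acceptable RMS landmark misfit in pixels
#'   (default 2; the bound is inclusive).
#' @return `"pass"` or `"fail"`.
#' @export
overlay_quality <- function(transform, max_rms = 2) {
  stopifnot(inherits(transform, "planar_transform"),
            is.numeric(max_rms), length(max_rms) == 1L, max_rms >= 0)
  if (transform$rms_residual <= max_rms) "pass" else "fail"
}
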