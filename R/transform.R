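#' Rigid transform objects
#'
#' A rigid transform is a proper rotation (3 x 3 orthonormal matrix with
#' determinant +1) followed by a translation (mm). Applied to a point `p` it
#' gives `R p + t`.
#'
#' @param rotation 3 x 3 rotation matrix (dimensionless).
#' @param translation Length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 0, 0))
#' transform_apply(t1, tibble::tibble(x = 0, y = 0, z = 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.double(translation)
  if (!all(dim(rotation) == c(3, 3))) abort("rotation must be a 3 x 3 matrix")
  if (length(translation) != 3) abort("translation must have length 3")
  if (anyNA(rotation) || anyNA(translation)) abort("transform must be finite")
  ortho_err <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho_err > 1e-6) abort("rotation matrix is not orthonormal")
  if (det(rotation) < 0) abort("rotation matrix is a reflection (det < 0)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation %.3f mm\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform()

#' Compose, invert and interrogate rigid transforms
#'
#' `transform_compose(a, b)` returns the transform applying `b` first, then
#' `a` (so `transform_apply(transform_compose(a, b), p)` equals
#' `transform_apply(a, transform_apply(b, p))`). `transform_invert` returns
#' the inverse motion; `rotation_angle_deg` the rotation angle in degrees.
#'
#' @param a,b,t `rigid_transform` objects.
#' @return A `rigid_transform`, or a scalar angle for `rotation_angle_deg`.
#' @export
transform_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @rdname transform_compose
#' @export
transform_invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rt <- t(t$rotation)
  rigid_transform(rt, -as.vector(rt %*% t$translation))
}

#' @rdname transform_compose
#' @export
rotation_angle_deg <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  tr <- sum(diag(t$rotation))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Apply a rigid transform to a point table
#'
#' Each point becomes `R p + t`; row order and the optional `label` and
#' `uple` columns are carried through unchanged.
#'
#' @param t A `rigid_transform`.
#' @param points Data frame with `x`, `y`, `z` (mm) and optional `label`,
#'   `uple` columns.
#' @return A tibble with the transformed coordinates.
#' @export
transform_apply <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- as_point_matrix(points)
  moved <- m %*% t(t$rotation)
  moved <- sweep(moved, 2, t$translation, "+")
  rebuild_points(points, moved)
}

# Matrix-in, matrix-out fast path used by the registration inner loops.
transform_apply_mat <- function(t, m) {
  sweep(m %*% t(t$rotation), 2, t$translation, "+")
}

#' Axis-angle rotation about an arbitrary line
#'
#' Builds the rigid transform rotating by `angle_deg` about the line through
#' `center` with direction `axis`, optionally followed by a translation of
#' `shift_mm` along the (unit-normalized) axis. This is the elementary motion
#' of the axis-constrained perturbation grid.
#'
#' @param axis Length-3 direction vector (need not be unit length).
#' @param center Point on the rotation axis (mm).
#' @param angle_deg Rotation angle in degrees.
#' @param shift_mm Translation along the axis (mm).
#' @return A `rigid_transform`.
#' @export
axis_transform <- function(axis, center = c(0, 0, 0), angle_deg = 0,
                           shift_mm = 0) {
  axis <- as.double(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) abort("axis must be non-zero")
  u <- axis / n
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  center <- as.double(center)
  # rotate about the line through `center`, then slide along the axis
  trans <- center - as.vector(R %*% center) + shift_mm * u
  rigid_transform(R, trans)
}

#' Closed-form rigid point-to-point registration
#'
#' Finds the proper rigid motion minimizing the mean squared correspondence
#' residual `1/n * sum_i || target_i - (R source_i + t) ||^2` by the standard
#' SVD (Kabsch) construction, which attains the global minimum of that
#' objective. A reflection in the SVD solution is corrected by flipping the
#' sign of the smallest singular vector, so the result is always a proper
#' rotation.
#'
#' @param source,target Data frames of corresponding points (equal row
#'   counts, n >= 3, not all collinear).
#' @return A `rigid_transform` with attribute `objective`, the mean squared
#'   residual (mm^2) at the optimum.
#' @examples
#' src <- tibble::tibble(x = rnorm(6), y = rnorm(6), z = rnorm(6))
#' tgt <- transform_apply(axis_transform(c(0, 0, 1), angle_deg = 30), src)
#' fit <- fit_rigid(src, tgt)
#' attr(fit, "objective")  # ~0
#' @export
fit_rigid <- function(source, target) {
  s <- as_point_matrix(source)
  x <- as_point_matrix(target)
  if (nrow(s) != nrow(x)) {
    abort("source and target must have the same number of corresponding points")
  }
  n <- nrow(s)
  if (n < 3) abort("at least 3 point correspondences are required")
  cs <- colMeans(s)
  cx <- colMeans(x)
  sc <- sweep(s, 2, cs)
  xc <- sweep(x, 2, cx)
  H <- crossprod(sc, xc)  # 3x3 cross-covariance
  sv <- svd(H)
  # collinear sources leave the objective rotationally degenerate
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    abort("degenerate (collinear or coincident) point configuration")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cx - as.vector(R %*% cs)
  fit <- rigid_transform(R, t)
  resid <- x - transform_apply_mat(fit, s)
  attr(fit, "objective") <- mean(rowSums(resid^2))
  fit
}

#' Draw a random rigid displacement
#'
#' Rotation axis and translation direction are uniform on the unit sphere;
#' the rotation angle is uniform on `[0, max_rotation_deg]` and the
#' translation norm uniform on `[0, max_translation_mm]`. Used to displace
#' ground-truth sample points to an arbitrary new location before
#' registration. Deterministic given the R RNG state.
#'
#' @param max_rotation_deg Upper bound on the rotation angle (degrees, >= 0).
#' @param max_translation_mm Upper bound on the translation norm (mm, >= 0).
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_rotation_deg = 10,
                                   max_translation_mm = 20) {
  if (max_rotation_deg < 0 || max_translation_mm < 0) {
    abort("displacement bounds must be non-negative")
  }
  axis <- rnorm(3)
  while (sum(axis^2) == 0) axis <- rnorm(3)
  angle <- runif(1, 0, max_rotation_deg)
  dir <- rnorm(3)
  while (sum(dir^2) == 0) dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  mag <- runif(1, 0, max_translation_mm)
  rot <- axis_transform(axis, center = c(0, 0, 0), angle_deg = angle)
  rigid_transform(rot$rotation, mag * dir)
}

#' Serialize rigid transforms to and from JSON
#'
#' The JSON form is `{"rotation": [9 numbers, row-major], "translation":
#' [3 numbers]}`.
#'
#' @param t A `rigid_transform`.
#' @param json A JSON string or file path (for reading).
#' @return `transform_to_json` returns a JSON string; `transform_from_json`
#'   a `rigid_transform`.
#' @export
transform_to_json <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::toJSON(list(rotation = as.vector(t(t$rotation)),
                        translation = t$translation),
                   digits = NA, auto_unbox = FALSE)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation)
}
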