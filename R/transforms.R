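#' Rigid transforms in micron coordinates
#'
#' A rigid transform rotates a point counter-clockwise by `theta` radians
#' about `center` and then translates it by `t`. All coordinates are in
#' microns, so a single transform is valid at every pyramid level of a
#' whole-slide image. The linear part always has determinant +1: no
#' reflection, no scaling.
#'
#' @param theta rotation angle in radians (counter-clockwise).
#' @param t translation vector, length 2, microns.
#' @param center rotation center, length 2, microns.
#' @return an object of class `rigid_transform`.
#' @examples
#' T1 <- rigid_transform(pi / 2, t = c(5, 0))
#' apply_transform(T1, cbind(1, 0))
#' @export
rigid_transform <- function(theta = 0, t = c(0, 0), center = c(0, 0)) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            length(t) == 2L, all(is.finite(t)),
            length(center) == 2L, all(is.finite(center)))
  structure(list(theta = as.numeric(theta), t = as.numeric(t),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: theta = %.6f rad (%.3f deg), t = (%.3f, %.3f) um, center = (%.3f, %.3f) um\n",
              x$theta, x$theta * 180 / pi, x$t[1], x$t[2], x$center[1], x$center[2]))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform(0, c(0, 0), c(0, 0))

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = FALSE)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  storage.mode(points) <- "double"
  points
}

#' Apply a rigid transform to points
#'
#' @param T a [rigid_transform()].
#' @param points n x 2 matrix of (x, y) micron coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(T, points) {
  stopifnot(inherits(T, "rigid_transform"))
  p <- as_points(points)
  R <- rotation_matrix(T$theta)
  out <- sweep(p, 2L, T$center) %*% t(R)
  sweep(out, 2L, T$center + T$t, "+")
}

#' Invert a rigid transform
#'
#' `apply_transform(invert_transform(T), apply_transform(T, p))` recovers `p`
#' exactly (to numerical precision).
#' @param T a [rigid_transform()].
#' @export
invert_transform <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rinv <- rotation_matrix(-T$theta)
  rigid_transform(-T$theta, t = -as.numeric(Rinv %*% T$t), center = T$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `T1` first, then `T2`:
#' `apply(compose(T2, T1), p) == apply(T2, apply(T1, p))`.
#' @param T2,T1 [rigid_transform()] objects; `T1` is applied first.
#' @export
compose_transform <- function(T2, T1) {
  stopifnot(inherits(T2, "rigid_transform"), inherits(T1, "rigid_transform"))
  R2 <- rotation_matrix(T2$theta)
  # T2(T1(p)) = R2 R1 (p - c1) + R2 (c1 + t1 - c2) + c2 + t2
  t_new <- as.numeric(R2 %*% (T1$center + T1$t - T2$center)) + T2$center + T2$t - T1$center
  rigid_transform(T2$theta + T1$theta, t = t_new, center = T1$center)
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' Format: `{"theta_rad": ..., "t_um": [x, y], "center_um": [x, y]}`.
#' @param T a [rigid_transform()].
#' @param path file path.
#' @export
write_transform <- function(T, path) {
  stopifnot(inherits(T, "rigid_transform"))
  jsonlite::write_json(list(theta_rad = T$theta, t_um = T$t, center_um = T$center),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$theta_rad, t = x$t_um, center = x$center_um)
}

# numerically stable squared pairwise distances (difference first, then
# square): avoids the cancellation of the expanded-form computation
dist2 <- function(A, B) {
  outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
}
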