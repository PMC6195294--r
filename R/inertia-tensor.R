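#' Construct an inertia tensor
#'
#' A symmetric second-moment description of a rigid body about a stated point,
#' stored as six components: the three moments of inertia \code{I_xx},
#' \code{I_yy}, \code{I_zz} and the three products of inertia \code{P_xy},
#' \code{P_xz}, \code{P_yz}. Products use the integral convention
#' \eqn{P_{ab} = \int ab\, dm}; the off-diagonal entries of the tensor matrix
#' are \eqn{-P_{ab}}. All components are in kg m^2.
#'
#' For any tensor arising from a physical mass distribution the
#' perpendicular-axis-type inequality \eqn{I_{aa} + I_{bb} \ge I_{cc}} holds
#' for every permutation of axes. The constructor does not enforce it (measured
#' data can violate it; see \code{\link{triangle_check}}), but it does warn on
#' negative diagonal moments.
#'
#' @param ixx,iyy,izz Moments of inertia about the x, y, z axes (kg m^2).
#' @param pxy,pxz,pyz Products of inertia (kg m^2), \eqn{\int ab\, dm} form.
#' @param frame_point Point the tensor is taken about: \code{"com"},
#'   \code{"pivot"} or \code{"box_origin"}.
#' @param axes_label Free-text label for the axis set (e.g. \code{"box"},
#'   \code{"solid"}, \code{"anatomical"}).
#' @return An object of class \code{"inertia_tensor"}.
#' @examples
#' it <- inertia_tensor(1, 2, 3)
#' as.matrix(it)
#' @export
inertia_tensor <- function(ixx, iyy, izz, pxy = 0, pxz = 0, pyz = 0,
                           frame_point = c("com", "pivot", "box_origin"),
                           axes_label = "box") {
  frame_point <- match.arg(frame_point)
  vals <- c(ixx, iyy, izz, pxy, pxz, pyz)
  if (length(vals) != 6L || !all(is.finite(vals)))
    stop("inertia tensor components must be six finite numbers", call. = FALSE)
  if (any(c(ixx, iyy, izz) < 0))
    warning("negative diagonal moment of inertia: not a physical mass distribution",
            call. = FALSE)
  structure(
    list(I = c(xx = ixx, yy = iyy, zz = izz),
         P = c(xy = pxy, xz = pxz, yz = pyz),
         frame_point = frame_point,
         axes_label = axes_label),
    class = "inertia_tensor")
}

#' @export
as.matrix.inertia_tensor <- function(x, ...) {
  m <- matrix(c(x$I[["xx"]], -x$P[["xy"]], -x$P[["xz"]],
                -x$P[["xy"]], x$I[["yy"]], -x$P[["yz"]],
                -x$P[["xz"]], -x$P[["yz"]], x$I[["zz"]]), 3, 3)
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  m
}

#' Build an inertia_tensor from a symmetric 3x3 matrix
#'
#' Inverse of \code{\link{as.matrix.inertia_tensor}}: reads the diagonal as
#' moments and the negated off-diagonals as products.
#'
#' @param m Symmetric 3x3 numeric matrix.
#' @param frame_point,axes_label Passed to \code{\link{inertia_tensor}}.
#' @return An \code{inertia_tensor}.
#' @export
tensor_from_matrix <- function(m, frame_point = "com", axes_label = "box") {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  if (max(abs(m - t(m))) > 1e-9 * max(1, max(abs(m))))
    stop("matrix is not symmetric", call. = FALSE)
  inertia_tensor(m[1, 1], m[2, 2], m[3, 3],
                 pxy = -m[1, 2], pxz = -m[1, 3], pyz = -m[2, 3],
                 frame_point = frame_point, axes_label = axes_label)
}

#' @export
print.inertia_tensor <- function(x, digits = 4, ...) {
  cat("Inertia tensor about", x$frame_point,
      sprintf("(axes: %s), kg m^2\n", x$axes_label))
  cat(sprintf("  I_xx %.*g  I_yy %.*g  I_zz %.*g\n",
              digits, x$I[["xx"]], digits, x$I[["yy"]], digits, x$I[["zz"]]))
  cat(sprintf("  P_xy %.*g  P_xz %.*g  P_yz %.*g\n",
              digits, x$P[["xy"]], digits, x$P[["xz"]], digits, x$P[["yz"]]))
  invisible(x)
}

#' Parallel-axis transform of an inertia tensor
#'
#' Shifts a tensor between the centre of mass and a displaced point. With
#' displacement vector \code{d} (from the CoM to the new point, or vice versa;
#' the transform is even in \code{d}):
#' \deqn{I'_{aa} = I_{aa} + m(|d|^2 - d_a^2), \quad P'_{ab} = P_{ab} + m d_a d_b.}
#' \code{direction = "to_com"} applies the inverse (subtracts the same terms),
#' so a round trip recovers the input exactly.
#'
#' @param tensor An \code{inertia_tensor}. Must be about the CoM for
#'   \code{"from_com"}, and about a displaced point for \code{"to_com"}.
#' @param mass Body mass (kg).
#' @param d Displacement 3-vector (m).
#' @param direction \code{"from_com"} (CoM to displaced point) or
#'   \code{"to_com"}.
#' @param frame_point Frame label for the result; defaults to \code{"pivot"}
#'   when shifting away from the CoM.
#' @return An \code{inertia_tensor} about the new point.
#' @examples
#' it <- inertia_tensor(0, 0, 0)
#' parallel_axis(it, mass = 2, d = c(1, 0, 0))  # point mass: I_yy = I_zz = 2
#' @export
parallel_axis <- function(tensor, mass, d,
                          direction = c("from_com", "to_com"),
                          frame_point = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(tensor, "inertia_tensor"), length(d) == 3L,
            is.finite(mass), mass >= 0)
  if (direction == "from_com" && tensor$frame_point != "com")
    stop("parallel_axis from_com requires a tensor about the CoM", call. = FALSE)
  s <- if (direction == "from_com") 1 else -1
  d2 <- sum(d^2)
  I <- tensor$I + s * mass * (d2 - d^2)
  P <- tensor$P + s * mass * c(d[1] * d[2], d[1] * d[3], d[2] * d[3])
  if (is.null(frame_point))
    frame_point <- if (direction == "from_com") "pivot" else "com"
  inertia_tensor(I[[1]], I[[2]], I[[3]], P[[1]], P[[2]], P[[3]],
                 frame_point = frame_point, axes_label = tensor$axes_label)
}

#' Moment of inertia about an arbitrary axis
#'
#' Evaluates the quadratic form \eqn{u^T M u} where \code{M} is the tensor
#' matrix (off-diagonals \eqn{-P_{ab}}) and \code{u} a unit axis direction
#' through the tensor's frame point.
#'
#' @param tensor An \code{inertia_tensor}.
#' @param axis Numeric 3-vector; must have unit length within \code{tol}
#'   unless \code{normalize = TRUE}.
#' @param normalize If \code{TRUE}, non-unit axes are normalized with a
#'   warning instead of raising an error.
#' @param tol Tolerance on \code{|axis| - 1}.
#' @return Moment of inertia about the axis (kg m^2).
#' @examples
#' it <- inertia_tensor(2, 3, 4, pxy = 0.5)
#' moi_about_axis(it, c(1, 1, 0) / sqrt(2))  # 0.5*(2+3) - 0.5 = 2
#' @export
moi_about_axis <- function(tensor, axis, normalize = FALSE, tol = 1e-8) {
  stopifnot(inherits(tensor, "inertia_tensor"), length(axis) == 3L)
  n <- sqrt(sum(axis^2))
  if (abs(n - 1) > tol) {
    if (!normalize)
      stop("axis is not a unit vector (|axis| = ", format(n),
           "); set normalize = TRUE to rescale", call. = FALSE)
    warning("normalizing non-unit axis", call. = FALSE)
    axis <- axis / n
  }
  drop(crossprod(axis, as.matrix(tensor) %*% axis))
}

#' Rotate an inertia tensor
#'
#' Applies \eqn{R M R^T} to the tensor matrix, i.e. expresses the same body in
#' a frame rotated by \code{R} (components of the old axes in the new frame).
#'
#' @param tensor An \code{inertia_tensor}.
#' @param R 3x3 rotation matrix.
#' @return The rotated \code{inertia_tensor}.
#' @export
rotate_tensor <- function(tensor, R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("R is not orthonormal", call. = FALSE)
  m <- R %*% as.matrix(tensor) %*% t(R)
  m <- (m + t(m)) / 2
  tensor_from_matrix(m, frame_point = tensor$frame_point,
                     axes_label = tensor$axes_label)
}

#' Perpendicular-axis-type (triangle) inequality check
#'
#' For a physical mass distribution every pair of diagonal moments bounds the
#' third: \eqn{I_{aa} + I_{bb} \ge I_{cc}}. Measured tensors can violate this
#' (the packaged tail tensor does), so this validator reports rather than
#' raises.
#'
#' @param tensor An \code{inertia_tensor}.
#' @param tol Slack allowed before a margin counts as a violation.
#' @return A list with \code{ok} (logical), \code{margins} (named vector of
#'   \eqn{I_{aa} + I_{bb} - I_{cc}}, negative = violated) and
#'   \code{violations} (names of failing permutations).
#' @export
triangle_check <- function(tensor, tol = 0) {
  stopifnot(inherits(tensor, "inertia_tensor"))
  I <- tensor$I
  margins <- c(
    xx = I[["yy"]] + I[["zz"]] - I[["xx"]],
    yy = I[["xx"]] + I[["zz"]] - I[["yy"]],
    zz = I[["xx"]] + I[["yy"]] - I[["zz"]])
  bad <- names(margins)[margins < -tol]
  list(ok = length(bad) == 0L, margins = margins, violations = bad)
}
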