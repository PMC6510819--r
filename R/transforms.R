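## Rigid-body transforms and landmark registration.

#' Construct a rigid transform
#'
#' A rigid transform is stored as a list with a 3x3 rotation matrix `R`
#' (det = +1) and a length-3 translation `t`, acting as `x -> R x + t`
#' (coordinates in mm).
#'
#' @param R 3x3 rotation matrix (proper orthonormal).
#' @param t length-3 translation vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("R is not orthonormal")
  if (det(R) < 0)
    stop("R is a reflection (det < 0), not a rotation")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rot_to_axis_angle(x$R)
  cat(sprintf("Rigid transform: rotation %.3f deg about (%.3f, %.3f, %.3f), translation (%.3f, %.3f, %.3f) mm\n",
              aa$angle_deg, aa$axis[1], aa$axis[2], aa$axis[3],
              x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf `rigid_transform`.
#' @param pts numeric matrix (n x 3) or length-3 vector.
#' @return Transformed points, same shape as input.
#' @export
transform_points <- function(tf, pts) {
  if (is.null(dim(pts))) return(as.numeric(tf$R %*% pts + tf$t))
  sweep(pts %*% t(tf$R), 2L, tf$t, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return The composite `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Rotation about an arbitrary axis through a point
#'
#' @param axis length-3 direction (need not be unit).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @param point a point on the axis, mm (default origin).
#' @return `rigid_transform`.
#' @export
rotation_about_axis <- function(axis, angle_deg, point = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  # re-orthonormalise against rounding
  s <- svd(R); R <- s$u %*% t(s$v)
  rigid_transform(R, as.numeric(point - R %*% point))
}

#' Axis-angle decomposition of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return list with `angle_deg` in [0, 180] and unit `axis`.
#' @export
rot_to_axis_angle <- function(R) {
  ctheta <- (sum(diag(R)) - 1) / 2
  ctheta <- min(1, max(-1, ctheta))
  th <- acos(ctheta)
  if (th < 1e-12) return(list(angle_deg = 0, axis = c(0, 0, 1)))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(v^2)) < 1e-12) {
    # angle ~ pi: axis from R + I columns
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    v <- M[, j]
  }
  list(angle_deg = th * 180 / pi, axis = v / sqrt(sum(v^2)))
}

#' Least-squares rigid landmark registration
#'
#' Finds the rigid transform (rotation with det = +1 plus translation, no
#' scaling) minimising the RMS distance between corresponding landmark sets,
#' by the SVD (Kabsch) solution of the orthogonal Procrustes problem.
#'
#' @param source n x 3 matrix of source landmarks, mm (n >= 3, non-collinear).
#' @param target n x 3 matrix of corresponding target landmarks, mm.
#' @return list with `transform` (`rigid_transform`) and `rms` residual (mm).
#' @export
landmark_transform <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3L, all(dim(source) == dim(target)))
  n <- nrow(source)
  if (n < 3L) stop("need at least 3 corresponding landmarks")
  cs <- colMeans(source); ct <- colMeans(target)
  A <- sweep(source, 2L, cs); B <- sweep(target, 2L, ct)
  # collinearity check: second singular value of the centred source cloud
  sv <- svd(A)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-30) || sv[1] < 1e-12)
    stop("degenerate (collinear or coincident) landmark configuration")
  H <- crossprod(A, B)           # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- ct - as.numeric(R %*% cs)
  tf <- rigid_transform(R, t)
  res <- transform_points(tf, source) - target
  list(transform = tf, rms = sqrt(mean(rowSums(res^2))))
}

#' Mirror points about the sagittal midplane (x = 0)
#'
#' Utility for the left/right symmetry properties of the synthetic knee:
#' reflection negates the mediolateral (x) coordinate.
#' @param pts n x 3 matrix or length-3 vector.
#' @return Reflected points.
#' @export
mirror_sagittal <- function(pts) {
  if (is.null(dim(pts))) return(pts * c(-1, 1, 1))
  pts[, 1] <- -pts[, 1]
  pts
}
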