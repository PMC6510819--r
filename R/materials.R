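## Constitutive models: isotropic cartilage, transversely isotropic meniscus.
##
## Voigt ordering is fixed throughout the package as
##   (11, 22, 33, 23, 13, 12)
## with engineering shear strains (gamma = 2*eps), stresses in MPa,
## lengths in mm, forces in N.

#' Isotropic linear-elastic material
#'
#' Default constants are those used for articular cartilage throughout the
#' package: E = 13 MPa, nu = 0.42.
#'
#' @param E Young's modulus, MPa (> 0).
#' @param nu Poisson's ratio (-1 < nu < 0.5).
#' @return Object of class `c("elastic_isotropic", "elastic_material")`.
#' @export
elastic_isotropic <- function(E = 13, nu = 0.42) {
  if (!is.finite(E) || E <= 0) stop("inadmissible isotropic material: E must be > 0")
  if (!is.finite(nu) || nu <= -1 || nu >= 0.5)
    stop("inadmissible isotropic material: need -1 < nu < 0.5")
  structure(list(E = E, nu = nu), class = c("elastic_isotropic", "elastic_material"))
}

#' Transversely isotropic linear-elastic material
#'
#' Axis 1 of the local frame is the fiber (circumferential) direction; the
#' 2-3 plane is the plane of isotropy. Defaults are the meniscal constants
#' used throughout the package: in-plane E = 20 MPa, nu = 0.2, G = 8.3 MPa;
#' circumferential E = 150 MPa, nu = 0.3, G = 57.7 MPa. `nu_f` is taken as
#' the major ratio nu_12 (fiber-driven contraction of the isotropy plane).
#'
#' The compliance in the local frame is
#' S11 = 1/E_f, S22 = S33 = 1/E_p, S12 = S13 = -nu_f/E_f, S23 = -nu_p/E_p,
#' S44 = 1/G_p (2-3 shear), S55 = S66 = 1/G_f.
#'
#' @param E_p,nu_p,G_p in-plane modulus (MPa), Poisson ratio, shear modulus (MPa).
#' @param E_f,nu_f,G_f fiber-direction modulus (MPa), Poisson ratio, shear modulus (MPa).
#' @return Object of class `c("elastic_transverse_isotropic", "elastic_material")`
#'   carrying the local-frame stiffness `C_local`.
#' @export
elastic_transverse_isotropic <- function(E_p = 20, nu_p = 0.2, G_p = 8.3,
                                         E_f = 150, nu_f = 0.3, G_f = 57.7) {
  for (v in c(E_p = E_p, G_p = G_p, E_f = E_f, G_f = G_f))
    if (!is.finite(v) || v <= 0) stop("inadmissible material: moduli must be > 0")
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / E_f
  S[2, 2] <- S[3, 3] <- 1 / E_p
  S[1, 2] <- S[2, 1] <- S[1, 3] <- S[3, 1] <- -nu_f / E_f
  S[2, 3] <- S[3, 2] <- -nu_p / E_p
  S[4, 4] <- 1 / G_p
  S[5, 5] <- S[6, 6] <- 1 / G_f
  C <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(C))
    stop("inadmissible transversely isotropic material: compliance matrix is not positive definite")
  C <- (C + t(C)) / 2
  structure(list(E_p = E_p, nu_p = nu_p, G_p = G_p,
                 E_f = E_f, nu_f = nu_f, G_f = G_f,
                 C_local = C),
            class = c("elastic_transverse_isotropic", "elastic_material"))
}

#' @export
print.elastic_material <- function(x, ...) {
  if (inherits(x, "elastic_isotropic")) {
    cat(sprintf("Isotropic elastic material: E = %g MPa, nu = %g\n", x$E, x$nu))
  } else {
    cat(sprintf("Transversely isotropic elastic material (axis 1 = fiber):\n  in-plane E = %g MPa, nu = %g, G = %g MPa\n  fiber     E = %g MPa, nu = %g, G = %g MPa\n",
                x$E_p, x$nu_p, x$G_p, x$E_f, x$nu_f, x$G_f))
  }
  invisible(x)
}

#' Isotropic stiffness matrix (Voigt)
#'
#' @param mat `elastic_isotropic` material.
#' @return 6x6 stiffness, MPa, ordering (11,22,33,23,13,12), engineering shear.
#' @export
stiffness_isotropic <- function(mat) {
  E <- mat$E; nu <- mat$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lam
  C
}

## Bond (Voigt) transformation matrix for stress under x_global = Q x_local.
## sigma_voigt_global = M %*% sigma_voigt_local; C_global = M C_local t(M).
voigt_rotation_matrix <- function(Q) {
  ij <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  M <- matrix(0, 6, 6)
  for (I in 1:6) {
    i <- ij[I, 1]; j <- ij[I, 2]
    for (J in 1:6) {
      k <- ij[J, 1]; l <- ij[J, 2]
      M[I, J] <- if (k == l) Q[i, k] * Q[j, k]
                 else Q[i, k] * Q[j, l] + Q[i, l] * Q[j, k]
    }
  }
  M
}

## Deterministic local orthonormal frame with axis 1 = fiber. Axis 3 is the
## global +z direction projected off the fiber (falls back to +y for fibers
## within 1e-6 of vertical); axis 2 completes the right-handed triad.
fiber_frame <- function(fiber) {
  a1 <- fiber / sqrt(sum(fiber^2))
  ref <- c(0, 0, 1)
  if (abs(sum(ref * a1)) > 1 - 1e-6) ref <- c(0, 1, 0)
  a3 <- ref - sum(ref * a1) * a1
  a3 <- a3 / sqrt(sum(a3^2))
  a2 <- c(a3[2] * a1[3] - a3[3] * a1[2],
          a3[3] * a1[1] - a3[1] * a1[3],
          a3[1] * a1[2] - a3[2] * a1[1])
  cbind(a1, a2, a3)
}

#' Transversely isotropic stiffness in the global frame
#'
#' Builds the local-frame stiffness (axis 1 = fiber) and rotates it to the
#' global frame by the fourth-order tensor (Bond) transformation.
#'
#' @param mat `elastic_transverse_isotropic` material.
#' @param fiber_dir unit fiber direction in the global frame.
#' @return 6x6 stiffness, MPa, global frame.
#' @export
stiffness_transverse_isotropic <- function(mat, fiber_dir) {
  n <- sqrt(sum(fiber_dir^2))
  if (abs(n - 1) > 1e-6) stop("fiber_dir must be a unit vector")
  Q <- fiber_frame(fiber_dir)
  M <- voigt_rotation_matrix(Q)
  C <- M %*% mat$C_local %*% t(M)
  (C + t(C)) / 2
}

## Dispatch: stiffness for any material, optional fiber direction.
material_stiffness <- function(mat, fiber_dir = NULL) {
  if (inherits(mat, "elastic_isotropic")) return(stiffness_isotropic(mat))
  if (is.null(fiber_dir)) stop("fiber direction required for transversely isotropic material")
  stiffness_transverse_isotropic(mat, fiber_dir)
}

#' Principal stresses of a symmetric stress tensor
#'
#' @param sigma either a 3x3 symmetric matrix or a length-6 Voigt vector
#'   (11,22,33,23,13,12), MPa.
#' @return Sorted eigenvalues `c(s1, s2, s3)` with `s1 >= s2 >= s3`; `s1` is
#'   the maximum principal stress (hoop-stress indicator in the meniscus),
#'   `s3` the minimum principal stress (compression indicator).
#' @export
principal_stresses <- function(sigma) {
  if (is.null(dim(sigma))) {
    stopifnot(length(sigma) == 6L)
    sigma <- matrix(c(sigma[1], sigma[6], sigma[5],
                      sigma[6], sigma[2], sigma[4],
                      sigma[5], sigma[4], sigma[3]), 3, 3)
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("stress tensor must be symmetric")
  sort(eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Principal stresses for many Voigt stress rows
#'
#' Vectorised closed-form (trigonometric) eigenvalues of symmetric 3x3
#' tensors; used for whole-field postprocessing.
#'
#' @param S m x 6 matrix of Voigt stresses (11,22,33,23,13,12).
#' @return m x 3 matrix, columns sorted `s1 >= s2 >= s3`.
#' @export
principal_stresses_many <- function(S) {
  S <- matrix(as.numeric(S), ncol = 6L)
  s11 <- S[, 1]; s22 <- S[, 2]; s33 <- S[, 3]
  s23 <- S[, 4]; s13 <- S[, 5]; s12 <- S[, 6]
  p1 <- s12^2 + s13^2 + s23^2
  q <- (s11 + s22 + s33) / 3
  p2 <- (s11 - q)^2 + (s22 - q)^2 + (s33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  out <- matrix(q, nrow = length(q), ncol = 3L)
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (s11 - q) / p; b22 <- (s22 - q) / p; b33 <- (s33 - q) / p
    b12 <- s12 / p; b13 <- s13 / p; b23 <- s23 / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    out[nz, 1] <- e1[nz]; out[nz, 2] <- e2[nz]; out[nz, 3] <- e3[nz]
  }
  out
}
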