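## Verification experiments: small numerical tests that recover the model
## constants and classical closed-form solutions from actual FE solves.
## These drive the package's validation suite and the acceptance report.

#' Structured tetrahedral mesh of a rectangular block
#'
#' Unit-cube-style sample meshed with the same Freudenthal template as the
#' anatomical parts. Facet sets: xmin/xmax/ymin/ymax/zmin/zmax.
#'
#' @param n element divisions per edge (scalar or length-3).
#' @param size edge lengths, mm (scalar or length-3).
#' @param origin minimum corner, mm.
#' @param breaks optional list with `x`, `y`, `z`: explicit grid coordinates
#'   (overriding `n`/`size`/`origin` per axis), e.g. for graded meshes.
#' @return `fe_mesh`.
#' @export
block_mesh <- function(n = 2, size = 1, origin = c(0, 0, 0), breaks = NULL) {
  n <- rep(as.integer(n), length.out = 3L)
  size <- rep(size, length.out = 3L)
  xs <- seq(0, size[1], length.out = n[1] + 1L) + origin[1]
  ys <- seq(0, size[2], length.out = n[2] + 1L) + origin[2]
  zs <- seq(0, size[3], length.out = n[3] + 1L) + origin[3]
  if (!is.null(breaks)) {
    if (!is.null(breaks$x)) xs <- sort(breaks$x)
    if (!is.null(breaks$y)) ys <- sort(breaks$y)
    if (!is.null(breaks$z)) zs <- sort(breaks$z)
    n <- c(length(xs), length(ys), length(zs)) - 1L
  }
  g <- expand.grid(k = 0:n[3], j = 0:n[2], i = 0:n[1])[, c("i", "j", "k")]
  nodes <- cbind(xs[g$i + 1L], ys[g$j + 1L], zs[g$k + 1L])
  st <- structured_tets(n[1], n[2], n[3])
  tets <- orient_tets(nodes, st$tets)
  bf <- boundary_faces(tets)
  facets <- classify_grid_boundary(bf, as.matrix(g), n,
                                   c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax"))
  new_fe_mesh(nodes, tets, part = "block", facets = facets,
              node_ijk = as.matrix(g), elem_cell = as.matrix(st$cell))
}

## attach a uniform fiber direction to a block sample
fibered_block <- function(mesh, fiber) {
  mesh$fiber <- matrix(rep(fiber, nrow(mesh$tets)), ncol = 3L, byrow = TRUE)
  mesh
}

#' Effective Young's modulus from a uniaxial-stress FE test
#'
#' One-sample numerical experiment: a cube of the material (fiber along
#' `fiber_dir` for transversely isotropic samples) under unit uniaxial
#' stress along `axis`, with symmetry rollers on the three minimum faces
#' and all other faces traction-free. Returns stress over strain.
#'
#' @param material `elastic_material`.
#' @param axis loading axis, 1 = x, 2 = y, 3 = z.
#' @param fiber_dir fiber direction for anisotropic samples (default +x).
#' @param n mesh divisions per edge.
#' @return list with `E_eff` (stress over axial strain, MPa) and `nu_eff`
#'   (minus the two lateral strains over the axial strain).
#' @export
material_test_uniaxial <- function(material, axis = 1, fiber_dir = c(1, 0, 0), n = 1) {
  mesh <- block_mesh(n)
  if (inherits(material, "elastic_transverse_isotropic"))
    mesh <- fibered_block(mesh, fiber_dir)
  model <- fe_model(list(sample = list(mesh = mesh, material = material)))
  fx <- NULL
  for (d in 1:3) {
    nn <- facet_nodes(mesh, paste0(c("x", "y", "z")[d], "min"))
    fx <- rbind(fx, data.frame(dof = 3L * (nn - 1L) + d, value = 0))
  }
  tr <- c(0, 0, 0); tr[axis] <- 1                      # 1 MPa
  ft <- face_tractions(mesh, paste0(c("x", "y", "z")[axis], "max"), tr)
  nodal <- numeric(3L * nrow(mesh$nodes))
  nodal[as.integer(t(outer(3L * (ft$nodes - 1L), 1:3, "+")))] <- as.numeric(t(ft$forces))
  model <- fe_model(list(sample = list(mesh = mesh, material = material)),
                    fixed = fx, loads = list(nodal = nodal))
  sol <- solve_static(fe_assemble(model), load_steps = 1, rtol = 1e-9,
                      step_limit = 10)
  top <- facet_nodes(mesh, paste0(c("x", "y", "z")[axis], "max"))
  eps_ax <- mean(sol$u[top, axis])
  lat <- setdiff(1:3, axis)
  eps_lat <- vapply(lat, function(d)
    mean(sol$u[facet_nodes(mesh, paste0(c("x", "y", "z")[d], "max")), d]),
    numeric(1))
  list(E_eff = 1 / eps_ax, nu_eff = stats::setNames(-eps_lat / eps_ax,
                                                    c("x", "y", "z")[lat]))
}

#' Effective shear modulus from a simple-shear FE test
#'
#' Prescribes the affine simple-shear field on the boundary nodes of a
#' material sample, solves for the interior, and returns the volume-average
#' shear stress over the applied engineering shear strain.
#'
#' @param material `elastic_material`.
#' @param plane "yz" (plane of isotropy, 2-3 shear), "xy" or "xz" (planes
#'   containing the fiber).
#' @param fiber_dir fiber direction (default +x).
#' @param n mesh divisions per edge (>= 2 so interior nodes exist).
#' @param gamma applied engineering shear strain.
#' @return Effective shear modulus, MPa.
#' @export
material_test_shear <- function(material, plane = c("yz", "xy", "xz"),
                                fiber_dir = c(1, 0, 0), n = 2, gamma = 1e-3) {
  plane <- match.arg(plane)
  mesh <- block_mesh(n)
  if (inherits(material, "elastic_transverse_isotropic"))
    mesh <- fibered_block(mesh, fiber_dir)
  A <- matrix(0, 3, 3)
  comp <- switch(plane, yz = {A[2, 3] <- gamma; 4L},
                 xy = {A[1, 2] <- gamma; 6L},
                 xz = {A[1, 3] <- gamma; 5L})
  bnodes <- sort(unique(unlist(lapply(mesh$facets, as.integer))))
  ub <- mesh$nodes[bnodes, , drop = FALSE] %*% t(A)
  fx <- do.call(rbind, lapply(1:3, function(d)
    data.frame(dof = 3L * (bnodes - 1L) + d, value = ub[, d])))
  model <- fe_model(list(sample = list(mesh = mesh, material = material)),
                    fixed = fx)
  sol <- solve_static(fe_assemble(model), load_steps = 1, rtol = 1e-9,
                      step_limit = 10)
  V <- tet_volumes(mesh$nodes, mesh$tets)
  sum(sol$stresses$sample$voigt[, comp] * V) / sum(V) / gamma
}

#' Sliding-block friction test
#'
#' An elastic block pressed onto a rigid frictional plane while its top
#' face is dragged tangentially far beyond the regularisation scale; the
#' ratio of total tangential to normal contact force recovers the Coulomb
#' friction coefficient.
#'
#' @param friction_mu friction coefficient.
#' @param slide prescribed tangential displacement of the top face, mm.
#' @param press prescribed downward displacement of the top face, mm.
#' @param n mesh divisions.
#' @return list with `ratio` (tangential/normal force), `normal_force` (N).
#' @export
block_friction_test <- function(friction_mu = 0.02, slide = 2, press = 0.05, n = 3) {
  mesh <- block_mesh(n, size = c(10, 10, 5))
  top <- facet_nodes(mesh, "zmax")
  fx <- rbind(data.frame(dof = 3L * (top - 1L) + 1L, value = slide),
              data.frame(dof = 3L * (top - 1L) + 2L, value = 0),
              data.frame(dof = 3L * (top - 1L) + 3L, value = -press))
  cp <- contact_pair(follower_nodes = facet_nodes(mesh, "zmin"),
                     follower_faces = mesh$facets$zmin,
                     analytic = list(type = "plane", point = c(0, 0, 0),
                                     normal = c(0, 0, 1)),
                     friction_mu = friction_mu,
                     penalty_normal = 100, penalty_tangent = 0.5,
                     kind = "deformable-rigid")
  model <- fe_model(list(block = list(mesh = mesh,
                                      material = elastic_isotropic(10, 0.3))),
                    fixed = fx, contacts = list(cp))
  sol <- solve_static(fe_assemble(model), load_steps = 4, rtol = 1e-6,
                      max_iter = 80, step_limit = 2)
  f <- sol$contacts[[1]]$follower_force
  tot <- colSums(f)
  list(ratio = sqrt(sum(tot[1:2]^2)) / abs(tot[3]), normal_force = tot[3],
       solution = sol)
}

#' Rigid sphere-on-elastic-block contact test (Hertz verification)
#'
#' Presses a rigid analytic sphere into the top surface of an elastic
#' block by a prescribed approach and integrates the contact force, for
#' comparison with the Hertz closed form F = 4/3 E* sqrt(R) d^(3/2).
#'
#' @param depth approach of the sphere into the surface, mm.
#' @param R sphere radius, mm.
#' @param E,nu block material constants.
#' @param h_fine element size across the contact patch, mm.
#' @param width,height block dimensions, mm.
#' @return list with `force_fe` (N), `force_hertz` (N), `contact_radius`.
#' @export
hertz_contact_test <- function(depth = 0.8, R = 100, E = 10, nu = 0.3,
                               h_fine = 1.5, width = 44, height = 36) {
  ## graded grid: uniformly fine across the contact circle (radius
  ## a = sqrt(R*depth) plus margin), geometric coarsening outside and with
  ## depth below the surface
  a <- sqrt(R * depth)
  patch <- 1.25 * a
  fine <- seq(-patch, patch, length.out = 2L * ceiling(patch / h_fine) + 1L)
  outer_x <- patch * 1.6^(1:3)
  outer_x <- outer_x[outer_x < width / 2]
  gx <- sort(unique(c(-width / 2, -rev(outer_x), fine, outer_x, width / 2)))
  zt <- height - seq(0, 1.2 * h_fine * 4, by = 1.2 * h_fine)
  zb <- height - 1.2 * h_fine * 4 * 1.9^(1:3)
  gz <- sort(unique(c(0, zb[zb > 0], zt)))
  mesh <- block_mesh(breaks = list(x = gx, y = gx, z = gz))
  bot <- facet_nodes(mesh, "zmin")
  fx <- do.call(rbind, lapply(1:3, function(d)
    data.frame(dof = 3L * (bot - 1L) + d, value = 0)))
  cp <- contact_pair(follower_nodes = facet_nodes(mesh, "zmax"),
                     follower_faces = mesh$facets$zmax,
                     analytic = list(type = "sphere",
                                     centre = c(0, 0, height + R - depth),
                                     radius = R),
                     friction_mu = 0,
                     penalty_normal = 2000, penalty_tangent = 1,
                     kind = "deformable-rigid")
  model <- fe_model(list(block = list(mesh = mesh,
                                      material = elastic_isotropic(E, nu))),
                    fixed = fx, contacts = list(cp))
  sol <- solve_static(fe_assemble(model), load_steps = 1, rtol = 2e-2,
                      max_iter = 60)
  Fz <- -colSums(sol$contacts[[1]]$follower_force)[3]
  Estar <- E / (1 - nu^2)
  list(force_fe = abs(Fz),
       force_hertz = 4 / 3 * Estar * sqrt(R) * depth^1.5,
       contact_radius = sqrt(R * depth),
       solution = sol)
}
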