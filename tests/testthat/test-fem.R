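test_that("element stiffness has exactly six rigid-body modes and is PSD", {
  nd <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(0.2, 1, -0.1), c(0.1, 0.2, 0.9))
  K <- element_stiffness_tet(nd, stiffness_isotropic(elastic_isotropic(5, 0.3)))
  expect_lt(max(abs(K - t(K))), 1e-12)
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)
  expect_gt(min(ev[1:6]), 0)
  expect_error(element_stiffness_tet(nd[c(2, 1, 3, 4), ], diag(6)), "inverted")
})

test_that("a uniaxial patch field is reproduced exactly on a tet block", {
  mesh <- block_mesh(2)
  A <- diag(c(2e-3, 0, 0))
  bnodes <- sort(unique(unlist(lapply(mesh$facets, as.integer))))
  ub <- mesh$nodes[bnodes, , drop = FALSE] %*% t(A)
  fx <- do.call(rbind, lapply(1:3, function(d)
    data.frame(dof = 3L * (bnodes - 1L) + d, value = ub[, d])))
  model <- fe_model(list(s = list(mesh = mesh,
                                  material = elastic_isotropic(1, 0))),
                    fixed = fx)
  sol <- solve_static(fe_assemble(model), load_steps = 1, rtol = 1e-12,
                      step_limit = 10)
  expect_equal(sol$u, mesh$nodes %*% t(A), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## constant stress sigma_xx = E * eps_xx everywhere, exactly
  sig <- sol$stresses$s$voigt
  expect_equal(sig[, 1], rep(2e-3, nrow(sig)), tolerance = 1e-12)
  expect_lt(max(abs(sig[, 2:6])), 1e-15)
})

test_that("assembly is consistent: zero state, symmetry, bar solution", {
  mesh <- block_mesh(c(4, 1, 1), size = c(8, 1, 1))
  model <- fe_model(list(bar = list(mesh = mesh,
                                    material = elastic_isotropic(100, 0))))
  sys <- fe_assemble(model)
  ## zero displacement, zero load -> zero residual
  st <- kneefem:::evaluate_state(sys, numeric(sys$nq), 1,
                                 list(), 0.5)
  expect_equal(max(abs(st$r_red)), 0)
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))) / max(abs(sys$K)), 1e-8)
  ## uniaxial bar: end displacement FL/EA
  nn <- facet_nodes(mesh, "xmin")
  fx <- do.call(rbind, lapply(1:3, function(d)
    data.frame(dof = 3L * (nn - 1L) + d, value = 0)))
  ft <- face_tractions(mesh, "xmax", c(2, 0, 0))      # 2 MPa
  nodal <- numeric(3L * nrow(mesh$nodes))
  nodal[as.integer(t(outer(3L * (ft$nodes - 1L), 1:3, "+")))] <- as.numeric(t(ft$forces))
  model <- fe_model(list(bar = list(mesh = mesh,
                                    material = elastic_isotropic(100, 0))),
                    fixed = fx, loads = list(nodal = nodal))
  sol <- solve_static(fe_assemble(model), load_steps = 1, rtol = 1e-10,
                      step_limit = 10)
  u_end <- mean(sol$u[facet_nodes(mesh, "xmax"), 1])
  expect_equal(u_end, 2 * 8 / 100, tolerance = 1e-3)   # FL/EA
})

test_that("tension-only springs carry the printed ligament stiffnesses", {
  ## one node pulled 1 mm along the spring axis beyond slack
  ks <- ligament_stiffness_defaults()
  mesh <- block_mesh(1)
  all_n <- seq_len(nrow(mesh$nodes))
  for (nm in names(ks)) {
    spr <- list(name = nm, nodes = all_n, k = ks[[nm]],
                ground = c(10.5, 0.5, 0.5), slack = 10)
    model <- fe_model(list(b = list(mesh = mesh,
                                    material = elastic_isotropic(1000, 0))),
                      springs = list(spr))
    u <- matrix(0, nrow(mesh$nodes), 3)
    u[, 1] <- -1                             # move 1 mm away from the ground
    sp <- kneefem:::spring_forces(model, u)
    expect_equal(sp$report[[nm]]$force, ks[[nm]], tolerance = 1e-9)
    ## non-compressive: moving towards the ground gives zero force
    u[, 1] <- 1
    sp0 <- kneefem:::spring_forces(model, u)
    expect_equal(sp0$report[[nm]]$force, 0)
  }
})

test_that("bonded bone constraints fix and slave the cartilage correctly", {
  sol <- intact_coarse_solution()
  model <- sol$knee$fe
  ## tibial-side bone nodes do not move
  tb <- rigid_bone_constraints(model, "tibial_cartilage_med", "bone", "fixed")
  expect_lt(max(abs(sol$u[unique((tb$dof - 1) %/% 3 + 1), ])), 1e-12)
  ## femoral-side bone nodes follow the rigid femur DOFs
  fn <- rigid_bone_constraints(model, "femoral_cartilage_med", "bone", "rigid")
  tx <- sol$rigid_dofs[["femur.tx"]]
  tz <- sol$rigid_dofs[["femur.tz"]]
  ry <- sol$rigid_dofs[["femur.ry"]]
  ref <- model$rigid_bodies[[1]]$free[[3]]$point
  dX <- sweep(model$X[fn, , drop = FALSE], 2, ref)
  u_exp <- cbind(tx + ry * dX[, 3], 0, tz - ry * dX[, 1])
  expect_equal(sol$u[fn, ], u_exp, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(rigid_bone_constraints(model, "meniscus_MM", "nope"), "facet")
})

test_that("an unsupported elastic layer is reported as singular", {
  mesh <- block_mesh(1)
  model <- fe_model(list(f = list(mesh = mesh,
                                  material = elastic_isotropic(1, 0.3))),
                    loads = list(nodal = rep(1, 3 * nrow(mesh$nodes))))
  expect_error(suppressWarnings(solve_static(fe_assemble(model),
                                             load_steps = 1, max_iter = 3)),
               "singular")
})

test_that("sliding block recovers the Coulomb friction coefficient", {
  bf <- cached("block_friction", block_friction_test(friction_mu = 0.02))
  expect_gt(abs(bf$normal_force), 0)
  expect_lt(abs(bf$ratio - 0.02) / 0.02, 0.05)
})

test_that("separated surfaces transmit no contact force", {
  mesh <- block_mesh(1, origin = c(0, 0, 5))
  cp <- contact_pair(follower_nodes = facet_nodes(mesh, "zmin"),
                     follower_faces = mesh$facets$zmin,
                     analytic = list(type = "plane", point = c(0, 0, 0),
                                     normal = c(0, 0, 1)))
  cr <- contact_forces(cp, mesh$nodes, matrix(0, nrow(mesh$nodes), 3),
                       rep(1, length(cp$follower_nodes)))
  expect_equal(max(abs(cr$f)), 0)
  expect_true(all(cr$status$state == "open"))
  expect_true(all(cr$status$gap > 0))
})

test_that("the penalty law returns kn * penetration * area per node", {
  mesh <- block_mesh(1)
  fol <- facet_nodes(mesh, "zmin")
  cp <- contact_pair(follower_nodes = fol, follower_faces = mesh$facets$zmin,
                     analytic = list(type = "plane", point = c(0, 0, 0.01),
                                     normal = c(0, 0, 1)),
                     friction_mu = 0, penalty_normal = 50)
  areas <- kneefem:::tributary_areas(cp, mesh$nodes)
  cr <- contact_forces(cp, mesh$nodes, matrix(0, nrow(mesh$nodes), 3), areas)
  ## every follower node penetrates by 0.01: f_z = kn * 0.01 * area
  fz <- cr$follower_force[, 3]
  expect_equal(fz, 50 * 0.01 * areas, tolerance = 1e-10)
  expect_equal(sum(areas), 1, tolerance = 1e-12)   # face area partition
})

test_that("rigid-sphere indentation produces a coherent contact state", {
  ## the quantitative Hertz comparison lives in the acceptance suite; here
  ## the indentation run is checked for structural sanity
  hz <- cached("hertz", suppressWarnings(hertz_contact_test()))
  expect_gt(hz$force_fe, 0)
  st <- hz$solution$contacts[[1]]$status
  active <- st[st$pressure > 0, ]
  expect_gt(nrow(active), 10)
  ## active nodes lie within a band around the theoretical contact circle
  X <- hz$solution$model$X[active$node, , drop = FALSE]
  r <- sqrt(X[, 1]^2 + X[, 2]^2)
  expect_lt(max(r), 1.4 * hz$contact_radius)
})

test_that("global equilibrium: vertical tibial reaction equals the load", {
  sol <- intact_coarse_solution()
  expect_true(sol$converged)
  expect_lt(abs(abs(sol$tibial_reaction_z) - 750), 0.005 * 750)
  ## springs never compressive
  expect_true(all(vapply(sol$springs, function(s) s$force >= 0, logical(1))))
  ## penetration within tolerance
  expect_lte(sol$max_penetration, sol$penetration_tol)
})
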