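test_that("structured sweep meshing gives the closed-form element count", {
  geom <- default_geometry()
  res <- mesh_resolution(12, 3, 2, 4)
  m <- mesh_meniscus(geom, "MM", res)
  expect_equal(nrow(m$tets), 6 * 12 * 3 * 2)
  expect_equal(nrow(m$nodes), 13 * 4 * 3)
  expect_gt(min(tet_volumes(m$nodes, m$tets)), 0)
  tc <- mesh_tibial_cartilage(geom, "MM", res)
  expect_equal(nrow(tc$tets), 6 * 4 * 4 * 2)
  fc <- mesh_femoral_cartilage(geom, "MM", res)
  expect_equal(nrow(fc$tets), 6 * 4 * 4 * 2)
})

test_that("mesh volume converges to the analytic solid volume", {
  geom <- default_geometry()
  va <- meniscus_volume_analytic(geom, "MM")
  err <- sapply(c(12, 24, 60), function(nc) {
    vm <- mesh_volume(mesh_meniscus(geom, "MM", mesh_resolution(nc, 3, 2, 4)))
    abs(vm - va) / va
  })
  expect_lt(err[3], 0.02)            # default circumferential resolution
  expect_true(all(diff(err) < 0))    # monotone decrease under refinement
})

test_that("resolution invariants are enforced", {
  expect_error(mesh_resolution(radial = 4), "multiple of 3")
  expect_error(mesh_resolution(circumferential = 1), ">= 2")
  geom0 <- knee_geometry(knee_params(inner_rim_height = 0))
  expect_error(mesh_meniscus(geom0, "MM"), "degenerate")
})

test_that("fiber directions are unit circumferential tangents", {
  geom <- default_geometry()
  for (side in c("MM", "LM")) {
    m <- mesh_meniscus(geom, side, mesh_resolution(12, 3, 2, 4))
    expect_lt(max(abs(sqrt(rowSums(m$fiber^2)) - 1)), 1e-12)
    cen <- (m$nodes[m$tets[, 1], ] + m$nodes[m$tets[, 2], ] +
              m$nodes[m$tets[, 3], ] + m$nodes[m$tets[, 4], ]) / 4
    rad <- cen[, 1:2] - matrix(geom$menisci[[side]]$centre, nrow(cen), 2,
                               byrow = TRUE)
    costh <- rowSums(m$fiber[, 1:2] * rad) / sqrt(rowSums(rad^2))
    expect_lt(max(abs(costh)), 1e-6)   # orthogonal to the local radial direction
    expect_lt(max(abs(m$fiber[, 3])), 1e-12)
  }
  ## idempotent
  m <- mesh_meniscus(geom, "MM", mesh_resolution(12, 3, 2, 4))
  expect_identical(assign_fiber_directions(m)$fiber, m$fiber)
})

test_that("flipping the fiber sign leaves the stiffness unchanged", {
  mat <- elastic_transverse_isotropic()
  f <- c(-0.6, 0.8, 0)
  expect_equal(stiffness_transverse_isotropic(mat, f),
               stiffness_transverse_isotropic(mat, -f), tolerance = 1e-12)
})

test_that("region and zone labels are equal terciles of arc and rim width", {
  geom <- default_geometry()
  m <- mesh_meniscus(geom, "MM", mesh_resolution(12, 3, 2, 4))
  expect_true(all(table(m$region) == nrow(m$tets) / 3))
  expect_true(all(table(m$zone) == nrow(m$tets) / 3))
  ## element at arc fraction 0.1 -> anterior; s = 0.5 -> middle zone
  frac <- (m$elem_param[, "psi"] - m$sweep$psi0) / (m$sweep$psi1 - m$sweep$psi0)
  e1 <- which.min(abs(frac - 0.1))
  expect_equal(as.character(m$region[e1]), "anterior")
  e2 <- which.min(abs(m$elem_param[, "s"] - 0.5))
  expect_equal(as.character(m$zone[e2]), "middle")
})

test_that("labels are determined by element centroids, not resolution", {
  geom <- default_geometry()
  for (res in list(mesh_resolution(12, 3, 2, 4), mesh_resolution(24, 6, 2, 4))) {
    m <- mesh_meniscus(geom, "LM", res)
    frac <- (m$elem_param[, "psi"] - m$sweep$psi0) / (m$sweep$psi1 - m$sweep$psi0)
    expect_true(all((frac < 1 / 3) == (m$region == "anterior")))
    expect_true(all((m$elem_param[, "s"] > 2 / 3) == (m$zone == "outer")))
  }
})

test_that("facet sets are a watertight partition of the boundary", {
  geom <- default_geometry()
  meshes <- list(mesh_meniscus(geom, "MM", mesh_resolution(12, 3, 2, 4)),
                 mesh_tibial_cartilage(geom, "LM", mesh_resolution(12, 3, 2, 4)),
                 mesh_femoral_cartilage(geom, "LM", mesh_resolution(12, 3, 2, 4)))
  for (m in meshes) {
    bf <- kneefem:::boundary_faces(m$tets)
    n_sets <- sum(vapply(m$facets, nrow, numeric(1)))
    expect_equal(n_sets, nrow(bf$faces))
    keys <- function(fc) apply(t(apply(fc, 1, sort)), 1, paste, collapse = "-")
    all_keys <- unlist(lapply(m$facets, keys))
    expect_false(any(duplicated(all_keys)))
    expect_setequal(all_keys, keys(bf$faces))
  }
})

test_that("cartilage layers lie within their bone-offset thickness", {
  geom <- default_geometry()
  res <- mesh_resolution(12, 3, 2, 6)
  tc <- mesh_tibial_cartilage(geom, "MM", res)
  t_t <- geom$tibia$cartilage_thickness
  expect_true(all(tc$nodes[, 3] >= -1e-12 & tc$nodes[, 3] <= t_t + 1e-12))
  fc <- mesh_femoral_cartilage(geom, "LM", res)
  cdl <- geom$femur$condyles$LM
  d <- sqrt(rowSums(sweep(fc$nodes, 2, cdl$centre)^2))
  expect_true(all(d >= cdl$radius_bone - 1e-9 &
                    d <= cdl$radius_outer + 1e-9))
  ## bone-bonded facet sets are non-empty and cover the full layer face
  n <- res$cartilage
  expect_equal(nrow(tc$facets$bone), 2 * n^2)
  expect_equal(nrow(fc$facets$bone), 2 * n^2)
})
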