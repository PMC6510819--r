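test_that("default parameters give the expected anatomy", {
  geom <- default_geometry()
  expect_length(geom$menisci, 2)
  expect_length(geom$ligaments, 4)
  expect_equal(nrow(geom$landmarks), 3)
  ## arc spans: the medial meniscus is the more open C
  spanMM <- geom$menisci$MM$psi1 - geom$menisci$MM$psi0
  spanLM <- geom$menisci$LM$psi1 - geom$menisci$LM$psi0
  expect_gt(spanMM, spanLM)
})

test_that("parameter invariants are validated with informative errors", {
  expect_error(knee_params(meniscus_inner_radius_MM = 25),
               "outer_radius > inner_radius")
  expect_error(knee_params(arc_start_deg_LM = 320, arc_end_deg_LM = 310),
               "arc_end > arc_start")
  expect_error(knee_params(meniscus_peripheral_height_MM = -1),
               "peripheral_height")
  expect_error(knee_params(arc_start_deg_MM = 100, arc_end_deg_MM = 200),
               "arc span")
})

test_that("geometry generation is deterministic given the seed", {
  g1 <- knee_geometry(knee_params(roughness_amplitude = 0.02, random_seed = 1))
  g2 <- knee_geometry(knee_params(roughness_amplitude = 0.02, random_seed = 1))
  psi <- seq(g1$menisci$MM$psi0, g1$menisci$MM$psi1, length.out = 50)
  p1 <- kneefem:::meniscus_point(g1$menisci$MM, psi, rep(1, 50), rep(0.5, 50))
  p2 <- kneefem:::meniscus_point(g2$menisci$MM, psi, rep(1, 50), rep(0.5, 50))
  expect_identical(p1, p2)
  g3 <- knee_geometry(knee_params(roughness_amplitude = 0.02, random_seed = 2))
  p3 <- kneefem:::meniscus_point(g3$menisci$MM, psi, rep(1, 50), rep(0.5, 50))
  expect_false(isTRUE(all.equal(p1, p3)))
})

test_that("meniscus inferior surface is congruent with the tibial cartilage", {
  geom <- default_geometry()
  for (side in c("MM", "LM")) {
    men <- geom$menisci[[side]]
    psi <- seq(men$psi0, men$psi1, length.out = 40)
    inf <- kneefem:::meniscus_point(men, psi, runif(40), rep(0, 40))
    expect_equal(inf[, 3], rep(geom$tibia$cartilage_thickness, 40),
                 tolerance = 1e-12)
  }
})

test_that("no interpenetration at the reference pose", {
  geom <- default_geometry()
  for (side in c("MM", "LM")) {
    men <- geom$menisci[[side]]
    cdl <- geom$femur$condyles[[side]]
    psi <- seq(men$psi0, men$psi1, length.out = 120)
    for (s in c(0, 0.25, 0.5, 0.75, 1)) {
      sup <- kneefem:::meniscus_point(men, psi, rep(s, 120), rep(1, 120))
      gap <- sqrt(rowSums(sweep(sup, 2, cdl$centre)^2)) - cdl$radius_outer
      expect_gte(min(gap), -1e-6)
    }
  }
})

test_that("posing the femur is exact and invertible", {
  geom <- default_geometry()
  expect_equal(pose_femur(geom, 0)$transform$R, diag(3), tolerance = 1e-12)
  p20 <- pose_femur(geom, 20)
  lm <- geom$landmarks
  back <- transform_points(invert_transform(p20$transform),
                           transform_points(p20$transform, lm))
  expect_lt(max(abs(back - lm)), 1e-9)
  ## extracted rotation equals the flexion angle within the coupling
  p30 <- pose_femur(geom, 30)
  aa <- rot_to_axis_angle(p30$transform$R)
  expect_lt(abs(aa$angle_deg - 30), p30$screw_home_deg + 1e-9)
  expect_error(pose_femur(geom, 45), "range")
  ## condylar spheres are invariant under flexion (axis through centres)
  cM <- geom$femur$condyles$MM$centre
  expect_equal(transform_points(p30$transform, cM), cM, tolerance = 1e-9)
})

test_that("landmark-registered poses recover the parametric pose", {
  geom <- default_geometry()
  p <- pose_femur(geom, 20)
  obs <- transform_points(p$transform, geom$landmarks)
  reg <- pose_from_landmarks(geom, obs, flexion_angle = 20)
  expect_equal(reg$transform$R, p$transform$R, tolerance = 1e-9)
  expect_lt(reg$rms, 1e-9)
})

test_that("mirrored parameters generate the sagittally reflected knee", {
  p <- knee_params()
  gm <- knee_geometry(mirror_params(p))
  g <- knee_geometry(p)
  res <- mesh_resolution(12, 3, 2, 4)
  for (side in c("MM", "LM")) {
    m <- mesh_meniscus(g, side, res)
    mm <- mesh_meniscus(gm, side, res)
    expect_equal(mirror_sagittal(m$nodes), mm$nodes, tolerance = 1e-12)
  }
  expect_equal(mirror_sagittal(g$landmarks), unname(gm$landmarks),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("analytic meniscal volume matches a fine swept mesh within 1%", {
  geom <- default_geometry()
  res <- mesh_resolution(96, 12, 4, 4)
  for (side in c("MM", "LM")) {
    va <- meniscus_volume_analytic(geom, side)
    vm <- mesh_volume(mesh_meniscus(geom, side, res))
    expect_lt(abs(vm - va) / va, 0.01)
  }
})
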