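# Postprocessing operators are checked on manufactured stress fields with
# known closed-form behaviour, on a small intact model.

pp_model <- function() cached("pp_model",
                              knee_model(resolution = mesh_resolution(12, 6, 2, 4, 2),
                                         loadcase = load_case(0, 750)))

test_that("a uniform stress field gives a flat transect with exact endpoints", {
  km <- pp_model()
  sig <- c(2, 1, 0.5, 0.1, -0.2, 0.3)
  sol <- manufactured_solution(km, function(p, mesh, cen)
    matrix(sig, nrow(mesh$tets), 6, byrow = TRUE))
  pr <- sample_transect(sol, "MM", "middle", n_samples = 9)
  expect_equal(pr$s[1], 0)
  expect_equal(pr$s[length(pr$s)], 1)
  expect_true(all(diff(pr$s) > 0))
  expect_equal(pr$max_pcs, rep(principal_stresses(sig)[1], 9), tolerance = 1e-9)
})

test_that("a field linear in the radial coordinate samples linearly", {
  km <- pp_model()
  mesh <- km$fe$parts$meniscus_MM$mesh
  sol <- manufactured_solution(km, function(p, mesh, cen) {
    v <- matrix(0, nrow(mesh$tets), 6)
    if (!is.null(mesh$elem_param)) v[, 1] <- 1 + 3 * mesh$elem_param[, "s"]
    v
  })
  pr <- sample_transect(sol, "MM", "anterior", n_samples = 13)
  ## element-wise constant sampling gives a staircase around the line
  fit <- stats::lm(max_pcs ~ s, data = pr)
  expect_equal(unname(stats::coef(fit)[2]), 3, tolerance = 0.1)
  expect_gt(stats::summary.lm(fit)$r.squared, 0.95)
})

test_that("tear-surface differences follow the favourability definition", {
  km <- cached("pp_torn_model",
               knee_model(resolution = mesh_resolution(30, 12, 2, 4, 2),
                          loadcase = load_case(0, 750),
                          tear = tear_spec("longitudinal", "MM", "middle", "stable"),
                          resolution_other = mesh_resolution(12, 6, 2, 4, 2)))
  topo <- km$tear$topology
  mk <- function(inner, outer) {
    sol <- manufactured_solution(km, function(p, mesh, cen) {
      v <- matrix(0, nrow(mesh$tets), 6)
      if (p == "meniscus_MM") {
        hoop <- rep(0, nrow(mesh$tets))
        hoop[topo$elem_neg] <- inner
        hoop[topo$elem_pos] <- outer
        ## stress tensor sigma = hoop * f f' in Voigt components
        f <- mesh$fiber
        v <- cbind(hoop * f[, 1]^2, hoop * f[, 2]^2, hoop * f[, 3]^2,
                   hoop * f[, 2] * f[, 3], hoop * f[, 1] * f[, 3],
                   hoop * f[, 1] * f[, 2])
      }
      v
    })
    tear_surface_difference(sol, topo)
  }
  eq <- mk(1.5, 1.5)
  expect_equal(eq$difference, 0, tolerance = 1e-12)
  expect_equal(eq$classification, "unfavourable")   # strict > for favourable
  fav <- mk(1, 2)
  expect_equal(fav$difference, 1, tolerance = 1e-9)
  expect_equal(fav$classification, "favourable")
  swapped <- mk(2, 1)
  expect_equal(swapped$difference, -1, tolerance = 1e-9)
  expect_equal(swapped$classification, "unfavourable")
  ## radial tears are rejected with a clear error
  kmr <- cached("pp_torn_radial",
                knee_model(resolution = mesh_resolution(12, 12, 2, 4, 2),
                           loadcase = load_case(0, 750),
                           tear = tear_spec("radial", "MM", "middle", "stable"),
                           resolution_other = mesh_resolution(12, 6, 2, 4, 2)))
  solr <- manufactured_solution(kmr, function(p, mesh, cen)
    matrix(0, nrow(mesh$tets), 6))
  expect_error(tear_surface_difference(solr, kmr$tear$topology), "longitudinal")
})

test_that("apex deltas vanish for identical runs and are frame-indifferent", {
  kmr <- cached("pp_torn_radial",
                knee_model(resolution = mesh_resolution(12, 12, 2, 4, 2),
                           loadcase = load_case(0, 750),
                           tear = tear_spec("radial", "MM", "middle", "stable"),
                           resolution_other = mesh_resolution(12, 6, 2, 4, 2)))
  set.seed(3)
  base_fun <- function(p, mesh, cen) matrix(rnorm(nrow(mesh$tets) * 6), ncol = 6)
  sol1 <- manufactured_solution(kmr, base_fun)
  rep0 <- apex_stress_delta(sol1, sol1, kmr$tear$topology)
  expect_equal(rep0$delta, 0, tolerance = 1e-12)
  ## rotating all stress tensors rigidly leaves the delta unchanged
  R <- rotation_about_axis(c(1, 1, 0), 30)$R
  M <- kneefem:::voigt_rotation_matrix(R)
  sol2 <- sol1
  for (p in names(sol2$stresses)) {
    vr <- sol1$stresses[[p]]$voigt %*% t(M)
    sol2$stresses[[p]] <- list(voigt = vr,
                               principal = principal_stresses_many(vr))
  }
  set.seed(4)
  soli1 <- manufactured_solution(kmr, base_fun)
  soli2 <- soli1
  for (p in names(soli2$stresses)) {
    vr <- soli1$stresses[[p]]$voigt %*% t(M)
    soli2$stresses[[p]] <- list(voigt = vr,
                                principal = principal_stresses_many(vr))
  }
  d1 <- apex_stress_delta(sol1, soli1, kmr$tear$topology)$delta
  d2 <- apex_stress_delta(sol2, soli2, kmr$tear$topology)$delta
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("segment displacements report the stated sign conventions", {
  km <- pp_model()
  zero <- manufactured_solution(km, function(p, mesh, cen)
    matrix(0, nrow(mesh$tets), 6))
  same <- segment_displacements(zero, zero)
  expect_true(all(abs(same$ap_mm) < 1e-12) && all(abs(same$ml_mm) < 1e-12))
  ## translating every node +1 mm anteriorly: AP displacement +1 everywhere
  shifted <- zero
  shifted$u <- zero$u + matrix(rep(c(0, 1, 0), each = nrow(zero$u)),
                               ncol = 3)
  sd <- segment_displacements(zero, shifted)
  expect_equal(sd$ap_mm, rep(1, nrow(sd)), tolerance = 1e-12)
  ## translating +1 mm laterally (+x): medial displacement is -1 (right knee)
  shifted$u <- zero$u + matrix(rep(c(1, 0, 0), each = nrow(zero$u)), ncol = 3)
  sd2 <- segment_displacements(zero, shifted)
  expect_equal(sd2$ml_mm, rep(-1, nrow(sd2)), tolerance = 1e-12)
})

test_that("compartment metrics vanish without load", {
  km <- pp_model()
  zero <- manufactured_solution(km, function(p, mesh, cen)
    matrix(0, nrow(mesh$tets), 6))
  cm <- compartment_contact_metrics(zero)
  expect_equal(cm$contact_area, c(0, 0))
  expect_equal(cm$peak_compressive_stress, c(0, 0))
})

test_that("reports are pure functions of their inputs", {
  km <- pp_model()
  set.seed(8)
  fun <- function(p, mesh, cen) matrix(rnorm(nrow(mesh$tets) * 6), ncol = 6)
  sol <- manufactured_solution(km, fun)
  a <- sample_transect(sol, "LM", "posterior")
  b <- sample_transect(sol, "LM", "posterior")
  expect_identical(a, b)
})
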