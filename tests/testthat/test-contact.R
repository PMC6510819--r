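test_that("closest point on triangle matches a dense sampling oracle", {
  set.seed(17)
  for (rep in 1:20) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3); p <- rnorm(3) * 2
    cp <- kneefem:::closest_point_triangle(matrix(p, 1), matrix(a, 1),
                                           matrix(b, 1), matrix(c, 1))
    ## oracle: dense barycentric sampling of the triangle
    g <- expand.grid(u = seq(0, 1, length.out = 60),
                     v = seq(0, 1, length.out = 60))
    g <- g[g$u + g$v <= 1, ]
    pts <- outer(1 - g$u - g$v, a) + outer(g$u, b) + outer(g$v, c)
    dmin <- min(sqrt(rowSums(sweep(pts, 2, p)^2)))
    dcp <- sqrt(sum((cp$point - p)^2))
    expect_lte(dcp, dmin + 1e-9)
    expect_equal(dcp, dmin, tolerance = 0.05)
    expect_equal(sum(cp$w), 1, tolerance = 1e-12)
  }
})

test_that("projection onto a faceted surface returns continuous gaps", {
  ## follower sliding across a two-triangle ridge: the smoothed-normal gap
  ## must vary continuously across the shared edge
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0.05), c(0, 1, 0.05),
                  c(2, 0, 0.0), c(2, 1, 0.05))
  faces <- rbind(c(1, 2, 3), c(1, 3, 4), c(2, 5, 6), c(2, 6, 3))
  xs <- seq(0.5, 1.5, length.out = 101)
  pts <- cbind(xs, 0.5, 0.4)
  pr <- kneefem:::project_on_faces(pts, faces, coords)
  expect_lt(max(abs(diff(pr$gap))), 0.02)
  expect_true(all(pr$gap > 0))
})

test_that("tributary areas partition the follower surface area", {
  mesh <- block_mesh(3, size = c(6, 6, 2))
  cp <- contact_pair(follower_nodes = facet_nodes(mesh, "zmax"),
                     follower_faces = mesh$facets$zmax,
                     analytic = list(type = "plane", point = c(0, 0, 10),
                                     normal = c(0, 0, -1)))
  a <- kneefem:::tributary_areas(cp, mesh$nodes)
  expect_equal(sum(a), 36, tolerance = 1e-9)
  expect_true(all(a > 0))
})

test_that("contact pair construction validates its inputs", {
  expect_error(contact_pair(1:3, friction_mu = -1), "friction_mu")
  expect_error(contact_pair(1:3, penalty_normal = 0,
                            analytic = list(type = "plane")), "penalt")
  expect_error(contact_pair(1:3), "target")
})
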