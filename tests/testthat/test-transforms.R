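test_that("rigid transforms compose, invert and validate", {
  a <- rotation_about_axis(c(0, 0, 1), 90, point = c(1, 0, 0))
  b <- rotation_about_axis(c(1, 1, 0), 33, point = c(0, 2, 1))
  p <- matrix(rnorm(15), 5, 3)
  expect_equal(transform_points(compose_transforms(a, b), p),
               transform_points(a, transform_points(b, p)), tolerance = 1e-12)
  expect_equal(transform_points(compose_transforms(invert_transform(a), a), p),
               p, tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "reflection")
})

test_that("axis-angle decomposition recovers the rotation", {
  tf <- rotation_about_axis(c(2, -1, 0.5), 57)
  aa <- rot_to_axis_angle(tf$R)
  expect_equal(aa$angle_deg, 57, tolerance = 1e-9)
  ax <- c(2, -1, 0.5) / sqrt(sum(c(2, -1, 0.5)^2))
  expect_equal(abs(sum(aa$axis * ax)), 1, tolerance = 1e-9)
})

test_that("landmark registration recovers exact correspondences", {
  set.seed(11)
  src <- matrix(rnorm(12, sd = 20), 4, 3)
  ## identity
  fit0 <- landmark_transform(src, src)
  expect_equal(fit0$transform$R, diag(3), tolerance = 1e-10)
  expect_equal(fit0$rms, 0, tolerance = 1e-10)
  ## 90 degree rotation about a coordinate axis plus translation
  tf <- compose_transforms(rigid_transform(t = c(5, -3, 12)),
                           rotation_about_axis(c(0, 0, 1), 90))
  fit <- landmark_transform(src, transform_points(tf, src))
  expect_equal(fit$transform$R, tf$R, tolerance = 1e-9)
  expect_equal(fit$transform$t, tf$t, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
})

test_that("perturbed 3-point registration matches a grid-search oracle", {
  set.seed(7)
  src <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 25, 8))
  tf <- compose_transforms(rigid_transform(t = c(2, 1, -4)),
                           rotation_about_axis(c(1, 2, 0.3), 21))
  tgt <- transform_points(tf, src) + matrix(rnorm(9, sd = 0.4), 3, 3)
  fit <- landmark_transform(src, tgt)

  ## brute force over an axis-angle grid around the fitted rotation; for
  ## each candidate rotation the optimal translation aligns the centroids
  rms_of <- function(R) {
    cs <- colMeans(src); ct <- colMeans(tgt)
    res <- sweep(sweep(src, 2, cs) %*% t(R), 2, ct, "+") - tgt
    sqrt(mean(rowSums(res^2)))
  }
  best <- Inf
  for (ax1 in seq(1.6, 2.4, length.out = 9))
    for (ax2 in seq(-0.1, 0.7, length.out = 9))
      for (th in seq(-3, 3, length.out = 13)) {
        Rc <- rotation_about_axis(c(1, ax1, ax2), 21 + th)$R
        best <- min(best, rms_of(Rc))
      }
  expect_lte(fit$rms, best + 1e-9)
  expect_equal(fit$rms, best, tolerance = 0.05)
})

test_that("registration is left-invariant under a common rigid motion", {
  set.seed(5)
  src <- matrix(rnorm(15, sd = 10), 5, 3)
  tgt <- src + matrix(rnorm(15, sd = 0.3), 5, 3)
  pre <- rotation_about_axis(c(1, -2, 2), 40, point = c(3, 3, 3))
  r1 <- landmark_transform(src, tgt)$rms
  r2 <- landmark_transform(transform_points(pre, src),
                           transform_points(pre, tgt))$rms
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("degenerate landmark configurations are rejected", {
  line <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(landmark_transform(line, line + 1), "degenerate")
  expect_error(landmark_transform(matrix(0, 2, 3), matrix(0, 2, 3)), "3")
})

test_that("rigid fit agrees with an independent Procrustes solution", {
  skip_if_not_installed("vegan")
  set.seed(9)
  src <- matrix(rnorm(18, sd = 12), 6, 3)
  tgt <- transform_points(rotation_about_axis(c(0.3, 1, 0.2), 28,
                                              point = c(1, 2, 3)), src) +
    matrix(rnorm(18, sd = 0.2), 6, 3)
  fit <- landmark_transform(src, tgt)
  pr <- vegan::procrustes(tgt, src, scale = FALSE, symmetric = FALSE)
  rms_vegan <- sqrt(mean(stats::residuals(pr)^2))
  expect_equal(fit$rms, rms_vegan, tolerance = 1e-6)
})
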