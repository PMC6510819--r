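test_that("isotropic stiffness has its closed form and round-trips", {
  C <- stiffness_isotropic(elastic_isotropic(1, 0))
  expect_equal(C, diag(c(1, 1, 1, 0.5, 0.5, 0.5)), tolerance = 1e-14)
  Cc <- stiffness_isotropic(elastic_isotropic(13, 0.42))
  expect_true(all(eigen(Cc, symmetric = TRUE, only.values = TRUE)$values > 0))
  ## inverse equals the compliance closed form
  E <- 13; nu <- 0.42
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- -nu / E
  diag(S)[1:3] <- 1 / E
  diag(S)[4:6] <- 2 * (1 + nu) / E
  expect_equal(solve(Cc), S, tolerance = 1e-12)
})

test_that("transversely isotropic stiffness reduces to the isotropic limit", {
  E <- 20; nu <- 0.2; G <- E / (2 * (1 + nu))
  m <- elastic_transverse_isotropic(E_p = E, nu_p = nu, G_p = G,
                                    E_f = E, nu_f = nu, G_f = G)
  f <- c(0.3, 0.5, sqrt(1 - 0.09 - 0.25))
  expect_equal(stiffness_transverse_isotropic(m, f),
               stiffness_isotropic(elastic_isotropic(E, nu)), tolerance = 1e-10)
})

test_that("meniscal constants give an admissible, nearly consistent material", {
  m <- elastic_transverse_isotropic()        # 20/0.2/8.3, 150/0.3/57.7
  C <- stiffness_transverse_isotropic(m, c(1, 0, 0))
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  ## printed in-plane shear modulus vs the exact transverse-isotropy value
  expect_lt(abs(m$G_p - m$E_p / (2 * (1 + m$nu_p))) / m$G_p, 0.005)
  expect_error(elastic_transverse_isotropic(nu_f = 2),
               "positive definite")
})

test_that("fiber rotation acts as the Voigt congruence transformation", {
  ## an exactly transversely isotropic sample: the in-plane axis choice is
  ## then immaterial and the two routes must agree to round-off
  m <- elastic_transverse_isotropic(G_p = 20 / (2 * 1.2))
  R <- rotation_about_axis(c(1, 2, 3), 37)$R
  C_rot <- stiffness_transverse_isotropic(m, as.numeric(R %*% c(1, 0, 0)))
  M <- kneefem:::voigt_rotation_matrix(R)
  C_cong <- M %*% stiffness_transverse_isotropic(m, c(1, 0, 0)) %*% t(M)
  expect_equal(C_rot, C_cong, tolerance = 1e-10)
})

test_that("both stiffness builders return symmetric positive work forms", {
  mats <- list(stiffness_isotropic(elastic_isotropic(13, 0.42)),
               stiffness_transverse_isotropic(elastic_transverse_isotropic(),
                                              c(0, 1, 0)))
  set.seed(21)
  for (C in mats) {
    expect_lt(max(abs(C - t(C))), 1e-12)
    eps <- matrix(rnorm(6 * 1000), 1000, 6)
    w <- rowSums((eps %*% C) * eps)
    expect_true(all(w > 0))
  }
})

test_that("principal stresses sort eigenvalues and respect invariants", {
  expect_equal(principal_stresses(diag(c(3, 1, 2))), c(3, 2, 1))
  expect_equal(principal_stresses(diag(3) * -2.5), rep(-2.5, 3))
  set.seed(31)
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3, 3); S <- (A + t(A)) / 2
    p <- principal_stresses(S)
    expect_equal(p, sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE),
                 tolerance = 1e-10)
    expect_equal(sum(p), sum(diag(S)), tolerance = 1e-10)
  }
})

test_that("vectorised principal stresses match the eigensolver", {
  set.seed(41)
  V <- matrix(rnorm(6 * 300, sd = 3), 300, 6)
  many <- principal_stresses_many(V)
  for (i in sample(300, 40)) {
    expect_equal(many[i, ], principal_stresses(V[i, ]), tolerance = 1e-8)
  }
  ## frame invariance: rotate then solve equals solve then sort
  R <- rotation_about_axis(c(1, 0.4, -1), 63)$R
  M <- kneefem:::voigt_rotation_matrix(R)
  Vr <- V %*% t(M)
  expect_equal(principal_stresses_many(Vr), many, tolerance = 1e-8)
})
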