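test_that("quadric evaluation matches a term-by-term monomial sum", {
  # brute-force oracle: sum the ten monomials one by one
  monomial_sum <- function(cf, p) {
    cf <- as.numeric(cf)
    terms <- c(p[1]^2, p[1] * p[2], p[1] * p[3], p[1], p[2]^2,
               p[2] * p[3], p[2], p[3]^2, p[3], 1)
    s <- 0
    for (k in 1:10) s <- s + cf[k] * terms[k]
    s
  }
  for (seed in 1:20) {
    cf <- rand_quadric(seed)
    p <- as.numeric(rand_points(1, seed + 100))
    expect_equal(evaluate_quadric(cf, p), monomial_sum(cf, p),
                 tolerance = 1e-12)
  }
  # unit sphere: on-surface zero, interior negative
  s <- quadric_coefficients(c(1, 0, 0, 0, 1, 0, 0, 1, 0, -1))
  expect_equal(evaluate_quadric(s, c(1, 0, 0)), 0)
  expect_lt(evaluate_quadric(s, c(0, 0, 0)), 0)
})

test_that("normalization fixes scale and sign; trivial solution excluded", {
  for (seed in 1:10) {
    cf <- rand_quadric(seed)
    expect_equal(sum(cf^2), 1, tolerance = 1e-14)
    expect_gte(cf[["a33"]], 0)
  }
  expect_error(quadric_coefficients(rep(0, 10)), "trivial")
  expect_error(quadric_coefficients(1:5), "10 coefficients")
  # sign rule falls through to the first nonzero second-order term
  cf <- quadric_coefficients(c(-2, 0, 0, 1, 0, 0, 0, 0, 0, 3))
  expect_gt(cf[["a11"]], 0)
})

test_that("algebraic fitness is the mean squared residual, scale-quadratic", {
  for (seed in 1:5) {
    cf <- rand_quadric(seed)
    p <- rand_points(5, seed + 50)
    acc <- 0
    for (i in 1:5) acc <- acc + evaluate_quadric(cf, p[i, ])^2
    expect_equal(algebraic_fitness(cf, p), acc / 5, tolerance = 1e-12)
    # Q(k a) = k Q(a) pointwise, so the fitness scales as k^2
    k <- 3.7
    expect_equal(algebraic_fitness(k * as.numeric(cf), p),
                 k^2 * algebraic_fitness(cf, p), tolerance = 1e-10)
  }
  expect_error(algebraic_fitness(rand_quadric(1), matrix(0, 0, 3)),
               "empty")
  # points exactly on the surface give zero fitness
  tc <- test_cloud()
  expect_lt(algebraic_fitness(tc$truth$coefficients, tc$cloud), 1e-28)
})

test_that("elevation solving picks the branch nearest the reference", {
  # sphere x^2 + y^2 + z^2 = 100
  s <- quadric_coefficients(c(1, 0, 0, 0, 1, 0, 0, 1, 0, -100))
  expect_equal(solve_elevation(s, 0, 0, z_ref = 9)$z, 10)
  expect_equal(solve_elevation(s, 0, 0, z_ref = -9)$z, -10)
  # tangent: (6, 8) touches at z = 0 (double root)
  expect_equal(solve_elevation(s, 6, 8, z_ref = 1)$z, 0)
  # outside the sphere: no real root
  out <- solve_elevation(s, 11, 0, z_ref = 0)
  expect_false(out$ok)
  expect_true(is.na(out$z))
  # linear case: plane-like quadric a33 = 0, x^2 - z = 0
  lin <- quadric_coefficients(c(1, 0, 0, 0, 0, 0, 0, 0, -1, 0))
  expect_equal(solve_elevation(lin, 2, 0, z_ref = 0)$z, 4,
               tolerance = 1e-12)
  # random ellipsoid: on-surface nodes are recovered exactly
  tc <- test_cloud()
  p <- tc$cloud$points
  sol <- solve_elevation(tc$truth$coefficients, p[, 1], p[, 2],
                         z_ref = p[, 3])
  expect_true(all(sol$ok))
  expect_lt(max(abs(sol$z - p[, 3])), 1e-10)
})

test_that("elevation MSE: exact fit, constant offset, noise expectation", {
  tc <- test_cloud()
  em <- elevation_mse(tc$truth$coefficients, tc$cloud)
  expect_lt(em$mse, 1e-18)
  expect_equal(em$unresolved, 0L)
  # shifting every measured elevation by delta makes the MSE delta^2
  delta <- 0.013
  shifted <- tc$cloud$points
  shifted[, 3] <- shifted[, 3] + delta
  expect_equal(elevation_mse(tc$truth$coefficients, shifted)$mse, delta^2,
               tolerance = 1e-6)
  # Gaussian noise of SD sigma gives MSE ~ sigma^2 (N = 6144)
  sigma <- 0.005
  syn <- make_ellipsoid_grid(synthetic_spec(noise_sigma = sigma,
                                            seed = 21))
  noisy <- polar_to_cartesian(syn$grid)
  expect_equal(elevation_mse(syn$truth$coefficients, noisy)$mse, sigma^2,
               tolerance = 0.2)
})

test_that("elevation MSE is invariant to rotation about the optical axis", {
  tc <- test_cloud(noise_sigma = 0.004)
  cf <- fit_direct_linear(tc$cloud)$coefficients
  base <- elevation_mse(cf, tc$cloud)$mse
  phi <- 0.83
  Rz <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1),
               3, 3)
  rot_cloud <- tc$cloud$points %*% t(Rz)
  # rotate the quadric with the cloud: A -> R A R', b -> R b
  m <- corneaga:::quadric_matrices(cf)
  cf_rot <- corneaga:::quadric_from_matrices(Rz %*% m$A %*% t(Rz),
                                             as.numeric(Rz %*% m$b), m$k)
  expect_equal(elevation_mse(cf_rot, rot_cloud)$mse, base,
               tolerance = 1e-10)
})
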