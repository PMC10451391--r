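test_that("ground truth is self-consistent and exactly recoverable", {
  sp <- synthetic_spec(Rx = 7.8, Ry = 7.8, Qx = -0.3, Qy = -0.3)
  syn <- make_ellipsoid_grid(sp)
  tr <- syn$truth
  expect_equal(tr$morpho$Qx, -0.3)
  expect_equal(tr$morpho$Rx, 7.8)
  m2 <- morpho_parameters(to_canonical_ellipsoid(tr$coefficients))
  expect_equal(unlist(m2), unlist(tr$morpho), tolerance = 1e-10)
  # the noiseless cloud lies exactly on the truth quadric
  d <- fit_direct_linear(polar_to_cartesian(syn$grid))
  expect_lt(coef_dev(d$coefficients, tr$coefficients), 1e-8)
})

test_that("mismatched meridian c-axes share the geometric-mean axis", {
  sp <- synthetic_spec(Rx = 7.8, Ry = 7.4, Qx = -0.3, Qy = -0.2)
  syn <- make_ellipsoid_grid(sp)
  tr <- syn$truth
  c0 <- sqrt((7.8 / 0.7) * (7.4 / 0.8))
  expect_equal(tr$ellipsoid$semi_axes[3], c0)
  # radii are preserved, asphericities recomputed from realized axes
  expect_equal(tr$morpho$Rx, 7.8)
  expect_equal(tr$morpho$Ry, 7.4)
  expect_equal(tr$morpho$Qx, 7.8 / c0 - 1)
  m2 <- morpho_parameters(to_canonical_ellipsoid(tr$coefficients))
  expect_equal(unlist(m2), unlist(tr$morpho), tolerance = 1e-10)
})

test_that("dropout is exact in count, reproducible, and mode-shaped", {
  sp <- synthetic_spec(dropout_fraction = 0.3, seed = 17)
  g1 <- make_ellipsoid_grid(sp)$grid
  g2 <- make_ellipsoid_grid(sp)$grid
  expect_identical(g1$elevations, g2$elevations)
  expect_equal(sum(g1$elevations == -1000), floor(0.3 * 6144))
  # wedge mode blanks whole contiguous meridian columns
  gw <- make_ellipsoid_grid(synthetic_spec(dropout_fraction = 0.25,
                                           dropout_mode = "wedge",
                                           seed = 4))$grid
  blanked <- which(colSums(gw$elevations == -1000) == 24)
  expect_equal(length(blanked), round(0.25 * 256))
  expect_true(all(diff(blanked) == 1) ||
                sum(diff(blanked) != 1) == 1)  # contiguous modulo wrap
  # ring mode blanks the outermost rings
  gr <- make_ellipsoid_grid(synthetic_spec(dropout_fraction = 0.25,
                                           dropout_mode = "ring",
                                           seed = 4))$grid
  expect_true(all(gr$elevations[19:24, ] == -1000))
  expect_true(all(gr$elevations[1:18, ] != -1000))
})

test_that("elevation noise has the prescribed variance", {
  sigma <- 0.005
  sp_noisy <- synthetic_spec(noise_sigma = sigma, seed = 31)
  sp_clean <- synthetic_spec(noise_sigma = 0, seed = 31)
  zn <- make_ellipsoid_grid(sp_noisy)$grid$elevations
  zc <- make_ellipsoid_grid(sp_clean)$grid$elevations
  dz <- (zn - zc)[zc != -1000]
  expect_gte(length(dz), 4000)
  expect_equal(var(dz), sigma^2, tolerance = 0.1)
})

test_that("cone deformation: identity, locality, monotone distortion", {
  syn <- make_ellipsoid_grid(synthetic_spec())
  g0 <- syn$grid
  expect_equal(add_cone(g0, 0, 1.5)$elevations, g0$elevations)
  far <- add_cone(g0, 0.05, 0.5, center = c(50, 50))
  expect_lt(max(abs(far$elevations - g0$elevations)), 1e-12)
  # true-surface MSE grows monotonically with cone amplitude
  mses <- vapply(c(0.01, 0.02, 0.05, 0.1), function(a) {
    gb <- add_cone(g0, a, 1.5, center = c(1, -1))
    elevation_mse(syn$truth$coefficients, polar_to_cartesian(gb))$mse
  }, numeric(1))
  expect_true(all(diff(mses) > 0))
})

test_that("cohorts are deterministic, graded, and format-conformant", {
  c1 <- make_cohort(4, "control", seed = 9)
  c2 <- make_cohort(4, "control", seed = 9)
  expect_identical(lapply(c1, function(x) x$grid$elevations),
                   lapply(c2, function(x) x$grid$elevations))
  ak <- make_cohort(6, "AK34", seed = 9)
  q_ctrl <- mean(vapply(c1, function(x) x$truth$morpho$Qx, numeric(1)))
  q_ak <- mean(vapply(ak, function(x) x$truth$morpho$Qx, numeric(1)))
  expect_lt(q_ak, q_ctrl)
  # every cohort grid survives a CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  for (case in c1[1:2]) {
    write_polar_csv(case$grid, f)
    expect_identical(read_polar_csv(f)$elevations, case$grid$elevations)
  }
  # truth sidecar round-trips the key fields
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_synthetic_case(c1[[1]], f2)
  side <- jsonlite::read_json(sub("\\.csv$", ".truth.json", f2),
                              simplifyVector = TRUE)
  expect_equal(side$morpho$Rx, c1[[1]]$truth$morpho$Rx)
  expect_equal(side$group, "control")
})
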