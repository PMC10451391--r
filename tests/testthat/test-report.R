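test_that("FQN aggregation equals the brute-force failure count", {
  expect_equal(aggregate_fqn(as.list(c(0L, 0L, 0L))), 0L)
  expect_equal(aggregate_fqn(as.list(c(1L, 0L, 1L))), 2L)
  set.seed(14)
  for (rep in 1:5) {
    flags <- sample(0:1, 25, replace = TRUE)
    count <- 0L
    for (f in flags) if (f == 1L) count <- count + 1L
    expect_equal(aggregate_fqn(as.list(flags)), count)
    expect_lte(aggregate_fqn(as.list(flags)), length(flags))
  }
  expect_error(aggregate_fqn(list()), "no results")
  expect_error(aggregate_fqn(list(2L)), "0 or 1")
})

test_that("method comparison table has a stable, machine-readable schema", {
  tc <- test_cloud()
  tab <- compare_methods(list(tc$grid), methods = "LSQ")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$method, "LSQ")
  expect_lt(tab$mse_mean, 1e-12)
  expect_identical(names(tab),
                   c("method", "group", "n", "mse_mean", "mse_sd", "fqn",
                     "Rx_mean", "Rx_sd", "Ry_mean", "Ry_sd", "Qx_mean",
                     "Qx_sd", "Qy_mean", "Qy_sd", "n_failed"))
  # a grid a method cannot fit is recorded, not fatal
  tiny <- polar_elevation_grid({
    m <- matrix(-1000, 24, 256); m[1, 1:8] <- 0.1; m
  })
  tab2 <- compare_methods(list(tc$grid, list(grid = tiny)),
                          methods = c("LSQ", "DIRECT"))
  expect_equal(unique(tab2$n_failed), 1L)
  expect_equal(nrow(tab2), 2L)
  cases <- attr(tab2, "cases")
  expect_equal(sum(cases$failed), 2L)
})

test_that("comparison groups mixed cohorts and writes CSV", {
  cohort <- c(make_cohort(2, "control", seed = 5),
              make_cohort(2, "AK2", seed = 6))
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- compare_methods(cohort, methods = c("LSQ", "DIRECT"),
                         seed = 2, path = f)
  expect_equal(nrow(tab), 4L)  # 2 methods x 2 groups
  expect_setequal(unique(tab$group), c("control", "AK2"))
  expect_true(file.exists(f))
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 4L)
})

test_that("STL export writes on-surface, upward-facing Delaunay meshes", {
  tc <- test_cloud()
  d <- fit_direct_linear(tc$cloud)
  f <- withr::local_tempfile(fileext = ".stl")
  p <- export_stl(d$coefficients, footprint_radius = 4, resolution = 24L,
                  path = f)
  n <- 24L^2
  expect_equal(attr(p, "n_vertices"), n)
  # double-precision samples sit on the implicit surface
  e <- to_canonical_ellipsoid(d$coefficients)
  xy <- corneaga:::sunflower_disc(n, 4, e$center[1:2])
  sol <- solve_elevation(d$coefficients, xy[, 1], xy[, 2],
                         z_ref = e$center[3] + 10 * max(e$semi_axes))
  expect_lt(max(abs(evaluate_quadric(d$coefficients,
                                     cbind(xy, sol$z)))), 1e-8)
  # triangle count agrees with the Euler bound 2n - 2 - hull for Delaunay
  hull <- length(grDevices::chull(xy))
  expect_equal(attr(p, "n_triangles"), 2L * n - 2L - hull)
  stl <- read_binary_stl(f)
  expect_equal(stl$n_triangles, attr(p, "n_triangles"))
  expect_true(all(stl$normals[, 3] > 0))
  # float32 storage keeps vertices within quantization of the surface
  v <- rbind(stl$vertices[, 1, ], stl$vertices[, 2, ],
             stl$vertices[, 3, ])
  expect_lt(max(abs(evaluate_quadric(d$coefficients, v))), 1e-5)
  expect_error(export_stl(d$coefficients, footprint_radius = 20,
                          resolution = 8L, path = f),
               "beyond the surface")
})

test_that("Delaunay triangulation matches brute-force circumcircle checks", {
  set.seed(19)
  xy <- cbind(runif(60), runif(60))
  tri <- delaunay_triangulate(xy)
  expect_equal(nrow(tri), 2L * 60L - 2L - length(grDevices::chull(xy)))
  # no point lies strictly inside any triangle's circumcircle
  for (t in seq_len(nrow(tri))) {
    cc <- corneaga:::circumcircle(xy[tri[t, 1], 1], xy[tri[t, 1], 2],
                                  xy[tri[t, 2], 1], xy[tri[t, 2], 2],
                                  xy[tri[t, 3], 1], xy[tri[t, 3], 2])
    d2 <- (xy[, 1] - cc$x)^2 + (xy[, 2] - cc$y)^2
    expect_equal(sum(d2 < cc$r2 * (1 - 1e-9)), 0L)
  }
  expect_error(delaunay_triangulate(xy[1:2, ]), "at least 3")
})

test_that("command-line interface: simulate, fit, compare, export", {
  dir <- withr::local_tempdir()
  expect_equal(corneaga_cli(c("simulate", "--preset", "control",
                              "--n", "3", "--seed", "1",
                              "--out", dir)), 0L)
  expect_length(list.files(dir, pattern = "\\.csv$"), 3L)
  expect_length(list.files(dir, pattern = "truth\\.json$"), 3L)
  # deterministic fit: same seed twice gives byte-identical JSON
  csv1 <- file.path(dir, "case_control_001.csv")
  j1 <- file.path(dir, "a.json"); j2 <- file.path(dir, "b.json")
  expect_equal(corneaga_cli(c("fit", "--input", csv1, "--method", "lsq",
                              "--seed", "4", "--out", j1)), 0L)
  expect_equal(corneaga_cli(c("fit", "--input", csv1, "--method", "lsq",
                              "--seed", "4", "--out", j2)), 0L)
  expect_identical(readBin(j1, "raw", file.size(j1)),
                   readBin(j2, "raw", file.size(j2)))
  cmp <- file.path(dir, "cmp.csv")
  expect_equal(corneaga_cli(c("compare", "--input", dir, "--methods",
                              "lsq,direct", "--seed", "1",
                              "--out", cmp)), 0L)
  tab <- utils::read.csv(cmp)
  expect_equal(nrow(tab), 2L)  # 2 methods x 1 group
  stl <- file.path(dir, "cap.stl")
  expect_equal(corneaga_cli(c("export", "--fit", j1, "--radius", "4",
                              "--resolution", "12", "--out", stl)), 0L)
  expect_gt(file.size(stl), 84)
  # unknown subcommand and missing flags exit nonzero
  expect_equal(suppressMessages(corneaga_cli("frobnicate")), 1L)
  expect_equal(suppressMessages(corneaga_cli("fit")), 1L)
  # the installed wrapper script exists and is a plain Rscript shim
  shim <- system.file("cli", "corneaga", package = "corneaga")
  expect_true(nzchar(shim))
  expect_match(readLines(shim)[1], "Rscript")
})
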