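# Shared fixtures: everything is generated in code at test time.

# A random unit-norm quadric coefficient vector (not necessarily an
# ellipsoid; used for algebraic identities only).
rand_quadric <- function(seed) {
  set.seed(seed)
  quadric_coefficients(stats::rnorm(10))
}

rand_points <- function(n, seed, box = 5) {
  set.seed(seed)
  matrix(stats::runif(3 * n, -box, box), n, 3L)
}

# Small polar geometry for fast GA unit tests: 12 x 64 nodes, 0.4 mm ring
# spacing so the cap still spans the full 4.8 mm aperture (the default
# 24 x 256 grid is reserved for the acceptance checks).
small_dialect <- function() polar_grid_dialect(n_rings = 12L,
                                               n_meridians = 64L,
                                               ring_spacing_mm = 0.4)

small_ga <- function(seed = 1L, ...) {
  ga_config(pop_per_variable = 40L, max_generations = 150L,
            stall_generations = 30L, seed = seed, ...)
}

# Noiseless cloud of a mildly astigmatic prolate cornea.
test_cloud <- function(dialect = polar_grid_dialect(), ...) {
  args <- utils::modifyList(list(Rx = 7.8, Ry = 7.6, Qx = -0.3,
                                 Qy = -0.25), list(...))
  syn <- make_ellipsoid_grid(do.call(synthetic_spec, args),
                             dialect = dialect)
  list(cloud = polar_to_cartesian(syn$grid), truth = syn$truth,
       grid = syn$grid)
}

# Coefficient comparison up to the canonical sign (both vectors unit norm).
coef_dev <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  min(max(abs(a - b)), max(abs(a + b)))
}
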