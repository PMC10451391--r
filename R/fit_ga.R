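#' Genetic algorithm configuration
#'
#' Defaults follow the published CORNEAGA settings: 100 individuals per
#' variable (10 variables, hence 1000 individuals per generation), crossover
#' rate 0.8, cloning (survival) rate 0.2, mutation rate 0, and a stopping
#' tolerance of 1e-50 on the objective and constraints.  The tolerance is
#' below double-precision resolution, so termination is additionally
#' guaranteed by a stall window and a generation cap.
#'
#' @param pop_per_variable individuals per variable.
#' @param n_variables number of genes (10 quadric coefficients).
#' @param crossover_rate fraction of the population produced by crossover.
#' @param survival_rate fraction of elites cloned unchanged.
#' @param mutation_rate per-gene Gaussian mutation probability (default 0).
#' @param function_tolerance,constraint_tolerance stopping tolerances.
#' @param max_generations generation cap.
#' @param stall_generations stall window for the tolerance test.
#' @param gene_bounds per-gene interval in preconditioned coordinates.
#' @param seed RNG seed.
#' @param selection tournament selection, size 2 (the only option).
#' @param crossover blend (BLX-alpha) crossover (the only option).
#' @param blend_alpha BLX-alpha expansion factor.
#' @param penalty_nodes size of the coarse node subsample used for the
#'   unresolved-node steering penalty inside the GA loop.
#' @param warm_start start the population around the direct-linear solution
#'   instead of uniformly at random (off by default, so the GA's own search
#'   is what is being exercised).
#' @return a `ga_config` list, serializable with [write_ga_config()].
#' @export
ga_config <- function(pop_per_variable = 100L, n_variables = 10L,
                      crossover_rate = 0.8, survival_rate = 0.2,
                      mutation_rate = 0,
                      function_tolerance = 1e-50,
                      constraint_tolerance = 1e-50,
                      max_generations = 300L, stall_generations = 50L,
                      gene_bounds = c(-1, 1), seed = 1L,
                      selection = "tournament_k2",
                      crossover = "blend_alpha", blend_alpha = 0.5,
                      penalty_nodes = 384L, warm_start = FALSE) {
  stopifnot(pop_per_variable >= 1L, n_variables >= 1L,
            crossover_rate >= 0, survival_rate >= 0,
            crossover_rate + survival_rate <= 1 + 1e-12,
            mutation_rate >= 0, mutation_rate <= 1,
            max_generations >= 1L, stall_generations >= 1L,
            length(gene_bounds) == 2L, gene_bounds[1L] < gene_bounds[2L])
  selection <- match.arg(selection, "tournament_k2")
  crossover <- match.arg(crossover, "blend_alpha")
  structure(list(pop_per_variable = as.integer(pop_per_variable),
                 n_variables = as.integer(n_variables),
                 crossover_rate = crossover_rate,
                 survival_rate = survival_rate,
                 mutation_rate = mutation_rate,
                 function_tolerance = function_tolerance,
                 constraint_tolerance = constraint_tolerance,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 gene_bounds = as.numeric(gene_bounds),
                 seed = as.integer(seed),
                 selection = selection, crossover = crossover,
                 blend_alpha = blend_alpha,
                 penalty_nodes = as.integer(penalty_nodes),
                 warm_start = isTRUE(warm_start)),
            class = "ga_config")
}

#' Serialize / restore a GA configuration as YAML
#'
#' @param config a [ga_config()].
#' @param path file path.
#' @return `path` / a `ga_config`.
#' @export
write_ga_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_ga_config
#' @export
read_ga_config <- function(path) {
  do.call(ga_config, yaml::read_yaml(path))
}

# Rows projected to the unit sphere (the constraint of the algebraic
# problem; enforced by projection after every operator).
renorm_rows <- function(P) P / sqrt(rowSums(P^2))

# BLX-alpha blend crossover, before bound clipping and norm projection:
# each offspring gene is uniform on [min - alpha*d, max + alpha*d] where d
# is the per-gene parent spread.  With alpha = 0 offspring genes lie inside
# the parents' per-gene interval.
blend_offspring <- function(u, v, alpha) {
  lo <- pmin(u, v); hi <- pmax(u, v)
  d <- hi - lo
  lo - alpha * d + matrix(stats::runif(length(d)), nrow(u)) *
    (1 + 2 * alpha) * d
}

# Ellipsoid-signature feasibility of each gene vector, via Sylvester's
# criterion on the quadratic-form matrix (positive- or negative-definite
# <=> all leading principal minors of the right sign).  Closed-form, so it
# vectorizes over the whole population.
ellipsoid_signature <- function(pop) {
  a11 <- pop[, 1L]; a12 <- pop[, 2L]; a13 <- pop[, 3L]
  a22 <- pop[, 5L]; a23 <- pop[, 6L]; a33 <- pop[, 8L]
  m1 <- a11
  m2 <- a11 * a22 - a12^2 / 4
  m3 <- a11 * (a22 * a33 - a23^2 / 4) -
    (a12 / 2) * (a12 * a33 / 2 - a23 * a13 / 4) +
    (a13 / 2) * (a12 * a23 / 4 - a22 * a13 / 2)
  (m1 > 0 & m2 > 0 & m3 > 0) | (m1 < 0 & m2 > 0 & m3 < 0)
}

# Population fitness: exact mean squared algebraic residual via the 10x10
# normal matrix, plus two constraint terms implementing feasibility
# ranking: individuals whose quadratic form does not have an ellipsoid
# signature (the corneal-validity constraint), and individuals that miss
# data columns (no real elevation root; checked on a coarse fixed node
# subsample, scaled to the full cloud), are pushed below every feasible
# individual.
ga_fitness <- function(pop, M, pen) {
  f <- rowSums((pop %*% M) * pop)
  if (!is.null(pen)) {
    f <- f + ifelse(ellipsoid_signature(pop), 0, pen$unit)
    A33 <- pop[, 8L]
    B <- pen$Xb %*% t(pop[, c(3L, 6L, 9L), drop = FALSE])
    C <- pen$Xc %*% t(pop[, c(1L, 2L, 4L, 5L, 7L, 10L), drop = FALSE])
    disc <- B^2 - 4 * sweep(C, 2L, A33, "*")
    quad <- abs(A33) >= 1e-14
    miss <- colSums(disc < 0)
    miss[!quad] <- colSums(abs(B[, !quad, drop = FALSE]) < 1e-12)
    f <- f + (miss / nrow(pen$Xb)) * pen$unit
  }
  f
}

#' Advance one GA generation
#'
#' Builds the next population from the current one: the top
#' `ceiling(survival_rate * P)` elites are cloned unchanged,
#' `ceiling(crossover_rate * P)` offspring are produced by BLX-alpha blend
#' crossover of tournament-selected (k = 2) parents, and any remainder is
#' filled with tournament-selected clones.  Offspring genes are clipped to
#' the gene bounds and every vector is re-projected to unit norm.  Elitism
#' makes the best fitness non-increasing across generations.  Uses the
#' caller's RNG stream.
#'
#' @param population P x n matrix of unit-norm gene vectors.
#' @param fitnesses length-P fitness values (lower is better).
#' @param config a [ga_config()].
#' @return the next P x n population matrix.
#' @export
evolve_generation <- function(population, fitnesses, config) {
  P <- nrow(population)
  stopifnot(length(fitnesses) == P)
  n_elite <- min(P, ceiling(config$survival_rate * P))
  n_cross <- min(P - n_elite, ceiling(config$crossover_rate * P))
  n_fill <- P - n_elite - n_cross
  ord <- order(fitnesses)
  tournament <- function(k) {
    if (k == 0L) return(integer(0))
    i <- sample.int(P, k, replace = TRUE)
    j <- sample.int(P, k, replace = TRUE)
    ifelse(fitnesses[i] <= fitnesses[j], i, j)
  }
  parts <- list(population[ord[seq_len(n_elite)], , drop = FALSE])
  if (n_cross > 0L) {
    u <- population[tournament(n_cross), , drop = FALSE]
    v <- population[tournament(n_cross), , drop = FALSE]
    off <- blend_offspring(u, v, config$blend_alpha)
    off <- pmin(pmax(off, config$gene_bounds[1L]), config$gene_bounds[2L])
    if (config$mutation_rate > 0) {
      hit <- matrix(stats::runif(length(off)) < config$mutation_rate,
                    n_cross)
      off[hit] <- off[hit] + stats::rnorm(sum(hit), 0,
                                          0.1 * diff(config$gene_bounds))
      off <- pmin(pmax(off, config$gene_bounds[1L]),
                  config$gene_bounds[2L])
    }
    parts <- c(parts, list(renorm_rows(off)))
  }
  if (n_fill > 0L)
    parts <- c(parts, list(population[tournament(n_fill), , drop = FALSE]))
  do.call(rbind, parts)
}

#' Stopping rule for the GA
#'
#' Stops when the best fitness has improved by less than
#' `function_tolerance` over the last `stall_generations` generations, or
#' when the generation cap is reached.
#'
#' @param history best fitness per generation so far.
#' @param config a [ga_config()].
#' @return list with `stop` (logical) and `reason`
#'   (`"tolerance"`, `"max_generations"` or `"none"`).
#' @export
stopping_check <- function(history, config) {
  g <- length(history)
  stopifnot(g >= 1L)
  if (g >= config$max_generations)
    return(list(stop = TRUE, reason = "max_generations"))
  if (g > config$stall_generations) {
    gain <- history[g - config$stall_generations] - history[g]
    if (gain < config$function_tolerance)
      return(list(stop = TRUE, reason = "tolerance"))
  }
  list(stop = FALSE, reason = "none")
}

#' Fit a corneal quadric with the CORNEAGA genetic algorithm
#'
#' The evolutionary fitter: an elitist real-coded multivariable GA over the
#' ten quadric coefficients, minimizing the mean squared algebraic residual
#' of the implicit surface over the point cloud under a unit-norm
#' constraint (enforced by projection, so the trivial zero solution is
#' excluded without pinning any coefficient).  Because every individual is
#' a complete candidate surface, the search is insensitive to gaps and
#' local discontinuities in the data that destabilize local descent
#' methods.  The cloud is preconditioned (centered, scaled to unit radius)
#' and the winning coefficients are mapped back analytically.
#'
#' @param cloud a [point_cloud()] or N x 3 matrix (>= 10 points after
#'   sentinel removal).
#' @param config a [ga_config()]; `config$seed` makes the run
#'   bit-reproducible.
#' @return a `corneal_fit` with `method_tag = "CORNEAGA"`: unit-norm
#'   coefficients, elevation MSE (mm^2), generation count, convergence flag
#'   (`TRUE` when stopped by the tolerance/stall rule rather than the
#'   generation cap), the quadric-order flag `fq` and the seed used.
#' @export
#' @examples
#' \donttest{
#' syn <- make_ellipsoid_grid(synthetic_spec(noise_sigma = 0.003))
#' cloud <- polar_to_cartesian(syn$grid)
#' fit <- fit_nsmvga(cloud, ga_config(seed = 7))
#' morpho_parameters(to_canonical_ellipsoid(fit$coefficients))
#' }
fit_nsmvga <- function(cloud, config = ga_config()) {
  p <- check_cloud_for_fit(cloud)
  N <- nrow(p)
  pre <- precondition_cloud(p)
  D <- design_matrix(pre$points)
  M <- crossprod(D) / N
  # coarse penalty subsample: deterministic stride over the cloud
  np <- min(config$penalty_nodes, N)
  idx <- unique(round(seq(1L, N, length.out = np)))
  zr <- diff(range(pre$points[, 3L]))
  pen <- list(Xb = cbind(pre$points[idx, 1L], pre$points[idx, 2L], 1),
              Xc = cbind(pre$points[idx, 1L]^2,
                         pre$points[idx, 1L] * pre$points[idx, 2L],
                         pre$points[idx, 1L],
                         pre$points[idx, 2L]^2,
                         pre$points[idx, 2L], 1),
              unit = (2 * zr)^2)
  P <- config$pop_per_variable * config$n_variables
  nv <- config$n_variables
  res <- with_seed(config$seed, {
    if (config$warm_start) {
      base <- as.numeric(svd(D)$v[, 10L])
      pop <- matrix(rep(base, each = P), P) +
        matrix(stats::rnorm(P * nv, 0, 0.05), P)
    } else {
      pop <- matrix(stats::runif(P * nv, config$gene_bounds[1L],
                                 config$gene_bounds[2L]), P)
    }
    pop <- renorm_rows(pop)
    fit <- ga_fitness(pop, M, pen)
    history <- min(fit)
    repeat {
      sc <- stopping_check(history, config)
      if (sc$stop) break
      pop <- evolve_generation(pop, fit, config)
      fit <- ga_fitness(pop, M, pen)
      history <- c(history, min(fit))
    }
    list(best = pop[which.min(fit), ], history = history,
         reason = sc$reason)
  })
  cf <- transform_quadric(quadric_coefficients(res$best),
                          pre$center, pre$scale, to = "data")
  out <- fit_result(cf, p, "CORNEAGA",
                    generations = length(res$history),
                    converged = identical(res$reason, "tolerance"),
                    seed = config$seed)
  out$history <- res$history
  out
}
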