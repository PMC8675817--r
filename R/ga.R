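#' Genetic-algorithm configuration
#'
#' Settings for the real-coded GA used to optimize the MPC move sequence.
#' Defaults follow the benchmark tuning: population 100, 10 generations,
#' crossover probability 0.7, per-gene mutation probability 0.005, full
#' generational replacement with one elite individual.
#'
#' @param population population size (>= 2).
#' @param generations number of generations (>= 1).
#' @param p_crossover crossover probability in \[0, 1\].
#' @param p_mutation per-gene mutation probability in \[0, 1\].
#' @param elite number of elite individuals copied unchanged each generation.
#' @param seed optional integer; when given, [ga_optimize()] seeds the RNG
#'   itself, otherwise it consumes the ambient RNG stream.
#' @return an object of class \code{ga_config}.
#' @export
ga_config <- function(population = 100L, generations = 10L,
                      p_crossover = 0.7, p_mutation = 0.005,
                      elite = 1L, seed = NULL) {
  abort_if(population < 2, "'population' must be >= 2")
  abort_if(generations < 1, "'generations' must be >= 1")
  for (p in c(p_crossover, p_mutation)) {
    abort_if(!is_scalar_num(p) || p < 0 || p > 1, "probabilities must lie in [0, 1]")
  }
  abort_if(elite < 0 || elite >= population, "'elite' must be in [0, population)")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elite = as.integer(elite), seed = seed),
            class = "ga_config")
}

check_bounds <- function(bounds) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) == 1L) bounds <- t(bounds)
  abort_if(ncol(bounds) != 2L, "'bounds' must be an M x 2 matrix (lower, upper)")
  abort_if(any(!is.finite(bounds)), "bounds must be finite")
  abort_if(any(bounds[, 1] >= bounds[, 2]), "each lower bound must be < upper bound")
  bounds
}

eval_objective <- function(objective, x) {
  v <- objective(x)
  if (!is_scalar_num(v)) {
    stop(paste0("objective returned a non-finite value for chromosome (",
                paste(signif(x, 6), collapse = ", "), ")"), call. = FALSE)
  }
  v
}

# Evaluate a whole population (rows = chromosomes). Objectives carrying
# attr(., "vectorized") = TRUE accept the matrix directly and return one
# cost per row; plain objectives are applied row by row.
eval_population <- function(objective, pop) {
  if (isTRUE(attr(objective, "vectorized"))) {
    v <- objective(pop)
    if (length(v) != nrow(pop) || any(!is.finite(v))) {
      stop("vectorized objective returned an invalid cost vector", call. = FALSE)
    }
    v
  } else {
    apply(pop, 1L, eval_objective, objective = objective)
  }
}

#' Real-coded genetic algorithm
#'
#' Generational GA over a bounded box: tournament selection (size 2),
#' whole-arithmetic (blend) crossover with a uniform per-pair mixing
#' coefficient, additive Gaussian mutation per gene (standard deviation 10%
#' of the gene's bound width, clipped to bounds), and elitism. Any supplied
#' seed candidates are injected into generation 0, so the returned best cost
#' never exceeds theirs. Fully deterministic given the RNG state (or
#' \code{cfg$seed}).
#'
#' @param objective function mapping a chromosome (numeric vector, one gene
#'   per decision variable) to a scalar cost to minimize.
#' @param bounds M x 2 matrix of per-gene (lower, upper) bounds.
#' @param cfg a [ga_config()].
#' @param seeds optional matrix (rows = candidate chromosomes) injected into
#'   the initial population.
#' @return list of class \code{ga_result}: \code{par} (best chromosome),
#'   \code{value} (best cost), \code{trace} (best cost after each generation,
#'   non-increasing when \code{elite >= 1}).
#' @examples
#' res <- ga_optimize(function(x) sum(x^2), rbind(c(-1, 1), c(-1, 1)),
#'                    ga_config(seed = 1))
#' res$value  # near 0
#' @export
ga_optimize <- function(objective, bounds, cfg = ga_config(), seeds = NULL) {
  bounds <- check_bounds(bounds)
  M <- nrow(bounds)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  width <- hi - lo
  np <- cfg$population

  pop <- matrix(runif(np * M, rep(lo, each = np), rep(hi, each = np)), np, M)
  if (!is.null(seeds)) {
    seeds <- matrix(seeds, ncol = M)
    ns <- min(nrow(seeds), np)
    for (i in seq_len(ns)) pop[i, ] <- clip(seeds[i, ], lo, hi)
  }
  fit <- eval_population(objective, pop)

  best_i <- which.min(fit)
  best_par <- pop[best_i, ]; best_val <- fit[best_i]
  trace <- numeric(cfg$generations)

  n_elite <- cfg$elite
  n_off <- np - n_elite
  n_pairs <- ceiling(n_off / 2)
  for (g in seq_len(cfg$generations)) {
    # tournament selection (size 2), all pairs at once
    p1 <- tournament(fit, np, n_pairs)
    p2 <- tournament(fit, np, n_pairs)
    C1 <- pop[p1, , drop = FALSE]; C2 <- pop[p2, , drop = FALSE]
    # whole-arithmetic blend crossover, one mixing coefficient per pair
    xover <- runif(n_pairs) < cfg$p_crossover
    gamma <- runif(n_pairs)
    g1 <- ifelse(xover, gamma, 1)             # gamma = 1 reproduces parents
    B1 <- g1 * C1 + (1 - g1) * C2
    B2 <- (1 - g1) * C1 + g1 * C2
    off <- rbind(B1, B2)[seq_len(n_off), , drop = FALSE]
    # per-gene Gaussian mutation, sd = 10% of the bound width
    mut <- matrix(runif(n_off * M) < cfg$p_mutation, n_off, M)
    if (any(mut)) {
      sd_m <- matrix(0.1 * width, n_off, M, byrow = TRUE)[mut]
      off[mut] <- off[mut] + rnorm(sum(mut), 0, sd_m)
    }
    off <- clip(off, rep(lo, each = n_off), rep(hi, each = n_off))
    if (n_elite > 0L) {
      ord <- order(fit)
      pop <- rbind(pop[ord[seq_len(n_elite)], , drop = FALSE], off)
    } else {
      pop <- off
    }
    fit <- eval_population(objective, pop)
    gi <- which.min(fit)
    if (fit[gi] < best_val) { best_val <- fit[gi]; best_par <- pop[gi, ] }
    trace[g] <- best_val
  }
  structure(list(par = best_par, value = best_val, trace = trace),
            class = "ga_result")
}

# Vectorized tournaments of size 2: returns `n` winner indices.
tournament <- function(fit, np, n) {
  a <- sample.int(np, n, replace = TRUE)
  b <- sample.int(np, n, replace = TRUE)
  ifelse(fit[a] <= fit[b], a, b)
}

#' Best-cost-per-generation trace of a GA run
#'
#' @param result a \code{ga_result} from [ga_optimize()].
#' @return numeric vector, one best cost per generation; monotone
#'   non-increasing whenever elitism is active.
#' @export
convergence_trace <- function(result) {
  abort_if(!inherits(result, "ga_result"), "'result' must be a ga_result")
  result$trace
}

#' Exhaustive grid search over a bounded box
#'
#' Verification oracle: evaluates the objective on a regular grid
#' (\code{points_per_gene} points per gene, bounds included) and returns the
#' argmin. Ties are broken toward the lexicographically smallest chromosome
#' (first gene most significant).
#'
#' @param objective function chromosome -> scalar cost.
#' @param bounds M x 2 matrix of per-gene bounds.
#' @param points_per_gene grid resolution per gene (>= 2).
#' @return list with \code{par} (best chromosome) and \code{value}.
#' @export
grid_oracle <- function(objective, bounds, points_per_gene = 101L) {
  bounds <- check_bounds(bounds)
  abort_if(points_per_gene < 2, "'points_per_gene' must be >= 2")
  M <- nrow(bounds)
  axes <- lapply(seq_len(M), function(i)
    seq(bounds[i, 1], bounds[i, 2], length.out = points_per_gene))
  # lexicographic row order: first gene varies slowest
  grid <- as.matrix(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE))[, M:1, drop = FALSE]
  costs <- eval_population(objective, grid)
  i <- which.min(costs)   # first minimum in lexicographic order
  list(par = unname(grid[i, ]), value = costs[i])
}
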