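#' Configuration for the hybrid GA-PSO optimizer
#'
#' Defaults follow the method's reported settings where stated (population
#' 50; stop when the best fitness varies by less than 1e-5 over 50
#' successive generations) and standard practice elsewhere (constriction
#' PSO coefficients w = 0.729, c1 = c2 = 1.49445).
#'
#' @param pop_size Population size (mu), even and >= 4. Default 50.
#' @param stagnation_window Generations N over which best-fitness
#'   variation is measured. Default 50.
#' @param stagnation_tol Stagnation threshold on that variation.
#'   Default 1e-5.
#' @param stagnation_measure `"range"` (max - min of the window, default)
#'   or `"delta"` (largest successive change).
#' @param mutation_rate Per-gene mutation probability in (0, 1\].
#'   Default 0.05.
#' @param mutation_scale Standard deviation of the additive gaussian
#'   mutation. Default 0.1.
#' @param elitism Carry the incumbent best unchanged into each new
#'   generation (default `TRUE`; makes the best-fitness history
#'   non-increasing).
#' @param opponent_fraction Tournament opponents as a fraction of the
#'   mixed-population size. Default 0.1.
#' @param ga_max_gen Hard cap on GA generations. Default 500.
#' @param pso_inertia,pso_c1,pso_c2 PSO velocity coefficients.
#' @param pso_max_iter Hard cap on PSO iterations. Default 500.
#' @param pso_tol Stop PSO once gbest fitness falls below this. Default 1e-8.
#' @param velocity_clamp Per-coordinate velocity limit. Default 1.
#' @param init_lo,init_hi Uniform initialization range. Default \[-0.5, 0.5\].
#' @param seed Integer seed; a run is a pure function of (objective,
#'   config, seed).
#' @param node_shape Genome layout for node-level crossover; see
#'   [node_crossover()]. `NULL` treats each gene as its own node.
#' @return A `genpso_config` list.
#' @export
genpso_config <- function(pop_size = 50L,
                          stagnation_window = 50L,
                          stagnation_tol = 1e-5,
                          stagnation_measure = c("range", "delta"),
                          mutation_rate = 0.05,
                          mutation_scale = 0.1,
                          elitism = TRUE,
                          opponent_fraction = 0.1,
                          ga_max_gen = 500L,
                          pso_inertia = 0.729,
                          pso_c1 = 1.49445,
                          pso_c2 = 1.49445,
                          pso_max_iter = 500L,
                          pso_tol = 1e-8,
                          velocity_clamp = 1,
                          init_lo = -0.5,
                          init_hi = 0.5,
                          seed = 1L,
                          node_shape = NULL) {
  pop_size <- as.integer(pop_size)
  if (pop_size < 4L || pop_size %% 2L != 0L)
    stop("`pop_size` must be even and >= 4", call. = FALSE)
  if (stagnation_tol <= 0 || pso_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  if (mutation_rate <= 0 || mutation_rate > 1)
    stop("`mutation_rate` must be in (0, 1]", call. = FALSE)
  structure(list(
    pop_size = pop_size,
    stagnation_window = as.integer(stagnation_window),
    stagnation_tol = stagnation_tol,
    stagnation_measure = match.arg(stagnation_measure),
    mutation_rate = mutation_rate,
    mutation_scale = mutation_scale,
    elitism = isTRUE(elitism),
    opponent_fraction = opponent_fraction,
    ga_max_gen = as.integer(ga_max_gen),
    pso_inertia = pso_inertia, pso_c1 = pso_c1, pso_c2 = pso_c2,
    pso_max_iter = as.integer(pso_max_iter),
    pso_tol = pso_tol,
    velocity_clamp = velocity_clamp,
    init_lo = init_lo, init_hi = init_hi,
    seed = as.integer(seed),
    node_shape = node_shape
  ), class = "genpso_config")
}

#' Initialize a GA population
#'
#' Genomes are i.i.d. uniform on \[lo, hi\] (default \[-0.5, 0.5\]) and fully
#' determined by the seed.
#'
#' @param mu Population size, >= 4.
#' @param dim Genome length, >= 1.
#' @param seed Integer seed.
#' @param lo,hi Initialization range.
#' @return `dim` x `mu` numeric matrix, one genome per column.
#' @export
init_population <- function(mu, dim, seed = 1L, lo = -0.5, hi = 0.5) {
  mu <- as.integer(mu); dim <- as.integer(dim)
  if (mu < 4L) stop("`mu` must be >= 4", call. = FALSE)
  if (dim < 1L) stop("`dim` must be >= 1", call. = FALSE)
  with_seed(seed, matrix(runif(mu * dim, lo, hi), dim, mu))
}

# Index slices of the genome, one per "node". For a network genome the
# nodes are the hidden and output units and a slice is the unit's full
# incoming weights plus its bias (hidden unit j: w_in[, j], b_hidden[j] and,
# when recurrent, w_rec[j, ]; output unit k: w_out[, k], b_out[k]). For a
# codebook genome each codeword is a node. NULL shape: every gene is a node.
node_slices <- function(node_shape, dim) {
  if (is.null(node_shape)) return(lapply(seq_len(dim), identity))
  if (identical(node_shape$type, "net")) {
    H <- as.integer(node_shape$n_hidden)
    rec <- isTRUE(node_shape$recurrent)
    o_win <- 0L
    o_bh <- 64L * H
    o_wrec <- o_bh + H
    o_wout <- o_wrec + (if (rec) H * H else 0L)
    o_bout <- o_wout + H * 64L
    slices <- vector("list", H + 64L)
    for (j in seq_len(H)) {
      s <- c(o_win + (j - 1L) * 64L + seq_len(64L), o_bh + j)
      if (rec) s <- c(s, o_wrec + j + H * (seq_len(H) - 1L))  # row j of w_rec
      slices[[j]] <- s
    }
    for (k in seq_len(64L)) {
      slices[[H + k]] <- c(o_wout + (k - 1L) * H + seq_len(H), o_bout + k)
    }
    return(slices)
  }
  if (identical(node_shape$type, "vector")) {
    nn <- as.integer(node_shape$n_nodes)
    ln <- as.integer(node_shape$node_len)
    if (nn * ln != dim) stop("node_shape does not cover the genome", call. = FALSE)
    return(lapply(seq_len(nn), function(j) (j - 1L) * ln + seq_len(ln)))
  }
  stop("unknown node_shape type", call. = FALSE)
}

#' Node-level crossover
#'
#' Picks one node uniformly at random (hidden and output units with equal
#' probability for network genomes) and swaps that node's complete
#' incoming-weight slice, bias included, between the two parents. The
#' multiset of node slices across the two offspring equals that across the
#' parents.
#'
#' Uses the ambient RNG stream; seed it (or run inside [genpso_optimize()],
#' which seeds everything) for reproducibility.
#'
#' @param a,b Parent genomes (equal-length numeric vectors).
#' @param node_shape Genome layout (see [genpso_config()]); `NULL` swaps a
#'   single random gene.
#' @return List of two offspring genomes.
#' @export
node_crossover <- function(a, b, node_shape = NULL) {
  if (length(a) != length(b))
    stop("parent genomes must have equal length", call. = FALSE)
  slices <- node_slices(node_shape, length(a))
  s <- slices[[sample.int(length(slices), 1L)]]
  ca <- a; cb <- b
  ca[s] <- b[s]
  cb[s] <- a[s]
  list(ca, cb)
}

#' Gaussian gene mutation
#'
#' Each gene is independently perturbed, with probability `rate`, by
#' additive zero-mean gaussian noise of standard deviation `scale`.
#'
#' @param genome Numeric vector.
#' @param rate Per-gene mutation probability in (0, 1\].
#' @param scale Noise standard deviation.
#' @return Mutated genome.
#' @export
mutate_genome <- function(genome, rate, scale) {
  if (rate <= 0 || rate > 1) stop("`rate` must be in (0, 1]", call. = FALSE)
  hit <- runif(length(genome)) < rate
  if (any(hit) && scale != 0)
    genome[hit] <- genome[hit] + rnorm(sum(hit), 0, scale)
  genome
}

#' Mixed-population tournament selection
#'
#' Every chromosome of the mixed parent+offspring population meets
#' `round(opponent_fraction * 2mu)` distinct random opponents (at least
#' one, never itself) and scores a win against each opponent with strictly
#' worse (higher) fitness. The `mu` highest scorers survive; ties are
#' broken by better fitness, then by stable input order.
#'
#' @param genomes dim x 2mu matrix of mixed-population genomes.
#' @param fitness Fitness vector of length 2mu (all evaluated).
#' @param mu Number of survivors.
#' @param opponent_fraction Fraction of the mixed population each
#'   chromosome is compared against. Default 0.1.
#' @return List with `genomes` (dim x mu), `fitness`, `wins` and the
#'   selected `index` into the input.
#' @export
tournament_select <- function(genomes, fitness, mu,
                              opponent_fraction = 0.1) {
  n <- ncol(genomes)
  if (length(fitness) != n || anyNA(fitness))
    stop("all fitness values must be set", call. = FALSE)
  k <- max(1L, as.integer(round(opponent_fraction * n)))
  wins <- integer(n)
  for (i in seq_len(n)) {
    opp <- sample.int(n - 1L, k)
    opp[opp >= i] <- opp[opp >= i] + 1L  # distinct opponents excluding self
    wins[i] <- sum(fitness[i] < fitness[opp])
  }
  ord <- order(-wins, fitness, seq_len(n))
  idx <- ord[seq_len(mu)]
  list(genomes = genomes[, idx, drop = FALSE], fitness = fitness[idx],
       wins = wins[idx], index = idx)
}

eval_columns <- function(objective, genomes) {
  f <- vapply(seq_len(ncol(genomes)), function(j) objective(genomes[, j]),
              numeric(1))
  if (any(!is.finite(f)))
    stop("objective returned a non-finite value", call. = FALSE)
  f
}

stagnated <- function(history, window, tol, measure) {
  if (length(history) < window) return(FALSE)
  h <- utils::tail(history, window)
  v <- if (measure == "range") max(h) - min(h) else max(abs(diff(h)))
  v < tol
}

#' Genetic-algorithm phase
#'
#' One full GA run: uniform random initialization (or supplied seed
#' genomes), offspring by node crossover on uniformly drawn parent pairs
#' plus gaussian mutation, random mixing of parents and offspring,
#' 10%-opponent tournament selection, optional elitism, and stagnation
#' termination — stop once the best fitness has varied by less than
#' `stagnation_tol` over `stagnation_window` successive generations, or at
#' `ga_max_gen`.
#'
#' Uses the ambient RNG stream (seed it, or call via [genpso_optimize()]).
#'
#' @param objective Function from genome vector to finite scalar fitness
#'   (lower is better).
#' @param dim Genome length.
#' @param config A [genpso_config()].
#' @param init_genomes Optional dim x mu matrix of starting genomes
#'   (overrides uniform initialization; used e.g. to inject codebook
#'   candidates built from training vectors).
#' @return List with `genomes`, `fitness` (final population), `best_genome`,
#'   `best_fitness`, `history` (best fitness after each generation),
#'   `evaluations` (objective call count), `generations`.
#' @export
ga_phase <- function(objective, dim, config = genpso_config(),
                     init_genomes = NULL) {
  mu <- config$pop_size
  if (is.null(init_genomes)) {
    pop <- matrix(runif(mu * dim, config$init_lo, config$init_hi), dim, mu)
  } else {
    if (nrow(init_genomes) != dim || ncol(init_genomes) != mu)
      stop("`init_genomes` must be dim x pop_size", call. = FALSE)
    pop <- init_genomes
  }
  fit <- eval_columns(objective, pop)
  evals <- mu
  bi <- which.min(fit)
  best_genome <- pop[, bi]; best_fitness <- fit[bi]
  history <- numeric(0)
  gen <- 0L
  while (gen < config$ga_max_gen) {
    gen <- gen + 1L
    # offspring: mu children from mu/2 random parent pairs
    off <- matrix(0, dim, mu)
    for (p in seq_len(mu %/% 2L)) {
      pr <- sample.int(mu, 2L)
      kids <- node_crossover(pop[, pr[1]], pop[, pr[2]], config$node_shape)
      off[, 2L * p - 1L] <- mutate_genome(kids[[1]], config$mutation_rate,
                                          config$mutation_scale)
      off[, 2L * p] <- mutate_genome(kids[[2]], config$mutation_rate,
                                     config$mutation_scale)
    }
    off_fit <- eval_columns(objective, off)
    evals <- evals + mu
    mixed <- cbind(pop, off)
    mixed_fit <- c(fit, off_fit)
    perm <- sample.int(2L * mu)  # parents and children randomly mixed
    sel <- tournament_select(mixed[, perm, drop = FALSE], mixed_fit[perm],
                             mu, config$opponent_fraction)
    pop <- sel$genomes; fit <- sel$fitness
    # track incumbent best across everything evaluated so far
    mbi <- which.min(mixed_fit)
    if (mixed_fit[mbi] < best_fitness) {
      best_fitness <- mixed_fit[mbi]
      best_genome <- mixed[, mbi]
    }
    if (config$elitism && min(fit) > best_fitness) {
      wi <- which.max(fit)
      pop[, wi] <- best_genome
      fit[wi] <- best_fitness
    }
    history <- c(history, if (config$elitism) best_fitness else min(fit))
    if (stagnated(history, config$stagnation_window, config$stagnation_tol,
                  config$stagnation_measure)) break
  }
  list(genomes = pop, fitness = fit, best_genome = best_genome,
       best_fitness = best_fitness, history = history,
       evaluations = evals, generations = gen)
}

#' Particle-swarm phase
#'
#' Particles start at the supplied (GA-final) genomes with zero velocity;
#' per iteration `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` and
#' `x <- x + v`, with r1, r2 i.i.d. uniform\[0,1\] per coordinate and a
#' per-coordinate velocity clamp. pbest/gbest update only on strict
#' improvement, and gbest is a copy, so its fitness trace is
#' non-increasing. Stops when gbest fitness < `pso_tol` or at
#' `pso_max_iter`.
#'
#' Uses the ambient RNG stream (seed it, or call via [genpso_optimize()]).
#'
#' @param positions dim x n matrix of starting positions.
#' @param fitness Their fitness values (length n).
#' @param objective Objective function (lower is better).
#' @param config A [genpso_config()].
#' @return List with `best_position`, `best_fitness`, `history` (gbest per
#'   iteration), `evaluations`, `iterations`.
#' @export
pso_phase <- function(positions, fitness, objective,
                      config = genpso_config()) {
  if (is.null(dim(positions)) || ncol(positions) == 0L)
    stop("empty seed population", call. = FALSE)
  n <- ncol(positions); d <- nrow(positions)
  x <- positions
  v <- matrix(0, d, n)
  pbest <- x
  pbest_fit <- fitness
  gi <- which.min(pbest_fit)
  gbest <- pbest[, gi]; gbest_fit <- pbest_fit[gi]
  history <- numeric(0)
  evals <- 0L
  iter <- 0L
  while (iter < config$pso_max_iter && gbest_fit >= config$pso_tol) {
    iter <- iter + 1L
    r1 <- matrix(runif(d * n), d, n)
    r2 <- matrix(runif(d * n), d, n)
    v <- config$pso_inertia * v +
      config$pso_c1 * r1 * (pbest - x) +
      config$pso_c2 * r2 * (gbest - x)
    v <- pmin(pmax(v, -config$velocity_clamp), config$velocity_clamp)
    x <- x + v
    f <- eval_columns(objective, x)
    evals <- evals + n
    imp <- f < pbest_fit
    if (any(imp)) {
      pbest[, imp] <- x[, imp]
      pbest_fit[imp] <- f[imp]
      gi <- which.min(pbest_fit)
      if (pbest_fit[gi] < gbest_fit) {
        gbest <- pbest[, gi]   # copy; later movement cannot corrupt it
        gbest_fit <- pbest_fit[gi]
      }
    }
    history <- c(history, gbest_fit)
  }
  list(best_position = gbest, best_fitness = gbest_fit, history = history,
       evaluations = evals, iterations = iter)
}

#' Hybrid GA-PSO optimization
#'
#' Runs one GA phase, seeds a particle swarm with the GA's final
#' population, and returns the better of the two incumbents (with elitism
#' the hand-off is monotone: the PSO starts from the GA best). The run is
#' a pure function of (objective, dim, config): identical seeds give
#' bit-identical traces.
#'
#' @inheritParams ga_phase
#' @return List with `best_position`, `best_fitness`, `ga` and `pso`
#'   sub-results, `evaluations` (total objective calls) and `trace`, a
#'   data frame (phase, iteration, best_fitness, evaluations) suitable for
#'   convergence plots or CSV export.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- genpso_config(pop_size = 20, ga_max_gen = 30, pso_max_iter = 50,
#'                      stagnation_window = 10, seed = 7)
#' res <- genpso_optimize(sphere, dim = 2, config = cfg)
#' res$best_fitness < 1e-4
genpso_optimize <- function(objective, dim, config = genpso_config(),
                            init_genomes = NULL) {
  if (dim < 1L) stop("`dim` must be >= 1", call. = FALSE)
  res <- with_seed(config$seed, {
    ga <- ga_phase(objective, dim, config, init_genomes)
    pso <- pso_phase(ga$genomes, ga$fitness, objective, config)
    list(ga = ga, pso = pso)
  })
  ga <- res$ga; pso <- res$pso
  if (pso$best_fitness <= ga$best_fitness) {
    best <- pso$best_position; bf <- pso$best_fitness
  } else {
    best <- ga$best_genome; bf <- ga$best_fitness
  }
  trace <- rbind(
    data.frame(phase = rep("ga", length(ga$history)),
               iteration = seq_along(ga$history),
               best_fitness = ga$history,
               evaluations = config$pop_size * (1L + seq_along(ga$history))),
    data.frame(phase = rep("pso", length(pso$history)),
               iteration = seq_along(pso$history),
               best_fitness = pso$history,
               evaluations = ga$evaluations +
                 config$pop_size * seq_along(pso$history))
  )
  list(best_position = best, best_fitness = bf, ga = ga, pso = pso,
       evaluations = ga$evaluations + pso$evaluations, trace = trace)
}

#' Write an optimizer trace as CSV
#'
#' @param result A [genpso_optimize()] result.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
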