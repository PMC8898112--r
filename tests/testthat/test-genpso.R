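sphere <- function(x) sum(x^2)

test_that("population initialization is seeded uniform on [-0.5, 0.5]", {
  p1 <- init_population(50, 10, seed = 2)
  p2 <- init_population(50, 10, seed = 2)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(10L, 50L))
  big <- init_population(100, 100, seed = 3)
  expect_true(all(big >= -0.5 & big <= 0.5))
  expect_lt(abs(mean(big)), 0.01)  # 10^4 genes, law of large numbers
  expect_error(init_population(2, 10), ">= 4")
})

test_that("node crossover swaps exactly one node's incoming slice", {
  shape <- list(type = "net", n_hidden = 4, recurrent = TRUE)
  np <- net_n_params(4, TRUE)
  set.seed(11)
  a <- runif(np); b <- runif(np)
  # identical parents: offspring are clones
  same <- node_crossover(a, a, shape)
  expect_identical(same[[1]], a)
  set.seed(12)
  kids <- node_crossover(a, b, shape)
  slices <- genpsowvq:::node_slices(shape, np)
  diff_a <- which(kids[[1]] != a)
  # the changed genes form exactly one node slice (where parents differ)
  hit <- which(vapply(slices, function(s) all(diff_a %in% s), logical(1)))
  expect_length(hit, 1)
  s <- slices[[hit]]
  expect_identical(kids[[1]][s], b[s])
  expect_identical(kids[[2]][s], a[s])
  expect_identical(kids[[1]][-s], a[-s])
  expect_identical(kids[[2]][-s], b[-s])
  # conservation: per-node slices across offspring = across parents
  off_slices <- c(lapply(slices, function(s) kids[[1]][s]),
                  lapply(slices, function(s) kids[[2]][s]))
  par_slices <- c(lapply(slices, function(s) a[s]),
                  lapply(slices, function(s) b[s]))
  key <- function(l) sort(vapply(l, function(v) paste(signif(v, 15),
                                                      collapse = ","), ""))
  expect_identical(key(off_slices), key(par_slices))
})

test_that("node slices tile the genome for network and codeword layouts", {
  shape <- list(type = "net", n_hidden = 8, recurrent = TRUE)
  np <- net_n_params(8, TRUE)
  s <- genpsowvq:::node_slices(shape, np)
  expect_length(s, 8 + 64)
  expect_identical(sort(unlist(s)), seq_len(np))  # partition, no overlap
  s2 <- genpsowvq:::node_slices(list(type = "vector", n_nodes = 4,
                                     node_len = 3), 12)
  expect_identical(sort(unlist(s2)), 1:12)
})

test_that("mutation hits genes at the configured frequency", {
  set.seed(21)
  g <- numeric(1e5)
  m <- mutate_genome(g, rate = 0.1, scale = 0.5)
  freq <- mean(m != 0)
  expect_lt(abs(freq - 0.1), 0.01)
  expect_identical(mutate_genome(g, rate = 0.5, scale = 0), g)
  expect_error(mutate_genome(g, rate = 0, scale = 1), "rate")
})

test_that("tournament selection keeps the best and returns mu survivors", {
  dim <- 3
  for (s in 1:20) {
    set.seed(s)
    n <- 8
    genomes <- matrix(rnorm(dim * n), dim, n)
    fitness <- sample(seq_len(n))  # strictly ordered, shuffled
    sel <- tournament_select(genomes, fitness, mu = 4)
    expect_length(sel$fitness, 4)
    expect_true(min(fitness) %in% sel$fitness)  # best always survives
  }
  # opponent count: round(0.1 * 100) = 10 distinct opponents each
  set.seed(99)
  genomes <- matrix(rnorm(100), 1, 100)
  sel <- tournament_select(genomes, runif(100), mu = 50)
  expect_length(sel$index, 50)
  expect_error(tournament_select(genomes, c(NA, runif(99)), 50), "fitness")
})

test_that("the GA stagnation rule fires after exactly N flat generations", {
  cfg <- genpso_config(pop_size = 10, stagnation_window = 12,
                       stagnation_tol = 1e-5, ga_max_gen = 100, seed = 1)
  set.seed(2)
  res <- ga_phase(function(x) 1, dim = 3, config = cfg)
  expect_identical(res$generations, 12L)
  expect_identical(res$evaluations, 10L * 13L)  # init + 12 offspring waves
})

test_that("the GA finds a 1-D quadratic minimum and elitism is monotone", {
  cfg <- genpso_config(pop_size = 20, stagnation_window = 30,
                       ga_max_gen = 120, mutation_rate = 0.3,
                       mutation_scale = 0.2, init_lo = -2, init_hi = 2,
                       seed = 5)
  set.seed(6)
  res <- ga_phase(function(x) (x - 3)^2, dim = 1, config = cfg)
  expect_lt(abs(res$best_genome - 3), 0.1)
  expect_true(all(diff(res$history) <= 0))
})

test_that("objective errors are surfaced, not swallowed", {
  cfg <- genpso_config(pop_size = 10, ga_max_gen = 5, seed = 1)
  set.seed(1)
  expect_error(ga_phase(function(x) NaN, dim = 2, config = cfg),
               "non-finite")
})

test_that("PSO gbest is non-increasing, copied, and converges on the sphere", {
  cfg <- genpso_config(pop_size = 20, ga_max_gen = 40, pso_max_iter = 120,
                       stagnation_window = 15, seed = 7)
  res <- genpso_optimize(sphere, dim = 5, config = cfg)
  expect_true(all(diff(res$pso$history) <= 0))
  expect_lt(res$best_fitness, 1e-3)
  expect_lte(res$best_fitness, res$ga$best_fitness)  # monotone hand-off
  # particles seeded at the optimum exit at the first tolerance check
  at_opt <- matrix(0, 5, 4)
  set.seed(8)
  still <- pso_phase(at_opt, rep(0, 4), sphere, cfg)
  expect_identical(still$iterations, 0L)
  expect_identical(still$best_fitness, 0)
})

test_that("runs are bit-identical given the same seed", {
  cfg <- genpso_config(pop_size = 10, ga_max_gen = 15, pso_max_iter = 20,
                       stagnation_window = 10, seed = 42)
  r1 <- genpso_optimize(sphere, dim = 3, config = cfg)
  r2 <- genpso_optimize(sphere, dim = 3, config = cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
  # and evaluation counts are exact for a fixed config
  expect_identical(r1$evaluations,
                   10L * (1L + r1$ga$generations) + 10L * r1$pso$iterations)
})

test_that("GenPSO is no worse than random search on rastrigin at equal budget", {
  rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  cfg <- genpso_config(pop_size = 20, ga_max_gen = 124, pso_max_iter = 125,
                       stagnation_window = 200, init_lo = -2, init_hi = 2,
                       seed = 9)
  res <- genpso_optimize(rastrigin, dim = 2, config = cfg)
  expect_lte(res$evaluations, 5000)
  set.seed(10)
  rand_best <- min(vapply(seq_len(5000), function(i) {
    rastrigin(runif(2, -2, 2))
  }, numeric(1)))
  expect_lte(res$best_fitness, rand_best)
})

test_that("optimizer traces can be exported as CSV", {
  cfg <- genpso_config(pop_size = 10, ga_max_gen = 5, pso_max_iter = 5,
                       stagnation_window = 10, seed = 3)
  res <- genpso_optimize(sphere, dim = 2, config = cfg)
  f <- tempfile(fileext = ".csv")
  write_trace(res, f)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), nrow(res$trace))
  expect_named(back, c("phase", "iteration", "best_fitness", "evaluations"))
})
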