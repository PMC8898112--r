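test_that("distortion matches the exhaustive nearest-neighbour oracle", {
  set.seed(1)
  cb <- new_codebook(matrix(runif(8 * 4), 8, 4))
  V <- matrix(runif(8 * 20), 8, 20)
  expect_equal(vq_distortion(V, cb), oracle_distortion(V, cb$codewords),
               tolerance = 1e-12)
  # vectors drawn from the codewords themselves have zero distortion
  expect_equal(vq_distortion(cb$codewords[, c(2, 4, 1)], cb), 0,
               tolerance = 1e-12)
  # single vector / single codeword is the squared distance
  v <- matrix(runif(8)); c1 <- new_codebook(matrix(runif(8)))
  expect_equal(vq_distortion(v, c1), sum((v - c1$codewords)^2))
  expect_error(vq_distortion(matrix(1, 3, 2), cb), "dimension")
})

test_that("encoding picks the argmin codeword with lowest-index ties", {
  set.seed(2)
  cb <- new_codebook(matrix(runif(4 * 8), 4, 8))
  V <- matrix(runif(4 * 50), 4, 50)
  got <- vq_encode(V, cb)
  want <- vapply(seq_len(50), function(j) {
    oracle_nearest(V[, j], cb$codewords)["index"]
  }, numeric(1))
  expect_equal(got$indices, as.integer(want))
  expect_identical(got$bitwidth, 3L)
  # exact codeword inputs return their own indices
  ex <- vq_encode(cb$codewords[, c(4, 1, 2)], cb)
  expect_identical(ex$indices, c(4L, 1L, 2L))
  # duplicated codewords: tie resolves to the lowest index
  dup <- new_codebook(cbind(cb$codewords[, 1], cb$codewords[, 1]))
  expect_identical(vq_encode(matrix(cb$codewords[, 1]), dup)$indices, 1L)
  # K = 1 maps everything to index 1
  k1 <- new_codebook(matrix(runif(4)))
  expect_true(all(vq_encode(V, k1)$indices == 1L))
})

test_that("decode inverts encode on codewords and reproduces distortion", {
  set.seed(3)
  cb <- new_codebook(matrix(runif(6 * 4), 6, 4))
  V <- matrix(runif(6 * 30), 6, 30)
  st <- vq_encode(V, cb)
  rec <- vq_decode(st, cb)
  expect_equal(mean(colSums((rec - V)^2)), vq_distortion(V, cb),
               tolerance = 1e-12)
  # nearest-neighbour optimality: no codeword strictly closer than assigned
  d <- genpsowvq:::sqdist_matrix(V, cb)
  assigned <- d[cbind(st$indices, seq_len(30))]
  expect_true(all(assigned <= apply(d, 2, min) + 1e-12))
  # codeword-exact round trip is the identity
  expect_equal(vq_decode(vq_encode(cb$codewords, cb), cb), cb$codewords)
  expect_error(vq_decode(c(0L, 1L), cb), "out of")
  expect_error(new_codebook(matrix(1, 2, 3)), "power of two")
})

test_that("GenPSO codebooks reach centroid/Lloyd/exact-cover quality", {
  set.seed(7)
  V <- matrix(runif(16 * 40, 0, 1), 16, 40)
  cfg <- genpso_config(pop_size = 20, ga_max_gen = 200, pso_max_iter = 150,
                       stagnation_window = 50, stagnation_tol = 1e-8,
                       mutation_rate = 0.5, mutation_scale = 0.02, seed = 5)
  cb1 <- build_codebook(V, 1, cfg)
  centroid_d <- mean(colSums((V - rowMeans(V))^2))
  expect_lt(vq_distortion(V, cb1) - centroid_d, 1e-3)

  # two well-separated clusters vs the Lloyd oracle
  set.seed(8)
  V2 <- cbind(matrix(rnorm(8 * 30, -2, 0.3), 8, 30),
              matrix(rnorm(8 * 30, 2, 0.3), 8, 30))
  cb2 <- build_codebook(V2, 2, genpso_config(pop_size = 20, ga_max_gen = 150,
                                             pso_max_iter = 120,
                                             stagnation_window = 50,
                                             stagnation_tol = 1e-8,
                                             mutation_rate = 0.5,
                                             mutation_scale = 0.02, seed = 6))
  lloyd_d <- oracle_distortion(V2, oracle_lloyd(V2, 2, seed = 60))
  expect_lt(vq_distortion(V2, cb2), 1.1 * lloyd_d)

  # exact cover: K >= distinct vectors reaches zero distortion
  V3 <- matrix(runif(4 * 6), 4, 6)
  cb3 <- build_codebook(V3, 8, genpso_config(pop_size = 20, ga_max_gen = 20,
                                             pso_max_iter = 30,
                                             stagnation_window = 10, seed = 7))
  expect_lt(vq_distortion(V3, cb3), 1e-12)
})

test_that("doubling K with the smaller codebook injected never hurts", {
  set.seed(9)
  V <- matrix(runif(4 * 60), 4, 60)
  cfg <- function(s) genpso_config(pop_size = 20, ga_max_gen = 60,
                                   pso_max_iter = 60, stagnation_window = 30,
                                   mutation_rate = 0.5, mutation_scale = 0.02,
                                   seed = s)
  cbK <- build_codebook(V, 4, cfg(11))
  # inject the K-codebook (padded with duplicates) into the 2K population
  pad <- cbind(cbK$codewords, cbK$codewords)
  c2 <- cfg(12)
  c2$node_shape <- list(type = "vector", n_nodes = 8, node_len = 4)
  init <- init_population(20, 32, seed = 13, lo = min(V), hi = max(V))
  init[, 1] <- as.numeric(pad)
  res <- genpso_optimize(function(g) {
    vq_distortion(V, new_codebook(matrix(g, 4, 8)))
  }, 32, c2, init_genomes = init)
  cb2K <- new_codebook(matrix(res$best_position, 4, 8))
  expect_lte(vq_distortion(V, cb2K), vq_distortion(V, cbK) + 1e-12)
})
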