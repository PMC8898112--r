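#' Construct a codebook object
#'
#' @param codewords H x K numeric matrix, one codeword per column.
#' @return A `codebook` object with fields `codewords`, `K`, `dim` and
#'   `bitwidth` (log2 K, the per-index bit cost).
#' @export
new_codebook <- function(codewords) {
  if (!is.matrix(codewords) || ncol(codewords) < 1L)
    stop("`codewords` must be a non-empty matrix", call. = FALSE)
  K <- ncol(codewords)
  b <- log2(K)
  if (b != round(b))
    stop("codebook size K must be a power of two", call. = FALSE)
  structure(list(codewords = codewords, K = K, dim = nrow(codewords),
                 bitwidth = as.integer(round(b))),
            class = "codebook")
}

# K x n matrix of squared euclidean distances codeword x vector.
sqdist_matrix <- function(vectors, codebook) {
  cw <- codebook$codewords
  if (nrow(vectors) != codebook$dim)
    stop("vector dimension does not match codebook", call. = FALSE)
  cn <- colSums(cw^2)
  vn <- colSums(vectors^2)
  d <- outer(cn, vn, "+") - 2 * crossprod(cw, vectors)
  pmax(d, 0)  # guard tiny negatives from cancellation
}

#' Mean VQ distortion
#'
#' Mean over the input vectors of the squared euclidean distance to the
#' nearest codeword — the objective minimized when building a codebook.
#'
#' @param vectors H x n matrix of vectors (columns).
#' @param codebook A `codebook`.
#' @return Non-negative scalar.
#' @export
vq_distortion <- function(vectors, codebook) {
  if (!is.matrix(vectors) || ncol(vectors) == 0L)
    stop("`vectors` must be a non-empty matrix", call. = FALSE)
  mean(apply(sqdist_matrix(vectors, codebook), 2, min))
}

#' Vector-quantize vectors to codebook indices
#'
#' Each vector maps to the index of its nearest codeword (squared
#' euclidean); exact ties resolve to the lowest index, which keeps encoding
#' deterministic across platforms.
#'
#' @inheritParams vq_distortion
#' @return An `index_stream`: list with 1-based `indices`, `bitwidth` and
#'   `K`.
#' @export
vq_encode <- function(vectors, codebook) {
  if (!is.matrix(vectors) || ncol(vectors) == 0L)
    stop("`vectors` must be a non-empty matrix", call. = FALSE)
  D <- sqdist_matrix(vectors, codebook)
  idx <- apply(D, 2, which.min)  # which.min takes the first (lowest) index
  structure(list(indices = as.integer(idx), bitwidth = codebook$bitwidth,
                 K = codebook$K),
            class = "index_stream")
}

#' Reconstruct vectors from an index stream
#'
#' @param stream An `index_stream` (or plain 1-based integer vector).
#' @param codebook A `codebook`.
#' @return H x n matrix of codewords.
#' @export
vq_decode <- function(stream, codebook) {
  idx <- if (inherits(stream, "index_stream")) stream$indices else as.integer(stream)
  if (any(idx < 1L | idx > codebook$K))
    stop("index out of codebook range", call. = FALSE)
  codebook$codewords[, idx, drop = FALSE]
}

#' Build a codebook with the hybrid GA-PSO optimizer
#'
#' The genome is the concatenation of the K codewords (length K*H) and the
#' objective is [vq_distortion()] on the training vectors. Half of the GA's
#' initial population is seeded with K-column subsets of the training
#' vectors (the first such individual uses the first K distinct vectors, so
#' when K covers the distinct training vectors a zero-distortion candidate
#' is injected and elitism retains it); the other half is uniform random
#' over the data's bounding box.
#'
#' @param training_vectors H x n matrix of training vectors (columns).
#' @param K Codebook size, a power of two.
#' @param config A [genpso_config()]; its `node_shape` is set to treat each
#'   codeword as a crossover node.
#' @return A `codebook`.
#' @export
build_codebook <- function(training_vectors, K,
                           config = genpso_config()) {
  if (!is.matrix(training_vectors) || ncol(training_vectors) == 0L)
    stop("empty training set", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L || log2(K) != round(log2(K)))
    stop("K must be a power of two", call. = FALSE)
  H <- nrow(training_vectors)
  dim <- K * H
  config$node_shape <- list(type = "vector", n_nodes = K, node_len = H)
  lo <- min(training_vectors); hi <- max(training_vectors)
  if (hi <= lo) hi <- lo + 1e-6
  n <- ncol(training_vectors)
  mu <- config$pop_size
  init <- with_seed(config$seed + 1L, {
    m <- matrix(0, dim, mu)
    uq <- unique(t(training_vectors))  # distinct vectors, stable order
    for (j in seq_len(mu)) {
      if (j <= mu %/% 2L) {
        if (j == 1L) {
          take <- min(K, nrow(uq))
          cw <- t(uq[seq_len(take), , drop = FALSE])
          if (take < K)
            cw <- cbind(cw, training_vectors[, sample.int(n, K - take,
                                                          replace = TRUE),
                                             drop = FALSE])
        } else {
          cw <- training_vectors[, sample.int(n, K, replace = K > n),
                                 drop = FALSE]
        }
        m[, j] <- as.numeric(cw)
      } else {
        m[, j] <- runif(dim, lo, hi)
      }
    }
    m
  })
  objective <- function(g) {
    vq_distortion(training_vectors,
                  new_codebook(matrix(g, H, K)))
  }
  res <- genpso_optimize(objective, dim, config, init_genomes = init)
  new_codebook(matrix(res$best_position, H, K))
}
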