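#' The 64-H-64 compressor network
#'
#' A sigmoid autoencoder mapping a normalized 64-vector (one flattened 8x8
#' block) to an H-dimensional hidden code and back. An optional Elman-style
#' context matrix feeds the previous block's hidden state into the current
#' hidden layer, giving the codec sequence context along the raster scan.
#' Forward maps:
#'   hidden = sigmoid(t(w_in) %*% x + w_rec %*% h_prev + b_hidden)
#'   output = sigmoid(t(w_out) %*% hidden + b_out)
#' All weights are trained derivative-free by [genpso_optimize()]; no
#' gradients are used, which sidesteps vanishing/exploding-gradient issues
#' in the recurrent path.
#'
#' The flat parameter vector used by the optimizer concatenates, in this
#' fixed order: `w_in` (column-major 64xH), `b_hidden` (H), `w_rec`
#' (column-major HxH, only when recurrent), `w_out` (column-major Hx64),
#' `b_out` (64).
#'
#' @param n_hidden Hidden width H, one of 2, 4, 8, 16, 32, 64.
#' @param recurrent Enable the hidden-to-hidden context matrix
#'   (default `TRUE`).
#' @param seed Integer seed; parameters are i.i.d. uniform on
#'   \[-0.5, 0.5\] and fully determined by the seed.
#' @return A `compressor_net` object.
#' @export
#' @examples
#' net <- init_network(16, recurrent = FALSE, seed = 1)
#' length(flatten_net(net))  # 2128
init_network <- function(n_hidden, recurrent = TRUE, seed = 1L) {
  n_hidden <- as.integer(n_hidden)
  if (!n_hidden %in% c(2L, 4L, 8L, 16L, 32L, 64L))
    stop("`n_hidden` must be one of 2, 4, 8, 16, 32, 64", call. = FALSE)
  np <- net_n_params(n_hidden, recurrent)
  params <- with_seed(seed, runif(np, -0.5, 0.5))
  unflatten_net(params, n_hidden, recurrent)
}

#' Parameter count of a compressor network
#' @inheritParams init_network
#' @return Integer number of free parameters.
#' @export
net_n_params <- function(n_hidden, recurrent = TRUE) {
  n_hidden <- as.integer(n_hidden)
  64L * n_hidden + n_hidden + (if (recurrent) n_hidden^2 else 0L) +
    n_hidden * 64L + 64L
}

#' @rdname init_network
#' @param net A `compressor_net`.
#' @export
flatten_net <- function(net) {
  c(as.numeric(net$w_in), net$b_hidden,
    if (net$recurrent) as.numeric(net$w_rec),
    as.numeric(net$w_out), net$b_out)
}

#' @rdname init_network
#' @param params Flat numeric parameter vector in the documented order.
#' @export
unflatten_net <- function(params, n_hidden, recurrent = TRUE) {
  n_hidden <- as.integer(n_hidden)
  np <- net_n_params(n_hidden, recurrent)
  if (length(params) != np)
    stop(sprintf("expected %d parameters, got %d", np, length(params)),
         call. = FALSE)
  i <- 0L
  take <- function(n) {
    out <- params[i + seq_len(n)]
    i <<- i + n
    out
  }
  w_in <- matrix(take(64L * n_hidden), 64L, n_hidden)
  b_hidden <- take(n_hidden)
  w_rec <- if (recurrent) matrix(take(n_hidden^2), n_hidden, n_hidden) else NULL
  w_out <- matrix(take(n_hidden * 64L), n_hidden, 64L)
  b_out <- take(64L)
  structure(list(w_in = w_in, b_hidden = b_hidden, w_rec = w_rec,
                 w_out = w_out, b_out = b_out, n_hidden = n_hidden,
                 recurrent = isTRUE(recurrent), activation = "sigmoid"),
            class = "compressor_net")
}

#' Single forward pass through the compressor network
#'
#' @param net A `compressor_net`.
#' @param input64 Numeric vector of length 64 (normalized block).
#' @param prev_hidden Previous hidden state (length H) or `NULL` for the
#'   zero vector. Ignored when recurrence is disabled.
#' @return List with `hidden` (H-vector in (0,1)) and `output` (64-vector
#'   in (0,1)).
#' @export
net_forward <- function(net, input64, prev_hidden = NULL) {
  if (length(input64) != 64L)
    stop("`input64` must have length 64", call. = FALSE)
  h_pre <- drop(crossprod(net$w_in, input64)) + net$b_hidden
  if (net$recurrent) {
    if (is.null(prev_hidden)) prev_hidden <- numeric(net$n_hidden)
    if (length(prev_hidden) != net$n_hidden)
      stop("`prev_hidden` must have length n_hidden", call. = FALSE)
    h_pre <- h_pre + drop(net$w_rec %*% prev_hidden)
  }
  hidden <- sigmoid(h_pre)
  output <- sigmoid(drop(crossprod(net$w_out, hidden)) + net$b_out)
  list(hidden = hidden, output = output)
}

# Hidden activations for a 64 x B matrix of blocks, threading the hidden
# state across consecutive columns when recurrent. `reset = TRUE` starts
# from the zero context.
encode_matrix <- function(net, X, h0 = NULL) {
  Z <- crossprod(net$w_in, X) + net$b_hidden
  if (!net$recurrent) return(sigmoid(Z))
  B <- ncol(X)
  Hm <- matrix(0, net$n_hidden, B)
  h <- if (is.null(h0)) numeric(net$n_hidden) else h0
  Wr <- net$w_rec
  for (j in seq_len(B)) {
    h <- 1 / (1 + exp(-(Z[, j] + Wr %*% h)))
    Hm[, j] <- h
  }
  Hm
}

decode_matrix <- function(net, Hm) {
  sigmoid(crossprod(net$w_out, Hm) + net$b_out)
}

#' Encode the blocks of a block set to hidden codes
#'
#' Blocks are processed in raster order; with recurrence enabled the hidden
#' state is threaded across consecutive blocks (and starts from zero at the
#' first block).
#'
#' @param net A `compressor_net`.
#' @param blockset A `block_set` with 64-row blocks.
#' @return H x n matrix of hidden activations, one column per block.
#' @export
encode_blocks <- function(net, blockset) {
  if (!inherits(blockset, "block_set"))
    stop("`blockset` must be a block_set", call. = FALSE)
  if (nrow(blockset$blocks) != 64L)
    stop("compressor network consumes 64-component blocks", call. = FALSE)
  if (ncol(blockset$blocks) == 0L) stop("empty block_set", call. = FALSE)
  encode_matrix(net, blockset$blocks)
}

#' Decode hidden codes back to a block set
#'
#' @param net A `compressor_net`.
#' @param hidden_vectors H x n matrix of hidden codes (columns), e.g. from
#'   [encode_blocks()] or [vq_decode()].
#' @param template A `block_set` providing the grid metadata of the
#'   encode-side tiling.
#' @return A `block_set` with reconstructed 64-row blocks.
#' @export
decode_hidden <- function(net, hidden_vectors, template) {
  if (is.vector(hidden_vectors)) hidden_vectors <- matrix(hidden_vectors)
  if (nrow(hidden_vectors) != net$n_hidden)
    stop("hidden vectors must have length n_hidden", call. = FALSE)
  out <- template
  out$blocks <- decode_matrix(net, hidden_vectors)
  out
}

#' Reconstruction objective for derivative-free training
#'
#' Mean squared error between normalized blocks and their
#' encode-then-decode reconstruction under a candidate flat parameter
#' vector. This is the objective [genpso_optimize()] minimizes when
#' training the codec. `blocks` may be a single 64 x B matrix, a
#' `block_set`, or a list of matrices; with a list the recurrent hidden
#' state is reset at the start of each matrix (the codec resets context at
#' each subband plane).
#'
#' @param params Flat parameter vector (see [init_network()] for the
#'   ordering).
#' @param blocks Training blocks (matrix, `block_set` or list of matrices).
#' @param n_hidden Hidden width of the candidate network.
#' @param recurrent Whether `params` includes the context matrix.
#' @return Non-negative scalar MSE in normalized (0-1) units.
#' @export
reconstruction_fitness <- function(params, blocks, n_hidden,
                                   recurrent = TRUE) {
  net <- unflatten_net(params, n_hidden, recurrent)
  if (inherits(blocks, "block_set")) blocks <- list(blocks$blocks)
  if (is.matrix(blocks)) blocks <- list(blocks)
  se <- 0; n <- 0
  for (X in blocks) {
    Y <- decode_matrix(net, encode_matrix(net, X))
    se <- se + sum((Y - X)^2)
    n <- n + length(X)
  }
  se / n
}
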