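# Independent scalar oracles used across the suite. These are deliberately
# naive (explicit loops over pixels/vectors) so they share no code with the
# package's vectorized implementations.

oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (as.numeric(b[i, j]) - as.numeric(a[i, j]))^2
  s / (nrow(a) * ncol(a))
}

oracle_psnr <- function(a, b) {
  m <- oracle_mse(a, b)
  if (m == 0) Inf else 10 * log10(255 * 255 / m)
}

oracle_snr <- function(a, b) {
  sig <- 0; err <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    sig <- sig + as.numeric(a[i, j])^2
    err <- err + (as.numeric(b[i, j]) - as.numeric(a[i, j]))^2
  }
  if (err == 0) Inf else 10 * log10(sig / err)
}

oracle_ssim <- function(a, b) {
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  va <- 0; vb <- 0; cab <- 0
  for (k in seq_len(n)) {
    va <- va + (a[k] - ma)^2
    vb <- vb + (b[k] - mb)^2
    cab <- cab + (a[k] - ma) * (b[k] - mb)
  }
  va <- va / n; vb <- vb / n; cab <- cab / n
  ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

# scalar forward pass through a compressor net, one unit at a time
oracle_forward <- function(net, x, h_prev = NULL) {
  H <- net$n_hidden
  if (is.null(h_prev)) h_prev <- rep(0, H)
  hidden <- numeric(H)
  for (j in seq_len(H)) {
    z <- net$b_hidden[j]
    for (i in seq_len(64)) z <- z + net$w_in[i, j] * x[i]
    if (net$recurrent)
      for (k in seq_len(H)) z <- z + net$w_rec[j, k] * h_prev[k]
    hidden[j] <- 1 / (1 + exp(-z))
  }
  output <- numeric(64)
  for (o in seq_len(64)) {
    z <- net$b_out[o]
    for (j in seq_len(H)) z <- z + net$w_out[j, o] * hidden[j]
    output[o] <- 1 / (1 + exp(-z))
  }
  list(hidden = hidden, output = output)
}

oracle_nearest <- function(v, codewords) {
  best <- 1; bestd <- Inf
  for (k in seq_len(ncol(codewords))) {
    d <- sum((v - codewords[, k])^2)
    if (d < bestd) { bestd <- d; best <- k }
  }
  c(index = best, dist = bestd)
}

oracle_distortion <- function(vectors, codewords) {
  tot <- 0
  for (j in seq_len(ncol(vectors)))
    tot <- tot + oracle_nearest(vectors[, j], codewords)["dist"]
  unname(tot / ncol(vectors))
}

# Lloyd's algorithm (k-means for VQ), used as an independent clustering
# oracle for codebook quality checks.
oracle_lloyd <- function(vectors, K, iters = 100, seed = 1) {
  set.seed(seed)
  C <- vectors[, sample(ncol(vectors), K), drop = FALSE]
  for (it in seq_len(iters)) {
    assign <- integer(ncol(vectors))
    for (j in seq_len(ncol(vectors)))
      assign[j] <- oracle_nearest(vectors[, j], C)["index"]
    for (k in seq_len(K)) {
      if (any(assign == k))
        C[, k] <- rowMeans(vectors[, assign == k, drop = FALSE])
    }
  }
  C
}

random_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# small noisy copy of an image, clipped to pixel range
perturb_image <- function(img, sd, seed) {
  set.seed(seed)
  out <- floor(pmin(pmax(img + rnorm(length(img), 0, sd), 0), 255) + 0.5)
  storage.mode(out) <- "integer"
  out
}
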