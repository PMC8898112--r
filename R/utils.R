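#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators (phantoms, network init) never perturb
#' the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Logistic sigmoid
#' @param x Numeric vector or matrix.
#' @return Values in (0, 1).
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Round a double vector through IEEE float32, the precision used for
# bitstream header fields, so encoder and decoder use identical constants.
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
          "double", size = 4, n = length(x), endian = "little")
}

stopifnot_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix of greylevels", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` must have positive dimensions", arg), call. = FALSE)
  if (any(img < 0 | img > 255) || any(img != round(img)))
    stop(sprintf("`%s` must contain integer greylevels in [0, 255]", arg),
         call. = FALSE)
  invisible(TRUE)
}

check_same_dims <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("image dimensions differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  invisible(TRUE)
}

# FNV-1a 32-bit hash over a raw vector, used as the model fingerprint that
# ties a model-based bitstream to its codec model. Arithmetic is done in
# doubles (exact below 2^53) with explicit mod 2^32 reduction.
fnv1a32 <- function(bytes) {
  h <- 2166136261
  p <- 16777619
  two32 <- 4294967296
  for (b in as.integer(bytes)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * p) %% two32
  }
  h
}

# XOR of a value in [0, 2^32) with a byte, in double arithmetic.
bitwXor_dbl <- function(h, b) {
  lo <- h %% 2^31
  hi <- (h - lo) / 2^31
  lo_x <- bitwXor(as.integer(lo), as.integer(b))
  hi * 2^31 + lo_x
}
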