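#' @name wavelets
#' @title Periodized orthonormal 2-D discrete wavelet transform
#'
#' @description
#' Separable multi-level 2-D DWT with periodic boundary extension and
#' orthonormal filters (`haar`, `db2`, `db4`). Periodization with
#' orthonormal filters makes the transform an orthogonal map: energy is
#' preserved exactly and the inverse is the transpose, which gives perfect
#' reconstruction to floating-point precision.
#'
#' Each decomposed level halves both dimensions, so every transformed
#' dimension must be even at every level (dimensions divisible by
#' `2^level`).
NULL

wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db4 = c(0.230377813308855230, 0.714846570552541500,
          0.630880767929590400, -0.027983769416983850,
          -0.187034811718881140, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

# N x N orthogonal one-level analysis matrix for a periodized filter:
# rows 1..N/2 are the lowpass at even shifts, rows N/2+1..N the highpass
# (quadrature mirror g_n = (-1)^n h_{L-1-n}).
dwt_matrix <- function(n, family) {
  h <- wavelet_filters[[family]]
  if (is.null(h)) stop("unknown wavelet family: ", family, call. = FALSE)
  L <- length(h)
  if (n %% 2L != 0L) stop("transform length must be even, got ", n, call. = FALSE)
  if (n < L) stop(sprintf("length %d too small for %s (filter length %d)",
                          n, family, L), call. = FALSE)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  W <- matrix(0, n, n)
  half <- n %/% 2L
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (j in seq_len(L)) {
      W[k, idx[j]] <- W[k, idx[j]] + h[j]
      W[half + k, idx[j]] <- W[half + k, idx[j]] + g[j]
    }
  }
  W
}

#' 2-D wavelet decomposition
#'
#' @param image Numeric matrix (greylevels or any real plane).
#' @param level Decomposition depth (1-3 typical); every dimension must be
#'   divisible by `2^level`.
#' @param family One of `"haar"` (default), `"db2"`, `"db4"`.
#' @return A `subband_set`: list with `approx` (coarsest approximation
#'   plane), `details` (list of `level` triples, coarsest first, each with
#'   `h`orizontal, `v`ertical and `d`iagonal planes), `level`, `family`,
#'   `original_dims`.
#' @export
#' @examples
#' x <- matrix(runif(64, 0, 255), 8, 8)
#' sb <- dwt2(x, level = 1)
#' max(abs(idwt2(sb) - x)) < 1e-9
dwt2 <- function(image, level = 1L, family = "haar") {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix", call. = FALSE)
  level <- as.integer(level)
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  if (H %% 2^level != 0L || W %% 2^level != 0L)
    stop(sprintf("dimensions %dx%d not divisible by 2^level = %d",
                 H, W, 2^level), call. = FALSE)
  a <- image
  details <- vector("list", level)
  for (l in seq_len(level)) {
    Wr <- dwt_matrix(nrow(a), family)
    Wc <- dwt_matrix(ncol(a), family)
    t2 <- Wr %*% a %*% t(Wc)   # [LL LH; HL HH] layout
    hr <- nrow(a) %/% 2L; hc <- ncol(a) %/% 2L
    ll <- t2[seq_len(hr), seq_len(hc), drop = FALSE]
    lh <- t2[seq_len(hr), hc + seq_len(hc), drop = FALSE]        # horizontal detail
    hl <- t2[hr + seq_len(hr), seq_len(hc), drop = FALSE]        # vertical detail
    hh <- t2[hr + seq_len(hr), hc + seq_len(hc), drop = FALSE]   # diagonal detail
    details[[level - l + 1L]] <- list(h = lh, v = hl, d = hh)
    a <- ll
  }
  structure(list(approx = a, details = details, level = level,
                 family = family, original_dims = c(H, W)),
            class = "subband_set")
}

#' 2-D wavelet reconstruction
#'
#' Inverse of [dwt2()]; restores a plane of the original dimensions.
#'
#' @param subbands A `subband_set` from [dwt2()].
#' @return Numeric matrix of the original dimensions.
#' @export
idwt2 <- function(subbands) {
  if (!inherits(subbands, "subband_set"))
    stop("`subbands` must be a subband_set", call. = FALSE)
  if (length(subbands$details) != subbands$level)
    stop("malformed subband_set: detail count != level", call. = FALSE)
  a <- subbands$approx
  for (l in seq_len(subbands$level)) {
    d <- subbands$details[[l]]
    if (is.null(d$h) || is.null(d$v) || is.null(d$d))
      stop("malformed subband_set: missing detail plane", call. = FALSE)
    if (!identical(dim(d$h), dim(a)) || !identical(dim(d$v), dim(a)) ||
        !identical(dim(d$d), dim(a)))
      stop("malformed subband_set: detail dims do not match approximation",
           call. = FALSE)
    t2 <- rbind(cbind(a, d$h), cbind(d$v, d$d))
    Wr <- dwt_matrix(nrow(t2), subbands$family)
    Wc <- dwt_matrix(ncol(t2), subbands$family)
    a <- t(Wr) %*% t2 %*% Wc   # orthogonal inverse
  }
  if (!identical(dim(a), as.integer(subbands$original_dims)) &&
      !identical(as.integer(dim(a)), as.integer(subbands$original_dims)))
    stop("reconstruction does not match original_dims", call. = FALSE)
  a
}

# Flat ordered list of the planes of a subband set: approximation first,
# then coarsest-to-finest h, v, d. This ordering is the contract used by
# the codec bitstream.
subband_planes <- function(subbands) {
  out <- list(approx = subbands$approx)
  for (l in seq_along(subbands$details)) {
    d <- subbands$details[[l]]
    out[[paste0("h", l)]] <- d$h
    out[[paste0("v", l)]] <- d$v
    out[[paste0("d", l)]] <- d$d
  }
  out
}

# Rebuild a subband_set from the flat plane list produced by subband_planes.
planes_to_subbands <- function(planes, level, family, original_dims) {
  details <- vector("list", level)
  for (l in seq_len(level)) {
    details[[l]] <- list(h = planes[[paste0("h", l)]],
                         v = planes[[paste0("v", l)]],
                         d = planes[[paste0("d", l)]])
  }
  structure(list(approx = planes$approx, details = details, level = level,
                 family = family, original_dims = original_dims),
            class = "subband_set")
}
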