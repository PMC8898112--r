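#' Tile a plane into flattened square blocks
#'
#' Splits a real-valued plane into `block_size` x `block_size` tiles in
#' raster order (left-to-right, top-to-bottom, 0-based top-left origin).
#' When the dimensions are not multiples of `block_size` the plane is
#' padded by replicating its last row/column (replicate-edge padding avoids
#' the ringing a zero pad would create at borders). Each tile is flattened
#' row-major into a column of the `blocks` matrix.
#'
#' @param plane Numeric matrix.
#' @param block_size Tile side, default 8 (giving the 64-dimensional block
#'   vectors the compressor network consumes).
#' @return A `block_set`: list with `blocks` (a `block_size^2` x n matrix,
#'   one column per tile), `grid_dims` (tile rows, tile cols),
#'   `source_dims` (original plane dims), `block_size`.
#' @export
#' @examples
#' p <- matrix(1:16, 4, 4)
#' bs <- tile_blocks(p, block_size = 2)
#' all(untile_blocks(bs) == p)
tile_blocks <- function(plane, block_size = 8L) {
  if (!is.matrix(plane) || !is.numeric(plane) || length(plane) == 0L)
    stop("`plane` must be a non-empty numeric matrix", call. = FALSE)
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("`block_size` must be >= 1", call. = FALSE)
  h <- nrow(plane); w <- ncol(plane)
  gr <- ceiling(h / block_size); gc <- ceiling(w / block_size)
  ph <- gr * block_size; pw <- gc * block_size
  padded <- plane[c(seq_len(h), rep(h, ph - h)),
                  c(seq_len(w), rep(w, pw - w)), drop = FALSE]
  n <- gr * gc
  blocks <- matrix(0, block_size^2, n)
  k <- 0L
  for (bi in seq_len(gr)) {
    for (bj in seq_len(gc)) {
      k <- k + 1L
      tile <- padded[(bi - 1L) * block_size + seq_len(block_size),
                     (bj - 1L) * block_size + seq_len(block_size)]
      blocks[, k] <- as.numeric(t(tile))  # row-major raster within the tile
    }
  }
  structure(list(blocks = blocks, grid_dims = c(gr, gc),
                 source_dims = c(h, w), block_size = block_size),
            class = "block_set")
}

#' Reassemble a plane from a block set
#'
#' Inverse of [tile_blocks()]; padding introduced by tiling is discarded so
#' the original `source_dims` are restored exactly.
#'
#' @param blockset A `block_set`.
#' @return Numeric matrix of dimensions `source_dims`.
#' @export
untile_blocks <- function(blockset) {
  if (!inherits(blockset, "block_set"))
    stop("`blockset` must be a block_set", call. = FALSE)
  b <- blockset$block_size
  gr <- blockset$grid_dims[1]; gc <- blockset$grid_dims[2]
  if (ncol(blockset$blocks) != gr * gc || nrow(blockset$blocks) != b^2)
    stop("inconsistent block_set grid metadata", call. = FALSE)
  padded <- matrix(0, gr * b, gc * b)
  k <- 0L
  for (bi in seq_len(gr)) {
    for (bj in seq_len(gc)) {
      k <- k + 1L
      tile <- matrix(blockset$blocks[, k], b, b, byrow = TRUE)
      padded[(bi - 1L) * b + seq_len(b), (bj - 1L) * b + seq_len(b)] <- tile
    }
  }
  padded[seq_len(blockset$source_dims[1]),
         seq_len(blockset$source_dims[2]), drop = FALSE]
}

#' Affine normalization to \[0, 1\] and its inverse
#'
#' `normalize_values` maps `x -> (x - lo) / (hi - lo)` and clips to
#' \[0, 1\]; `denormalize_values` inverts the map and optionally rounds to
#' the nearest integer when the target is pixel space.
#'
#' @param x Numeric vector or matrix.
#' @param lo,hi Range endpoints, `hi > lo`.
#' @param round_int Round the denormalized values to integers (pixel
#'   mapping), default `FALSE`.
#' @return Numeric object of the same shape.
#' @export
#' @examples
#' normalize_values(127.5, 0, 255)  # 0.5
#' denormalize_values(normalize_values(0:255, 0, 255), 0, 255,
#'                    round_int = TRUE)  # identity on the pixel lattice
normalize_values <- function(x, lo, hi) {
  if (hi <= lo) stop("`hi` must be greater than `lo`", call. = FALSE)
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' @rdname normalize_values
#' @export
denormalize_values <- function(x, lo, hi, round_int = FALSE) {
  if (hi <= lo) stop("`hi` must be greater than `lo`", call. = FALSE)
  v <- x * (hi - lo) + lo
  if (round_int) floor(v + 0.5) else v
}
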