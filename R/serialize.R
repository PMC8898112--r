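# Raw-buffer writer/reader used by the .gwq bitstream and .gwm model
# formats. Multi-byte integers and floats are little-endian; index payloads
# are packed big-endian within bytes (most significant bit first), padding
# bits zero.

new_writer <- function() {
  e <- new.env(parent = emptyenv())
  e$chunks <- list()
  e
}
put_raw <- function(w, r) { w$chunks[[length(w$chunks) + 1L]] <- r; invisible(w) }
put_u8 <- function(w, x) put_raw(w, as.raw(as.integer(x)))
put_u32 <- function(w, x) put_raw(w, writeBin(as.integer(x), raw(),
                                              size = 4, endian = "little"))
put_f32 <- function(w, x) put_raw(w, writeBin(as.numeric(x), raw(),
                                              size = 4, endian = "little"))
put_f64 <- function(w, x) put_raw(w, writeBin(as.numeric(x), raw(),
                                              size = 8, endian = "little"))
put_magic <- function(w, s) put_raw(w, charToRaw(s))
writer_bytes <- function(w) do.call(c, w$chunks)

new_reader <- function(bytes) {
  e <- new.env(parent = emptyenv())
  e$bytes <- bytes
  e$pos <- 0L
  e
}
need <- function(r, n, what) {
  if (r$pos + n > length(r$bytes))
    stop(sprintf("corrupt or truncated stream: need %d bytes for %s at offset %d (have %d)",
                 n, what, r$pos, length(r$bytes) - r$pos), call. = FALSE)
}
get_raw_n <- function(r, n, what = "bytes") {
  need(r, n, what)
  out <- r$bytes[r$pos + seq_len(n)]
  r$pos <- r$pos + n
  out
}
get_u8 <- function(r, what = "u8") as.integer(get_raw_n(r, 1L, what))
get_u32 <- function(r, what = "u32") {
  readBin(get_raw_n(r, 4L, what), "integer", size = 4, endian = "little")
}
get_f32 <- function(r, n = 1L, what = "f32") {
  readBin(get_raw_n(r, 4L * n, what), "double", size = 4, n = n,
          endian = "little")
}
get_f64 <- function(r, n = 1L, what = "f64") {
  readBin(get_raw_n(r, 8L * n, what), "double", size = 8, n = n,
          endian = "little")
}
get_magic <- function(r, s) {
  m <- rawToChar(get_raw_n(r, nchar(s), "magic"))
  if (m != s)
    stop(sprintf("bad magic: expected %s, found %s at offset 0", s, m),
         call. = FALSE)
  invisible(m)
}

# Pack 0-based indices into bytes, `bitwidth` bits each, MSB first.
pack_indices <- function(indices0, bitwidth) {
  if (bitwidth == 0L) return(raw(0))
  n <- length(indices0)
  bits <- matrix(0L, nrow = bitwidth, ncol = n)
  v <- as.integer(indices0)
  for (b in seq_len(bitwidth)) {        # most significant bit first
    shift <- bitwidth - b
    bits[b, ] <- bitwAnd(bitwShiftR(v, shift), 1L)
  }
  flat <- as.integer(bits)
  pad <- (8L - length(flat) %% 8L) %% 8L
  flat <- c(flat, integer(pad))
  m <- matrix(flat, nrow = 8L)
  as.raw(colSums(m * 2L^(7:0)))
}

unpack_indices <- function(bytes, n, bitwidth) {
  if (bitwidth == 0L) return(integer(n))
  needed <- ceiling(n * bitwidth / 8)
  if (length(bytes) < needed)
    stop("corrupt stream: index payload shorter than declared block count",
         call. = FALSE)
  iv <- as.integer(bytes)
  bits <- matrix(0L, nrow = 8L, ncol = length(iv))
  for (b in seq_len(8L)) bits[b, ] <- bitwAnd(bitwShiftR(iv, 8L - b), 1L)
  flat <- as.integer(bits)[seq_len(n * bitwidth)]
  m <- matrix(flat, nrow = bitwidth)
  as.integer(colSums(m * 2L^((bitwidth - 1L):0L)))
}

wavelet_family_id <- function(family) {
  id <- match(family, c("haar", "db2", "db4"))
  if (is.na(id)) stop("unknown wavelet family: ", family, call. = FALSE)
  id
}
wavelet_family_name <- function(id) {
  nm <- c("haar", "db2", "db4")[id]
  if (is.na(nm)) stop("corrupt stream: unknown wavelet family id ", id,
                      call. = FALSE)
  nm
}
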