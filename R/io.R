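#' Read an 8-bit greyscale image
#'
#' Supports PNG and binary PGM (P5, maxval 255). Colour PNGs are reduced to
#' greyscale by averaging channels and rounding. The result is an integer
#' matrix of greylevels in \[0, 255\], rows = image rows (top-left origin).
#'
#' @param path Path to a `.png` or `.pgm` file.
#' @return Integer matrix of greylevels.
#' @export
#' @examples
#' img <- make_phantom("chest", size = 64, seed = 1)
#' f <- tempfile(fileext = ".pgm")
#' write_image(img, f)
#' identical(read_image(f), img)
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      nc <- min(dim(arr)[3], 3L)  # drop alpha
      arr <- apply(arr[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
    }
    img <- round(arr * 255)
    storage.mode(img) <- "integer"
    return(img)
  }
  stop("unsupported image extension: ", ext, call. = FALSE)
}

#' Write an 8-bit greyscale image
#'
#' @param img Integer matrix of greylevels in \[0, 255\].
#' @param path Destination `.png` or `.pgm` path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    write_pgm(img, path)
  } else if (ext == "png") {
    png::writePNG(img / 255, target = path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval; '#' comments allowed
  tok <- character(0)
  buf <- ""
  while (length(tok) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {  # skip to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[ \t\r\n]", ch)) {
      if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  if (tok[1] != "P5") stop("not a binary PGM (P5) file", call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.integer(tok[4])
  if (mx != 255L) stop("only maxval 255 PGM supported", call. = FALSE)
  bytes <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
  if (length(bytes) < w * h) stop("truncated PGM pixel data", call. = FALSE)
  matrix(bytes, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
            eos = NULL, useBytes = TRUE)
  writeBin(as.integer(t(img)), con, size = 1L)
  invisible(path)
}
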