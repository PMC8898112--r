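#' Mean squared error between two images
#'
#' MSE = (1/n) * sum((g - f)^2) over all n = H*W pixels, in squared
#' greylevel units. All metrics are computed in double precision on the
#' integer pixel values.
#'
#' @param original,reconstructed Integer greylevel matrices of identical
#'   dimensions.
#' @return Non-negative scalar.
#' @export
#' @examples
#' a <- matrix(c(0L, 255L, 0L, 255L), 2)
#' b <- matrix(0L, 2, 2)
#' img_mse(a, b)  # 32512.5
img_mse <- function(original, reconstructed) {
  stopifnot_image(original); stopifnot_image(reconstructed)
  check_same_dims(original, reconstructed)
  mean((as.numeric(reconstructed) - as.numeric(original))^2)
}

#' Root mean squared error
#' @inheritParams img_mse
#' @return Non-negative scalar, `sqrt(img_mse(...))`.
#' @export
img_rmse <- function(original, reconstructed) {
  sqrt(img_mse(original, reconstructed))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(255^2 / MSE)` for 8-bit images. For identical images
#' (MSE = 0) the documented sentinel `Inf` is returned rather than an
#' error, so batch evaluation survives lossless cases.
#'
#' @inheritParams img_mse
#' @return Scalar in dB, or `Inf`.
#' @export
img_psnr <- function(original, reconstructed) {
  m <- img_mse(original, reconstructed)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' Structural similarity index
#'
#' SSIM = (2*mu_f*mu_g + c1)(2*cov_fg + c2) /
#'        ((mu_f^2 + mu_g^2 + c1)(var_f + var_g + c2))
#' with the standard stabilizers c1 = (0.01*255)^2, c2 = (0.03*255)^2.
#' By default the statistics are global (whole-image means, variances and
#' covariance); `window = 8` switches to the common sliding-window form
#' (8x8 windows, stride 1, mean of local SSIM). Variance and covariance use
#' the population (divide-by-n) convention.
#'
#' @inheritParams img_mse
#' @param window `NULL` for global statistics (default), or an integer
#'   window side for the windowed mean-SSIM variant.
#' @return Scalar in \[-1, 1\].
#' @export
img_ssim <- function(original, reconstructed, window = NULL) {
  stopifnot_image(original); stopifnot_image(reconstructed)
  check_same_dims(original, reconstructed)
  f <- as.numeric(original); g <- as.numeric(reconstructed)
  if (is.null(window)) return(ssim_stat(f, g))
  w <- as.integer(window)
  H <- nrow(original); W <- ncol(original)
  if (w < 1L || w > min(H, W))
    stop("window must be between 1 and min(H, W)", call. = FALSE)
  vals <- numeric((H - w + 1L) * (W - w + 1L))
  k <- 0L
  for (j in seq_len(W - w + 1L)) {
    for (i in seq_len(H - w + 1L)) {
      k <- k + 1L
      fi <- as.numeric(original[i:(i + w - 1L), j:(j + w - 1L)])
      gi <- as.numeric(reconstructed[i:(i + w - 1L), j:(j + w - 1L)])
      vals[k] <- ssim_stat(fi, gi)
    }
  }
  mean(vals)
}

ssim_stat <- function(f, g) {
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  n <- length(f)
  mf <- mean(f); mg <- mean(g)
  vf <- sum((f - mf)^2) / n
  vg <- sum((g - mg)^2) / n
  cfg <- sum((f - mf) * (g - mg)) / n
  ((2 * mf * mg + c1) * (2 * cfg + c2)) /
    ((mf^2 + mg^2 + c1) * (vf + vg + c2))
}

#' Signal-to-noise ratio (dB)
#'
#' `10 * log10(sum(f^2) / sum((g - f)^2))`. Returns the `Inf` sentinel when
#' the reconstruction is exact; an all-zero original has no defined signal
#' power and raises an error.
#'
#' @inheritParams img_mse
#' @return Scalar in dB, or `Inf`.
#' @export
img_snr <- function(original, reconstructed) {
  stopifnot_image(original); stopifnot_image(reconstructed)
  check_same_dims(original, reconstructed)
  sig <- sum(as.numeric(original)^2)
  if (sig == 0) stop("all-zero original: signal power undefined", call. = FALSE)
  err <- sum((as.numeric(reconstructed) - as.numeric(original))^2)
  if (err == 0) return(Inf)
  10 * log10(sig / err)
}

#' Normalized mean squared error
#'
#' Implemented as `MSE / mean(f^2)`, i.e. error power relative to signal
#' power. This is one of several NMSE conventions in the literature; the
#' choice is documented here so results are interpretable.
#'
#' @inheritParams img_mse
#' @return Non-negative scalar.
#' @export
img_nmse <- function(original, reconstructed) {
  stopifnot_image(original); stopifnot_image(reconstructed)
  check_same_dims(original, reconstructed)
  sig <- mean(as.numeric(original)^2)
  if (sig == 0) stop("all-zero original: signal power undefined", call. = FALSE)
  img_mse(original, reconstructed) / sig
}

#' Compression ratio (percent)
#'
#' `100 * compressed_bits / original_bits`; smaller means stronger
#' compression, 25 means a 4:1 reduction.
#'
#' @param original_bits,compressed_bits Positive integer bit counts.
#' @return Positive scalar percentage.
#' @export
compression_ratio <- function(original_bits, compressed_bits) {
  if (original_bits <= 0 || compressed_bits <= 0)
    stop("bit counts must be positive", call. = FALSE)
  100 * compressed_bits / original_bits
}

#' Full six-metric quality report
#'
#' Aggregates PSNR, SSIM, MSE, RMSE, SNR, NMSE and the compression ratio
#' into one record; each field equals the corresponding standalone metric.
#'
#' @inheritParams img_mse
#' @param stream_bits Size of the compressed representation in bits.
#' @param ssim_window Passed to [img_ssim()].
#' @return A `quality_report` object (named list) with fields `psnr_db`,
#'   `ssim`, `mse`, `rmse`, `snr_db`, `nmse`, `cr_percent`, `stream_bits`.
#' @export
quality_report <- function(original, reconstructed, stream_bits,
                           ssim_window = NULL) {
  rep <- list(
    psnr_db = img_psnr(original, reconstructed),
    ssim = img_ssim(original, reconstructed, window = ssim_window),
    mse = img_mse(original, reconstructed),
    rmse = img_rmse(original, reconstructed),
    snr_db = img_snr(original, reconstructed),
    nmse = img_nmse(original, reconstructed),
    cr_percent = compression_ratio(8 * length(original), stream_bits),
    stream_bits = stream_bits
  )
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Image quality report\n")
  cat(sprintf("  PSNR : %s dB\n", format(x$psnr_db, digits = 6)))
  cat(sprintf("  SSIM : %s\n", format(x$ssim, digits = 6)))
  cat(sprintf("  MSE  : %s\n", format(x$mse, digits = 6)))
  cat(sprintf("  RMSE : %s\n", format(x$rmse, digits = 6)))
  cat(sprintf("  SNR  : %s dB\n", format(x$snr_db, digits = 6)))
  cat(sprintf("  NMSE : %s\n", format(x$nmse, digits = 6)))
  cat(sprintf("  CR   : %s%% (%d bits)\n",
              format(x$cr_percent, digits = 6), x$stream_bits))
  invisible(x)
}
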