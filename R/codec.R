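#' Codec configuration
#'
#' Bundles every knob of the compression pipeline. The defaults are the
#' package's reference operating point: 1-level haar, H = 16 hidden units
#' with recurrent context, K = 256 codewords (8-bit indices).
#'
#' @param family Wavelet family (`"haar"`, `"db2"`, `"db4"`).
#' @param level Decomposition depth.
#' @param n_hidden Hidden width H of the compressor network.
#' @param recurrent Use the Elman context matrix.
#' @param K Codebook size (power of two).
#' @param net_opt [genpso_config()] for network training.
#' @param cb_opt [genpso_config()] for codebook construction.
#' @param seed Master seed; the sub-optimizer seeds are derived from it, so
#'   training is a pure function of (images, config).
#' @return A `codec_config` list.
#' @export
codec_config <- function(family = "haar", level = 1L, n_hidden = 16L,
                         recurrent = TRUE, K = 256L,
                         net_opt = genpso_config(ga_max_gen = 120L,
                                                 pso_max_iter = 300L),
                         cb_opt = genpso_config(ga_max_gen = 150L,
                                                pso_max_iter = 150L,
                                                mutation_rate = 0.5,
                                                mutation_scale = 0.02,
                                                stagnation_tol = 1e-8),
                         seed = 1L) {
  wavelet_family_id(family)  # validate
  if (!as.integer(n_hidden) %in% c(2L, 4L, 8L, 16L, 32L, 64L))
    stop("`n_hidden` must be one of 2, 4, 8, 16, 32, 64", call. = FALSE)
  if (log2(K) != round(log2(K))) stop("`K` must be a power of two", call. = FALSE)
  structure(list(family = family, level = as.integer(level),
                 n_hidden = as.integer(n_hidden), recurrent = isTRUE(recurrent),
                 K = as.integer(K), net_opt = net_opt, cb_opt = cb_opt,
                 seed = as.integer(seed), block_size = 8L),
            class = "codec_config")
}

# Per-plane normalization constants: the approximation plane by its own
# (min, max), detail planes symmetric (-m, m) with m = max |coefficient|.
# Constants are rounded through float32 (their header precision) before
# use, so encoder and decoder normalize identically. Degenerate planes
# (constant, or all-zero details) widen the range by 1 to keep hi > lo.
plane_norm_constants <- function(plane, is_approx) {
  if (is_approx) {
    lo <- min(plane); hi <- max(plane)
  } else {
    m <- max(abs(plane))
    lo <- -m; hi <- m
  }
  if (hi - lo < 1e-9) {  # (near-)constant plane: centre its content at 0.5
    mid <- (hi + lo) / 2
    lo <- mid - 0.5; hi <- mid + 0.5
  }
  lo <- as_float32(lo); hi <- as_float32(hi)
  c(lo = lo, hi = hi)
}

# Wavelet-transform an image and return, per subband plane, the normalized
# tiled blocks plus the metadata compress/decompress need.
image_to_plane_blocks <- function(image, family, level, block_size = 8L) {
  sb <- dwt2(image, level = level, family = family)
  planes <- subband_planes(sb)
  out <- vector("list", length(planes))
  names(out) <- names(planes)
  for (i in seq_along(planes)) {
    nc <- plane_norm_constants(planes[[i]], is_approx = i == 1L)
    norm <- normalize_values(planes[[i]], nc["lo"], nc["hi"])
    bs <- tile_blocks(norm, block_size)
    out[[i]] <- list(blockset = bs, lo = nc[["lo"]], hi = nc[["hi"]],
                     plane_dims = dim(planes[[i]]))
  }
  out
}

#' Train a codec model
#'
#' Implements the full training pipeline: wavelet-transform and tile every
#' training image, train the 64-H-64 compressor network with the hybrid
#' GA-PSO optimizer against the pooled-block reconstruction MSE, encode all
#' training blocks to hidden activations, and build the K-entry codebook
#' over those activations with a second GA-PSO run. With recurrence the
#' hidden state threads along each subband plane's raster order and resets
#' between planes. Deterministic given `config$seed`.
#'
#' @param images List of integer greylevel matrices (or a single matrix).
#' @param config A [codec_config()].
#' @param verbose Print phase progress.
#' @return A `codec_model` with fields `net`, `codebook`, `family`,
#'   `level`, `block_size`, `train_fitness` (final reconstruction MSE in
#'   normalized units), `seed`, `fingerprint`.
#' @export
train_codec <- function(images, config = codec_config(), verbose = FALSE) {
  if (is.matrix(images)) images <- list(images)
  if (length(images) < 1L) stop("need at least one training image", call. = FALSE)
  block_lists <- list()
  for (img in images) {
    stopifnot_image(img)
    pb <- image_to_plane_blocks(img, config$family, config$level,
                                config$block_size)
    block_lists <- c(block_lists, lapply(pb, function(p) p$blockset$blocks))
  }
  pooled <- do.call(cbind, block_lists)
  if (stats::sd(pooled) < 1e-12)
    warning("degenerate (constant) training set; model will be trivial")
  H <- config$n_hidden
  rec <- config$recurrent
  np <- net_n_params(H, rec)
  objective <- function(p) reconstruction_fitness(p, block_lists, H, rec)
  net_cfg <- config$net_opt
  net_cfg$seed <- config$seed
  net_cfg$node_shape <- list(type = "net", n_hidden = H, recurrent = rec)
  if (verbose) message(sprintf("training %d-%d-%d network on %d blocks ...",
                               64L, H, 64L, ncol(pooled)))
  opt <- genpso_optimize(objective, np, net_cfg)
  net <- unflatten_net(opt$best_position, H, rec)
  if (verbose) message(sprintf("  reconstruction MSE %.6g after %d evaluations",
                               opt$best_fitness, opt$evaluations))
  hidden <- do.call(cbind, lapply(block_lists,
                                  function(X) encode_matrix(net, X)))
  cb_cfg <- config$cb_opt
  cb_cfg$seed <- config$seed + 1L
  if (verbose) message(sprintf("building K = %d codebook on %d hidden vectors ...",
                               config$K, ncol(hidden)))
  codebook <- build_codebook(hidden, config$K, cb_cfg)
  model <- structure(list(net = net, codebook = codebook,
                          family = config$family, level = config$level,
                          block_size = config$block_size,
                          train_fitness = opt$best_fitness,
                          net_trace = opt$trace,
                          seed = config$seed, fingerprint = NA_real_),
                     class = "codec_model")
  model$fingerprint <- model_fingerprint(model)
  model
}

# FNV-1a over the model's serialized parameters; written into every
# bitstream so a model-based stream can be matched to its model.
model_fingerprint <- function(model) {
  body <- c(writeBin(flatten_net(model$net), raw(), size = 8, endian = "little"),
            writeBin(as.numeric(model$codebook$codewords), raw(), size = 8,
                     endian = "little"))
  fnv1a32(body)
}

#' @export
print.codec_model <- function(x, ...) {
  cat(sprintf("GenPSO wavelet-VQ codec model\n"))
  cat(sprintf("  network   : 64-%d-64 sigmoid autoencoder%s\n", x$net$n_hidden,
              if (x$net$recurrent) " (recurrent context)" else ""))
  cat(sprintf("  codebook  : K = %d codewords (%d-bit indices)\n",
              x$codebook$K, x$codebook$bitwidth))
  cat(sprintf("  transform : %d-level %s\n", x$level, x$family))
  cat(sprintf("  training reconstruction MSE: %.6g\n", x$train_fitness))
  invisible(x)
}

#' Compress an image to a binary bitstream
#'
#' Wavelet-transforms the image, normalizes each subband plane with
#' constants recorded in the stream header, tiles the planes into 8x8
#' blocks, encodes each block to a hidden activation vector (recurrent
#' context resets at each plane) and vector-quantizes the activations
#' against the model codebook. Indices are packed at log2(K) bits each.
#'
#' By default the stream carries a fingerprint of the codec model and is
#' decoded together with that model (the model is the shared side
#' information of the codec, like the trained tables of any learned
#' coder). With `self_contained = TRUE` the float32 codebook and decoder
#' layer are embedded so the stream decodes alone, at a large fixed header
#' cost.
#'
#' @param image Integer greylevel matrix with dimensions divisible by
#'   `2^level` and at least the block size.
#' @param model A `codec_model` from [train_codec()].
#' @param self_contained Embed codebook + decoder weights (default FALSE).
#' @return Raw vector: the `.gwq` bitstream.
#' @export
compress <- function(image, model, self_contained = FALSE) {
  stopifnot_image(image)
  if (nrow(image) < model$block_size || ncol(image) < model$block_size)
    stop("image dimensions below block size", call. = FALSE)
  pb <- image_to_plane_blocks(image, model$family, model$level,
                              model$block_size)
  w <- new_writer()
  put_magic(w, "GWQ1")
  put_u8(w, 1L)                                    # version
  put_u8(w, if (self_contained) 1L else 0L)        # flags
  put_u32(w, nrow(image)); put_u32(w, ncol(image))
  put_u8(w, wavelet_family_id(model$family))
  put_u8(w, model$level)
  put_u8(w, model$net$n_hidden)
  put_u8(w, if (model$net$recurrent) 1L else 0L)
  put_u32(w, model$codebook$K)
  put_u8(w, model$codebook$bitwidth)
  put_u32(w, model$fingerprint %% 2^31)            # fits a signed int32
  put_u8(w, length(pb))
  if (self_contained) {
    put_f32(w, as.numeric(model$codebook$codewords))
    put_f32(w, as.numeric(model$net$w_out))
    put_f32(w, model$net$b_out)
  }
  for (p in pb) {
    hidden <- encode_matrix(model$net, p$blockset$blocks)
    idx <- vq_encode(hidden, model$codebook)
    payload <- pack_indices(idx$indices - 1L, model$codebook$bitwidth)
    put_u32(w, p$plane_dims[1]); put_u32(w, p$plane_dims[2])
    put_u32(w, p$blockset$grid_dims[1]); put_u32(w, p$blockset$grid_dims[2])
    put_f32(w, c(p$lo, p$hi))
    put_u32(w, length(payload))
    put_raw(w, payload)
  }
  writer_bytes(w)
}

#' Decompress a bitstream back to an image
#'
#' Unpacks the VQ indices, looks up codewords, decodes hidden vectors
#' through the output layer, reassembles and denormalizes every subband
#' plane, inverts the wavelet transform, and clips/rounds to integer
#' greylevels (clip to \[0, 255\], round half-up). Decoder weights and the
#' codebook are rounded through float32 — their serialized precision — in
#' both stream modes, so model-based and self-contained decodes of the
#' same stream are identical. Corrupt or truncated streams raise a format
#' error naming the byte offset.
#'
#' @param stream Raw vector produced by [compress()] (or a file path).
#' @param model The `codec_model`, required unless the stream is
#'   self-contained; its fingerprint must match the stream's.
#' @return Integer greylevel matrix.
#' @export
decompress <- function(stream, model = NULL) {
  if (is.character(stream)) stream <- read_stream(stream)
  r <- new_reader(stream)
  get_magic(r, "GWQ1")
  ver <- get_u8(r, "version")
  if (ver != 1L) stop("unsupported bitstream version ", ver, call. = FALSE)
  flags <- get_u8(r, "flags")
  self_contained <- bitwAnd(flags, 1L) == 1L
  H <- get_u32(r, "height"); W <- get_u32(r, "width")
  family <- wavelet_family_name(get_u8(r, "family"))
  level <- get_u8(r, "level")
  n_hidden <- get_u8(r, "n_hidden")
  recurrent <- get_u8(r, "recurrent") == 1L
  K <- get_u32(r, "K")
  bitwidth <- get_u8(r, "bitwidth")
  fp <- get_u32(r, "fingerprint")
  n_planes <- get_u8(r, "n_planes")
  if (n_planes != 1L + 3L * level)
    stop("corrupt stream: plane count does not match level", call. = FALSE)
  if (self_contained) {
    cw <- matrix(get_f32(r, n_hidden * K, "codebook"), n_hidden, K)
    w_out <- matrix(get_f32(r, n_hidden * 64L, "decoder weights"),
                    n_hidden, 64L)
    b_out <- get_f32(r, 64L, "decoder bias")
  } else {
    if (is.null(model))
      stop("stream is model-based: supply the codec model", call. = FALSE)
    if ((model$fingerprint %% 2^31) != fp)
      stop("model fingerprint does not match stream", call. = FALSE)
    cw <- matrix(as_float32(as.numeric(model$codebook$codewords)),
                 n_hidden, K)
    w_out <- matrix(as_float32(as.numeric(model$net$w_out)), n_hidden, 64L)
    b_out <- as_float32(model$net$b_out)
  }
  codebook <- new_codebook(cw)
  planes <- vector("list", n_planes)
  for (i in seq_len(n_planes)) {
    ph <- get_u32(r, "plane height"); pw <- get_u32(r, "plane width")
    gr <- get_u32(r, "grid rows"); gc <- get_u32(r, "grid cols")
    nc <- get_f32(r, 2L, "normalization constants")
    np_bytes <- get_u32(r, "payload length")
    payload <- get_raw_n(r, np_bytes, "index payload")
    idx0 <- unpack_indices(payload, gr * gc, bitwidth)
    if (any(idx0 < 0L | idx0 >= K))
      stop("corrupt stream: VQ index out of range", call. = FALSE)
    hidden <- vq_decode(idx0 + 1L, codebook)
    blocks <- sigmoid(crossprod(w_out, hidden) + b_out)
    bs <- structure(list(blocks = blocks, grid_dims = c(gr, gc),
                         source_dims = c(ph, pw), block_size = 8L),
                    class = "block_set")
    norm_plane <- untile_blocks(bs)
    planes[[i]] <- denormalize_values(norm_plane, nc[1], nc[2])
  }
  names(planes) <- c("approx", as.vector(t(outer(c("h", "v", "d"),
                                                 seq_len(level), paste0))))
  sb <- planes_to_subbands(planes, level, family, c(H, W))
  rec <- idwt2(sb)
  rec <- floor(pmin(pmax(rec, 0), 255) + 0.5)
  storage.mode(rec) <- "integer"
  rec
}

#' Compress, decompress and measure
#'
#' Runs the full round trip and returns the six-metric [quality_report()],
#' including the compression ratio measured from the actual stream bytes.
#'
#' @inheritParams compress
#' @param ssim_window Passed to [img_ssim()].
#' @return A `quality_report`.
#' @export
evaluate_codec <- function(image, model, self_contained = FALSE,
                           ssim_window = NULL) {
  stream <- compress(image, model, self_contained)
  rec <- decompress(stream, model)
  quality_report(image, rec, 8L * length(stream), ssim_window = ssim_window)
}

#' Predicted bitstream size
#'
#' Computes the stream size in bits from the format definition alone
#' (header fields, per-plane metadata, `ceil(blocks * log2(K) / 8)` payload
#' bytes per plane). [compress()] output matches this exactly; the codec's
#' bit accounting is auditable.
#'
#' @inheritParams compress
#' @return Integer number of bits.
#' @export
predict_stream_bits <- function(image, model, self_contained = FALSE) {
  level <- model$level
  bs <- model$block_size
  # magic, version, flags, H, W, family, level, n_hidden, recurrent, K,
  # bitwidth, fingerprint, n_planes
  header <- 4L + 1L + 1L + 4L + 4L + 1L + 1L + 1L + 1L + 4L + 1L + 4L + 1L
  if (self_contained)
    header <- header + 4L * (model$codebook$K * model$net$n_hidden +
                               model$net$n_hidden * 64L + 64L)
  total <- header
  h <- nrow(image); w <- ncol(image)
  # plane dims: approximation at the coarsest level, then details per level
  plane_dims <- list(c(h %/% 2L^level, w %/% 2L^level))
  for (l in seq_len(level)) {
    d <- c(h %/% 2L^l, w %/% 2L^l)
    plane_dims <- c(plane_dims, list(d, d, d))
  }
  for (pd in plane_dims) {
    gr <- ceiling(pd[1] / bs); gc <- ceiling(pd[2] / bs)
    payload <- ceiling(gr * gc * model$codebook$bitwidth / 8)
    total <- total + 28L + payload
  }
  as.integer(8L * total)
}

#' Write / read a bitstream file
#' @param stream Raw bitstream vector.
#' @param path File path (conventionally `.gwq`).
#' @return `path` / the raw vector.
#' @export
write_stream <- function(stream, path) {
  writeBin(stream, path)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  readBin(path, "raw", n = file.size(path))
}

#' Write a codec model to a `.gwm` file
#'
#' Binary container (magic "GWM1") holding the network shape, full
#' double-precision parameters and codebook; the model round trips
#' bit-exactly.
#'
#' @param model A `codec_model`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  w <- new_writer()
  put_magic(w, "GWM1")
  put_u8(w, 1L)
  put_u8(w, model$net$n_hidden)
  put_u8(w, if (model$net$recurrent) 1L else 0L)
  put_u8(w, wavelet_family_id(model$family))
  put_u8(w, model$level)
  put_u8(w, model$block_size)
  put_u32(w, model$codebook$K)
  put_u32(w, model$seed)
  put_f64(w, model$train_fitness)
  params <- flatten_net(model$net)
  put_u32(w, length(params))
  put_f64(w, params)
  put_f64(w, as.numeric(model$codebook$codewords))
  writeBin(writer_bytes(w), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  r <- new_reader(readBin(path, "raw", n = file.size(path)))
  get_magic(r, "GWM1")
  ver <- get_u8(r, "version")
  if (ver != 1L) stop("unsupported model version ", ver, call. = FALSE)
  n_hidden <- get_u8(r, "n_hidden")
  recurrent <- get_u8(r, "recurrent") == 1L
  family <- wavelet_family_name(get_u8(r, "family"))
  level <- get_u8(r, "level")
  block_size <- get_u8(r, "block_size")
  K <- get_u32(r, "K")
  seed <- get_u32(r, "seed")
  train_fitness <- get_f64(r, 1L, "train_fitness")
  np <- get_u32(r, "n_params")
  params <- get_f64(r, np, "parameters")
  net <- unflatten_net(params, n_hidden, recurrent)
  cw <- matrix(get_f64(r, n_hidden * K, "codebook"), n_hidden, K)
  model <- structure(list(net = net, codebook = new_codebook(cw),
                          family = family, level = level,
                          block_size = block_size,
                          train_fitness = train_fitness,
                          net_trace = NULL, seed = seed,
                          fingerprint = NA_real_),
                     class = "codec_model")
  model$fingerprint <- model_fingerprint(model)
  model
}
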