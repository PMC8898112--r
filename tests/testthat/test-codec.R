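# one small trained model shared across the file (tiny budget: these tests
# exercise the pipeline plumbing, not rate-distortion quality)
tiny_config <- function(seed = 1, n_hidden = 8, K = 16) {
  codec_config(
    n_hidden = n_hidden, K = K, seed = seed,
    net_opt = genpso_config(pop_size = 10, ga_max_gen = 6, pso_max_iter = 10,
                            stagnation_window = 10),
    cb_opt = genpso_config(pop_size = 10, ga_max_gen = 6, pso_max_iter = 10,
                           stagnation_window = 10, mutation_rate = 0.5,
                           mutation_scale = 0.02, stagnation_tol = 1e-8))
}
tiny_images <- lapply(1:2, function(s) make_phantom("brain_ct", 16, seed = s))
tiny_model <- train_codec(tiny_images, tiny_config())

test_that("index packing round trips at every bitwidth", {
  for (b in c(1L, 3L, 4L, 6L, 8L)) {
    set.seed(b)
    idx <- sample(0:(2^b - 1L), 37, replace = TRUE)
    bytes <- genpsowvq:::pack_indices(idx, b)
    expect_identical(length(bytes), as.integer(ceiling(37 * b / 8)))
    expect_identical(genpsowvq:::unpack_indices(bytes, 37, b), idx)
  }
  # big-endian bit order within bytes: 1,0 at bitwidth 4 packs to 0x10
  expect_identical(genpsowvq:::pack_indices(c(1L, 0L), 4L), as.raw(0x10))
  expect_identical(genpsowvq:::unpack_indices(as.raw(0x10), 2L, 4L), c(1L, 0L))
})

test_that("training is deterministic and structurally consistent", {
  m2 <- train_codec(tiny_images, tiny_config())
  expect_identical(flatten_net(tiny_model$net), flatten_net(m2$net))
  expect_identical(tiny_model$codebook$codewords, m2$codebook$codewords)
  expect_identical(tiny_model$fingerprint, m2$fingerprint)
  expect_identical(tiny_model$codebook$dim, tiny_model$net$n_hidden)
  expect_warning(train_codec(matrix(7L, 16, 16), tiny_config()), "degenerate")
})

test_that("compression is byte-deterministic and bit accounting is exact", {
  img <- tiny_images[[1]]
  s1 <- compress(img, tiny_model)
  s2 <- compress(img, tiny_model)
  expect_identical(s1, s2)
  expect_identical(8L * length(s1), predict_stream_bits(img, tiny_model))
  ss <- compress(img, tiny_model, self_contained = TRUE)
  expect_identical(8L * length(ss),
                   predict_stream_bits(img, tiny_model, self_contained = TRUE))
  expect_gt(length(ss), length(s1))
})

test_that("decompression restores dimensions and is stream-determined", {
  img <- tiny_images[[2]]
  stream <- compress(img, tiny_model)
  rec <- decompress(stream, tiny_model)
  expect_identical(dim(rec), dim(img))
  expect_true(all(rec >= 0 & rec <= 255))
  # through a file and a freshly re-read model: identical pixels
  fs <- tempfile(fileext = ".gwq"); fm <- tempfile(fileext = ".gwm")
  write_stream(stream, fs); write_model(tiny_model, fm)
  rec2 <- decompress(read_stream(fs), read_model(fm))
  expect_identical(rec2, rec)
  # self-contained stream decodes with no model at all, to the same pixels
  ss <- compress(img, tiny_model, self_contained = TRUE)
  expect_identical(decompress(ss), rec)
  unlink(c(fs, fm))
})

test_that("corrupt and truncated streams raise format errors", {
  stream <- compress(tiny_images[[1]], tiny_model)
  expect_error(decompress(stream[1:10], tiny_model), "truncated")
  bad <- stream; bad[1] <- as.raw(0x58)
  expect_error(decompress(bad, tiny_model), "magic")
  expect_error(decompress(stream, NULL), "supply the codec model")
  other <- train_codec(tiny_images, tiny_config(seed = 9))
  expect_error(decompress(stream, other), "fingerprint")
})

test_that("model files round trip bit-exactly", {
  f <- tempfile(fileext = ".gwm")
  write_model(tiny_model, f)
  back <- read_model(f)
  expect_identical(flatten_net(back$net), flatten_net(tiny_model$net))
  expect_identical(back$codebook$codewords, tiny_model$codebook$codewords)
  expect_identical(back$fingerprint, tiny_model$fingerprint)
  expect_identical(back$family, tiny_model$family)
  expect_identical(back$level, tiny_model$level)
  unlink(f)
})

test_that("evaluate_codec reports the measured stream exactly", {
  img <- tiny_images[[1]]
  rep <- evaluate_codec(img, tiny_model)
  stream <- compress(img, tiny_model)
  expect_equal(rep$cr_percent, 100 * 8 * length(stream) / (8 * length(img)))
  expect_equal(rep$mse, img_mse(img, decompress(stream, tiny_model)))
  # deterministic
  expect_identical(rep, evaluate_codec(img, tiny_model))
})

test_that("a near-lossless corner case exists for constant-ish content", {
  # one repeated easy block pattern: train on the image itself; with K
  # covering the distinct hidden vectors the VQ step is exact and only the
  # network error remains
  img <- matrix(120L, 16, 16)
  img[5:12, 5:12] <- 121L
  cfg <- tiny_config(seed = 3, n_hidden = 8, K = 16)
  cfg$net_opt$ga_max_gen <- 20L; cfg$net_opt$pso_max_iter <- 60L
  m <- suppressWarnings(train_codec(img, cfg))
  rep <- evaluate_codec(img, m)
  expect_gt(rep$psnr_db, 40)
  expect_gt(rep$ssim, 0.9)
})
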