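Package: genpsowvq
Title: Medical Image Compression with a Wavelet-Domain Neural Codec and
    Hybrid GA-PSO Trained Vector Quantization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossy compression of 8-bit greyscale medical images. Images are
    decomposed with a periodized orthonormal 2-D discrete wavelet transform,
    subband planes are tiled into 8x8 blocks, and each block is squeezed through
    a small 64-H-64 sigmoid autoencoder (optionally with Elman-style recurrent
    context) whose hidden activations are vector-quantized against a learned
    codebook. Both the network weights and the codebook are trained by a hybrid
    derivative-free optimizer: a genetic algorithm with node-level crossover and
    tournament selection whose final population seeds a particle swarm. The
    package provides the full codec (train, compress to a binary bitstream,
    decompress, evaluate), a six-metric quality suite (PSNR, SSIM, MSE, RMSE,
    SNR, compression ratio), seeded anatomy-like phantom generators for four
    imaging modalities, and PNG/PGM image input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
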