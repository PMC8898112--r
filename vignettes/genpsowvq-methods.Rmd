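---
title: "Wavelet-domain neural vector quantization with hybrid GA-PSO training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-domain neural vector quantization with hybrid GA-PSO training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genpsowvq)
```

## The codec in one paragraph

`genpsowvq` is a lossy codec for 8-bit greyscale medical images. An image is
decomposed by a periodized orthonormal 2-D discrete wavelet transform
(default 1-level haar); every subband plane is affinely normalized to
$[0,1]$ and tiled into $8\times8$ blocks; each flattened 64-vector is pushed
through a small sigmoid autoencoder $64 \to H \to 64$; the $H$-dimensional
hidden activation — not the block itself — is vector-quantized against a
learned codebook of $K$ codewords, so a block costs $\log_2 K$ bits in the
payload. Decoding inverts each step: codeword lookup, output layer, untile,
denormalize, inverse transform, clip and round to integer greylevels. Both
the network weights and the codebook are trained by the same hybrid
derivative-free optimizer: a genetic algorithm (GA) whose final population
seeds a particle swarm (PSO).

## The pipeline, step by step

**Wavelet front end.** The transform uses orthonormal filters (`haar`,
`db2`, `db4`) with periodic boundary extension, implemented as orthogonal
transform matrices, so analysis followed by synthesis is exact to
floating-point precision and coefficient energy equals pixel energy
(Parseval). Each level halves both dimensions; dimensions must therefore be
divisible by $2^{\mathrm{level}}$. Haar at one level is the default: it is
the simplest orthonormal choice, keeps all subband sizes integer for
8-divisible images, and concentrates the phantoms' energy almost entirely
(>98%) in the approximation band.

**Normalization.** Sigmoid outputs live in $(0,1)$, so every plane is mapped
affinely into $[0,1]$ before encoding. The approximation plane uses its own
$(\min,\max)$; detail planes use the symmetric range $(-m, m)$ with
$m = \max|c|$, which maps the typical near-zero detail coefficient to $0.5$
— the sigmoid's easiest operating point. A constant plane would make the
range degenerate, so it is widened to width 1 centred on the constant,
again mapping content to $0.5$. The constants are rounded through IEEE
float32 — their precision in the bitstream header — *before* use, so the
encoder and the decoder normalize with bit-identical values.

**Blocks and recurrence.** Tiling is row-major with replicate-edge padding
(zero padding would manufacture artificial edges at borders). The
compressor network optionally carries an Elman-style context matrix feeding
the previous block's hidden state into the current one; the context threads
along each plane's raster order and resets between planes, so a plane can
always be decoded from its own indices. Recurrence is on by default; with
it off the codec is a pure block autoencoder and block codes are
permutation-equivariant.

**Vector quantization.** Hidden vectors are matched to the nearest codeword
in squared euclidean distance, ties to the lowest index (a determinism
requirement across platforms). The payload for a plane with $B$ blocks is
exactly $\lceil B \log_2 K / 8 \rceil$ bytes; `predict_stream_bits()`
computes the whole stream size from the format definition and the tests
assert the measured size equals it bit for bit.

**Bitstream modes.** The default stream records dimensions, transform
metadata, per-plane normalization constants and packed indices, plus a
32-bit FNV-1a fingerprint tying it to its codec model (`.gwm` file); model
and stream together fully determine the output. With
`self_contained = TRUE` the float32 codebook and decoder layer are embedded
so the stream decodes alone. The embedded side information is large
relative to small images — for a $64\times64$ image the float32 codebook
plus decoder layer alone ($4(KH + 64H + 64)$ bytes) can exceed the 4096
raw bytes — which is why the model-based mode is the default: the model is
trained per corpus and shared across many streams, as in any learned
codec. In both modes the decoder rounds weights and codewords through
float32 so the two modes reconstruct identical pixels.

## The hybrid optimizer

The GA phase evolves a population of $\mu$ flat genomes (default 50):
uniform random initialization on $[-0.5, 0.5]$; offspring from uniformly
drawn parent pairs by *node crossover* — one hidden or output unit is
picked uniformly and its complete incoming-weight slice (bias included, and
the context row for recurrent hidden units) is exchanged between the
parents — followed by per-gene gaussian mutation; parents and offspring are
randomly mixed and each of the $2\mu$ candidates plays
$\mathrm{round}(0.2\mu)$ distinct random opponents, scoring a win per
opponent with strictly worse fitness; the $\mu$ highest scorers survive,
ties broken by fitness then stable order. The GA stops when the best
fitness varies by less than $10^{-5}$ over 50 successive generations (both
defaults configurable; the variation measure is the window's range, with a
successive-delta option) or at a hard generation cap. Elitism is on by
default, making the best-fitness history non-increasing.

The PSO phase starts every particle at a GA-final genome with zero
velocity, then iterates
$v \leftarrow wv + c_1 r_1 (p_{\text{best}} - x) + c_2 r_2 (g_{\text{best}} - x)$,
$x \leftarrow x + v$ with the standard constriction-style coefficients
$w = 0.729$, $c_1 = c_2 = 1.49445$, per-coordinate uniform $r_1, r_2$, and a
velocity clamp of $\pm1$ per coordinate to bound divergence. `gbest` is
stored as a copy and only replaced on strict improvement, so its trace is
non-increasing. The whole run is a pure function of (objective, config,
seed): identical seeds give bit-identical traces, and objective evaluations
are counted exactly.

**A dynamics note that shaped the defaults.** Because particles start *at*
the GA population with zero velocity, the swarm's search energy comes
entirely from the diversity of that population. For codebook construction —
a smooth, almost-quadratic distortion landscape — the most effective
configuration drives the GA as a fine-scale stochastic hill climber
(mutation rate 0.5, scale 0.02) so the PSO inherits a tight, diverse cloud
it can contract precisely; with these settings the optimizer reproduces the
closed-form centroid at $K=1$ to ~1e-9 and matches Lloyd's algorithm within
a few percent on clustered data. Network training keeps the broader
defaults (rate 0.05, scale 0.1), which explore more. Both are exposed in
`codec_config()`.

## Codebook construction

The codebook genome stacks the $K$ codewords ($K \cdot H$ genes, each
codeword a crossover node); the objective is the mean squared euclidean
distance of the training vectors to their nearest codeword. Half of the
initial GA population is built from $K$-column subsets of the training
vectors (the first such candidate takes the first $K$ *distinct* vectors,
guaranteeing a zero-distortion candidate whenever $K$ covers the distinct
training set — elitism then never loses it); the other half is uniform
random over the data's bounding box.

## The phantom generator

The four archetypes mimic the modality mix of typical greyscale medical
acquisitions at the statistical level the codec cares about — large
piecewise-smooth regions, sharp boundaries, dark background, bright
anatomy, mild texture — not anatomical fidelity: chest (two lung ellipses
in a soft-tissue thorax, three rib arcs, bright mediastinum), brain CT
(bright skull annulus, parenchyma, dark ventricles, thin falx), mammogram
(textured disc with a gradient and a cluster of bright specks), abdominal
CT (nested organ ellipses, bright aorta and vertebra). Soft-tissue texture
is a sum of a few low-frequency random cosines; sensor noise is additive
gaussian with default `noise_sd = 2` greylevels, a mild level chosen so the
noise-free piecewise structure still dominates (at sd 2 the lossless PSNR
ceiling from rounding alone is far above anything the codec reaches).
Phantoms are pure functions of their spec; the generator restores the
caller's RNG state.

What the phantoms do *not* emulate: detector physics (Poisson noise,
scatter), anatomy-scale texture spectra, pathology, or bit depths beyond 8.
Passing tests demonstrate the pipeline's correctness and its behaviour on
piecewise-smooth content; they do not certify diagnostic quality on real
studies.

Structural checks on the generator (measured at $192\times192$, where
boundary blocks are a small fraction of all blocks): at `noise_sd = 0` at
least 60% of $8\times8$ blocks have within-block variance below 25
greylevels² and 1-level haar detail energy is below 15% of total energy; at
`noise_sd = 5` histograms span at least 100 distinct greylevels.

## Problem sizes and study conditions

The reference evaluation trains on the 8-image phantom suite (two per
modality, $64\times64$, `noise_sd = 2`) at the operating point H = 16,
K = 64, 1-level haar, recurrence on, then round trips every image. Network
training uses population 50 with a 60-generation GA and 300 PSO iterations
(≈18,000 evaluations of the pooled 512-block reconstruction MSE); the
codebook run uses population 30 with fine-scale mutation. Unit tests use
$16\times16$ images and few-hundred-evaluation budgets: they exercise
plumbing, not rate-distortion performance.

## Known limitations, honestly measured

At this operating point the codec spends 6 bits per 64 coefficients
(≈0.09 bpp plus header) — an extremely aggressive rate. Two factors bound
the reachable quality:

* **Rate ceiling.** With K = 64 the decoder can emit at most 64 distinct
  reconstructions per block (codeword → output layer is deterministic), so
  a whole $64\times64$ image is assembled from a 64-entry block dictionary.
  Sharp-boundary content at arbitrary offsets cannot be represented well by
  so small a dictionary regardless of how the network and codebook are
  trained; this binds long before high-fidelity thresholds, independently
  of the optimizer.
* **Optimization gap.** GenPSO at the reference budget reaches a pooled
  reconstruction MSE of ≈0.02 in normalized units, which the acceptance run
  turns into mean round-trip PSNR of ≈12–14 dB on the suite. More budget
  narrows this gap only slowly (derivative-free search over thousands of
  weights), and the rate ceiling above caps what any budget could buy.

A related consequence, asserted honestly in the acceptance suite: at
matched evaluation budgets, *larger* hidden layers train *worse* (H = 4
typically beats H = 32 end to end), because in the derivative-free regime
optimization error grows with genome dimension faster than representation
error shrinks with capacity. Capacity monotonicity would only re-emerge
near convergence, outside desk-scale budgets for the larger genomes.

Other limitations: no entropy coding of indices (indices are near-uniform
only by accident; a Huffman stage would cut the payload further); no
rate-control loop (the operating point is chosen by configuration); colour,
video, DICOM containers and perceptual metrics beyond SSIM are out of
scope.

## Numerical conventions

* Metrics: PSNR $= 10\log_{10}(255^2/\mathrm{MSE})$ dB; SSIM uses global
  (whole-image) statistics by default with $c_1 = (0.01\cdot255)^2$,
  $c_2 = (0.03\cdot255)^2$ and population (divide-by-$n$) variance and
  covariance — an 8×8 sliding-window mean-SSIM is available via
  `window = 8`; SNR $= 10\log_{10}(\sum Y^2 / \sum(\hat{Y}-Y)^2)$ dB; NMSE
  $= \mathrm{MSE}/\overline{Y^2}$ (one of several conventions, stated so
  oracles can match). Lossless cases return the documented `Inf` sentinel
  rather than erroring, so batch evaluation survives them.
* Reconstruction clips to $[0,255]$ then rounds half-up.
* Serialization: little-endian integers and floats, float32 header
  constants and embedded weights, big-endian bit order inside payload
  bytes, zero padding bits. VQ ties break to the lowest index.
* All randomness flows from explicit integer seeds; generators restore the
  caller's RNG state.

```{r example, eval = FALSE}
suite <- make_test_suite(2, c(64, 64), seed = 1)
model <- train_codec(lapply(suite, `[[`, "image"),
                     codec_config(n_hidden = 16, K = 64, seed = 42))
evaluate_codec(suite[[1]]$image, model)
```
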