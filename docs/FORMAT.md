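# Binary formats

All multi-byte integers and floats are little-endian. Index payloads are
packed big-endian within bytes (most significant bit first); padding bits
are zero.

## `.gwq` bitstream

| field | type | notes |
|---|---|---|
| magic | 4 bytes | `"GWQ1"` |
| version | u8 | 1 |
| flags | u8 | bit 0: self-contained |
| height, width | u32 ×2 | image dimensions |
| family | u8 | 1 = haar, 2 = db2, 3 = db4 |
| level | u8 | decomposition depth |
| n_hidden | u8 | hidden width H |
| recurrent | u8 | 0/1 |
| K | u32 | codebook size |
| bitwidth | u8 | log2(K) |
| fingerprint | u32 | FNV-1a of the model parameters (mod 2^31) |
| n_planes | u8 | 1 + 3·level |
| *if self-contained:* codebook | f32 × H·K | column-major codewords |
| *if self-contained:* w_out | f32 × H·64 | decoder weights, column-major |
| *if self-contained:* b_out | f32 × 64 | decoder bias |

Then for each plane (approximation first, then h/v/d per level, coarsest
first):

| field | type |
|---|---|
| plane height, width | u32 ×2 |
| grid rows, cols | u32 ×2 |
| lo, hi | f32 ×2 (normalization range) |
| payload length | u32 (bytes) |
| payload | packed 0-based VQ indices, `ceil(blocks·bitwidth/8)` bytes |

Total size in bits always equals `predict_stream_bits()`.

## `.gwm` model

`"GWM1"`, version u8, n_hidden u8, recurrent u8, family u8, level u8,
block_size u8, K u32, seed u32, train_fitness f64, n_params u32, the flat
parameter vector as f64 (order: w_in, b_hidden, w_rec if recurrent, w_out,
b_out, all column-major), then the codebook as f64 (column-major). Full
double precision so a model round trips bit-exactly.
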