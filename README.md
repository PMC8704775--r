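# ctdual

Degradation-aware dual-domain reconstruction for sparse-view CT, as a
self-contained R package: a fan-beam acquisition simulator, a hand-built
convolutional network that couples a blockwise-DCT frequency-attention
module with an image-domain spatial-attention and refining module, the
four-stage training curriculum that ties them together, and an
evaluation/statistics suite — all exercisable on seeded synthetic
phantoms with no external data.

## The problem and the model

Sparse-view CT (60/120/240 projection angles instead of hundreds) trades
dose for streak artifacts after filtered back projection (FBP). Networks
trained at one degradation level generalize poorly to others. The model
implemented here handles all levels with a single parameter set by
sensing the degradation in two domains:

* the image is expanded into 64 blockwise 8×8 DCT channels (zig-zag
  order) by a stride-8 convolution whose kernels are the orthonormal
  cosine basis
  `W(i,j) = c(ξ1)c(ξ2) cos((i+0.5)πξ1/8) cos((j+0.5)πξ2/8)`;
  a squeeze-and-excite attention (64→32→64, sigmoid) reweights each
  frequency per input before a densely connected encoder–decoder
  restores the coefficients and an IDCT layer returns to image space;
* a 4-level U-Net predicts a *critical map* — the probability that a
  pixel is a ground-truth edge pixel with reconstruction error above
  0.01 on the normalized scale — which guides a 6-ResBlock residual
  refining block.

The physics follows the Lambert–Beer chain
`μ = 0.02 (hu/1000 + 1) mm⁻¹`, `I = 1e5 · exp(−p)`,
`Ĩ = Poisson(I) + N(0, 10)`, `p̃ = −log(Ĩ/I0)`, on a fan-beam geometry
(346 mm source–center, 261 mm center–detector, 370 mm FOV, 1024 bins of
0.75 mm, 0.5 mm pixels) with exact Siddon forward projection and
Hann-windowed weighted fan-beam FBP. Evaluation reports PSNR/SSIM with
normal-theory confidence intervals, per-frequency (8×8) error maps,
frequency-attention-map extraction, and the paired two-sided t-test
`t = d̄/(s_D/√n)`, `p = 2·tcdf(−|t|)`.

## Worked example

```r
library(ctdual)

ph <- make_ellipse_phantom(phantom_spec(64, seed = 42))
s  <- degrade(ph, n_views = 60, seed = 1)   # fan-beam + noise + FBP
psnr(s$degraded, s$gt)
#> [1] 31.87823

ds    <- make_dataset(32, size = 64, seed = 1)
model <- train_curriculum(ds, seed = 1, max_iters = 300)  # ~15 min, 1 CPU

r <- forward_full(model, s$degraded)
psnr(matrix(r$final, 64, 64), s$gt)
#> [1] 39.73606

round(critical_value(0.005, 1000), 4)
#> [1] 2.8133
```

The numbers above are what the code printed at these seeds: the trained
model gains about 8 dB over its FBP input on this 60-view phantom, and
the two-sided t critical value at α = 0.005 with 1000 test images is
2.8133.

A command-line surface wraps the same functions
(`inst/cli/ctdual.R`): `fixtures`, `simulate`, `train`, `reconstruct`,
`evaluate`, `compare`, `audit`, e.g.

```sh
Rscript inst/cli/ctdual.R simulate --in phantoms/ --out degraded/ \
    --views 60,120,240 --seed 1 --i0 1e5 --gauss-var 10
```

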