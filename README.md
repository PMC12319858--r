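# tcmap — temporal coherence mapping for time series and fMRI volumes

Resting-state brain activity is neither pure noise nor pure rhythm: a
voxel's signal partly repeats its own past (coherence) and partly
mirrors it (anti-coherence), over delays far longer than one sampling
step. `tcmap` quantifies both sides and their balance for any
one-dimensional series, and maps them voxelwise over 4D NIfTI volumes.
It is aimed at neuroimaging researchers who want per-voxel long-range
temporal-coherence metrics with test–retest reliability assessment, and
at anyone who needs the underlying time-series statistic on its own.

## The statistic

A series `x` of length `N` is expanded into embedding vectors
`u_i = [x_{(i-1)g+1}, …, x_{(i-1)g+w}]` — sliding windows of `w`
samples with stride `g`. The correlation matrix of all window pairs
(the **TCM matrix**) is summarized by six metrics:

* `TC = Σ cc·H(cc) / Totnum_cc` — mean positive correlation,
* `TAC = Σ (−cc)·H(−cc) / Totnum_cc` — mean magnitude of negative
  correlation (`H` = Heaviside, `H(0) = 0`),
* `CAB1 = TC − TAC` — the coherence/anti-coherence balance,
* `MLP`, `MLN` — total length of diagonal runs (length ≥ 2) in the
  matrices binarized at `cc > r` and `cc < −r`, normalized by
  `Totnum_cc`; these measure how long revisited states persist,
* `CAB2 = MLP − MLN`.

Sums run over upper-triangle diagonals `dia_s ≤ d < nv − dia_e`
(excluding trivially correlated near-diagonals and unstable short
trailing diagonals), with
`Totnum_cc = nv(nv−1)/2 − dia_e(dia_e+1)/2`. The production path
streams diagonal-by-diagonal with rolling Pearson sums — `O(N)` memory,
never materializing the `nv × nv` matrix — and is verified against an
explicit full-matrix reference path to `1e-10`.

## Worked example

```r
library(tcmap)
x <- gen_pink_noise(400, seed = 3)        # 1/f noise, long-range correlated
tcm_metrics(x, tcm_config(w = 20))
#> TCM metrics (N = 400 , nv = 381 embedding vectors)
#>   TC   = 0.1256   TAC  = 0.1328   CAB1 = -0.0072
#>   MLP  = 0.1749   MLN  = 0.1899   CAB2 = -0.0150
#>   pairs evaluated 70290 / Totnum_cc 72180; 34598 positive, 35692 negative
```

TC ≈ TAC ≈ 0.13 says this 1/f signal revisits and mirrors its past in
near balance; the slightly negative CAB1 and CAB2 show the
anti-coherent side dominates, a signature 1/f noise shares with
resting-state BOLD. For white Gaussian noise the same call gives TC and
TAC near 0.09 with CAB1 ≈ −0.002 — memoryless signals carry no
comparable excess, and the gap widens with longer series.

Voxelwise mapping and reliability:

```r
vol  <- gen_synthetic_volume(c(8, 8, 4), 300,
          recipe = list(pink = list(kind = "pink"),
                        white = list(kind = "white")), seed = 1)
maps <- compute_tcm_maps(as_volume_series(vol), tcm_config(), workers = 4)
write_maps(maps, "out/")                  # six NIfTI maps + JSON sidecar
icc_map(maps$tc, maps$tc)                 # 1: identical sessions agree exactly
```

A command-line front end wraps the same functions
(`exec/tcm map|series|simulate|average|icc|physio`), e.g.

```sh
tcm map --in bold.nii.gz --mask mask.nii.gz --w 30 --r 0.3 --workers 8 --out maps/
tcm physio --in rec.csv --fs 400 --kind cardiac --out rates.json
```

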