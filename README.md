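# chromsig

Characterize the multichannel chromatin landscape around a set of anchor
loci, and find more loci like them, genome-wide.

Given several histone-modification ChIP-seq tracks (possibly at several
time points) and a set of anchor peaks — for example the early binding
sites of a pioneer transcription factor — chromsig:

1. **Extracts** a chromatin signature per locus: an M × L matrix of M
   channels over L positional bins (default 10 Kb windows at 10 bp, so
   L = 1000).
2. **Orients** each locus with an iterative Max–Max algorithm: starting
   from random strands, alternate between computing the mean signature and
   flipping every locus to the orientation closer to it, until no locus
   flips. This recovers one-sided features (promoter-style H3K4me3) that
   plain averaging would cancel.
3. **Clusters** the oriented signatures by spectral clustering. Per
   channel m, pairwise distances are RMSDs,
   `dist_ij = sqrt(sum((x_i − x_j)^2) / L)`, mapped to adjacencies by a
   Gaussian kernel `w_ij = exp(−dist_ij² / 2σ_m²)` with σ_m calibrated at
   the 10th percentile of that channel's distance distribution (so exactly
   10% of pairs per channel exceed `exp(−1/2) ≈ 0.606`, equalizing channel
   influence). Channel adjacencies are summed into W, and loci are
   embedded with the symmetric normalized Laplacian
   `L_sym = D^{−1/2}(D − W)D^{−1/2}` (Ng–Jordan–Weiss: k smallest
   eigenvectors, rows normalized to the unit sphere, then k-means), with k
   chosen by the eigengap heuristic.
4. **Scans** the genome with a cluster's mean signature at a 100 bp
   stride, in both orientations, scoring each window per channel by
   `Score_i^m = Corr(cl^m, x_i^m) · P_m(height_i^m)` — Pearson correlation
   regularized by the empirical relative frequency of the window's mean
   signal among the training loci — and summing over channels. The prior
   penalizes windows with the right shape at the wrong ChIP magnitude.
   Hits are local maxima (centres ≥ 5 Kb apart); the top 2500 are
   reported.

A synthetic-track generator plants promoter-like, enhancer-like and
featureless signatures with known orientations into noisy tracks, so every
stage is testable end-to-end without external data. See the methods
vignette (`vignettes/chromatin-signatures.Rmd`) for the model, parameter
choices and known limitations.

## Worked example

```r
library(chromsig)

sim <- simulate_tracks(sim_config(n_promoter = 60, n_enhancer = 60,
                                  n_flat = 60, seed = 42))
sim$tracks
#> <track_set> 6 channels, 4 chromosomes, bin 10 bp
#>   channels: H3K4me1_c14, H3K4me3_c14, H3K27me3_c14, H3K4me1_c13, ...
#>   genome:   2,160,000 bp

sigs <- extract_signatures(sim$tracks, sim$peaks)
fit <- reorient(sigs, seed = 17)
fit
#> <reorient_fit> 180 loci, 5 iteration(s), converged
#>   flips per iteration: 56, 56, 6, 2, 0

cfit <- cluster_signatures(fit$signatures, seed = 17)
cfit
#> <cluster_fit> 180 loci in 3 clusters (sizes: 60, 60, 60)
#>   leading eigenvalues: 0.0000, 0.0234, 0.0613, 0.9592
head(tidy(cfit), 4)
#> # A tibble: 4 × 4
#>   chrom summit orientation cluster
#> 1 chrS1   6000 +                 3
#> 2 chrS1  18000 -                 3
#> 3 chrS1  30000 -                 2
#> 4 chrS1  42000 +                 1
```

The re-orientation converged in 5 sweeps (the final sweep flips nothing),
and the eigengap — three near-zero Laplacian eigenvalues, then a jump to
0.96 — selects k = 3, recovering the three planted classes exactly (60
loci each). `autoplot(cfit)` draws the per-cluster mean profiles per
modification.

Scanning a fresh 2 Mb synthetic genome with the strongest cluster's
signature (cycle-14 channels) and its height prior:

```r
c14 <- c("H3K4me1_c14", "H3K4me3_c14", "H3K27me3_c14")
tmpl <- cluster_template(cfit, cluster = 1, channels = c14)
members <- subset_signatures(cfit$signatures, cfit$labels == 1)
prior <- fit_height_prior(members, channels = c14)

genome <- simulate_scan_genome(genome_bp = 2e6, n_implant = 10, seed = 7)
hits <- scan_genome(genome$tracks, tmpl, prior, top_n = 10)
head(hits[, c("chrom", "center", "orientation", "score", "rank")], 5)
#> # A tibble: 5 × 5
#>   chrom  center orientation score  rank
#> 1 chrS1  972000 +           0.706     1
#> 2 chrS1 1920000 -           0.704     2
#> 3 chrS1 1980000 +           0.604     3
#> 4 chrS1 1968000 -           0.582     4
#> 5 chrS1  672000 -           0.581     5
evaluate_recall(hits, genome$truth, tolerance_bp = 200)
#> [1] 1
```

All 10 implanted loci are recovered within ±200 bp among the top 10 hits,
in both planted orientations. The per-hit score is the sum of the
per-channel `score_*` columns; `write_bed(hits, "hits.bed")` exports
browser-ready BED6.

## Command line

A thin CLI wraps the same functions:

```sh
exec/chromsig simulate --seed 7 --n-per-class 60 -o simdir/
exec/chromsig reorient --config cfg.yaml --peaks simdir/peaks.bed --seed 17 -o out/
exec/chromsig cluster  --config cfg.yaml --peaks simdir/peaks.bed --seed 17 -o out/
exec/chromsig scan     --config cfg.yaml --peaks simdir/peaks.bed --cluster 1 -o out/
exec/chromsig evaluate --hits out/hits.bed --reference simdir/peaks.bed
```

The YAML config maps channel names to bedGraph paths and may override
`bin_bp`, `window_bp`, `percentile`, `k_max`, `stride_bp`, `top_n` and
`seed`; every run writes a JSON metadata sidecar (seed, parameters,
parameter hash) sufficient to reproduce it. Exit codes: 0 success, 2
config error, 3 data error.

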