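# sodamap

Object-based colocalization analysis for fluorescence microscopy.
`sodamap` decides whether two spot or localization populations inside a
cell are statistically coupled, and at what distance — the question
behind synaptic-protein association (e.g. presynaptic synapsin vs
postsynaptic PSD-95), but applicable to any pair of labeled populations
in any cell type, in conventional microscopy or SMLM/STORM, in 2D or 3D.

The pipeline:

1. **Spot detection** — undecimated à-trous B3-spline wavelet
   decomposition; voxels whose detail coefficients exceed
   `k_sigma` robust noise units at every selected scale become spots
   (intensity-weighted sub-pixel centroids). SMLM tables skip this
   stage — localizations are already points.
2. **Cell mask** — K-class intensity K-means thresholding of a
   counterstain channel (MAP2/membrane stain) with component-size
   filtering and morphological closing. The mask supplies the domain
   measure |Ω| and the boundary geometry.
3. **Coupling statistics** — ring-wise bivariate Ripley analysis with
   isotropic edge correction:

   K̂ₖ = |Ω|/(N₁N₂) · Σ_{pairs in ring k} w_ij,  E[K̂ₖ | CSR] = Aₖ (ring measure)

   Significance per ring against a seeded Monte-Carlo CSR null (Šidák
   over rings, skew-corrected tails); significant excess converts to
   pair coupling probabilities pₖ = (K̂ₖ−Aₖ)/K̂ₖ, which aggregate into
   the expected couple count, per-channel coupling fractions, the
   probability-weighted mean ± sd coupling distance, and a global
   p-value.
4. **Outputs** — fixed-schema results CSVs (single + batch) and a
   molecular association map: mask in deep blue, isolated channel-1
   spots green, associated ones cyan, isolated channel-2 spots red,
   associated ones pink.

A seeded synthetic-data generator (`sim_scenario`, `simulate_patterns`,
`render_image`, `simulate_batch`) produces ground-truth point patterns
with a known coupled fraction and distance, plus rendered
Gaussian-PSF/Poisson images, and backs every statistical test.

## Worked example

```r
library(sodamap)

# ground truth: 300 points/channel in a 10x10 um cell, half of channel 2
# coupled at 50 +/- 10 nm
pat <- simulate_patterns(sim_scenario(coupled_fraction = 0.5,
                                      coupling_distance = 50,
                                      jitter_sd = 10, seed = 3))
res <- run_soda(pat$spots1, pat$spots2, pat$mask,
                rings_uniform(r_max = 300, width = 30), B = 500, seed = 42)
res$coupling
#> coupling_result: n_coupled = 161.45, fraction ch1 = 0.538 / ch2 = 0.538
#>   distance = 50.7 +/- 12.4 nm, p = 0
```

161 of 300 channel-2 points are estimated to be coupled (fraction 0.54,
true value 0.50) at 50.7 ± 12.4 nm (true law 50 ± 10 nm), with a global
p-value indistinguishable from zero. Under the same conditions with
`coupled_fraction = 0` the analysis reports `n_coupled = 0`, NA
distances, and a large p-value.

Image-mode end to end, from a directory of multichannel TIFFs
(channels: ch1, ch2, mask stain):

```r
cfg <- run_config(mode = "image", pixel_size_nm = 100,
                  channels = list(ch1 = 1, ch2 = 2, mask = 3),
                  resamples = 500, seed = 1, out_dir = "out")
agg <- run_batch(cfg, "my_tiffs/")   # per-image CSV/PNG + batch CSV
```

The same protocol runs from the shell via the thin CLI in
`inst/cli/sodamap` (subcommands `simulate`, `run`, `batch`; YAML config
mirrored by `run_config()`).

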