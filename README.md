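# ryrscape

Spatial statistics, pattern reconstruction and calcium dynamics of
ryanodine-receptor (RyR) cluster landscapes in cardiomyocytes.

RyRs cluster into couplons at the z-discs of heart muscle cells and release
the Ca²⁺ that triggers contraction. Where those clusters sit relative to the
myofibrils and mitochondria shapes the rising Ca²⁺ transient — but no single
microscope sees both the clusters (confocal, ~200 nm) and the organelle
landscape (electron tomography, ~30 nm) at once. `ryrscape` implements the
two computational halves of that hybrid-scale workflow, for cardiac
modellers and microscopists:

* **Point-pattern statistics** — the empty-space function F(r), the
  nearest-neighbour CDF G(r), Ripley's K(r) and the pair correlation g(r),
  with Monte-Carlo min/max **envelope tests** (99 simulations by
  convention) against any generating model.
* **Reconstruction** — places n clusters inside the admissible window W
  (cytosolic voxels within 0.7 µm of a myofibril) snapped to z-disc planes,
  minimising the squared discrepancy between target and current
  nearest-neighbour / radial-distance histograms,
  `E = Σ_s w_s Σ_b (target_s(b) − current_s(b))²`,
  by greedy single-point relocation (simulated annealing optional).
  Species presets: rat (1.3 couplons/µm², NN 0.59 ± 0.16 µm, 2 pA) and
  human (87 clusters per 94.8 µm², NN 0.79 µm, 2.8 pA compensated).
* **Synthetic templates** — seeded Voronoi myofibril packings with
  mitochondria, so everything is testable without any imaging data.
* **Calcium dynamics** — Strang-split reaction–diffusion of free Ca²⁺,
  Fluo-4 and Troponin C on the voxel grid; 2 pA release spheres (100 nm
  radius) with exponential trigger latencies (mean 6.7 ms); mitochondria as
  zero-flux barriers; exact closed-form buffer kinetics; machine-precision
  mass audit.
* **Imaging** — F/F₀ fields, Gaussian-PSF confocal rendering with 10×
  downsampling and Poisson noise, line scans, cluster-density profiles and
  heterogeneity metrics.

## Worked example

Reconstruct a rat-like cluster distribution on a synthetic template and
simulate the first 30 ms of the transient:

```r
library(ryrscape)

vol    <- make_template(template_spec(), seed = 1)   # 94.8 um^2, 0.05 um voxels
win    <- build_window(vol, max_radial = 0.7)
planes <- zdisc_planes(vol)

preset <- species_presets("rat", cross_section_area = 94.8)
rec    <- reconstruct(preset$targets, win, planes, seed = 7)
rec
#> <ryr_recon: 123 points, E = 0.000119 after 200000 proposals (112 accepted)>
mean(nn_distances(rec$pattern))
#> [1] 0.5889693
```

The reconstructed pattern has 123 clusters (1.3 per µm² of cross-section)
with mean nearest-neighbour distance 0.589 µm against the 0.59 µm target.
Validate it with an envelope test and run the calcium model (0.1 µm voxel
template for speed):

```r
vol01  <- make_template(template_spec(voxel_size = 0.1), seed = 1)
win01  <- build_window(vol01)
rec01  <- reconstruct(preset$targets, win01, zdisc_planes(vol01), seed = 2)
sites  <- mark_release_sites(rec01$pattern, vol01)   # 100 nm release spheres
sim    <- simulate_transient(vol01, sites, sim_params(t_end = 30, seed = 3))
tail(sim$trace, 1)
#>    time ca_mean f4ca_mean  f_f0 mass_rel_err
#>      30   0.962      11.1  5.32    -7.46e-16
```

At 30 ms the volume-averaged free Ca²⁺ is ≈ 0.96 µM and F/F₀ ≈ 5.3 — the
physiological rising-phase peak — with the mass audit at round-off.
`autoplot(sim)`, `line_scan()` and `heterogeneity_metrics()` turn the run
into figures and summary tables; `run_experiment()` wires the four canned
experiments (heterogeneity, distribution families, orphaned clusters,
rat-vs-human) end to end.

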