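---
title: "Methods: RyR cluster landscapes and the rising calcium transient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RyR cluster landscapes and the rising calcium transient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ryrscape)
```

## The problem

Ryanodine receptors (RyRs) cluster into couplons at the z-discs of
cardiomyocytes and release the calcium that drives contraction. Confocal
microscopy resolves where the clusters are (~200 nm) but not the fine
myofibril/mitochondria landscape they sit in; electron tomography resolves
the landscape (~30 nm) but not cluster positions over a whole cross-section.
`ryrscape` implements the two halves of a hybrid-scale modelling workflow:

1. **Spatial statistics and reconstruction.** Characterise an observed
   cluster pattern with the four classical point-pattern summaries (empty
   space function F, nearest-neighbour distance CDF G, Ripley's K, pair
   correlation g), test models by Monte-Carlo envelopes, and *reconstruct*
   statistically equivalent cluster patterns on any voxelised
   myofibril/mitochondria template by energy minimisation.
2. **Reaction–diffusion simulation.** Simulate the first 30 ms of the
   intracellular Ca²⁺ transient on the voxel grid — release sites at the
   reconstructed clusters, Fluo-4 dye and Troponin C buffering, mitochondria
   as diffusion barriers — and render the result as confocal-like line-scan
   images.

## Point-pattern summaries and envelope testing

For a pattern $X = \{x_i\}$ with intensity $\lambda = n/|W|$ over an
admissible window $W$:

* $G(r)$ — fraction of points whose nearest neighbour lies within $r$;
* $F(r)$ — fraction of admissible locations $u$ with $d(u, X) \le r$,
  estimated on a fixed seeded lattice of admissible voxels jittered within
  the voxel, so estimates are reproducible;
* $K(r) = \lambda^{-1}\,\mathbb{E}[\#\{j : 0 < d(x_i, x_j) \le r\}]$,
  estimated by pairwise counting;
* $g(r)$ — numerical derivative of $K$ (moving-average smoothing, window 5,
  then centered differences) divided by $2\pi r$ in 2D or $4\pi r^2$ in 3D.

No edge correction is applied by default. In min/max-envelope testing the
observed and simulated curves share the same estimator and window, hence the
same bias, so uncorrected estimators compare like with like; a reduced-sample
border correction is available (`correction = "border"`) for absolute use.
The pair-correlation normalisation is explicit (`dimension`), defaulting to
the pattern's effective dimensionality, because z-disc-confined patterns are
planar even though K is defined with spheres.

`envelope_test()` follows the standard Monte-Carlo construction: 99
simulations of the null model, pointwise minimum/maximum envelopes per
statistic, verdict "outside" when the observed curve exits the band
anywhere. All four statistics should be inspected together — each captures
only one aspect of the interaction structure.

## The reconstruction algorithm

`reconstruct()` places $n$ points inside the admissible window
$W$ — cytosolic voxels within 0.7 µm of the nearest myofibril voxel, never
mitochondria — snapped to the z-disc planes, and minimises

$$E = w_G \sum_b \left(G^{\mathrm{tgt}}_b - G^{\mathrm{cur}}_b\right)^2
    + w_{\mathrm{rad}} \sum_b \left(R^{\mathrm{tgt}}_b -
      R^{\mathrm{cur}}_b\right)^2,$$

the squared discrepancy between target and current histograms (as
proportions) of nearest-neighbour distances and of radial
distances-to-myofibril. Defaults: 0.05 µm bins over 0–2 µm (G) and
0–0.7 µm (radial); weights $w_G = w_{\mathrm{rad}} = 1$; the axial term is
collapsed to zero by snapping and carries weight 0. Reconstruction
energies in the literature vary in their exact functional form; the
squared-histogram form is this package's choice and is validated
behaviourally — reconstructed patterns must stay inside the envelopes of
their own generating model (`validate_against()`), which is the acceptance
logic the workflow prescribes.

The minimiser is the classical single-point relocation scheme: initialise
with hard-core CSR inside $W$, propose moving one uniformly chosen point to
one uniformly chosen admissible voxel (transverse jitter within the voxel,
axial coordinate snapped), reject proposals violating the 0.2 µm hard-core
spacing (the confocal resolution limit), and accept greedily
($\Delta E < 0$; default) or under a geometric simulated-annealing schedule.
Defaults: `max_iter = 2e5` proposals, `tol = 1e-4`. Because histogram
proportions are multiples of $1/n$, energies below `tol` are not always
attainable; the result reports `converged` accordingly and the energy trace
is non-increasing under greedy descent. Nearest-neighbour bookkeeping is
incremental between accepted moves and refreshed on acceptance; an internal
audit recomputes the energy from scratch every 1000 accepted moves and
reports the maximum discrepancy (`audit_max`, machine-precision in
practice). A hard failure is raised after 10⁴ consecutive spacing
rejections (infeasible window).

Species presets encode the measured organisation: rat — couplon density
1.3 µm⁻² of cross-section (123 clusters on the 94.8 µm² reference
template), NN distance 0.59 ± 0.16 µm, 2 pA per cluster; human — 87
clusters on the reference template (scaled proportionally), NN mean
0.79 µm, and per-cluster current raised to conserve total release
($2 \times n_{\mathrm{rat}} / n_{\mathrm{human}} \approx 2.8$ pA). The human
NN spread is not reported separately, so the preset reuses the rat value.

## The synthetic template generator

`make_template()` stands in for a segmented tomogram cross-section: packed
Voronoi myofibril cells separated by thin cytosolic gaps, a subset of cells
converted to mitochondria (randomly dispersed or as one contiguous clump),
extruded to the 0.9 µm half-sarcomere. The gap width is calibrated by
bisection so the realised cytosol fraction matches the specification.
Defaults chosen once: 94.8 µm² cross-section, myofibril fraction 0.50,
mitochondria fraction 0.25 (ventricular myocyte composition), myofibril
calibre 1.5 µm, 0.05 µm voxels, z-disc at the first axial slice. What the
generator does *not* emulate: irregular (non-convex) myofibril outlines,
longitudinal variation of the landscape, t-tubules, and sub-voxel boundary
geometry — so passing tests show the estimators, the reconstruction and the
solver behave correctly on landscapes with realistic *area fractions and
distance statistics*, not that any particular real cell is reproduced.

`make_nn_pattern()` generates ground-truth patterns with a prescribed
nearest-neighbour law for recovery experiments. All $n-1$ NN distances are
drawn up front from a truncated normal ($> 0.2$ µm), sorted ascending, and
each is attached to an anchor whose own NN distance cannot shrink, with
every other point required to stay at least $\max(d, \mathrm{NN}_j)$ away.
Under this rule the realised NN distances equal the drawn sample; a bounded
fallback (allowing shrinkage) handles crowded windows. It is a stand-in
generator, deliberately different from the reconstruction algorithm, so
recovery tests compare two independent routes.

## The calcium model

The solver integrates, on the voxel grid, free Ca²⁺, the Fluo-4 dye pair
and Ca-bound Troponin C:

* diffusivities $D_{\mathrm{Ca}} = 0.22$, $D_{\mathrm{dye}} = 0.042$
  µm²/ms (free dye is assigned the bound-dye value — same molecule give or
  take one ion); Troponin C stationary;
* kinetics $\mathrm{Ca} + B \rightleftharpoons \mathrm{Ca}B$ with Fluo-4
  $k_{on} = 0.1$ /(µM ms), $k_{off} = 0.11$ /ms ($K_D = 1.1$ µM, total
  25 µM) and Troponin C $k_{on} = 0.0327$, $k_{off} = 0.0196$
  ($K_D = 0.6$ µM, total 70 µM);
* resting Ca 0.1 µM, giving the equilibrium initials 2.08 µM bound dye,
  22.92 µM free dye and 10 µM Ca-TnC;
* release: 2 pA per cluster into the voxels within the 100 nm-radius
  release sphere (nominal volume $4.19\times10^{-3}$ µm³), converted as
  $\mathrm{flux} = i/(2 F V_{\mathrm{site}})$ with the realised voxel-sum
  volume so injected moles are exact; trigger latencies i.i.d. exponential
  with mean 6.7 ms;
* mitochondria are excluded from the domain with zero-flux faces, as are
  the outer boundary and both axial ends (half-sarcomere symmetry);
  myofibril voxels belong to the diffusive domain and carry Troponin C
  (the purely cytosolic gaps are a negligible fraction of the cell and are
  not distinguished chemically).

Numerics: Strang splitting — half reaction + release, full diffusion, half
reaction + release. The reaction half-step advances each Ca/buffer pair with
the exact closed-form solution of the constant-coefficient Riccati ODE,
which conserves the pair invariant to machine precision and is positivity
preserving for any step. Diffusion is an explicit conservative finite-volume
step with stability bound $\Delta t \le h^2/(6 D_{\max})$ (0.0076 ms at
$h = 0.1$ µm); the default $\Delta t = 0.005$ ms. A mass audit (free +
bound content versus initial + cumulative injection) is carried along the
recorded trace and sits at round-off in practice.

**Release profile calibration (frozen).** The per-cluster release time
course is a triangular pulse: 1 ms rise to 2 pA, then a linear decay whose
length is the one free parameter of the release model. It was calibrated
once on the reference rat scenario (94.8 µm² template, 0.1 µm voxels,
fixed seeds) so the 30 ms volume-averaged free Ca reaches ≈ 1 µM — the
sweep gave 0.82 µM at 2.2 ms, 0.96 µM at 2.6 ms, 1.63 µM at 3.9 ms — and
frozen at **2.6 ms** (3.6 fC per cluster). Every other scenario (human
preset, orphaned clusters, mitochondria removal, alternative
distributions) reuses the frozen profile, so their outcomes are genuine
predictions of the model, not re-fits.

An optional deterministic two-state gating mode replaces the prescribed
profile: mean-field open probability $dp/dt = \alpha
\mathrm{Ca}^\eta (1-p) - k_{\mathrm{close}} p$ per cluster of 50 RyRs,
triggered at $p = 0.02$ (one open channel). Its rate constants are not
printed in the sources we implement from, so they are configuration-only
and gating is off by default.

## Imaging

F/F₀ is the bound-dye field divided by its resting value (5.71 at full
equilibrium with 1 µM free Ca); mitochondria carry no dye and render as 0.
`render_confocal()` applies a Gaussian PSF (default lateral FWHM 0.25 µm,
axial 0.6 µm — a stand-in for a measured kernel, so PSF-dependent claims
are direction-only), block-average downsampling (exactly mean-preserving),
and Poisson noise $I' = \mathrm{Poisson}(sI)/s$ with photon scale
$s = 100$. Line scans sample the recorded z-disc plane at 1 ms cadence.
`cluster_density_profile()` counts clusters in a 1 µm-radius spherical
neighbourhood along the scan line; on the reference phantom its profile
correlates positively with rendered line intensity.

## Problem sizes and determinism

The shipped experiments and tests run on deliberately scaled geometries:
full-template runs use 0.1 µm voxels (≈ 65 000 domain voxels, 6000 time
steps) and the test suite mostly uses 9–16 µm² sections, sizes chosen so a
complete analysis reproduces on a single CPU in minutes. Every stochastic
stage takes an explicit seed (template, reconstruction, latencies, photon
noise) and all fixtures are bit-reproducible under a fixed seed.

## Known limitations

* No SR re-uptake (SERCA), no t-tubules, no L-type channel geometry, no
  stochastic per-channel gating, no mitochondrial Ca²⁺ uptake — the model
  covers only the rising phase of the transient, where these mechanisms
  contribute little.
* Latency insensitivity of the 30 ms pattern holds at the image level
  (the displayed transverse-plane F/F₀ field, whose structure is dominated
  by the organelle landscape); clusters triggered in the final ~10 ms are
  still concentrated plumes at 30 ms, so raw voxel-by-voxel free-Ca
  correlations across trigger-time draws are lower (~0.85–0.9).
* The energy functional and annealing defaults are behaviourally validated
  choices, not transcriptions of an original implementation.
* The exact heterogeneity range of a real cell (e.g. a specific 0.3–12.7 µM
  span) is geometry-specific; on synthetic templates only direction and
  order-of-magnitude claims are asserted.
* Voxel finite volumes replace the original tetrahedral finite elements;
  agreement is asserted on averaged quantities, conservation and
  grid-refinement stability, not on node-identical fields.
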