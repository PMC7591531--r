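---
title: "Methods: mechano-metabolic imaging of expanding epithelial monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechano-metabolic imaging of expanding epithelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanometab)
```

## Scope

`mechanometab` re-implements, as a tested pipeline, the image-analysis
chain used to map single-cell metabolism alongside mechanics in a
confluent MDCKII monolayer that unjams and migrates into free space
after barrier lift: Peredox biosensor calibration and redox conversion,
TCSPC lifetime fitting, nuclei tracking, Voronoi morphometrics,
traction microscopy, and layer-aligned spatial profiling. Because no
raw images of the original experiments are available, the package
includes a first-class synthetic-monolayer generator whose ground truth
makes every downstream stage verifiable end to end.

## The models

### Peredox calibration and the LDH equilibrium

The sensor's red (mCherry) channel normalizes expression; the green
(T-Sapphire) channel responds to cytoplasmic NADH. The normalized
red/green ratio during a lactate:pyruvate titration follows a logistic
(Hill) curve

$$F(X) = 1 + \frac{A}{1 + (B/X)^{1.7}},$$

with the Hill coefficient fixed at 1.7. Per-cell bounded nonlinear
least squares yields $(A, B)$; the package's reference values are the
population means $A = 1.04$ and $B = 44.13$. Lactate dehydrogenase
equilibrates lactate:pyruvate with the redox pair,

$$K = \frac{[\mathrm{Pyr}]\,[\mathrm{NADH}]\,[\mathrm{H^+}]}
           {[\mathrm{Lac}]\,[\mathrm{NAD^+}]} = 1.1\times 10^{-11},$$

so at pH 7.4 a fluorescence ratio maps to
$\mathrm{NAD^+}/\mathrm{NADH} = [\mathrm{H^+}]/(K X)$ with
$X = B\,(A/(F-1) - 1)^{-1/1.7}$. The transform is strictly decreasing
and nonlinear; dispersion in $F$ therefore maps to *asymmetric* redox
error bars, which is why compositing happens in ratio units first and
conversion afterwards (`transform_profile_to_redox()`).

Normalization anchors the lowest-$X$ (pyruvate-saturated) titration
step at $F = 1$, the curve's lower asymptote. The anchor step sits at
small but nonzero $X$, so fitted parameters carry a equally small,
shared offset; the suite's scale-consistency test pins down what the
anchor does and does not guarantee. Out-of-range ratios are clipped to
an $\varepsilon$-interior of $(1, 1+A)$ with $\varepsilon = 10^{-3}A$
and flagged, never dropped.

### TCSPC biexponential fitting

NADH autofluorescence decays are modeled as

$$I(t) = \alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2} + C,
\qquad \alpha_1 + \alpha_2 = 1,$$

convolved with a measured instrument response (here a Gaussian of
311 ps FWHM), with bounds $0 \le \alpha_i \le 1$ and
$0.02\,\mathrm{ns} \le \tau_i \le 100\,\mathrm{ns}$. The fast
component tracks free NADH, the slow one enzyme-bound NADH;
$\tau_m = \alpha_1\tau_1 + \alpha_2\tau_2$.

Numerical choices that matter:

* **Linear, not circular, convolution.** The TCSPC record is finite;
  photons do not wrap. Convolution is done on a zero-padded power-of-2
  grid with the IRF spectrum precomputed per fit.
* **Oversampled model evaluation.** Data binned 256 → 64 in time are
  *sums* of raw bins; evaluating the model at coarse bin centres with a
  coarse-binned IRF misfits badly (we measured ~40% τ~m~ error on
  noise-free binned decays). The model is therefore evaluated on the
  raw grid and aggregated, which makes noise-free binned fits exact.
* **Variable projection.** Amplitude and background are linear
  parameters and are solved exactly at every objective evaluation;
  only $(\alpha_1, \log\tau_1, \log\tau_2)$ are optimized (L-BFGS-B,
  5 seeded restarts by default, components re-ordered so
  $\tau_1 \le \tau_2$).
* **Unweighted least squares** matches the original description;
  photon pooling, not weighting, is what controls precision (below).
* Pixels under 500 total photons are skipped with a quality code.

A single 5000-photon decay supports only ~4% median τ~m~ error no
matter the estimator (we verified this against Poisson maximum
likelihood). The canonical workflow therefore pools photons before
fitting: a spatial moving-window sum (radius 2 px by default; the
source text for the window size is corrupt, so the radius is
configurable and no value is asserted) and 4-fold temporal
aggregation. With pooling, the suite demonstrates ~1% median τ~m~
error at 5000 photons/pixel.

### Traction microscopy

Bead displacements between a stressed and a relaxed (post-trypsin)
image are measured by windowed cross-correlation (32 px windows, 50%
overlap). Two details are load-bearing:

* Correlation is computed as *linear* correlation on zero-padded
  windows and normalized by the per-lag overlap area. Plain circular
  FFT correlation biases broad peaks toward zero lag; we measured a
  ~0.25 px bias on smooth texture that the normalization removes.
* Window decisiveness is judged by the ratio of the main correlation
  peak to the best peak *outside* a 3-px exclusion zone; indecisive
  windows are masked and filled from neighbours. A light Gaussian
  smoothing of the displacement field (1 grid node) suppresses
  window-level noise ahead of the ill-conditioned inversion.

Tractions follow from Tikhonov-regularized inversion of the
Fourier-space Boussinesq operator for a semi-infinite, incompressible
($\nu = 0.5$) substrate at shear modulus 9.6 kPa. The 100 µm gel is
treated as effectively infinite at cellular wavelengths. At
$\lambda = 0$ the inversion is the exact inverse of the forward
operator (round-trip relative $L^2$ error ~$10^{-5}$); the pipeline
default $\lambda = 10^{-3}$ µm/Pa was fixed once by an L-curve-style
sweep on synthetic fields. Regularization trades noise for
attenuation of ~60 µm features; rank comparisons across near-tied
bulk bins sit at that trade-off's mercy, which is why acceptance
checks rank profiles at the canonical bin width. The $k = 0$ mode is
zeroed: an isolated layer exerts no net force.

### Tracking, morphology, profiles

Nuclei are detected by a difference-of-Gaussians band-pass at a scale
finer than the nucleus (0.6 σ), with the threshold applied to the
band-pass response relative to its own maximum — never to raw
intensity — and 3×3 parabolic sub-pixel refinement (≈0.03 px error on
clean fixtures). Two equal Gaussian blobs merge into a single
intensity maximum below 2 σ separation; the implementation resolves
pairs down to ≈2.2 σ, and that physical limit is documented rather
than papered over.

Linking is optimal gated assignment (Hungarian) between flow-advected
track predictions and candidate detections; unmatched detections open
tracks, unmatched tracks end (no gap closing, no division handling).
Speeds are mean inter-frame displacement magnitudes — direction never
enters, so a reversed track has the same speed.

Morphology comes from a Voronoi tessellation of nuclear centroids
(`deldir`), clipped to the domain; polygons touching the boundary are
flagged and excluded from shape statistics. The aspect ratio is the
axis ratio of the ellipse sharing the polygon's second central
moments, computed from exact shoelace moment formulas and validated
against a rasterization oracle and an $O(n^2)$ half-plane oracle.

Profiles grid per-cell values by Delaunay-barycentric interpolation at
the canonical 35 px (~11 µm) spacing, align layers by their centre of
mass, split strips into two oriented fronts (+x toward free space),
composite pixel-wise, and bin along x in ~260 µm bins with
layer-to-layer standard deviation as the error bar. Alignment shifts
are snapped to the grid pitch to avoid interpolation smoothing. Bins
with fewer than 2 contributing layers report no dispersion.

## The synthetic world

The generator prescribes, rather than simulates mechanistically, the
fields the pipeline must resolve: cells seeded on a jittered lattice
whose spacing and anisotropy follow edge-to-bulk exponential
gradients, advected by a front-relative velocity field
$v(x) = v_{bulk} + (v_{edge} - v_{bulk})e^{-(x_f - x)/\ell}$ with the
front advancing at 20 µm/h; NAD+/NADH rising from 30 at the edge to
300 in the bulk (the physiologic decade range); free-NADH fraction
0.85 (edge) to 0.70 (bulk) over fixed lifetimes 0.4/2.5 ns, giving the
edge-short τ~m~; traction magnitude 300 → 30 Pa, rolled off at the
layer midline (zero by symmetry) and tapered in y, mean-removed for
force balance. Defaults (16–22 µm spacing, ℓ = 150 µm, 8 frames at
15 min, 0.2 µm beads at 0.05/µm²) were chosen once as realistic for
this system; none is a claim about the biology, and all are exposed in
`monolayer_params()` / `imaging_config()`.

Per-cell ground-truth traction is defined as the same estimand the
pipeline reports — the mean traction magnitude over the cell's
footprint — not a point sample at the centroid; the two differ
systematically where the field curves.

What the generator does *not* emulate: realistic nuclear texture,
shading/flat-field artifacts (inputs are assumed corrected), camera
noise beyond Poisson/Gaussian, mitosis, gap closing, 3D structure, or
any mechanistic jamming model. A green test therefore establishes that
the algorithms recover what they claim from data obeying the stated
forward models — not that the biology behaves this way.

## Known limitations

* Blob detection cannot split nuclei closer than ~2.2 σ; crowded
  epithelia at low magnification would need a shape prior.
* The B calibration parameter is weakly identified for cells whose
  midpoint approaches the top of the titration range; with the
  prescribed between-cell spread (SD 26.08, cv 0.59) the positivity
  constraint alone shifts the simulated population mean of B up by
  about +6%, which propagates to the recovered mean.
* Deep-bulk profile bins of an exponentially decaying gradient differ
  by less than the desk-scale measurement noise; rank agreement is
  asserted at bin widths the measurements actually resolve.
* The elastic model is a flat, semi-infinite, incompressible
  half-space; finite-thickness and substrate-curvature corrections are
  config hooks, not implemented physics.

## Reproducibility

Every stochastic stage takes an explicit integer seed;
`run_pipeline()` derives all stage seeds from one master seed and
records them, with parameter snapshots and output hashes, in a JSON
manifest. Two runs with the same configuration are bit-identical.
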