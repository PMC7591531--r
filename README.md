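# mechanometab

Single-cell **mechano-metabolic image analysis** for expanding
epithelial monolayers, written for experimentalists who image a
confluent layer (e.g. MDCKII) migrating into free space after barrier
lift and want, per cell and per position across the layer:

* cytoplasmic **NAD+/NADH** from the two-channel Peredox biosensor,
* free vs enzyme-bound NADH from **FLIM** (TCSPC) decays,
* migration **speed** from nuclei tracking,
* **cell shape** (area, perimeter, aspect ratio) from Voronoi
  tessellation of nuclear centroids,
* substrate **traction** from bead displacements, and
* layer-aligned **spatial profiles** of all of the above.

A synthetic-monolayer generator with full ground truth ships as a
first-class module, so every stage of the pipeline is verifiable
without any raw microscopy data.

## The science in two equations

Peredox calibration fits each cell's normalized red/green ratio during
a lactate:pyruvate titration to a logistic curve with Hill
coefficient 1.7,

    F(X) = 1 + A / (1 + (B/X)^1.7),

and the lactate-dehydrogenase equilibrium
`K = [Pyr][NADH][H+] / ([Lac][NAD+]) = 1.1e-11` at pH 7.4 converts the
titration ratio `X` into the redox ratio, giving the calibration
`NAD+/NADH = [H+] / (K X)`. FLIM decays are fit per pixel with an
IRF-convolved biexponential

    I(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) + C,    a1 + a2 = 1,

whose amplitude-weighted mean lifetime `tau_m = a1 tau1 + a2 tau2`
maps the free/bound NADH balance. Tractions come from
Tikhonov-regularized Fourier inversion of the Boussinesq half-space
operator (gel shear modulus 9.6 kPa, incompressible).

## Worked example

```r
library(mechanometab)

cal <- peredox_calibration()
cal
#> Peredox calibration model
#>   F(X) = 1 + A / (1 + (B/X)^1.70)
#>   A = 1.04, B = 44.13 (lactate:pyruvate units)
#>   LDH equilibrium: K = 1.1e-11 M, pH = 7.40

# at the sigmoid midpoint, X = B and the LDH equilibrium gives:
fluorescence_to_redox(1 + cal$A / 2, cal)
#> [1] 82.01124
```

A full synthetic run — simulate an unjamming monolayer, render its
channels, then track, tessellate, convert and invert:

```r
run <- run_pipeline(monolayer_params(), seed = 42)
run
#> Pipeline run (seed 42): 250/250 cells detected

cells <- run$cells   # per-cell table: x, y, speed, F_raw, redox,
                     # area, perimeter, aspect_ratio, traction, ...
edge <- cells$x > 400; bulk <- cells$x < 150
```

The run above prints the monolayer's mechano-metabolic signature: edge
cells migrate at 13.8 µm/h against 1.6 µm/h in the jammed bulk, are
more reduced (NAD+/NADH 111 vs 283), and pull harder on the substrate
(65 vs 22 Pa) — fast, elongated, glycolytically shifted cells at the
advancing front, exactly the gradients prescribed in the ground truth.

Profiles across the layer use the canonical ~11 µm grid and 260 µm
x-bins, composite in fluorescence-ratio units, and convert to redox
afterwards (the transform is nonlinear, so the error bars come out
asymmetric):

```r
g    <- grid_cell_values(cells[is.finite(cells$redox), ], "redox")
prof <- composite_layers(list(g), bin_width = 260)
prof$trace
#>   x_center     mean sd n_layers
#> 1      130 274.1053 NA        1
#> 2      390 172.5924 NA        1
```

The redox trace decreases toward the front (larger `x_center`): the
migrating edge runs a more reduced cytoplasm.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline calibration
numbers from scratch: it simulates 200 cells' titration series from
the population logistic parameters (A = 1.04 ± 0.24, B = 44.13 ± 26.08,
seven lactate:pyruvate steps from 0.1 to 400, 2% multiplicative
noise), fits every cell with the Hill coefficient fixed at 1.7, and
writes the mean fitted parameters to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

| module | file | role |
|---|---|---|
| calibration | `R/calibration.R` | titration fitting, redox conversion, error propagation |
| FLIM | `R/flim.R` | IRF, binning, biexponential fits, lifetime maps |
| tracking | `R/tracking.R` | nuclei detection, optical flow, linking, speeds |
| morphology | `R/morphology.R` | Voronoi tessellation, shape metrics |
| traction | `R/traction.R` | bead PIV, Fourier inversion, per-cell traction |
| profiles | `R/profiles.R` | gridding, alignment, compositing, traces |
| synthetic | `R/synthetic.R` | ground-truth monolayer and all renderers |
| io | `R/io.R` | text image interchange, pipeline orchestration, manifest |

The methods vignette (`vignettes/mechanometab-methods.Rmd`) documents
the models, the numerical choices, the synthetic world's assumptions,
and known limitations.
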