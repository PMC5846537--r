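# usblt — ultrasound-guided permissible-region bioluminescence tomography

Bioluminescence tomography (BLT) reconstructs internal light sources in
scattering tissue from multi-wavelength boundary images. The problem is a
severely underdetermined linear system

```
J x = y
```

where `x` holds the nodal source intensities of a finite-element model,
`y` the stacked boundary measurements (one row per detector and
wavelength), and `J` the sensitivity (Jacobian) matrix of the photon
diffusion forward model. Because the total sensitivity
`s_n = Σ_j J_{j,n}` spans several orders of magnitude across the mesh,
low-sensitivity nodes amplify measurement noise during inversion and ruin
quantitative recovery.

`usblt` implements a permissible-region strategy that attacks exactly this:
given an externally supplied source coordinate `(x0, y0, z0)` — in practice
read from an ultrasound image, in simulation the known source position —
the mesh node closest to it becomes the *reference node* with sensitivity
`s0`, and only the *nodes of interest*

```
NOI = { i : s0/d ≤ s_i ≤ s0·d }
```

for a configurable dynamic range `d` are allowed to carry intensity; the
Jacobian is truncated to those columns before solving. This confines the
reconstruction in all three dimensions (most importantly in depth) and
caps the dynamic range of the truncated system at `d²`. The package is
aimed at researchers studying BLT reconstruction strategies at desk scale:
it regenerates the whole simulation pipeline — slab meshes, spectral
diffusion forward model, noisy data, three reconstruction strategies
(whole mesh, laterally-bounded "large PR", ultrasound-guided PR), and
VR / DICE / MSE evaluation — in plain R.

What is inside:

* `build_slab_mesh()`, `place_detector_grid()` — structured tetrahedral
  slab meshes (Kuhn 6-tet cubes) and boundary detector grids.
* `blt_spectral_model()`, `build_jacobian()` — chromophore-based absorption,
  scattering power law `μs' = a·(λ/1 μm)^(−b)`, P1 finite-element solution
  of the CW diffusion equation `(−∇·κ∇ + μa)Φ = q` with Robin boundaries,
  and the stacked multi-wavelength Jacobian via adjoint solves.
* `total_sensitivity()`, `us_guided_region()`, `large_pr_region()`,
  `truncate_jacobian()` — the permissible-region machinery.
* `cscg_solve()`, `blt_reconstruct()` — sparsity-promoting nonnegative
  conjugate-gradient inversion behind a classed model fit with
  `print`/`summary`/`coef`/`fitted`/`residuals`/`plot` methods.
* `recon_metrics()`, `fwhm_profile()`, `two_source_contrast()` — evaluation.
* `slab_testbed()`, `run_repeated()`, `dynamic_range_sweep()`,
  `two_source_experiment()` — paired-noise experiment drivers.
* `blt_cli()` plus `inst/cli/usblt.R` — a small command-line front end
  (`mesh`, `simulate`, `reconstruct`, `metrics`, `experiment`).

## Worked example

Reconstruct a 15-mm-deep cylindrical source (radius 1.5 mm, length 5 mm,
intensity 10 a.u.) in a 40 × 40 × 20 mm slab from noisy five-wavelength
data, with the guided region centred on the known source position:

```r
library(usblt)
tb <- slab_testbed()   # 40x40x20 mm slab, 2 mm nodes, 11x11 detectors, 600-640 nm
tb
#> blt_testbed: 4851 nodes, 121 detectors, 5 wavelengths, 1 source(s)

dynamic_range_of(total_sensitivity(tb$jacobian))
#> [1] 11470.49

yn  <- add_noise(tb$y0, snr_db = 20, seed = 1)
fit <- blt_reconstruct(tb$jacobian, yn, method = "us_guided",
                       mesh = tb$mesh, us_position = c(0, 0, 5), d = 3)
summary(fit)
#> Reconstruction method: us_guided (dynamic range 3)
#>   permissible region: 2456 / 4851 nodes
#>   nonzero nodes: 8, max intensity 15.26, total 21.27 a.u.
#>   data misfit: 0.101 (relative), 387 CG iterations

recon_metrics(fit, tb$x_true, tb$volumes)
#>    vr dice        mse
#> 1 1.5  0.4 0.02853945
```

The guided fit concentrates 8 nonzero nodes around the true source: the
volume ratio (reconstructed over true source volume, ideal 1) is 1.5, the
DICE overlap 0.4, and the mean square intensity error over all 4851 nodes
0.029 a.u.². The same call with `method = "whole"` frees every node and,
over repeated noise realizations, yields a substantially larger mean MSE —
the comparison that motivates the guided region (see
`run_repeated()` for the paired-noise version).

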