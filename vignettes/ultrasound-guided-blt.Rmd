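---
title: "Ultrasound-guided permissible regions for bioluminescence tomography: models, solver and design choices"
author: "usblt"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
forward model and its assumptions, the permissible-region construction,
the inverse solver, the evaluation metrics, what the synthetic testbed
does and does not emulate, and the numerical and design decisions taken
where the design was genuinely open.

## Forward model

Light propagation in strongly scattering tissue is modelled by the
continuous-wave diffusion approximation

$$(-\nabla\cdot\kappa\nabla + \mu_a)\,\Phi = q,
\qquad \kappa = \frac{1}{3(\mu_a+\mu_s')},$$

valid when scattering dominates absorption ($\mu_s' \gg \mu_a$) and far
from sources and boundaries relative to one transport mean free path. At
the tissue–air interface a Robin condition
$\kappa\,\partial\Phi/\partial n + \Phi/(2A) = 0$ accounts for internal
reflection; $A(n)$ is computed from the refractive-index mismatch via the
critical-angle/Fresnel approximation ($A(1.33)\approx 2.35$, $A(1)=1$).

Discretisation is by linear (P1) tetrahedral finite elements on a
structured slab mesh: each cube of a regular node grid is split into six
tetrahedra sharing the cube's main diagonal (Kuhn triangulation), which
makes node counts exactly predictable — a $(L_x,L_y,L_z)$ slab at spacing
$h$ has $(L_x/h+1)(L_y/h+1)(L_z/h+1)$ nodes — and needs no external
mesher. The price is a preferred diagonal direction: mirror symmetries
hold only to discretisation accuracy (a few per cent at 2 mm spacing),
and nodal volumes of the lumped mass matrix are not corner-symmetric on a
single cube (diagonal endpoints carry 1/4, other corners 1/12). The test
suite checks the assembled system against an independent dense assembly,
and the point-source field against the infinite-medium Green's function
$\exp(-\mu_{\rm eff} r)/(4\pi\kappa r)$ within 15 % for
$r \in [3, 8]$ mm away from boundaries.

Optical properties are spectral: absorption is Beer's law over a
chromophore table (defaults: water fraction 0.5, oxy-haemoglobin 0.01 mM,
deoxy-haemoglobin 0.005 mM, with bundled approximate extinction spectra
that are explicitly replaceable), and reduced scattering follows
$\mu_s' = a\,(\lambda/1\,\mu\mathrm{m})^{-b}$ with $a = 0.14$, $b = 2.8$ —
the convention under which these values give tissue-like
$\mu_s' \approx 0.59\ \mathrm{mm^{-1}}$ at 600 nm. Interpolation inside
the extinction table is linear; extrapolation is refused.

The BLT Jacobian stacks one row per (detector, wavelength): by
reciprocity, the row equals the adjoint field of a unit source at the
boundary node nearest the detector, times the lumped nodal volume and a
per-wavelength emission weight $\gamma_\lambda$ (uniform by default; a
Gaussian-spectrum generator covers phantom-like sources, e.g. peak 640 nm,
FWHM 60 nm). One sparse Cholesky factorisation per wavelength serves all
detectors. Measurements are the nodal fluence at the detector node; an
exitance factor would be a constant common to all reconstruction methods
and is omitted. Small negative fluence values — an $O(h^2)$ undershoot of
linear elements near point sources — are clipped to zero, with a warning
only when the undershoot exceeds 1 % of the field maximum.

## The permissible region

The total sensitivity of node $n$ is $s_n = \sum_j J_{j,n}$ over all
stacked measurements. Its dynamic range across a whole model reaches four
orders of magnitude; the inversion amplifies noise on low-sensitivity
nodes accordingly. The guided region takes the mesh node nearest the
supplied guide coordinate (an ultrasound-derived source position; in
simulation, the true source centroid) as the reference node with
sensitivity $s_0$ and keeps the nodes of interest

$$\mathrm{NOI} = \{\, i : s_0/d \le s_i \le s_0\,d \,\},$$

with inclusive bounds and ties kept. The truncated sub-Jacobian's
sensitivity dynamic range is at most $d^2$ by construction. Truncation is
equivalent to constraining the intensity of every outside node to zero,
which the tests verify against a dense constrained solve. Two comparators
are built in: the whole mesh (no constraint) and a "large" permissible
region bounded only laterally (no depth limit — the conventional prior
when only a camera image locates the source; its lateral size is a free
choice, defaulting to a 7.5 mm half-width, five source radii, visibly
larger than the source, and configurable). For guided reconstructions of two sources the guide
coordinate is the midpoint of the two centres: both sources lie at the
same depth, so the midpoint's sensitivity is representative and a single
ultrasound-style coordinate suffices.

A practical helper converts an ultrasound-reported depth to the region
centre: a slab of thickness $L_z$ imaged from the face opposite the
detectors with the source seen at $z_{us}$ puts the region
$L_z - z_{us}$ below the detector face (20 mm slab, source at 15.5 mm
$\rightarrow$ 4.5 mm).

## Inverse solver

All three strategies share one solver, so method differences isolate the
region. The solver addresses $\min \|Ax - y\|^2$ subject to $x \ge 0$ with
a strong sparsity prior, in three stages:

1. **Column normalisation** to unit Euclidean norm, compensating the
   depth-dependent sensitivity scale (without it the minimum-norm solution
   is biased towards shallow, high-sensitivity nodes).
2. **Nonnegativity-constrained CGLS**: gradient-projection rounds, each
   running CGLS (conjugate gradients on the normal equations, matrix-free)
   on the current free set — variables that are positive or whose gradient
   pushes them positive — followed by projection onto $x \ge 0$. For an
   all-positive sensitivity matrix the nonnegative solution is naturally
   sparse and its coefficients are bounded: sign cancellation between
   correlated columns, the failure mode of unconstrained least squares on
   this problem, cannot occur.
3. **Support pruning and refit**: entries below
   $\tau \cdot \max(x)$ are discarded and stage 2 is repeated on the
   surviving support.

Defaults: 50 CG iterations per round, 5 rounds, $\tau = 0.1$, relative
residual tolerance $10^{-8}$. These were fixed on noiseless-recovery and
stability pilots: with them, a noiseless well-conditioned guided problem
returns the painted intensity exactly, while under 20 dB noise the
per-trial MSE stays bounded across seeds. An earlier unconstrained variant
(plain CGLS with per-round $\tau$-thresholding at $\tau = 0.01$) was
abandoned: it could not localise even noiseless data — the under-converged
minimum-norm iterate smears intensity below the source — and once the
support shrank, sign cancellation produced runaway intensities. A
divergence guard in CGLS (tracking the best-residual iterate) protects
against finite-precision conjugacy loss at high iteration counts. The
solver is homogeneous in the data ($y \mapsto cy$ scales the solution by
$c$), deterministic, and drops all-zero columns with a warning.

## Metrics

The reconstructed source is segmented at the median nodal value of the
nodes above 1 % of the expected intensity (median rather than half-max so
that a few very bright nodes do not move the threshold; the 1 % floor
removes the many exact zeros that would otherwise bias the median), with
strictly-greater membership. Against the true source nodes this gives

* **VR** — reconstructed over true source volume (lumped nodal volumes,
  not node counts), ideal 1, position-blind;
* **DICE** — volume-weighted overlap $2|ROI\cap tROI|/(|ROI|+|tROI|)$,
  ideal 1;
* **MSE** — mean squared intensity error over *all* $N$ mesh nodes (the
  printed formula's normalisation; not ROI-only).

1D profiles are sampled on the nodal lattice. `fwhm_profile()` uses a
strict single lattice line and linear interpolation of the half-maximum
crossings (undefined and flagged when a side never crosses). The
two-source driver instead uses `source_plane_profile()`: the maximum over
a window of ±1 node spacing in depth around the source plane, because at
2 mm resolution an essentially correct reconstruction routinely sits one
node off the nominal plane and a strict line would miss it entirely. The
two-source contrast is Michelson-style on the smaller of the two largest
local maxima, $(p_{\min}-v)/(p_{\min}+v)$ with $v$ the valley between
them; a single-peak profile is flagged as merged (`NA`) and counted as
contrast 0 in experiment summaries (no separation).

## Synthetic testbed

The default testbed regenerates the slab study conditions at desk scale:
a homogeneous 40 × 40 × 20 mm slab (detectors on $z = 20$ mm; "depth"
means distance below that face) with muscle-like optics, five wavelengths
600–640 nm in 10 nm steps with uniform emission weights (the neutral
choice absent a measured source spectrum), a cylindrical source of radius 1.5 mm, length 5 mm and
intensity 10 a.u. at 15 mm depth, and Gaussian noise at SNR 20 dB.
Noise is per-measurement and amplitude-proportional
($\sigma_i = |y_i|\,10^{-SNR/20}$), i.e. every measurement carries the
same relative noise; a global-RMS alternative sits behind a flag. Noise
seeds are paired: realization $k$ uses seed $base+k-1$ for every method
and every $d$, so comparisons are paired by construction, and the RNG
state of the session is left untouched.

Problem sizes are scaled for a desk run and chosen once: 2 mm node
spacing (4851 nodes), an 11 × 11 detector grid (30 × 30 mm at 3 mm
pitch), and 20 noise realizations; the full-scale configuration
(0.5 mm spacing, 0.75 mm pitch — 1681 detectors — and 100 realizations)
remains reachable through the same functions for overnight runs. Sources
are painted by node-centre inclusion, the simplest reproducible rule; at
2 mm spacing the standard cylinder covers exactly two nodes, so the
"true source" is deliberately coarse.

What the generator does *not* emulate: model mismatch (the same Jacobian
generates and inverts the data — both sides of the comparison share this
idealisation, but absolute metric values will flatter any method),
heterogeneous anatomy (per-region optical properties are supported, but
the bundled experiments are homogeneous), instrument effects (camera
noise floors, calibration, spectral response), and ultrasound guide error
(the guide is the true centroid; Gaussian jitter is available via
`us_jitter_sd` but defaults to 0, matching a simulation with exact
knowledge of the position). Passing tests therefore demonstrate the
internal consistency and the *relative* behaviour of the region
strategies under these conditions, not absolute performance on real data.

## Desk-scale behaviour of the metric orderings

Two qualitative orderings that hold in full-scale studies are fragile at
this deliberately coarse scale, and the test suite reports them as it
finds them rather than adjusting conditions until they flip. First, with
a two-node true source, DICE is quantised in large steps and a
single-node (2 mm) localisation error zeroes the overlap; the guided
region at $d = 3$ contains the node column one spacing below the source,
and under 20 dB noise the sparse solution often lands there, while at
0.5 mm resolution the same one-node shift would barely move DICE. Second,
the two-source contrast saturates: ultra-sparse reconstructions have
exact zeros between lobes, so any method that resolves the lobes at all
scores near 1 and the ordering between methods carries little signal.
The quantitative headline — the large reduction in mean MSE from the
guided region, and a sweep optimum at small $d$ — is robust across seeds.

## Numerical choices and degenerate inputs

Inclusive NOI bounds keep boundary ties; the nearest-node rule breaks
ties by lowest index everywhere; the median of an even-sized candidate
set is the midpoint of the central pair; zero-sensitivity nodes are
excluded from dynamic-range computations (their log-range is unbounded)
and a reference node with zero sensitivity is an error (the guide points
outside the sensitive volume); a source smaller than the lattice can
represent is an error rather than a silent empty source; degenerate
detector grids (extent 0) are a single detector; failed trials in
repeated runs are excluded with a warning and counted. Sparse systems are
factorised once per wavelength (CHOLMOD, permuted Cholesky); meshes up to
$10^5$ nodes are comfortably within a desk machine's budget.

## Known limitations

* The diffusion approximation misrepresents transport within ~1 mfp of
  sources and boundaries and in low-scattering regions; no
  radiative-transfer fallback is provided.
* Structured slabs only; no unstructured or atlas-based meshes, so
  published node counts from unstructured meshers are not reproduced.
* The solver is a documented sparsity-promoting CG variant, not a
  re-implementation of any specific published solver; comparisons between
  region strategies are meaningful because the solver is held fixed, but
  absolute metric values depend on it.
* The ultrasound guide is an input coordinate; image segmentation,
  registration and probe geometry are out of scope.
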