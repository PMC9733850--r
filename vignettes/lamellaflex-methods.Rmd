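---
title: "Models and methods behind lamellaflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lamellaflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellaflex)
```

`lamellaflex` analyzes compressed supported lipid multilayers (SLMs) on
elastomer substrates at three length scales: micron-scale buckle
delamination, meso-scale lamellar ordering seen by grazing-incidence X-ray
scattering, and molecular tilt/order statistics of coarse-grained
configurations. This vignette records the models, the assumptions behind
them, the defaults and numerical choices, and what the synthetic-data
generators do and do not emulate.

## Buckle-delamination mechanics

An elastic film of thickness $t$ on a compliant substrate, compressed by a
strain $\varepsilon$, can relieve stress by detaching and arching upward.
The width $\lambda$ of such a delamination buckle balances bending,
compression and adhesion energy:

$$\frac{\lambda}{t^{3/2}} = \pi\sqrt{\frac{2\,\bar E_f\,\varepsilon}{\Gamma}},$$

with $\bar E_f$ the in-plane Young's modulus of the film and $\Gamma$ the
film–substrate adhesion energy. The model assumes the strain carried by the
film itself is negligible relative to the applied substrate strain — the
regime in which buckling, not in-plane compression, relieves the load.

`buckle_width()` evaluates the forward model (inputs in nm and fractions at
the interface, SI internally). `fit_adhesion_energy()` inverts it through
the exact linearization $y = m\,x$ with $y = \lambda/t^{3/2}$ and
$x = \sqrt{\varepsilon}$:

* the slope comes from *unweighted through-origin least squares* — the
  error model for buckle-width measurements is unknown, so no weights are
  invented;
* $\hat\Gamma = 2\pi^2 \bar E_f / m^2$;
* the uncertainty is first-order (delta-method) propagation from the slope
  standard error, $\sigma_\Gamma = 2\hat\Gamma\,\sigma_m/m$. For a
  noise-free dataset the residuals, and hence $\sigma_\Gamma$, are zero.

Defaults: $\bar E_f$ = 42 MPa, the literature value for gel-phase DPPC
films, used as-is with no plane-strain $(1-\nu^2)$ correction; a `poisson`
argument applies that correction for sensitivity analysis. Thicknesses
outside 70–150 nm trigger a warning rather than a hard filter: outside that
band the roughness of DPPC films varies enough to bias width measurements,
but the algebra is unaffected.

The synthetic generator `simulate_buckles()` draws $t \sim U(70, 150)$ nm,
cycles strains through {5, 10, 14} % in balanced round-robin order (so the
default $n = 12$ gives four buckles per strain, mirroring a
twelve-buckle experimental design), and applies *multiplicative* Gaussian
noise to $\lambda$ — geometry measurement error plausibly scales with
feature size; nonpositive draws are redrawn. With 10 % noise and $n = 12$
the through-origin estimator is near-unbiased (the test suite checks the
median over 200 replicates to within 5 %).

## Scattering peak analysis

Radially averaged GISAXS/GIWAXS intensities are modeled per fitting window
as a single Lorentzian on a locally linear background:

$$I(q) = A\,\frac{(w/2)^2}{(q-q_0)^2 + (w/2)^2} + b_0 + b_1 (q - q_0).$$

Numerical choices:

* **Initialization** from the window maximum ($q_0$, $A$) and the
  half-height crossings ($w$); the background starts at the window-edge
  mean. Optimization is Levenberg–Marquardt (`minpack.lm`) with box
  constraints keeping $q_0$ inside the window and $w, A \ge 0$; up to five
  jittered restarts precede a classified fit-failure error. A window whose
  maximum sits on its edge is rejected up front (`no interior maximum`).
* **Window choice is the background model.** The broad PDMS substrate
  scattering near $q \approx 1\ \text{Å}^{-1}$ is handled by fitting
  windows that exclude it, not by an explicit substrate term. Windows are
  user-supplied; the auto-window convenience takes the global maximum ±5
  initial half-widths.
* **Conversions** are fixed to $d = 2\pi/q_0$ and $\xi = 2\pi/\mathrm{FWHM}$.
  The measured chain-packing numbers in this field (e.g. $q.\approx
  1.51\ \text{Å}^{-1} \leftrightarrow 4.15$ Å) follow the $2\pi/q$
  convention even when the packing is described as hexagonal; the hexagonal
  lattice parameter $a = 4\pi/(\sqrt3\,q_0)$ is available behind
  `lattice = "hexagonal"` but is not the default. No instrument-resolution
  deconvolution is applied, so correlation lengths are apparent values.
* **Lamellar indexing** (`lamellar_d_spacing()`) regresses $q_0$ on the
  order index $n$ through the origin and rejects assignments whose $q_0/n$
  scatter exceeds 10 % (range over mean — a two-point inconsistency like
  {0.1122, 0.25} must trigger, which a standard deviation criterion would
  miss).

The tests cross-check the optimizer against an independent brute-force
oracle: a 200×200 grid over $(q_0, w)$ with the linear parameters
$(A, b_0, b_1)$ solved analytically at each node; the optimizer's residual
sum of squares must not exceed the grid's.

## Directors, tilt and order parameters

For coarse-grained configurations (one integer `lipid_id`, a 0-based
`layer_index`, and a `bead_role` in head/tail/terminal per bead):

* the **director** of a lipid is the unit vector from its head bead to the
  mean of its terminal bead(s), flipped so $d_z \ge 0$ — tilt lives in
  $[0^\circ, 90^\circ]$, matching how tilt histograms are reported. A
  principal-axis variant (leading SVD axis of the centred bead cloud,
  sign-aligned head-to-tail) is available; for rigid straight chains the
  two coincide.
* the **tilt** is $\arccos |d_z|$; histograms use right-open 1° bins on
  $[0, 90]$ with ties broken toward the smaller angle.
* **P₂** $= \langle (3\cos^2\theta - 1)/2 \rangle$ over chain bonds, where
  $\theta$ is measured against the membrane normal (z) or against the
  owning lipid's director. Bonds are consecutive bead pairs *excluding* the
  head-to-first-tail bond by default — headgroup orientation is not tail
  order — with `include_head_bond = TRUE` to keep it. The
  director-referenced variant isolates internal conformational order: for
  rigid chains it is exactly 1 at any undulation amplitude or noise level,
  which is the computational statement that tilt, not conformational
  change, is what lowers the membrane-normal P₂ of an undulated stack.

## Inter-layer tilt correlation

The correlation between layers $l_1$ and $l_2$ is
$\langle \theta(l_1)\,\theta(l_2)\rangle / \langle \theta(l_1)\,\theta(l_1)\rangle$
with scalar (folded) tilt angles. The lateral plane is divided into a
configurable segment grid (50×50 by default; small synthetic systems use
fewer), membership decided by the lipid *base* (head-bead) position in
half-open bins with periodic wrap. Both the numerator and the denominator
average over **all ordered within-segment pairs, self-pairs included**;
averages pool pairs, segments and frames. Two consequences fix the
convention: a layer is exactly perfectly correlated (ratio 1) with a copy
of itself, and for two independent layers with one lipid per segment the
ratio reduces to $\overline{\theta}^2/\overline{\theta^2}$ of the noise
distribution. The normalization is deliberately asymmetric in $l_1$; a
symmetric Pearson correlation of segment-mean tilts is offered as a
clearly labeled alternative (`method = "pearson"`), not as the reference
definition. Whether the underlying convention bins by head bead or centre
of mass, and multiplies signed or folded angles, is not fixed by the
reference analyses; the defaults here are documented choices, not claims.

## What the synthetic generators emulate — and what they do not

`simulate_multilayer()` builds stacks of *rigid straight* bead chains whose
heads sit on the 1D sinusoidal surface
$z_l(x) = l\,d + A \sin(2\pi x/\lambda_u + l\,\phi)$ and whose axes follow
the local surface normal, plus optional director noise: a rotation away
from the normal by $|N(0, \sigma)|$ degrees (folded at 90°) about a
uniformly random azimuth. For the noise-free sinusoid the tilt at $x$ is
$\arctan|A k \cos kx|$, and because the slope of a sinusoid spends most of
its time near its extremes, the modal tilt is $\arctan(Ak)$ — the analytic
anchor used throughout the tests.

Defaults chosen once: $d$ = 56 Å (the gel-phase DPPC lamellar repeat),
bond length 1.5 Å and 12 beads per chain (coarse-grained-like tail
dimensions), lateral pitch 8 Å (≈0.64 nm² per lipid), wavelength 400 Å with
amplitude 11.2 Å so the default modal tilt is near 10°, typical of an
uncompressed stack. The undulation amplitude/wavelength of real compressed
systems are not pinned by published numbers, so they are free parameters
rather than asserted values.

What the generators do **not** emulate: thermal undulation spectra,
two-dimensional undulations, internal chain conformational disorder,
area-per-lipid changes, solvent, or substrate interactions. Passing tests
therefore demonstrate that the *analysis pipeline* recovers the quantities
its models define — not that those models capture every feature of
experimental AFM/GIWAXS data or of force-field trajectories.
Correspondingly, `simulate_scattering_profile()` makes ideal Lorentzians on
a linear background (no form factor, no resolution smearing), and
`simulate_topography()` composes a sinusoidal wrinkle field (ridges
perpendicular to x), raised-cosine buckle cross-sections and white height
noise — real AFM maps carry scanner drift and correlated noise that are
not modeled, which is why `rms_roughness()` exposes plane and per-line
detrending.

## Topography analysis

`rms_roughness()` reports the root mean square of heights about the mean
(`detrend = "none"`), about the least-squares plane, or about per-row
least-squares lines. A sinusoid of amplitude $A$ sampled over whole periods
gives $A/\sqrt2$ exactly.

`extract_buckle_geometry()` detects buckles on a line profile: baseline =
running median (window five times the largest expected width, or the global
median when no width is supplied); candidate pixels exceed the baseline by
$\max(3\times\mathrm{MAD}\cdot1.4826,\ 2\ \text{nm})$; candidates grow
outward to the baseline-crossing level, regions closer than 3 pixels merge,
and the width is the grown extent. The 3-robust-SD threshold, 2 nm floor
and 3-pixel merge are implementation choices tuned for nm-scale AFM noise;
widths of manually measured buckles are the quantity they stand in for.

## Interfaces and reproducibility

Configurations are written as fixed-column GRO (nm in file, Å in memory;
residue name encodes the layer as `L000…`, atom names `H`/`T1…`/`TE` encode
bead roles) and as labeled XYZ; profiles as two-column text; topographies
as CSV or 32-bit float TIFF. TIFF samples are affinely mapped to $[0,1]$
with the offset/scale and pixel size stored in a JSON sidecar, because
float TIFF payloads outside $[0,1]$ are not portable across readers;
the sidecar restores physical units exactly.

Every stochastic function takes an integer seed and is bit-reproducible.
`run_pipeline()` derives per-stage seeds from the config seed by fixed
offsets, validates the whole configuration (unknown keys rejected, numeric
preconditions checked) before any computation, and writes results plus a
provenance record. The CLI at `inst/scripts/lamellaflex.R` is a thin
argument-parsing layer over the exported functions; the package functions
and this vignette are the primary interface.

Problem sizes used in the shipped tests and acceptance script — 4 layers ×
2 500 lipids × 12 beads for tilt statistics, 200 replicates of 12 buckles
for the adhesion-energy median, 10⁵ random bond orientations for the
isotropic P₂ check, 512×512 pixels for roughness — are the package's
standard desk-scale study conditions; all run in seconds.

## Known limitations

* The mechanics inversion assumes a single shared $\bar E_f$; uncertainty
  in the modulus propagates linearly into $\hat\Gamma$ and is not folded
  into the reported standard error.
* Reported correlation lengths are apparent (no resolution deconvolution).
* The buckle-width model applies to the delamination regime of the ruga
  phase diagram; the package reports geometry descriptively and does not
  compute regime boundaries (wrinkle wavelength selection, fold/crease
  transitions) or time-dependent relaxation.
* Reading binary MD trajectory formats (XTC/TRR/DCD) is out of scope; the
  analyses consume GRO/XYZ snapshots, synthetic or user-supplied.
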