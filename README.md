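# lamellaflex

Mechanics and molecular order of supported lipid multilayer (SLM) films under
uniaxial compression.

When a stack of lipid bilayers is deposited on a pre-stretched elastomer
(e.g. PDMS) and the stretch is released, the film is compressed and responds
across length scales: delamination buckles and wrinkles appear at the micro
scale, the lamellar stack reorganizes at the meso scale, and the lipids
themselves tilt as nanoscale undulations develop. `lamellaflex` implements
the quantitative analyses that connect those observations to material
parameters, for researchers working with AFM topography, grazing-incidence
X-ray scattering (GISAXS/GIWAXS) and coarse-grained membrane simulations:

* **Buckle-delamination mechanics.** The width λ of a delamination buckle in
  an elastic film of thickness *t* under compressive strain ε obeys

  λ / t^{3/2} = π √(2 E̅_f ε / Γ)

  where E̅_f is the in-plane Young's modulus of the film and Γ the
  film–substrate adhesion energy. `fit_adhesion_energy()` inverts this
  relation by through-origin least squares of λ/t^{3/2} on √ε
  (Γ̂ = 2π²E̅_f/m² from the slope m), with a delta-method standard error.
* **Scattering peak analysis.** `fit_lorentzian_peak()` fits
  I(q) = A·(w/2)²/((q−q₀)² + (w/2)²) + b₀ + b₁(q−q₀) to a window of a 1D
  profile; peak position converts to a real-space spacing d = 2π/q₀ and peak
  width to a correlation length ξ = 2π/FWHM; `lamellar_d_spacing()` indexes
  several diffraction orders at once.
* **Membrane order statistics.** From bead-level multilayer configurations:
  per-lipid directors, tilt-angle histograms, the second-rank order
  parameter P₂ = ⟨(3cos²θ − 1)/2⟩ over chain bonds (against the membrane
  normal, or renormalized against each lipid's own director), and the
  segmented inter-layer tilt correlation ⟨θ(l₁)θ(l₂)⟩/⟨θ(l₁)θ(l₁)⟩.
* **Topography.** RMS roughness with optional plane/line detrending, and
  buckle width/height extraction from line profiles.
* **Synthetic data.** Seeded generators for every input the pipeline
  consumes: undulated multilayers, Lorentzian peak profiles, wrinkled
  height maps, and (λ, t, ε) buckle tables drawn from the mechanics model.

Everything is tibble-first and pipe-friendly; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Recover an adhesion energy from twelve synthetic buckles generated at
Γ = 0.22 J/m², E̅_f = 42 MPa with 10 % measurement noise:

```r
library(lamellaflex)

obs <- simulate_buckles(n = 12, gamma = 0.22, e_modulus = 42e6,
                        strains = c(0.05, 0.10, 0.14),
                        rel_noise = 0.10, seed = 7)
fit_adhesion_energy(obs, e_modulus = 42e6)
#> <adhesion_fit> Gamma = 0.19 +/- 0.012 J/m^2 (slope 6.602e+04 m^-1/2, n = 12, E = 4.2e+07 Pa)
```

A single noisy dataset scatters around the generating value; the median over
many replicates sits on 0.22 J/m² (see the acceptance script below). Fit a
synthetic gel-phase chain-packing peak and convert to real space:

```r
prof <- simulate_scattering_profile(
  tibble::tibble(q0 = 1.5141, fwhm = 0.061003, amplitude = 100),
  q_grid = seq(1.2, 1.8, by = 5e-4), background = c(2, 0))
fit_lorentzian_peak(prof, window = c(1.3, 1.7))
#> <peak_fit> q0 = 1.5141 1/A, fwhm = 0.061 1/A, amplitude = 100 (RSS 8.64e-13, 801 points)
#>   spacing 2*pi/q0 = 4.15 A, correlation length 2*pi/fwhm = 103 A
```

So a peak at q ≈ 1.51 Å⁻¹ corresponds to a 4.15 Å chain-packing spacing with
a ≈ 103 Å packing correlation length. Tilt statistics of an undulated
multilayer whose maximum surface slope is tan 22.5°:

```r
cfg <- simulate_multilayer(n_layers = 4, lipids_per_layer = 2500,
                           amplitude = 26.3695, wavelength = 400, seed = 1)
h <- tilt_histogram(tilt_angles(compute_directors(cfg)))
modal_tilt(h)
#> [1] 22.5
order_parameter_p2(cfg)$p2                     # disorder from tilt alone
#> [1] 0.8860483
order_parameter_p2(cfg, "lipid_director")$p2   # rigid chains: exactly 1
#> [1] 1
```

The drop of the membrane-normal P₂ below 1 while the director-renormalized
P₂ stays at 1 shows that, for rigid chains, orientational disorder comes
entirely from the undulation-induced tilts, not from internal chain
conformations.

A ready-made end-to-end run (simulate → analyze → fit, with JSON results and
a provenance record) ships as a demo configuration:

```r
run_pipeline(system.file("extdata", "demo-config.yaml",
                         package = "lamellaflex"),
             output_dir = "demo-results")
```

and the same operations are scriptable through the thin CLI at
`inst/scripts/lamellaflex.R` (`simulate`, `fit-scattering`, `fit-adhesion`,
`topography`, `order`, `tilt-hist`, `correlate`, `run`).

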