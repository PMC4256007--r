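# npmembrane

Analysis toolkit for coarse-grained (CG) simulations of ligand-coated
nanoparticles (NPs) interacting with lipid bilayers — the workflow used to
study how an anionic, MUS/OT-decorated gold NP partitions into
DPPC/cholesterol membranes: how far its charged termini "snorkel" up to
the head groups, how the bilayer disorders, thins, and sheds cholesterol
around it, and what free-energy barrier it must cross to translocate.

It is written for computational membrane biophysicists who have (or want to
emulate) CG trajectories and need the full observable stack in one tested,
pipe-friendly package:

* **Structure** — spatial maps and radial profiles of the second-rank lipid
  order parameter `P2 = ⟨(3 cos²α − 1)/2⟩` (α: tail-bond angle to the
  bilayer normal), with liquid-disordered/liquid-ordered phase
  classification (Ld: 0.2–0.5, Lo: 0.7–1); number-density maps; radial
  concentration `c(d)/c_bulk`; lateral 2D radial distribution functions;
  PO4–PO4 bilayer-thickness profiles; snorkeling fractions.
* **Energetics** — cutoff-and-shift Lennard-Jones and Coulomb kernels
  (potential and force exactly zero at the 1.2 nm cutoff) and NP–component
  interaction energies normalized per molecule within the cutoff.
* **Free energy** — umbrella-window layout, WHAM reconstruction of the PMF
  along the NP–bilayer-centre distance (200 bins, 1e-7 tolerance defaults),
  block-bootstrap error bars, barrier/minimum extraction, and
  sampling-time convergence scans.
* **Dynamics** — mean square displacements with multiple time origins and
  lateral self-diffusion coefficients (`MSD = 4Dτ`).
* **Synthetic data** — generators that plant analytically known structure
  (order fields, cholesterol depletion, thinning, snorkeling, 1D PMFs,
  Brownian paths), so every estimator has an exact recovery test without
  running molecular dynamics.

Everything is data-frame first: trajectories and topologies are tibbles,
results are tibbles with `autoplot()`, `tidy()`, and `glance()` methods.
GRO coordinate files, species-table TSVs, plain-text trajectories, and
two-column umbrella window records are read and written natively.

## Worked example

Plant an NP-perturbed membrane (Lo bulk turning Ld near the particle,
cholesterol depletion of depth 0.5, 1 nm thinning), then recover each
observable; run a synthetic umbrella campaign against a known 28 kJ/mol
double-well PMF; fit a planted diffusion coefficient.

```r
library(npmembrane)

sys <- gen_bilayer(bilayer_spec(n_lipids = 2000, chol_fraction = 0.3),
                   seed = 1, n_frames = 20)
planted <- planted_structure(
  p2_field       = function(d) 0.8 - 0.4 * exp(-d^2 / 8),
  chol_depletion = gaussian_well(0.5, 2),
  thinning       = gaussian_well(1.0, 2, bulk = 4.0))
traj <- plant_structure(sys$traj, sys$topology, planted, seed = 2)

p2 <- p2_profile(traj, sys$topology, bin_width = 1)
p2$phase <- classify_phase(pmin(pmax(p2$value, -0.5), 1))
head(p2[, c("d", "value", "se", "phase")], 5)
#>       d value      se phase
#> 1   0.5 0.455 0.00944 Ld
#> 2   1.5 0.506 0.00420 intermediate
#> 3   2.5 0.624 0.00259 intermediate
#> 4   3.5 0.713 0.00238 Lo
#> 5   4.5 0.771 0.00271 Lo

fit_gaussian_well(thickness_profile(traj, sys$topology), bulk_start = 4)
#>   depth sigma  bulk      rss
#> 1 0.993  2.00  4.00 0.000319

dw  <- pmf_double_well(barrier = 28)
lay <- make_windows(7, 0.2, k = 750)            # 36 windows: 0, 0.2, ..., 7 nm
w   <- gen_umbrella_samples(dw, centers = lay$center, k = 750,
                            n_per_window = 5000, seed = 3)
glance(wham(w, n_bins = 200, tolerance = 1e-7))
#>   min_xi min_G barrier_xi barrier converged iterations
#> 1   4.40 -5.50       1.59    28.0 TRUE           19623

fit_diffusion(msd(gen_brownian2d(5e-7, 1, 2000, 500, seed = 4)))
#> Lateral diffusion fit (dim = 2)
#>   D = 4.98e-07 cm^2/s (SE 1.2e-08), 95% CI [4.74e-07, 5.22e-07]
#>   fit range 100-500 ns, 500 particles
```

Reading: the order parameter rises from Ld (~0.45) at the NP to Lo (~0.8)
in the bulk, tracking the planted field; the thickness fit recovers the
planted 1.0 nm well with σ = 2 nm on a 4 nm bilayer; WHAM reproduces the
planted 28 kJ/mol barrier with an interfacial minimum near 4.4 nm; the
diffusion fit recovers the planted 5×10⁻⁷ cm²/s within its CI.

`autoplot()` works on every result type (`p2_map()`,
`number_density_map()`, radial profiles, PMFs, MSD curves); the methods
vignette (`vignettes/npmembrane-methods.Rmd`) documents the models,
conventions, and numerical choices.

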