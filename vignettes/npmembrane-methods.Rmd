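---
title: "Methods: synthetic membranes, structural observables, WHAM, and diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic membranes, structural observables, WHAM, and diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmembrane)
```

# Scope and design

`npmembrane` is the analysis layer for coarse-grained (CG) simulations of a
ligand-decorated, anionic nanoparticle (NP) embedded in DPPC/cholesterol
bilayers: spatial lipid order parameters with liquid-ordered/disordered
phase classification, NP-centred radial profiles (concentration, 2D RDF,
bilayer thickness), number-density maps and snorkeling metrics,
cutoff-and-shift interaction energetics normalized per molecule,
umbrella-sampling free-energy reconstruction by WHAM with block-bootstrap
errors, and lateral self-diffusion from mean square displacements.

The package deliberately does **not** run molecular dynamics. Instead it
ships a synthetic-configuration generator that plants analytically known
structure — a radial order-parameter field, cholesterol depletion, bilayer
thinning, a snorkeling fraction, a 1D free-energy curve, Brownian paths
with known diffusivity — so that every estimator has an exact recovery
test. Generated configurations are statistical stand-ins for MD ensembles,
not physical states: frames are independent draws, which makes ensemble
averages exactly computable but removes time correlation (see
*Limitations*).

All coordinates are in nm, energies in kJ/mol, times in ns, charges in e.
Boxes are orthorhombic; triclinic box lines are rejected on input because
the membranes this package targets are rectangular. `k_B` = 0.0083145
kJ/mol/K and the default temperature is 323 K, the DPPC fluid-phase
condition the defaults assume throughout.

# The synthetic bilayer and nanoparticle

`gen_bilayer()` builds two leaflets of 12-bead DPPC (choline +1e, phosphate
−1e, two glycerols, two 4-bead tails) and 8-bead cholesterol, split between
leaflets as evenly as possible (within one molecule per species, well
inside the 10-molecule symmetry budget the composition contract allows).
Defaults: area per lipid 0.64 nm², bulk PO4-PO4 separation 4.0 nm,
cholesterol fractions 0-0.5, bulk tail order parameter 0.4
(liquid-disordered). Water beads are not generated — no analysis in this
package consumes them — and the waters-per-lipid ratio is carried only as
a spec field for I/O realism, deliberately left a free parameter because
the CG literature quotes both per-bead and per-molecule hydration numbers
that disagree under a strict 4:1 mapping.

`gen_np()` builds a Fibonacci-lattice spherical core (default diameter 4.3
nm) decorated with anionic MUS and hydrophobic OT ligands at the fixed 2:1
ratio; each MUS terminal bead carries −1e, so the default 134:67 coat has
total charge −134 e. Ligand counts are primary; surface charge density is
derived, because a printed charge density and a total charge are only
mutually consistent for an effective radius that is itself a modelling
choice.

## Planting structure

`plant_structure()` rewrites a generated configuration so that its ensemble
structure matches target radial fields around a lateral centre (the NP
core centre of mass by default; core-only rather than core+ligands, with
the alternative available through `np_com(include_ligands = TRUE)`):

* **Order parameter.** Tail-bond orientations are drawn from the
  maximum-entropy distribution `p(u) ∝ exp(λ P2(u))` on `u = |cos α| ∈
  [0, 1]`, with λ solved by 1D root-finding so that `E[P2] = target`.
  This family is smooth, unique, and spans every target in (−0.5, 1);
  the endpoints are handled as their degenerate limits (all bonds
  in-plane / all along the normal). Sampling uses a trapezoidal
  inverse-CDF on a 2001-point grid; per-lipid targets are grouped at
  1e-3 resolution, an order of magnitude below the ±0.02 recovery
  tolerance the tests enforce.
* **Cholesterol depletion.** Lateral positions are resampled by rejection
  so the stationary density is proportional to the depletion profile;
  molecule counts are conserved (reassignment, not removal), keeping all
  frames on one topology.
* **Thinning.** Each leaflet's phosphate is moved to `z_mid ± t(d)/2` (plus
  0.05 nm thermal roughness) and the whole molecule translates with it.
* **Snorkeling.** Exactly the rounded target fraction of MUS termini is
  placed outside the hydrophobic core band (default half-width 1.0 nm, a
  modelling choice exposed as a parameter since the core-band boundary is
  not a measured quantity), the rest inside it.

The default perturbation width for planted wells is `gaussian_well(σ = 2
nm)`, matching the 2-3 nm range over which an embedded NP visibly perturbs
the surrounding bilayer.

Every generator is a pure function of `(spec, seed)`; sub-streams are
derived inside each generator through `withr` so repeated calls are
bitwise reproducible.

# Structural observables

**P2 maps and profiles.** `P2 = (3 cos²α − 1)/2` per bond, α against the z
axis. The bond set for DPPC is all consecutive tail-bead bonds plus the
glycerol-first-tail bond of each chain, equally weighted — the common
convention for 4-bead CG tails when no explicit pair list is given. Maps
bin bond midpoints on (lateral distance × z) or (x × z) grids (default
0.2 nm bins, the umbrella-spacing scale); bins never visited are `NA`
("empty"), not zero. Maps average both leaflets jointly. Phase labels:
Ld for P2 in [0.2, 0.5], Lo for [0.7, 1], `intermediate` elsewhere
(including the (0.5, 0.7) gap), total over [−0.5, 1].

**Radial concentration.** Molecule-COM counts per lateral annulus
(bead-count mode available), frame-averaged and normalized by `c_bulk`,
the mean annulus concentration over d ∈ [6 nm, box/2 − 1 nm] — 6 nm
because NP influence on cholesterol extends that far out. Counting COMs
rather than beads is the default because a per-molecule concentration is
what a depletion fraction naturally normalizes.

**2D RDF.** In-plane minimum-image pair distances normalized by the
ideal-gas expectation from the mean planar density of the partner group;
the production (vectorised) path is pinned to a brute-force O(N²) pair
histogram in the tests.

**Thickness.** Mean upper-leaflet minus lower-leaflet PO4 z per annulus,
ordered canonically so an intact bilayer gives positive values. Leaflets
are assigned per frame from the sign of z(PO4) against the midplane,
excluding PO4 beads within one core radius (2.15 nm) laterally of the NP
from the midplane estimate so local deformation does not bias the
reference plane.

**Standard errors.** Profile SEs use block averaging over 5 equal time
blocks: MD frames are autocorrelated, and a per-frame SE would
systematically understate the uncertainty. On the synthetic (independent)
frames the block SE is simply a valid SE.

**Well depths.** `fit_gaussian_well()` fits `bulk − depth·exp(−d²/2σ²)` by
least squares with annulus-area weights: the statistical exposure of an
annulus grows linearly with d, so unweighted fits let the noisy innermost
bins dominate.

# Energetics

The nonbonded kernels implement the cutoff-and-shift scheme of CG membrane
force fields: for each power term `1/r^p` a cubic/quartic polynomial is
added from the shift onset (0.9 nm for LJ, 0 for Coulomb) with
coefficients solved from `F(r_cut) = F'(r_cut) = 0` and the constant from
`V(r_cut) = 0`, making potential and force exactly zero at the 1.2 nm
cutoff and C¹ there. The coefficients are solved numerically from the
boundary conditions rather than transcribed, and the tests verify each
kernel against numerical quadrature of its own force — the value/force
consistency is checked, not assumed.

Electrostatics use `f·q_i·q_j/(ε_r·r)` with ε_r = 15, the customary
screened-dielectric choice for this CG lipid family (exposed in
`pair_params()`; the defaults table of σ/ε per role pair is illustrative
and user-overridable, since no σ/ε values are part of this package's
contract).

`group_interaction()` normalizes the NP-component energy by the number of
component molecules with **any bead** within the cutoff of any NP bead —
the more inclusive reading of "molecules within the cutoff distance", and
configurable by selecting beads differently. `interaction_report()`
averages the per-frame ratio over frames (rather than forming the ratio of
time averages), then attaches 5-block SEs; components absent from the
system print `N/A`.

Synthetic configurations are not energy-minimized, so absolute interaction
energies on planted systems can be dominated by hard-core overlaps; the
energetics tests therefore pin the implementation to the brute-force
oracle and to the kernels' analytic properties, not to magnitudes.

# Umbrella sampling and WHAM

`make_windows()` lays an inclusive-endpoint ladder: a 7 nm span at 0.2 nm
spacing gives 36 centres `0, 0.2, …, 7.0` — the convention under which the
span/spacing/window-count bookkeeping is self-consistent.
`campaign_time()` does the corresponding totals (36 × (200 + 400) ns =
21.6 µs; 18 µs with 300 ns production).

`wham()` iterates the coupled equations

```
p(b)  ∝  Σ_i n_i(b)  /  Σ_i N_i exp[(F_i − w_i(b))/k_BT]
F_i   =  −k_BT log Σ_b p(b) exp[−w_i(b)/k_BT]
```

from `F_i = 0`, undamped by default (a 0.5 damping flag exists for
oscillatory cases), until `max|ΔF_i| < tol·k_BT` (default 1e-7, 200 bins —
the conventional settings for this protocol). Bins span the pooled sample
range uniformly and the bias is evaluated at bin centres, the convention
of standard WHAM implementations. Windows must form a single
overlap-connected
component; disconnected ladders abort, since island-to-island free
energies are undetermined. `G = −k_BT log p`, re-referenced to zero as the
mean over the outermost 0.5 nm of sampled ξ — the flat-at-the-water-phase
convention.

`bootstrap_pmf()` block-resamples each window's series (10 ns blocks by
default, because umbrella series are autocorrelated and a naive bootstrap
understates the error), reruns WHAM on the full-data bin grid, re-references
each replicate, and reports per-bin SDs. Both error conventions mentioned
for such calculations — replicate-run SD and within-run bootstrap — are
available (run the pipeline on independent window sets for the former);
within-run bootstrap is the default.

## Recovery accuracy and replicate averaging

At the protocol conditions (36 windows, k = 750 kJ/mol/nm², 10⁴ samples
per window), reconstruction error is dominated by window-to-window free
energy linking noise through the modest histogram overlap (window sd 0.06
nm vs 0.2 nm spacing), so a single campaign's curve RMSE fluctuates
materially around its expectation while the barrier — a difference of two
well-sampled levels — is more stable. The test suite therefore
quantifies recovery as the **average over eight replicate campaigns**
(fixed consecutive seeds), asserting mean barrier error < 1 kJ/mol and
mean curve RMSE < 0.3 kJ/mol; the acceptance script reports the same
replicate-averaged quantities. Reported RMSEs compare curves after
removing the free additive gauge (mean over the 0-7 nm support).

`pmf_features()` returns the interfacial minimum (lowest G over a stated
interface region, default 3-6 nm) and the translocation barrier (highest G
between the bilayer centre and that minimum, relative to the minimum),
with first-bin tie-breaks. `convergence_scan()` truncates every window to
increasing sampling times after an equilibration discard and tracks the
barrier — the standard stationarity check for umbrella campaigns.

# Lateral diffusion

`msd()` averages squared displacements over all time origins and selected
particles, lateral (x, y) components by default, on a pseudo-logarithmic
lag grid; wrapped trajectories are detected (frame-to-frame jumps above
L/2) and must be unwrapped (`unwrap_trajectory()`, valid while true
per-frame steps stay below half a box edge). `fit_diffusion()` fits a line
over 10-50% of the lag range by default — excluding short lags where
apparent MSD curvature from the finite lag grid matters most — and
converts via `D = slope/(2·dim)`, 1 nm²/ns = 1e-5 cm²/s.

The standard error comes from the spread of per-particle slopes when
per-particle curves are available: particles are independent, so the CI is
honestly calibrated, which the suite verifies by a coverage test (95% CIs
over 100 seeded Brownian replicates must cover the planted D at least 90
times). At the recovery scale used in the tests (500 particles × 2000
steps, planted D = 5×10⁻⁷ cm²/s) the estimate lands within 5%.

# Problem sizes in the tests

The suite runs entirely on synthetic data generated at test time: planted
P2 recovery on ~1300-lipid bilayers (10⁴ bonds per level), depletion and
thinning recovery on 3000-lipid, 50% cholesterol bilayers over 100
independent frames (1.5×10⁵ cholesterol observations, enough to hold the
well-depth estimator's sampling error well inside its tolerance),
WHAM on 36 × 10⁴-sample campaigns, and diffusion on 10⁶ particle-steps.
These sizes were chosen so each estimator's standard error sits several
times below the tolerance it is tested against.

# Limitations

* Synthetic frames are independent draws: estimators of autocorrelated
  errors (block SEs, block bootstrap) are exercised mechanically but their
  autocorrelation-robustness is not probed by these tests.
* The bilayer generator places molecules with uniform lateral positions:
  no packing correlations, no undulations, no area fluctuations. RDF tests
  that need structure plant it explicitly.
* Planted-system interaction energies include hard-core overlaps;
  energetics validation is oracle- and property-based, not magnitude-based.
* One reaction coordinate, orthorhombic boxes, no binary trajectory
  codecs (convert externally and import the whitespace format or GRO).
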