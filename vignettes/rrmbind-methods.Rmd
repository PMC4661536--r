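---
title: "Methods: models, parameters and design choices in rrmbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in rrmbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmbind)
```

rrmbind implements the quantitative stages of a protein–RNA
interaction study — chemical-shift perturbation mapping, ITC
thermodynamics, ensemble and interface geometry, and RNA stem-loop
logic — as composable functions over tibbles. This vignette documents
the underlying models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do
not emulate.

## Chemical shift perturbations

Amide CSPs between a free and a bound state are combined as
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}$.
The nitrogen weighting $\alpha$ rescales ¹⁵N shift changes (which span
roughly a 5-fold larger ppm range) onto the ¹H scale. Published
conventions vary between about 0.10 and 0.20; we default to the most
widely used $\alpha = 0.14$ and expose it as `n_weight`, rather than
asserting any single literature value.

Significance tiers are drawn at the profile mean + 1 SD
(*significant*) and mean + 2 SD (*strong*), computed **only** over
residues whose amide H and N are observed in both states; prolines and
unassigned residues are classed `unobserved` and excluded. The SD is
the *population* SD (denominator $n$): the tiers describe the
dispersion of the measured profile itself, not an estimate for a
larger population, and this convention matches how the thresholds are
drawn on CSP histograms. Degenerate profiles (a single observed
residue, or zero variance) get SD 0, and the strict `>` comparison
then classifies nothing — a deliberate guard against false positives.

Cluster detection (`hotspot_clusters()`) joins consecutive
significant/strong residues and bridges a **single** unobserved (or
entirely unassigned) residue, because proline gaps would otherwise
split contiguous binding patches; a sub-threshold residue always
breaks a run. Run length is counted as residue span including the
bridged gap.

## Heteronuclear NOE profiles

`hetnoe_profile()` is the ratio estimator $I_{NOE}/I_{ref}$ with the
first-order error propagation
$\sigma_r = |r|\sqrt{(\sigma/I_{NOE})^2 + (\sigma/I_{ref})^2}$ from a
single global spectral-noise estimate. A per-peak noise model would be
more faithful to weak peaks but is rarely available from published
tables, so a global $\sigma$ is the default (and the error column is
simply 0 when $\sigma = 0$). Negative ratios are physical for highly
flexible segments and are never clipped. Region averages are plain
arithmetic means over the observed residues in a range; a region with
no observed residues is reported as `NA` rather than an error so that
partial assignments do not abort a profile.

## ITC: simulation and fitting

The single-site model is the standard Wiseman isotherm. After
injection $i$ the total cell concentrations are updated with the
per-injection displacement factor $(1 - dV_i/V_0)$ — the convention
used by common instrument software — and the bound fraction $\theta_i$
solves the mass-action quadratic at those concentrations. The
cumulative heat content is $Q_i = N\theta_i M_i V_0 \Delta H$ and the
per-injection observable is
$dQ_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$,
normalised per mole of injectant. Simulator and fitter share this
forward model exactly, which is what makes noise-free round trips
recover parameters to machine precision (verified in the tests against
an independently coded mass-balance implementation).

Fitting is weighted least squares via Levenberg–Marquardt
(`minpack.lm`), with $K_a$ on the log scale for conditioning.
Auto-initialisation takes $\Delta H$ from the first-plateau mean, $N$
from the molar ratio at which the heat falls through half that
plateau, and $K_a$ from a coarse $\log_{10} K_a \in [2, 9]$ grid —
robust across the c-value range without user input. A Wiseman c-value
$N M_0 K_a < 1$ triggers a warning that the stoichiometry is poorly
determined. Non-convergence is flagged in the result object, never
silently dropped. Derived quantities use $R = 1.9872$ cal mol⁻¹ K⁻¹:
$K_d[\mu M] = 10^6/K_a$, $\Delta G = -RT\ln K_a$,
$\Delta S = 1000(\Delta H - \Delta G)/T$, and both unit identities are
asserted by tests on every fit.

The sequential-sites model uses the stepwise partition function
$Z = 1 + \sum_j \beta_j x^j$ ($\beta_j = K_1\cdots K_j$), solving the
free-titrant concentration per injection by bisection on the mass
balance. Its least-squares surface is multi-modal, so
`fit_sequential()` multi-starts from dispersed random initial values
(seeded, hence reproducible) and keeps the best optimum; on noise-free
data this recovers three distinct sites to a relative error below
1e-4, and at $k = 1$ the model coincides with the one-site model at
$N = 1$. The number of sites $k$ is a user choice (1–3): nothing in a
single isotherm reliably selects $k$, so the package does not guess.

An optional `discard_first` flag drops the first injection (a common
instrumental anomaly); it defaults to off since the simulated data
have no such artefact.

## Ensembles, RMSD and RMSF

Superposition is the Kabsch SVD solution with the reflection
correction; fewer than three paired atoms or a collinear selection is
an error because the rotation is then degenerate. Ensemble RMSD is
exposed in two conventions — mean over all model pairs
(`pairwise_mean`, the default) and mean RMSD to the iteratively
re-fitted mean structure — because published ensemble statistics
rarely state which was used; the output records the mode. The backbone
selection is N, CA, C (carbonyl O excluded).

`find_ordered_range()` iterates: fit all models on the retained
backbone, compute each residue's RMS positional spread about the
ensemble mean, drop residues above the cutoff (default 1.5 Å), and
repeat until the retained set is stable or 20 iterations. The cutoff
is in Å of positional spread, and the final spread profile is attached
to the result for inspection. RMSF assumes frames are already
superposed on a stated selection (as MD trajectories typically are)
and averages per-atom fluctuations within each residue.

## Surface areas

SASA is Shrake–Rupley with a deterministic Fibonacci lattice (default
960 points, probe 1.4 Å), so results are exactly reproducible —
pseudo-random sphere samplings are not. At 960 points an isolated
sphere is exact and two-sphere overlaps agree with a 10⁶-point
latitude–longitude quadrature to better than 1%. Van der Waals radii
are a fixed table (C 1.70, N 1.55, O 1.52, P 1.80, S 1.80, H 1.20 Å);
hydrogens are used when present and united-atom radii are not.
Buried surface area is the per-residue SASA difference between the
isolated component and the complex, and the total interface area is
half the two-sided sum; the conservation identity
$\sum \mathrm{BSA} = \mathrm{SASA}(A) + \mathrm{SASA}(B) -
\mathrm{SASA}(AB)$ holds to numerical precision by construction.
Relative accessibility divides by the theoretical per-residue maxima
of Tien et al. (2013); fractions above 1 (distorted termini) are not
clipped.

## Interface geometry

Hydrogen bonds use distance $d(D,A) \le 3.5$ Å plus, when the donor's
hydrogens exist in the model, a D–H⋯A angle of at least 120° —
standard MD-analysis conventions, exposed as parameters since
different tools draw these lines differently. Donor/acceptor typing
comes from a plain-text template table covering the 20 amino acids and
4 ribonucleotides. Occupancy over a trajectory is the exact fraction
of frames in which a (donor, acceptor) pair satisfies the criteria,
plus per-interval mean bond counts for redundancy analysis.

Stacking uses unweighted centers of geometry (matching the
"centers of geometry" convention) and best-fit ring planes from an
SVD. π-π contacts (centroids ≤ 5.5 Å) are classified by interplanar
angle: ≤ 30° is the parallel family, split at a 1.0 Å lateral offset
into face-to-face and displaced; ≥ 60° is T-shaped; intermediate
inclinations are deliberately not labelled. The lateral offset
projects the centroid–centroid vector onto the mean ring plane. CH-π
groups are ribose rings or single aliphatic carbons (≤ 4.5 Å);
anion-π groups are phosphates (≤ 5.0 Å). Purine bases are treated as
one fused ring system.

## RNA stem-loops

`fold_terminal_stem()` implements exactly the hairpin-construction
rule for short synthetic RNAs: pair position $k$ with $L+1-k$ inward
while bases are Watson–Crick complementary (G·U optional, off by
default since the target hairpin is pure Watson–Crick) and at least 3
loop nucleotides remain, stopping at the first mismatch. This is a
construction procedure, not thermodynamic folding — bulged or
internally looped structures and pseudoknots are out of scope on
purpose. Positions are 1-based. Expected imino counts follow the
protection rule: one observable imino per AU or GC pair, two per G·U
wobble.

## Docking restraints

Active residues are those with CSPs above mean + 1 SD; passive
residues are non-active residues with relative SASA above 0.5 whose
nearest heavy atom lies within 6.5 Å of an active residue. The 6.5 Å
vicinity is our explicit approximation of docking servers' automatic
passive-surface definition, which is otherwise a black box; both
thresholds are parameters. Emitted restraints use the conventional
ambiguous-distance dialect with a 2.0 Å effective distance.
NOE restraint statistics use the standard sequence-separation classes
($|i-j| = 0$, $= 1$, $1 < |i-j| < 5$, $> 4$) with percentages rounded
half-up to two decimals to match printed-table formatting (base R
`round()` is round-half-even, which disagrees at the .xx5 boundary).

## Synthetic data: what it does and does not emulate

The generators produce every input format the analysis functions read,
with ground truth returned alongside:

* `make_shift_pair()` — spatially clustered CSP hotspots over Gaussian
  noise on a ~100-residue construct. It emulates effect size and noise
  structure, not real chemical-shift physics: base shifts are uniform
  draws from plausible amide ranges, and noise is added at hotspot
  residues too (a noise-free hotspot would be unphysical).
* `make_ensemble()` — an idealised extended backbone with a step
  sigma profile (ordered core, disordered tails), in Gaussian or
  deterministic (±σ along x) jitter modes. The deterministic mode
  makes RMSF equal the planted profile exactly, which is what the
  rank-correlation tests exploit.
* `make_hbond_trajectory()` — donor/acceptor pairs toggled between
  bonded (2.9 Å, 180°) and broken (6 Å) geometry on exact per-frame
  schedules, so occupancies are exactly k/n.
* `make_stack_fixture()` — idealised regular polygons (1.39 Å bond
  length) placed at exact centroid distance, interplanar angle and
  offset. For π-π the two rings are tilted half the angle each about
  the offset axis, which makes the detector's mean-plane projection
  return the construction values exactly, enabling 1e-6 round-trip
  tests.

Consequently, passing tests demonstrate correctness of the statistics
and geometry engines under known truth; they do not demonstrate
robustness to real-data pathologies (peak overlap, assignment errors,
baseline drift in raw thermograms, missing density), which are outside
the package's scope.

## Problem sizes and runtime choices

The test and acceptance workloads use sizes at which every check runs
comfortably on a laptop core: 100-seed batteries for the stochastic
recovery properties (CSP sensitivity, NOE region means, ITC bias),
20-model/60-residue ensembles, 50-atom interface toys, a 10⁶-point
quadrature oracle for SASA and a coarse-to-fine (5° then 1°) rotation
grid as the superposition oracle. These sizes were chosen as the
smallest at which the statistical assertions have comfortable margins.

## Known limitations

* The NMR-STAR reader covers only the `Atom_chem_shift` loop — enough
  to ingest deposited backbone assignments, nothing more.
* The sequential ITC fit reports stepwise constants; site-specific
  (microscopic) constants are not identifiable from a single isotherm.
* H-bond detection is purely geometric; no energy or wavefunction
  criteria, no water-mediated bridges, no salt-bridge inventory.
* `relative_sasa()` covers standard amino acids only; nucleotides
  have no reference maxima and return `NA`.
* General RNA secondary-structure prediction is out of scope; only
  terminal contiguous stems are folded.
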