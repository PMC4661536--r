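# rrmbind

A tidyverse-style R toolkit for characterising how an RNA recognition
motif (RRM) binds a stem-loop RNA, built around the data types of a
solution NMR + calorimetry study: chemical-shift tables, ITC
isotherms, multi-model structural ensembles, and protein–RNA
interface geometry. Every analysis stage has a matching synthetic-data
generator with known ground truth, so the whole pipeline is testable
end to end without any external downloads.

## What it computes

**Chemical shift perturbations.** For each backbone amide observed in
a free and an RNA-bound HSQC, the combined perturbation is

  Δδ = √( Δδ(¹Hᴺ)² + (α · Δδ(¹⁵N))² ),  α = 0.14 by default,

with significance tiers at the profile mean + 1 SD (*significant*) and
mean + 2 SD (*strong*), and cluster detection over consecutive
perturbed residues (proline gaps bridged). Classified profiles feed
directly into ambiguous interaction restraint (AIR) generation for
data-driven docking: active residues from the CSP tiers, passive
residues from relative solvent accessibility (> 50%) near the active
set.

**ITC thermodynamics.** Forward simulation and Levenberg–Marquardt
fitting of the single-site Wiseman isotherm (and a sequential-sites
model for multiphasic titrations), with displacement-dilution
bookkeeping, heat-of-dilution subtraction, and the standard
derivations K_d = 10⁶/K_a, ΔG = −RT ln K_a, ΔS = (ΔH − ΔG)/T.

**Ensemble statistics.** Kabsch superposition, ensemble RMSD (pairwise
or to-the-mean), iterative ordered-range detection, and per-residue
RMSF for trajectories.

**Surfaces and interfaces.** Shrake–Rupley SASA on a deterministic
Fibonacci lattice, per-residue buried surface area, geometric
hydrogen-bond detection (3.5 Å / 120° defaults) with per-frame
occupancy statistics, and π-π / CH-π / anion-π stacking detection
with centroid distances, interplanar angles and lateral offsets.

**RNA stem-loops.** Terminal-stem folding of short hairpin sequences
(Watson–Crick, optional G·U), dot-bracket output, and the expected
count of protected imino-proton resonances (one per AU/GC pair, two
per wobble).

**Backbone dynamics.** Steady-state ¹⁵N-{¹H} heteronuclear NOE ratios
I_NOE/I_ref with error propagation and region averages.

## Worked example

```r
library(rrmbind)

# fold the 25-mer stem-loop and count protected iminos
ss <- fold_terminal_stem("CGUAUCUUUAACUACUCAAGAUACG")
ss
#> stem-loop: 8 bp stem, 9 nt loop (9-17)
#> CGUAUCUUUAACUACUCAAGAUACG
#> ((((((((.........))))))))
expected_imino_count(ss)
#> [1] 8
```

The hairpin folds with an 8 base-pair stem enclosing a 9-nucleotide
loop, predicting 8 observable imino resonances — one protected G H1 or
U H3 per pair.

```r
# CSP mapping on a synthetic titration with two planted hotspots
sp <- make_shift_pair(seed = 42)
prof <- compute_csp(sp$free, sp$bound, n_weight = 0.14) |> classify_csp()
prof
#> CSP profile: 97 residues (97 observed), mean 0.0393 ppm, SD 0.0772 ppm
hotspot_clusters(prof, min_run = 3)
#> # A tibble: 2 × 3
#>   start   end n_significant
#> 1   262   267             6
#> 2   270   275             6
```

Both planted contact clusters are recovered as runs of significant
residues.

```r
# simulate a noisy titration and refit it
iso <- simulate_one_site(n = 0.72, dh = -6.64, kd_um = 10,
                         scheme = itc_scheme(), noise_sd = 0.1, seed = 1)
fit <- fit_one_site(iso)
tidy(fit)
#> # A tibble: 6 × 3
#>   term   estimate std.error
#> 1 n         0.710    0.0111
#> 2 ka    99530.    7891.
#> 3 dh       -6.69     0.140
#> 4 kd_um    10.0      0.797
#> 5 dg       -6.82    NA
#> 6 ds        0.429   NA
```

From 20 injections with 0.1 kcal/mol heat noise, the fit returns the
stoichiometry, affinity and enthalpy with realistic uncertainties;
`autoplot(fit)` overlays the fitted Wiseman curve on the observed
heats per mole of injectant.

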