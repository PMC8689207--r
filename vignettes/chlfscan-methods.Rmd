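---
title: "Methods: cone-scan discrimination of chlorophyll f and supporting analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cone-scan discrimination of chlorophyll f}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlfscan)
```

## The model

A cryo-EM reconstruction is a 3-D scalar field of electrostatic potential
(ESP). Working in map-σ units — values divided by the map standard
deviation after mean subtraction (`rescale_map()`) — makes contour levels
comparable across maps and is the convention assumed by every statistic in
this package.

Chlorophyll *a* carries a methyl and chlorophyll *f* a formyl substituent
at ring position C2; both carry a methyl at C7. The cone-scan statistic
exploits this internal control:

1. **Alignment.** Each chlorophyll is least-squares aligned (Kabsch) onto
   an ideal reference chlorophyll using four atoms: the first substituent
   atom (C2¹ or C7¹), its ring carbon, and the two flanking ring atoms
   (C2¹, C2, C1, C3 for the C2 position; C7¹, C7, C6, C8 for C7). This is
   the unique chemically coplanar quartet around the bond, so the fit is
   well conditioned; the fit RMSD is reported on every scan.
2. **Cone extraction.** The distal atom of the substituent (formyl O,
   methyl H) lies on a cone around the extended ring-carbon→substituent
   axis. ESP is sampled by trilinear interpolation every 5° of azimuth at
   probe radius 1.22 Å (the carbonyl C=O bond length) and half-angle 55°,
   with an optional radial profile from the apex outward at 0.01 Å steps.
   The azimuth origin is tied to the first flanking ring atom, so scans
   are equivariant under rigid motion of model and map.
3. **Null model.** C7 scans across all chlorophylls of a map, binned by
   local resolution of the central Mg (cutoff 2.91 Å, inclusive on the low
   side; a single bin when no local resolutions are supplied), give a
   per-angle empirical null. Assuming normality, the rejection threshold
   is μ + 3σ per angle — a one-sided nominal significance of about 0.002.
   σ is the unbiased (n−1) estimator because per-bin sample sizes can be
   small.
4. **Decision.** A C2 scan rejects "methyl" when it strictly exceeds the
   threshold over a run of at least `min_run` consecutive azimuths
   (wrap-around aware).

### Why the pipeline default is min_run = 3

The per-site decision aggregates 72 per-angle tests. Even with a
perfectly calibrated null, a single-angle exceedance criterion
(`min_run = 1`) falsely rejects ≈ 1 − 0.99865⁷² ≈ 9% of true methyl
scans by multiplicity alone. Interpolation and noise errors are also
smooth in azimuth (correlated over roughly five 5° steps at these
geometries), so pairs of consecutive false exceedances are common, while
a genuine formyl oxygen — a Gaussian of ≈ 0.7 Å width on a probe circle of
≈ 1.1 Å radius — produces sustained excess over tens of degrees.
Requiring three consecutive exceeding azimuths (15°) sits far below the
signal footprint but above typical noise runs; on methyl-only calibration
batteries it brings the per-scan false-positive rate to 2–4% with no
sensitivity loss. The low-level `test_substituent()` keeps `min_run = 1`
so single-angle exceedance remains inspectable; `run_chlf_analysis()` and
the validation batteries use 3.

## Chemical environment

Chl *f* sites tend to avoid His axial ligation and to provide an H-bond
donor to the formyl oxygen. `find_axial_ligand()` takes the nearest N/O
within 3.0 Å of the Mg (standard Mg coordination upper bound,
configurable) and classifies it by identity. `find_c2_hbond_donors()`
tests heavy-atom distances only, in a 2.4–3.5 Å window: at ~3 Å map
resolution hydrogens are unresolved, so donor geometry beyond heavy-atom
proximity is not knowable. For sites without a modeled formyl O, both
in-plane formyl rotamer positions (1.22 Å from C2¹ at 120° to the bond,
projected into the macrocycle least-squares plane) are tested and a hit at
either counts; a donor near both is reported once at closest approach.
Carbonyl and carboxylate oxygens are excluded as donors.

`classify_site()` combines the evidence:

* **high-specificity-f** — non-His ligand AND (cone rejection with a
  donor, OR homology support, meaning the donor environment is conserved
  with a confirmed Chl *f* site in a related structure). Homology support
  is deliberately allowed to substitute for a direct donor observation:
  peripheral sites can carry unresolved waters or disordered donors, and a
  site paired with a confirmed neighbour (a Chl *f* dimer partner) can be
  promoted on that evidence alone.
* **low-specificity-f-candidate** — no cone rejection, non-His ligand, no
  donor, sterically clash-free C2 neighbourhood, and location in an
  FRL-variable sequence region.
* **a** — otherwise.

Region flags (FRL-variable region, steric clash, homology support) are
inputs supplied per site, not derived quantities: the first two require a
cross-species sequence/structure comparison and the third a curated
homologue, all outside a single map-model pair.

## Occupancy from contour ratios

A component present in a fraction q of the particle ensemble contributes
its ESP at amplitude q, so the contour level at which its features become
visible scales with q. "Visible" is operationalized in
`visibility_level()` as: the highest level L (scanned downward in 0.1σ
steps) at which at least 50% of the selected atoms lie within 1.5 Å of a
voxel with value ≥ L. Coverage fraction, probe radius and step are
configurable and reported; the reference level is always explicit, never
assumed. `estimate_occupancy()` reports the ratio at 10% granularity
(half-up rounding), which is the precision the method supports. B-factor
differences between component and reference bias the ratio; the method
assumes comparable disorder, which is why the reference should be a
peripheral region of a core subunit rather than the well-ordered center.

## Structure and sequence comparison

Pairwise global alignment uses BLOSUM62 with gap open 10 / extend 0.5;
identity is matches over aligned columns (gaps in the denominator), which
makes it symmetric. Superposition is an all-pair Kabsch fit with no
outlier pruning — different superposition tools prune differently, which
is why reproduction of published RMSDs is checked to ±0.1 Å rather than
exactly. Conservation is the majority non-gap residue frequency per
column (simple, monotone, and exactly 1 for identical columns);
gap-majority columns score 0. Fe-S cluster geometry reports
center-to-center distances between centroids of all cluster Fe and S
atoms (not Fe only) and edge-to-edge minima that include coordinating Cys
SG atoms when selected via `select_cluster()`. The motif scan holds the
Glu and Gly of V-E-G-P strict and the flanks free, matching the observed
conservation pattern.

## The synthetic-data generator

`simulate_esp_map()` renders each atom as an isotropic Gaussian:

* weight = atomic number × occupancy (a proxy for ESP scattering
  amplitude; adequate for discrimination testing, not for quantitative
  scattering work);
* width σ² = (d / (π√2))² + B/(8π²) for resolution d — a real-space
  low-pass proxy added in quadrature with the B-factor spread;
* the formyl O amplitude is multiplied by 0.7 by default, emulating the
  reduced ESP visibility of the partially negatively charged formyl
  oxygen;
* i.i.d. Gaussian noise with sd = noise_sigma × sd(noiseless map) is
  added (absolute when the map is empty, which yields pure-noise
  calibration maps), then the map is rescaled to σ units.

`simulate_study()` places randomly oriented chlorophyll fixtures at
random non-clashing positions (minimum Mg–Mg separation 13 Å — safely
beyond the ~9 Å fixture radius) and renders one map per requested
resolution over the identical model, so resolution series are directly
comparable. The formyl count is exactly `round(f_fraction × n_chl)`.
Everything is reproducible from the seed; there is no hidden global
randomness.

What the simulator does *not* emulate: CTF effects, reconstruction
artifacts, solvent/lipid background, anisotropic B-factors, radiation
damage, or spatially varying local resolution. Passing the synthetic
batteries therefore demonstrates that the statistic and its calibration
behave correctly under controlled conditions; it does not by itself
guarantee performance on experimental maps, where the null distribution
absorbs some (but not all) of these effects because it is built from the
same map being tested.

### Study conditions used in validation

* Null calibration: 140 chlorophylls at occupancy 0 (pure noise), one
  map, 10,080 per-angle trials; the observed per-angle exceedance rate is
  required to be ≤ 0.5%, consistent with the 3σ nominal level of 0.135%
  plus threshold-estimation slack.
* Discrimination: 100 chlorophylls, half formyl, at 2.0/3.0/4.0 Å with
  noise 0.1 and occupancy 1; sensitivity ≥ 0.9 and methyl false-positive
  rate ≤ 0.05 at 2.0 Å, sensitivity non-increasing toward 4.0 Å. At these
  noise levels the formyl signal is strong enough that sensitivity stays
  at 1.0 across the range — the degradation the theory predicts appears
  as shrinking exceedance margins rather than missed detections.
* Occupancy recovery: helix pairs at occupancies 0.1/0.3/0.5/1.0 with
  noise 0.05, recovered within ±10 percentage points.

These sizes keep the full suite to a few minutes on one CPU while leaving
every estimate comfortably inside its binomial error.

## Numerical choices and degenerate inputs

* Maps are non-periodic boxes; sampling outside the extent is an error,
  never a wrap. Trilinear interpolation is used instead of
  structure-factor Fourier summation: at ≥3× Nyquist oversampling the
  difference is below the noise the tests tolerate, and it avoids
  reciprocal-space machinery. Interpolation accuracy is tested against a
  closed-form Gaussian (≤1% of peak at 0.2 Å voxels) and an independent
  brute-force oracle (1e-9).
* Map σ is the population standard deviation (cryo-EM convention).
* MRC output is mode 2 (float32), MRC2014, axis order x-fastest; reading
  rejects permuted axis orders rather than silently reordering. Origin
  precedence: ORIGIN header field if nonzero, else nstart × voxel.
* Constant maps cannot be rescaled (error); a flat zero map yields
  visibility level 0 with a warning.
* Exceedance uses strict `>`, so a scan exactly at threshold fails to
  reject; the resolution-bin boundary is inclusive on the low side.
* Collinear alignment quartets and sub-3-point superpositions are errors,
  not silently regularized.
* Chlorophylls missing Mg or C2 are excluded from site enumeration with a
  warning naming the residue.

## Known limitations

* The cone half-angle (55°) and probe radius (1.22 Å) are chemically
  motivated defaults, not fitted values; both are configurable and the
  same geometry is applied at C2 and C7 so the null remains comparable.
* The steric-clash criterion behind the low-specificity call is supplied
  as a per-site flag; the package does not itself compute contact scores.
* Sequence-to-structure residue pairing assumes contiguous residue
  numbering within a chain.
* The element-weight model (atomic number) ignores true electron
  scattering factors and charge effects beyond the single formyl-O
  attenuation factor.
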