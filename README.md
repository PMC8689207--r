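# chlfscan

Identification of chlorophyll *f* binding sites in cryo-EM maps of
photosystem I (PSI).

## The problem

Cyanobacteria capable of far-red-light photoacclimation (FaRLiP) swap six
PSI core subunits for far-red isoforms and replace roughly 10% of their
chlorophyll *a* with chlorophyll *f*. Chl *a* and Chl *f* differ at a
single ring position: a methyl versus a formyl substituent at C2. In a
cryo-EM electrostatic-potential (ESP) map at ~3 Å this is a one-atom
difference at the edge of visibility — made worse by the partial negative
charge of the formyl oxygen, which reduces its ESP contrast. Deciding
which of ~90 chlorophyll sites per PSI monomer carry Chl *f* therefore
needs a statistic, not just visual inspection.

`chlfscan` is aimed at structural biologists interpreting cryo-EM maps of
FRL-PSI (or any map where a methyl/formyl ambiguity arises) and provides:

* **Cone scans** — each chlorophyll is least-squares aligned onto an ideal
  reference via the first substituent atom and its three coplanar ring
  neighbours; the rescaled ESP (map-σ units) is sampled every 5° on a cone
  of candidate distal-atom positions around the C2 (and C7) bond axis at
  the expected bond length, with radial profiles at 0.01 Å increments.
* **A methyl null distribution** — C7 carries a methyl in *every*
  chlorophyll, so C7 scans give a per-angle empirical null. Scans are
  binned by local resolution of the central Mg (cutoff 2.91 Å); per bin
  and per angle the null is normal with threshold μ + 3σ (one-sided
  significance ≈ 0.002). A C2 scan exceeding the threshold over a
  sustained run of azimuths rejects "methyl" in favour of
  "formyl-consistent".
* **Chemical environment** — axial ligand of the central Mg (Chl *f*
  disfavours His ligation) and heavy-atom search for hydrogen-bond donors
  to the actual or hypothetical formyl oxygen (both in-plane rotamers are
  tested). Evidence is combined into site-specificity calls
  (high-specificity-f / low-specificity-f-candidate / a).
* **Contour-ratio occupancy** — a component visible at contour level L
  against a full-occupancy reference visible at L_ref has estimated
  occupancy L / L_ref, reported to the nearest 10%.
* **Structure comparison** — global alignment identity (BLOSUM62),
  Cα superposition RMSD (Kabsch), conservation profiles, Fe-S cluster
  center-to-center / edge-to-edge distances, and the VEGP (Glu-Gly core)
  motif scan.
* **A synthetic ESP simulator** — element-weighted Gaussians with
  resolution- and B-factor-dependent widths, per-component occupancy,
  formyl-O attenuation, and seeded noise, so the whole pipeline is
  testable with known ground truth and no downloads.

## Worked example

Simulate a study of 16 randomly placed and oriented chlorophylls (25%
Chl *f*) at 2.0 Å with noise, write the map/model/site table, and run the
full per-site analysis:

```r
library(chlfscan)
st <- simulate_study(16, 0.25, resolutions = 2.0, noise_sigma = 0.1, seed = 5)
write_map(st$maps[[1]], "study.mrc")
write_structure(st$model, "study.pdb")
write.table(st$sites, "sites.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

res <- run_chlf_analysis(list(map = "study.mrc", model = "study.pdb",
                              sites = "sites.tsv", out = "out"))
print(res$null)
#> null_model (mu + 3*sd, nominal one-sided p < 0.002):
#>   bin all   n = 16, mean threshold 4.620 sigma

table(decision = res$sites$cone_decision,
      truth = st$truth$substituent[res$sites$site_name])
#>                 truth
#> decision         formyl methyl
#>   fail-to-reject      0     12
#>   reject              4      0
```

All four simulated formyl sites reject the methyl null (sustained runs of
~30 exceeding azimuths); all twelve methyl sites fail to reject. The
per-site table (`out/sites.tsv`) also reports the axial ligand class,
H-bond donor count and combined call — on these bare fixtures there is no
protein environment, so no site reaches a high-specificity call despite
cone rejection (the rule table requires a donor or homology support).

Occupancy estimation is a one-liner:

```r
estimate_occupancy(2.5, 8.0, component_id = "PsaF2-like")
#> occupancy_estimate PsaF2-like: visible at 2.5 sigma vs reference 8.0 sigma -> ~30%
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/chlfscan-cli.R` (subcommands `simulate`, `run-all`, `compare`).

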