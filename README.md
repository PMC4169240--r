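# mtclone

Simulation and quantification of mitochondrial DNA (mtDNA) point-mutation
dynamics in an ageing, crypt-structured epithelium.

## The problem

As humans age, individual mtDNA point mutations inside single stem cells
expand clonally — by random genetic drift, over decades — until a pathogenic
variant dominates the cell and its clonal progeny, producing focal
respiratory-chain deficiency.  Distinguishing the *mutation rate* (how fast
new mutations arise) from *clonal expansion* (how fast existing mutations
rise in frequency) requires combining assays with very different detection
windows, each with its own estimator and quality-control logic:

- **Random Mutation Capture (RMC)**: single mutant molecules escaping TaqI
  digestion at a TCGA site; mutation frequency `f = m / b` (confirmed
  mutants over base pairs screened) with an exact Poisson (Garwood) 95% CI;
- **whole-mtDNA sequencing of biopsies**: variant calling from per-site
  strand-resolved pileup counts through a plasmid-calibrated filter cascade
  (quality > 20, ≤3-fold strand imbalance on variant fractions, ≥3 variant
  reads, ≥600× coverage, artefact blacklist, substitutions only,
  heteroplasmy > 0.8%);
- **paired-tissue partitioning**: variants shared between colon and buccal
  epithelium of one subject are germline/early-embryonic, colon-private
  ones somatic; a two-sided Fisher exact test on benign vs non-synonymous
  counts in the two sets detects purifying selection;
- **neutral Moran drift simulator**: a per-crypt mtDNA population of `N`
  copies in which one copy duplicates and one dies per event, generating
  cohorts (two tissues per subject, germline sharing, clonal crypt patches,
  Ion-Torrent-like pileups with 0.12% substitution error, mutation-free
  plasmid controls) so the whole chain runs and is tested with no external
  data.

The package is aimed at researchers modelling heteroplasmy dynamics or
re-analysing low-level mtDNA variant data who need the estimators, the
filter cascade and the study-design statistics as reusable, tested R
functions.

## Worked example

```r
library(mtclone)

# Low-level mutation frequency: 803 confirmed mutants in 2e8 bp screened
rmc_frequency(803, 2e8)
#> RMC mutation frequency: 803 mutants / 200,000,000 bp = 4.01e-06 per bp
#>   exact Poisson 95% CI: [3.74e-06, 4.3e-06]

# A simulated RMC run at that frequency: 100 wells x 10,000 target bases
ex <- simulate_rmc_experiment(4e-6, n_wells = 100, seed = 42)
rmc_frequency(ex)
#> RMC mutation frequency: 5 mutants / 1,000,000 bp = 5e-06 per bp
#>   exact Poisson 95% CI: [1.62e-06, 1.17e-05]

# Tissue-level detectability: how many fully clonal crypts (of ~200 in a
# biopsy) must share a mutation to exceed the 0.8% calling threshold?
detection_limit(0.008, 200)
#> [1] 2

# The whole simulated study, end to end
res <- run_pipeline(pipeline_config(seed = 1, n_young = 4, n_old = 4,
                                    cohort = cohort_config(n_crypts = 100),
                                    n_rmc_subjects = 20))
res
#> simulated mtDNA ageing study
#>   seed 1 | 4 young + 4 old NGS subjects | threshold > 0.80% (control noise max 0.31%)
#>   RMC: 20 subjects, frequency x age r = 0.014 (p = 0.955); decade ANOVA p = 0.234
#>   NGS old vs young per-Mb frequency:
#>     total:   old vs young: means 0.1286 / 0.05714 (2.2-fold), Student t: p = 0.01696
#>     somatic: old vs young: means 0.1143 / 0.02857 (4-fold), Student t: p = 0.005424
#>     germline:old vs young: means 0.01429 / 0.02857 (0.5-fold), Student t: p = 0.3559
#>   purifying-selection Fisher p = 0.4762
#>   % COX-deficient crypts x age: r = 0.845 (p = 0.00822)
#>   filter failures:  quality=1 strand=354220 min_reads=400982 coverage=0 blacklist=199 threshold=438562 indel=0
```

Reading the output: low-level frequency shows no age trend (r ≈ 0, flat
decade ANOVA) while the clonally expanded somatic burden is several-fold
higher in the old group and the fraction of COX-deficient crypts rises
strongly with age — the drift signature the simulator is built around.  The
germline contrast stays flat, as variants shared by both tissues predate
ageing.  The filter log shows where candidate calls died: almost all are
sub-threshold sequencing noise.

The bundled reference (`synthetic_rcrs()`) is an explicitly *synthetic*
16,569-bp stand-in carrying the real rCRS gene coordinates and a TCGA TaqI
site at 6562–6565; load the real NC_012920.1 FASTA with `load_reference()`
for real data.

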