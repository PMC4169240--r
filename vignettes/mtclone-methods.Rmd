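---
title: "Models and methods behind mtclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtclone)
```

# The problem

Ageing epithelia accumulate mitochondrial dysfunction because individual
mtDNA point mutations, many of them arising early in life, expand clonally
inside single stem cells until a pathogenic variant dominates the cell's
mtDNA population.  Three assays see three different windows of this process:

* **Random Mutation Capture (RMC)** counts single mutant molecules escaping
  TaqI digestion at one TCGA site, measuring the *low-level* mutation
  frequency (an indirect proxy of the mutation rate) per base pair;
* **whole-mtDNA amplicon sequencing (NGS)** of a tissue biopsy detects
  variants above a heteroplasmy threshold, i.e. *clonal expansions* spanning
  one or more crypts or low-level heteroplasmy distributed through the
  tissue;
* **COX/SDH histochemistry** scores crypts whose cells have lost cytochrome
  c oxidase activity, a surrogate for mid-to-high-level expansions of
  pathogenic mutations.

`mtclone` implements the full computational chain around these assays — a
drift simulator that generates realistic cohorts, the RMC frequency
estimator, the NGS quality-control cascade with its control-based threshold
calibration, germline/somatic partitioning with mitochondrial-code
annotation, and the cohort statistics — so that every stage is testable
without access to any sequencing data.

# The drift engine

## Model

Each colonic crypt is maintained by a small stem-cell niche whose effective
mtDNA population we model as a neutral **Moran process** on `N` copies: at
every replacement event one copy, drawn uniformly with replacement, is
duplicated and one is destroyed, so `N` is conserved exactly.  The
duplicated copy acquires a new point mutation with probability `u` per
event.  A new mutation therefore starts at heteroplasmy `1/N` and performs
an unbiased random walk: heteroplasmy is a martingale, the probability of
eventual fixation equals the starting heteroplasmy, and expansion to
homoplasmy conditional on fixation takes of the order of `N^2` events.
These three properties are asserted by Monte-Carlo in the test-suite
(10,000 replicates per check).

Concurrently segregating mutations are tracked as independent loci (free
recombination / infinite sites).  This ignores linkage between mutations
that co-segregate in one niche; at the default mutation rate two mutations
are essentially never simultaneously polymorphic in one crypt, so each
locus's marginal law — the only thing any downstream statistic consumes —
is the exact Moran chain.

## Implementation

The engine (C++ via Rcpp) simulates the *embedded jump chain*: per event the
count `k` changes with probability `c = 2 (k/N) (1 - k/N)`, so waiting times
between changes are geometric and can be skipped in one draw; conditional on
a change the step is ±1 with probability 1/2.  This is
distribution-identical to per-event simulation but costs O(number of
changes), which makes 80-year crypt lifetimes at `N = 500` take about a
millisecond.  All randomness flows through R's RNG, so every simulation is
bit-reproducible under `set.seed()`.

## Calibration of the defaults

The assays constrain the drift parameters only qualitatively: expansion to
biochemically relevant levels should take roughly two decades or more (the
youngest COX-deficient subject observed was 21), deficiency should be rare
before age 20 and affect several percent of crypts by the eighth decade.
The defaults

| parameter | default | rationale |
|---|---|---|
| `copies_per_crypt` (N) | 500 | conditional fixation time ≈ `N(N-1)` events ≈ 25 y at the default turnover |
| `events_per_year` | 10,000 | each of ~500 copies turned over every ~2–3 weeks |
| `mut_rate_per_copy_per_event` | 1e-4 | ≈1 new mutation per crypt-year; expected fixed mutations per crypt by age 75 ≈ `u·e·(t−25)/N` ≈ 0.1, i.e. ~5% of crypts carry an expanded pathogenic mutation (with `pathogenic_fraction = 0.5`) |
| `pathogenic_fraction` | 0.5 | roughly half of random coding changes are non-synonymous |
| `biochem_threshold` | 0.85 | biochemical deficiency requires high mutant loads |

were chosen once from this back-of-envelope argument and are all exposed in
`drift_params()`.  They are *effective* rates at the niche abstraction, not
measured molecular quantities.

COX deficiency is scored at crypt level — any pathogenic mutation at
heteroplasmy ≥ 0.85 marks the crypt deficient.  The histological rule
("most cells in the crypt have lost activity") lives at per-cell
resolution the simulator does not have; at the niche abstraction the two
are treated as equivalent.

# The simulated cohort

`simulate_cohort()` draws subject ages uniformly over 17–78 (the real
cohort is middle-age-heavy; uniform keeps every decade bin populated),
injects **germline / early-embryonic variants** into both tissues of a
subject (Poisson mean 1 per subject, heteroplasmy log-uniform on 1–5%, 95%
of them benign — reflecting purifying selection upstream of tissue
differentiation), and simulates colonic crypts by drift.  Buccal tissue is
represented as a variant table (germline variants plus rare low-level
somatic variants), not as crypts: its clonal architecture is different and
unneeded for any statistic the package computes.

A biopsy's ~200 crypts are **not** treated as fully independent lineages.
A mutation homoplasmic in exactly one of 200 equally weighted crypts
aggregates to 0.5% tissue heteroplasmy — below the 0.8% calling threshold —
so with full independence *no* somatic expansion would ever be callable at
tissue level, contradicting the detection-limit arithmetic the assay design
itself is based on (homoplasmic expansions in individual crypts *or
clusters of clonally related crypts*).  Crypts are therefore generated in
static clonal patches of size `1 + Geometric(0.5)` (mean 2): one drifted
lineage replicated across its patch.  This is a fixed patch-size law, not a
model of crypt fission dynamics; within-patch divergence after fission is
ignored.  `aggregate_biopsy()` itself remains a plain equal-weight mean
over crypts.

The spectrum generator reproduces the empirical substitution spectrum
(60% G>A/C>T, 24% T>C/A>G, 16% transversions) *and* the positional bias at
the TCGA recognition site (63% of changes at the third base).  Because the
site reads T-C-G-A, the class and the offset are linked: a G>A transition
can only occur at offset 3.  Drawing the offset first and a transition with
conditional probability `w_class / (position mass of the class's offsets)`
matches both printed marginals exactly in expectation; the feasibility of
this construction is validated in `spectrum_config()`.

# The pileup and error model

Read depth per site is Poisson around the mean coverage; each read reports
its template allele and is corrupted to one of the three alternative bases
with total probability 0.12% (the platform's published aggregate
base-substitution error rate), split evenly — the aggregate figure is all
the error model is calibrated to.  Strand is assigned independently per
read; quality is modelled as a per-site mean Phred-like score.  Indels and
homopolymer artefacts are not modelled: the analysis restricts itself to
substitutions, and the two recurrent artefact regions of the platform
(position 750 and the 3902–3908 tract) are blacklisted unconditionally in
the cascade instead.

# The filter cascade

A candidate call (any position/alternative-allele pair with ≥1 read)
passes when **all** of the following hold: mean quality `> 20`; seen on
both strands with strand-specific variant *fractions* within 3-fold (the
fraction interpretation implements "comparable frequencies"; a zero-read
strand fails — a deliberate reading of an ambiguous rule, erring
conservative); ≥3 variant reads; ≥600 total reads; not blacklisted; a
substitution; heteroplasmy strictly `> 0.8%`.  Heteroplasmy is
combined-strand: `(fwd_alt + rev_alt) / (fwd_total + rev_total)`.  Rejected
calls carry *every* failed reason, and the cascade is by construction
monotone (tightening any threshold can only shrink the passed set) and
idempotent — both tested over randomized configurations.

The final threshold is anchored in a **mutation-free clonal plasmid
control**: running the control through every filter except the threshold
measures the noise ceiling.  `calibrate_noise()` rounds the ceiling up to
the next 0.1 percentage point and adds one more 0.1-point safety step —
the reconstruction that maps an observed 0.65% ceiling to the adopted
"> 0.8%" rule; boundary comparisons are strict, so `h = 0.008` fails.  On
simulated controls (2,000×, 0.12% error) the ceiling is ~0.3–0.4%, safely
below 0.65%, and the pipeline pins the conservative 0.8% threshold while
reporting the control-derived value as QC evidence.

`detection_limit(t, n)` is the smallest integer `k` with `k/n > t`: at the
default threshold and 200 crypts, two fully clonal crypts.

# Annotation and partitioning

Variants are annotated against the rCRS gene map (13 protein genes,
22 tRNAs, 2 rRNAs, control region; 1-based inclusive coordinates).
Protein-coding consequences come from translating the affected codon under
the vertebrate mitochondrial genetic code (NCBI table 2, via Biostrings);
MT-ND6 is handled on the light strand; codons truncated by a gene end are
completed with adenines, as polyadenylation does in vivo; stop gain/loss
counts as non-synonymous.  Where genes overlap (ATP8/ATP6, ND4L/ND4),
protein-coding features take precedence and ties break on feature start.
The test-suite checks 100 random coding substitutions against a
brute-force oracle that translates the entire mutated gene and diffs the
peptide.

Because the real rCRS sequence cannot be redistributed with the package,
the bundled reference (`synthetic_rcrs()`,
`inst/extdata/synthetic_rCRS.fasta`) is an explicitly synthetic stand-in:
random bases at the rCRS length with the real gene coordinates and a TCGA
TaqI site at 6562–6565.  Every simulation and test runs against it; real
analyses should load the NC_012920.1 FASTA.

Partitioning matches variants across a subject's two tissues on
(position, ref, alt) only — heteroplasmy differences are ignored, since a
germline variant may have drifted to very different levels in different
tissues.  Variants under the calling threshold in one tissue are
necessarily misclassified as somatic; this threshold censoring is a known
limitation of the design, not of the implementation.  The
purifying-selection contrast is a two-sided Fisher exact test (implemented
from the hypergeometric pmf, cross-checked against `stats::fisher.test`)
on benign (synonymous or known-polymorphic) versus non-synonymous counts in
the germline and somatic sets, protein-coding variants only by default.
The test reports the direction of the difference alongside the p value.

# Statistics

The cohort statistics are thin, test-covered wrappers over base R:
Pearson correlation with t-based p (`cor.test`), Student's pooled-variance
t test by default with Welch by flag (`t.test`) — the source analyses say
only "unpaired t-test", and pooled is the stricter reading — one-way ANOVA
(`aov`) with Tukey HSD (`TukeyHSD`), the cohort's decade bins (17–26 …
67–77), and fold changes as ratios of group means.  Degenerate inputs are
resolved explicitly: all-identical data give `F = 0, p = 1`; two identical
groups give `t = 0, p = 1`; zero-variance correlations are an error.  Null
simulations in the suite verify the nominal type-I error and the
uniformity of p values.

Low-level (RMC) frequencies are reported per base pair with exact Poisson
(Garwood) confidence intervals — chosen because mutant counts are small and
the normal approximation fails there; subjects with zero mutants are
retained at `f = 0` (they are real observations), with exclusion available
as a sensitivity analysis.  Indels in RMC records are tallied separately
and never enter the three-class substitution spectrum.

# Problem sizes and determinism

Every stochastic check in the test-suite runs at a size chosen to make its
statistical tolerance meaningful on one CPU in minutes: 10,000 replicates
for the martingale/fixation checks (3-standard-error bands), 803 drawn
mutations for spectrum recovery (99% multinomial bands — 803 being the
cohort-scale mutant count), 20 seeds for the control noise ceiling, 100
random tables/substitutions for the oracle-equivalence checks, cohorts of
100 subjects × 200 crypts for the COX-age correlation, and a 12 + 12
subject pipeline for the old-versus-young sign check.  Every entry point
takes a seed and is bit-deterministic given it.

# What passing does and does not show

The generator emulates the statistical structure the analysis assumes:
neutral drift, a transition-dominated spectrum, Poisson sequencing depth
with uniform substitution error, germline sharing between tissues.  It does
not emulate amplification bias, strand-asymmetric or sequence-context error
(homopolymers), heteroplasmy-dependent selection, crypt fission dynamics,
mtDNA deletions, or haplogroup structure.  Tests passing on simulated data
therefore validate the *pipeline logic* — estimators, filters, partitioning
and statistics — not the biological fidelity of any particular parameter
value; the drift defaults in particular are effective, order-of-magnitude
choices, and the headline cohort effect sizes the pipeline prints depend on
them.
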