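---
title: "MNP marker panels: model, thresholds and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MNP marker panels: model, thresholds and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mnpkit)
```

## The marker model

A multiple nucleotide polymorphism (MNP) marker is a 200–300 bp amplicon
containing several tightly linked SNPs. Its allele is the full haplotype
sequence of the amplicon, so one locus behaves like a highly multi-allelic
marker: with $k$ SNPs a locus can in principle carry up to $2^k$ haplotype
alleles, and in diverse cohorts tens to >100 alleles per locus are
observed. mnpkit treats a genotype as a **set of allele sequences per
locus** rather than a diploid pair: many taxa where this marker system is
attractive (clonally propagated medicinal plants among them) have poorly
characterized or variable ploidy, so the caller reports every haplotype
passing a read-fraction threshold, capped at a configurable allele count
(default 2, raised freely when ploidy warrants).

Only the screening-stage SNP matrix is diploid-coded (hom-ref / het /
hom-alt), because genome-wide SNP calling from reduced-representation
sequencing conventionally produces diploid calls. Window haplotype labels
at that stage use IUPAC ambiguity codes for heterozygous sites and are
unphased; phasing is deliberately not attempted.

## Screening statistics

**Discriminative power.** For a window with genotype labels over $n$
accessions having multiplicities $n_i$,
$$\mathrm{DP} = 1 - \frac{\sum_i \binom{n_i}{2}}{\binom{n}{2}},$$
the exact fraction of unordered accession pairs the window distinguishes.
Missing labels are excluded from numerator and denominator. This is the
exact-pair form rather than the sampling-with-replacement form
$1-\sum f_i^2$; the two converge for large $n$, and the exact form is the
natural reading of "fraction of pairs distinguished". The admission
threshold is DP ≥ 0.2 with **more than three** SNPs per 300-bp window (a
strict inequality: windows with exactly three SNPs do not qualify).

**Window sweep.** The scan advances a 300-bp window by 1 bp. Because the
window's SNP content is piecewise-constant in the start coordinate, the
implementation sweeps SNP entry/exit events and scores each SNP-set
segment once; the test suite proves this equal to brute-force evaluation
of every start position, exhaustively on 10-kb contigs.

**Merging and amplicon feasibility.** A 1-bp step produces hundreds of
near-duplicate qualifying windows over each SNP cluster; overlapping
windows merge into runs. The run's representative is the best window by
(DP, SNP count, leftmost start) **whose amplicon is feasible**: the span
covering its SNPs plus 20 SNP-free flanking bases each side (a
primer-landing proxy replacing thermodynamic primer design), extended
symmetrically to at least 200 bp, must not exceed 300 bp and must keep
both flanks SNP-free. Skipping infeasible representatives instead of
discarding the run matters in practice: a background SNP near a dense
cluster otherwise inflates the top-ranked window's span past 300 bp and
would silently delete a perfectly designable locus (about a fifth of
planted loci in simulation). A run with no feasible representative is
dropped with a message. The reported DP and SNP count are recomputed over
the final amplicon's SNP set, and the DP threshold is re-checked there.

**Panel spacing.** Candidates are taken greedily in descending (DP, SNP
count) order subject to ≥ 10 kb start-to-start spacing per contig, up to
the target size (default 505). This is the package's reading of "evenly
distributed across the genome"; it is deterministic under the global
tie-break (higher DP, more SNPs, leftmost, lexicographic contig).

## SNP filters

Defaults: MAF ≥ 0.05 (allele copies counted over non-missing diploid
calls, two per call), call rate ≥ 0.80, exact Hardy–Weinberg p ≥ 0.01,
host contig > 250 bp. Missing genotypes are excluded, never imputed. The
HWE test is the exact conditional test on genotype counts: conditioning
on allele totals, the p-value sums the probabilities of all heterozygote
counts whose conditional probability does not exceed the observed one
(computed by the standard recurrence; the suite checks it against an
independent closed-form enumeration to 1e-12 for every table up to
n = 50). The copy-number filter has no standard formula, so a documented
heuristic is used — a locus is flagged when its mean depth exceeds 2× the
cohort median locus depth, or when > 10 % of samples exceed 2× their own
median — and it disables itself with a message when depths are absent.
The rejection tally attributes each removed record to its first failing
rule in the fixed order maf → call_rate → hwe → cnv → contig_length.

## Allele calling

Reads are assigned to loci either by the locus tag embedded in read names
(the simulator's and any upstream demultiplexer's contract) or by exact
matching of both 20-bp amplicon flanks in either orientation; no
alignment step is involved, keeping the caller deterministic. Within a
locus, exact sequences are tallied; sequences with < 5 % of reads lying
within one substitution of a ≥ 10× more abundant sequence are folded into
it (rarest processed first by descending count, ties lexicographic). A
locus with < 20 reads is a no-call; otherwise alleles are the sequences
with ≥ 20 % read fraction, capped at the allele limit. These three knobs
(20 reads, 0.2, one mismatch) are package defaults surfaced in
`genotyping_config()` — the proprietary tools in this space do not
publish theirs.

A known limitation of single-mismatch collapse: at a per-base error rate
of 0.005 a ~250-bp read carries on average 1.25 errors, so most reads are
*not* exact haplotype copies and multi-error reads survive collapse as
rare singletons, diluting true-allele fractions toward the 0.2 threshold.
At the error rates the generator models by default (0.001, typical of
modern short-read chemistry after quality trimming), collapse leaves
true-allele fractions near 0.5 per heterozygous allele and allele-set
recovery in simulation is complete; the suite asserts ≥ 99 % recovery
under that condition. Pushing the caller to 0.005-grade data would need
a quality-aware or multi-pass denoiser, which is out of scope.

## Identification statistics

* **Detection rate** = detected loci / total target loci, per sample.
* **Genetic similarity**: loci where both accessions are called and the
  allele sets are equal, divided by the **panel size** (default) or by
  the number of loci called in both (`shared_called`). The panel-size
  denominator is the literal reading of "identical loci over total core
  loci"; both modes are provided because published pairwise values do not
  always reconstruct exactly under either convention.
* **Reproducibility** between replicate runs counts accession × locus
  cells called in both; **accuracy** follows as
  $1 - (1 - r)/2$ — a discordant cell implies exactly one of the two
  independent calls is wrong, so half the discordance rate is the
  per-run error.
* **PIC** uses Botstein's form with frequencies counted one observation
  per member allele of each accession's called set (no ploidy weighting,
  consistent with the set-valued genotype model). Summaries use the
  sample (n−1) standard deviation.
* **Molecular IDs**: each locus's distinct alleles are indexed in
  lexicographic order; the canonical string concatenates the sorted
  index tuples locus by locus (`.` for no-calls) and is hashed (MD5) for
  a compact code. The canonical string is the normative identifier; the
  digest is a convenience.

## Cohort structure

The dissimilarity is $1 - \mathrm{GS}$. UPGMA is computed with
size-weighted average linkage (`stats::hclust`, labels pre-sorted so ties
resolve reproducibly) and node heights at half the merge distance, so
cophenetic distances on the ultrametric tree reproduce merge distances;
the suite checks equality with a naive O(n³) reference implementation.
The ordination is principal coordinates analysis (classical MDS of the
double-centered squared distances) on $1-\mathrm{GS}$ — the defensible
reading of running "PCA on pairwise similarity values". Negative
eigenvalues (non-Euclidean GS matrices) are truncated with a message and
explained fractions are relative to the positive spectrum; axis signs are
fixed by making each axis's largest-magnitude coordinate positive. A
one-hot allele-presence matrix (`allele_onehot()`) is provided for a
plain PCA alternative.

## The simulator and what it does (not) emulate

`sim_config()` defaults describe the study design this package targets:
30 accessions in 4 sub-clusters, 505 planted loci, 16 founder haplotypes
per locus partitioned among clusters (complete linkage within a window,
so planted DP is high), background unlinked SNPs at 0.001/bp, amplicon
read depth Poisson with mean 100×, substitution errors at 0.001/bp,
locus × sample dropout at 1 % (with an option to give designated
accessions an elevated rate, emulating poorly amplifying samples whose
detection rate drops toward 1 − rate). The reference is a fragmented
assembly of 550 × 2 kb contigs — short-contig genomes are the realistic
substrate for this marker system, and one locus per contig respects the
10-kb panel spacing by construction. Depth 100× stands in for the
thousands-fold coverage of production amplicon runs: beyond the 20-read
calling floor, additional depth changes nothing in the caller, and this
size keeps a full cohort simulation in seconds of CPU. Every stage is
deterministic given `rng_seed` (each stage derives its own sub-seed, so
stages are reproducible in isolation too).

Not emulated: PCR chemistry (primer competition, chimeras), indels and
structural variants, base-quality profiles, barcode demultiplexing, and
read mapping — reads arrive pre-assigned or are assigned by exact flank
match. Passing tests therefore demonstrate the correctness of the
statistics and the pipeline's bookkeeping on idealized reads, not
robustness to alignment artifacts or indel-bearing chemistry.

Negative-binomial per-cell depth (`depth_model = "nbinom"`) is available;
its default dispersion (size 5) is a guess, as locus-level depth
dispersion is rarely reported.

## Numerical conventions and degenerate inputs

Coordinates are 1-based inclusive in memory (the R/Bioconductor and VCF
convention); the BED-like panel TSV on disk is 0-based half-open, with
conversion confined to `write_panel()`/`read_panel()`. All tie-breaks
(window representatives, allele ordering, ID registries, UPGMA labels)
are lexicographic after the primary numeric keys, making every output
byte-reproducible. Monomorphic HWE tables return p = 1 (a single
configuration); a locus with sufficient depth but no allele reaching the
read fraction is reported as `no_call_ambiguous` rather than silently
called; empty cohorts, all-missing records, mismatched panels, duplicate
accessions and asymmetric distance matrices raise classed errors
(`mnp_config_error`, `mnp_data_error`) that the CLI maps to exit codes 2
and 3.

## Validation scales

The test suite runs the full default-scale cohort (30 accessions × 505
loci, ~1.5 M reads) once for the exact-recovery property and once for
planted-locus recovery (≥ 90 % of high-DP truth loci must enter the
screened panel after filtering; observed ≈ 99 %); window-sweep
equivalence is exhaustive on a 10-kb contig; the HWE oracle check covers
every genotype table up to n = 50; UPGMA is compared against the naive
reference on random matrices up to n = 12. The demonstration pipeline in
`run_pipeline()` and the README example use a 36–40 locus cohort, which
exercises every stage in a few seconds.
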