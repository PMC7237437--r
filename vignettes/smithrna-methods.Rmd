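---
title: "Discovering small mitochondrial RNAs and testing locus conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering small mitochondrial RNAs and testing locus conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smithscan)
```

## The problem

Animal mitochondrial genomes transcribe small non-coding RNAs. A subset of
these — small mitochondrial highly-transcribed RNAs, or smithRNAs — are
thought to leave the organelle and regulate nuclear messenger RNAs in a
miRNA-like fashion. `smithscan` implements a conservative discovery pipeline
for such candidates from gonad small RNA-seq libraries, a seed-plus-energy
target prediction against a 3' UTR collection, and a population-genetic test
of whether candidate loci are under selective constraint. All inputs can be
simulated with known ground truth, so every stage is testable without any
external download.

## Discovery model

Reads are aligned to the circular mitochondrial genome by an exhaustive
full-length, ungapped scan of both strands allowing at most one mismatch
(`map_reads_mito()`). This replaces a heuristic seeded mapper with an exact
search at the same mismatch cap: at mitogenome scale (roughly 14-22 kb) the
exhaustive scan is cheap and strictly more sensitive, so no candidate is
missed for mapper-heuristic reasons. Reads with a full-length hit (again at
most one mismatch) to a nuclear decoy set are discarded
(`screen_nuclear()`), guarding against NUMT-derived signal. Because the scan
is exact, re-mapping the screened survivors to the mitogenome reproduces
their original alignments, so the pipeline keeps the first-pass alignments
of the surviving reads.

Retained reads are clustered per strand by greedy abundance-ordered
clustering at identity 0.99 (`cluster_reads()`), which for typical 15-40 nt
reads amounts to exact sequence identity; the centroid is the most abundant
member sequence. Two requirements gate a cluster:

* **size**: strictly more than 200 reads (the relaxed mouse-style analysis
  uses 50); and
* **end sharpness**: the fraction of member reads sharing the modal 5' end
  and the fraction sharing the modal 3' end must both reach a threshold
  (default 0.75, inclusive). The source procedure required "sharp" 5'/3'
  coverage without quantifying it; we operationalize sharpness as the
  modal-end fraction and always report the raw fractions so users can apply
  their own cut-off. Note that at identity 0.99 cluster members are
  identical sequences and the fractions are trivially 1; the statistic
  becomes informative when clustering is relaxed below total identity.

Multi-mapping reads are reported at all of their best-scoring loci and
flagged; a cluster counts each read once per locus. Whether the original
analysis counted multi-mapped reads in more than one cluster is unstated;
reporting-all-with-flag is the choice that loses no information.

## Target prediction

A surviving centroid is tested against every 3' UTR with four requirements,
all applied with the published thresholds (strict inequalities where the
source prints "lower than"):

1. **seed**: a perfect Watson-Crick match of centroid nucleotides 4-10 (the
   shifted seed) somewhere in the UTR (`seed_scan()`); G:U is not accepted
   in the seed.
2. **matches**: at least 11 matched positions in the best gapless local
   alignment (match +1 / mismatch -3, the blastn-short scoring) between the
   centroid and the reverse complement of the UTR window around the seed
   site (`count_matches()`). The search window must contain the seed site;
   whether the original pipeline required positional coincidence is
   unstated.
3. **accessibility**: ddG = dG_duplex + dG_open < -9, where dG_open is the
   cost of forcing the site plus 3 nt (5') and 15 nt (3') flanks unpaired in
   the minimum-free-energy fold of a 140-nt window (`accessibility_ddG()`).
4. **duplex stability**: dG_duplex < -20 for the centroid:site duplex
   (`duplex_energy()`), with centroid positions 3-10 forced to pair — the
   helix constraint convention, which deliberately differs by one position
   from the seed definition; both are parameters.

Energies are nearest-neighbor stacking sums over gapless-and-bulge-free
pairing registers, with a Turner-style Watson-Crick stack table
(kcal/mol), one duplex initiation term (+4.09), and simplified flat values
for G:U-containing steps (-0.5 with one wobble, -0.3 with two). The flat
wobble values are deliberately weaker than the weakest Watson-Crick stack
(-0.93), which makes a provable property out of a desirable one: replacing
any pair of a perfect duplex strictly raises its energy. The thresholds -9
and -20 are applied on this native kcal/mol scale; the tools behind the
published numbers report kcal/mol even where their output is informally
labeled "kJ".

Site accessibility and the candidate-context fold use a nested
secondary-structure dynamic program scored with the same stack terms and no
loop or multiloop penalties (minimum hairpin loop 3). This is a
single-structure MFE opening cost, not an ensemble free energy: it
overestimates pairing relative to a full thermodynamic folder and parity
with PITA's ensemble ddG is not claimed. The constraint machinery
guarantees dG_open >= 0 because forcing positions unpaired can only remove
structures. The folding temperature (default 25) is recorded as metadata:
the simplified score table is temperature-fixed.

## Candidate annotation

Candidates are named `<species>_<sex>_smithRNA<number><category>` with
number = floor(5' coordinate / 100) and category `r` (rRNA gene), `t` (tRNA
gene) or `nc` (unassigned region), decided by the locus midpoint after URs
have been re-annotated to cover all inter-genic space. The midpoint rule is
our choice for intervals straddling a boundary (the source never states
one), as is floor rather than round for the 100-based position (floor
reproduces all three published example names); name collisions within a
100-bp bucket get letter suffixes. Clusters whose midpoint falls inside a
protein-coding gene have no published category and are reported in the
cluster table without being promoted to named candidates.

The pre-smithRNA context defaults to the 70-bp window centered on the
candidate, with the left flank taking the extra base for odd overhangs. The
window may run into a neighbouring feature, which automatically reproduces
the published special case of a candidate at the very start of a ribosomal
gene (the window extends into the upstream tRNA, keeping the candidate
central). For tRNA-hosted candidates the pre-region is instead the whole
tRNA extended through flanking unassigned nucleotides up to the next genes.

## Conservation analysis

Nucleotide diversity is estimated per window as

    pi_hat = N/(N-1) * sum_i sum_{j>i} p_i p_j pi_ij

over window haplotype frequencies, with pi_ij the uncorrected p-distance
(sites with a gap or ambiguity in either sequence excluded pairwise). This
follows the printed unordered-pair form, which is half the conventional
ordered-pair estimator; the doubled convention is available via
`convention = "ordered"`, and the rank tests downstream are invariant to the
global factor of two. Windows default to 10 bp with 5-bp steps; windows with
zero diversity are kept. Each window is labeled by the region type at its
midpoint with overlay precedence smithRNA > pre_smithRNA > tRNA > rRNA >
PCG > UR. For gap-free alignments the window estimator is computed from a
per-site pairwise-difference decomposition (algebraically identical to the
haplotype form, verified by property test); gapped alignments take the
haplotype path.

Group contrasts use a tie-corrected Kruskal-Wallis test, two-tailed Dunn
tests with Bonferroni correction over all k(k-1)/2 pairs, and (for assay
tables) one-tailed Mann-Whitney tests with an exact branch for tie-free
samples with n_x * n_y <= 400 and a tie- and continuity-corrected normal
approximation otherwise. These are implemented from the rank formulas so
the test suite can check them against independent references
(`stats::kruskal.test`, `stats::wilcox.test`, and direct formula
substitution for Dunn, which has no reference implementation installed).

A caveat the user should know: with the default 10/5 windows, neighbouring
windows share five sites and are therefore positively correlated, which
violates the independence the rank tests assume and inflates their type-I
error. The package's own simulation checks (and the acceptance script)
therefore run the calibration and contrast analyses on non-overlapping
windows (step = size = 10), where window values at independently mutated
sites are independent and the Kruskal-Wallis test is well calibrated
(rejection rate approximately 5% at alpha = 0.05 under equal rates). The
10/5 default is kept for descriptive window profiles because it is the
published setting.

## What the generators emulate — and what they do not

`simulate_genome()` builds a random-sequence circular genome (default
16.5 kb) with a 13-PCG / 2-rRNA / 22-tRNA plan on both strands and abundant
interspersed URs, bivalve-style; smithRNA loci (22 nt) and their 70-bp
pre-regions can be overlaid on rRNA/tRNA/UR hosts. `simulate_population()`
mutates each of n sequences independently at per-site rate mu times a
region multiplier (default UR = 5, everything else 1; mu = 0.005, n = 42 by
default, matching a gonad amplicon panel), Jukes-Cantor-like substitutions
with no indels — the real amplicon alignments are essentially indel-free.
`simulate_reads()` emits depth-250 perfectly sharp read stacks per planted
locus (end jitter configurable) over a uniform background;
`simulate_utrome()` plants perfect-complement or seed-only target sites in
random UTRs; `simulate_assay()` produces shifted Gaussian group
measurements.

The generators intentionally omit several features of real data:
phylogenetic correlation between population sequences (substitutions are
independent per lineage), sequencing errors and quality-score structure,
transcription-driven read-length distributions, base composition bias, and
NUMT-like nuclear paralogy beyond whatever decoy contigs the user supplies.
Passing tests therefore demonstrate that the pipeline's logic and
thresholds behave as specified under the stated statistical structure — not
that the thresholds are optimal for any particular real library.

## Numerical and design choices

* Coordinates are 1-based inclusive; features with end < start wrap the
  circular origin and are serialized to GFF3 unrolled (end > genome
  length), the usual circular-genome convention.
* Identity between unequal-length sequences during clustering is matches at
  aligned 5' ends over the longer length; this only matters below 0.99.
* Exact-vs-approximate Mann-Whitney branch cut-off: n_x * n_y <= 400,
  tie-free.
* The fold traceback prefers unpaired positions on ties, so zero-benefit
  lone pairs never appear in reported structures; reported pairs are
  Watson-Crick or G:U with hairpin loops of at least 3 nt.
* Degenerate inputs: all-equal samples give H = 0 / p = 1; empty UTR sets
  and empty read sets propagate as empty results; a window partition that
  fails to cover a midpoint is an error rather than a silent drop.
* Problem sizes used by the checks: 20 discovery runs at 1,050 reads each,
  100 conservation replicates at 40 sequences over the full 16.5-kb genome,
  and 1,000 null-calibration replicates at 40 sequences over a 4-kb
  genome — sizes chosen so the full suite exercises every stage at the
  study's sample sizes while remaining a desk-scale computation.

## Limitations

The duplex and folding energies are a simplified nearest-neighbor model:
good for ranking and for threshold semantics, not for quantitative parity
with RNAhybrid/PITA outputs. The sharpness statistic is only informative
below total-identity clustering (see above). The conservation test treats
windows as sampling units; with overlapping windows the published test is
anti-conservative, which is exactly why the calibration here uses
non-overlapping windows. Reproducing the published Kruskal-Wallis statistic
on the deposited clam amplicons requires those sequences and their region
partition as external inputs (see the acceptance test for the expected file
layout); they are not redistributable with the package.
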