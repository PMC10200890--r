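---
title: "Methods: block-level karyotype evolution, ploidy inference and introgression statistics"
author: "karyoploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-level karyotype evolution, ploidy inference and introgression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoploid)
```

# Scope

`karyoploid` implements the computational core of a comparative-cytogenomic
analysis of a hypotetraploid crucifer genome: (i) a genomic-block karyotype
model with the rearrangement operators that shape post-polyploid genomes,
plus a bounded parsimony search for minimal rearrangement scenarios; (ii)
ploidy inference from biallelic allele-frequency distributions; (iii)
Patterson's D statistic (ABBA-BABA) with block-jackknife significance; and
(iv) cluster-wise SNP partitioning. Every stage is paired with a seeded
synthetic-data generator so the whole pipeline is testable without any
sequencing download.

# The karyotype model

## Representation

Crucifer comparative chromosome painting resolves chromosomes into 22
conserved genomic blocks (labels A-X, with K-L and M-N atomic units) of the
Ancestral Crucifer Karyotype (ACK, n = 8, chromosomes AK1-AK8). A
`Chromosome` is an ordered, oriented run of sub-block segments — each a
fraction interval of an ancestral block, with a strand and a homeolog copy
index — and exactly one active centromere between two segments. A
`Karyotype` stores the gametic complement (n); every diploid number the
package reports is 2 x complement size, matching the way 2n = 32 and
2n = 30 are quoted for the tetraploid and hypotetraploid states.

Conventions that a painted-karyotype description leaves open, fixed here
once:

* **Arm assignments.** The block-to-arm table of AK1-AK8 ships as a
  user-overridable TSV (`ack_karyotype.tsv`). For AK7 the upper arm is taken
  as S,T (centromere between T and U); the alternative S | T,U placement
  yields the same fusion chromosome after centromere elimination and can be
  supplied through the override file.
* **Sub-block labels.** Derived labels (Fa, Fb, Fc, ...) are not stored; they
  are a function of the cut points observed in each (block, homeolog copy)
  across the karyotype, lettered in ancestral coordinate order independently
  per copy. Breakpoint fractions default to 0.5 of the cut segment and never
  affect label-level equality.
* **Reversal invariance.** A chromosome equals its full reversal. Canonical
  forms take the lexicographically smaller of the forward and
  reversed-flipped token readings; karyotype equality compares canonical
  multisets. The default comparison is copy-blind, because painting cannot
  phase homeolog copies.
* **Coalescing.** Two abutting fragments of the same block copy read in the
  same direction are indistinguishable from the intact block and are merged
  in the stored form (the centromere boundary blocks merging). This makes
  the pericentric inversion an involution at the object level.
* **Distal exchange.** The reciprocal translocation exchanges the fragments
  distal to the centromeres ("distal" in the standard cytogenetic sense).
  For any breakpoint pair this is the unique eucentric rejoining, so
  products are validated (exactly one centromere each) but the pairing is
  never ambiguous; swapping the two breakpoints is a no-op. The unequal
  translocation is the limiting case whose second breakpoint sits at a
  subtelomeric terminus.
* **Centromere fate in fusions.** An end-to-end translocation (EET) joins
  two whole chromosomes at named termini; the dicentric is resolved by
  eliminating the centromere not named in `keep`, recorded as a history
  note. No neocentromere support. A cut falling exactly at the centromere
  boundary leaves the centromere on the tail side unless `cenToHead` says
  otherwise.
* **Single-segment toys.** Because the centromere sits between two segments,
  the smallest representable chromosome has two segments; toy fixtures in
  the tests use two-segment chromosomes.

The packaged scenario (WGD; EET of the AK5/AK7 homeolog-b copies keeping the
AK5 centromere; a reciprocal translocation with AK3b; two pericentric
inversions; an unequal translocation onto AK6b) replays to the 15-chromosome
karyotype with all 22 blocks in two copies, 44 block placements, and six of
the 16 post-WGD chromosomes structurally changed. Megabase sizes and the
gene-interval breakpoint positions are carried as free-text annotations
only, never computed. A discussion-section sentence counts "five
rearrangements" after the fusion while enumerating four; the packaged
scenario follows the results-section enumeration (four post-EET events) and
the discrepancy is documented rather than resolved. The single
population-private inversion of Cp13 ships as an optional one-event scenario
(`population20Inversion()`), outside the canonical scenario.

# Parsimony search

The original reconstruction is by expert inspection; `searchScenarios()`
formalises it as bounded search. Design choices, in decreasing order of
consequence:

* **Target-implied breakpoints.** Search breakpoints are restricted to
  segment boundaries plus the interior cut points visible in the target
  (`impliedBreakpoints()`): a minimal scenario reaching the target can only
  cut where the target shows a cut. Both karyotypes are refined by this cut
  set up front, reducing every operation to whole-token granularity.
* **Adjacency-guided moves.** Each candidate event must create at least one
  *missing target adjacency* — a consecutive token pair (the pair flanking a
  centromere forms a single bridging unit, since centromeres carry no
  identity of their own) present in the target and absent from the current
  state. Move generation scans token occurrences, so branching scales with
  the number of missing adjacencies rather than with all breakpoint pairs.
  This is the search's core assumption: a minimal scenario in which some
  event creates only adjacencies that are later destroyed again would be
  missed. Such scenarios require a later event to cut exactly at a junction
  formed earlier and are not observed in practice at small depths; the
  limitation is stated rather than hidden.
* **Admissible pruning.** Every operator creates at most two adjacency
  units, so ceil(missing / 2) lower-bounds the remaining distance; combined
  with the fact that only EET changes the chromosome count (no fission
  operator exists), states needing more events than the remaining depth are
  cut. Iterative deepening returns the first depth with solutions, i.e. the
  minimal guided-reachable distance.
* **Deduplication.** States are memoised by canonical form; a state reached
  again at the same or greater depth is not re-expanded. Returned scenarios
  are therefore deduplicated up to operand symmetry and up to the order of
  events passing through identical intermediate karyotypes; all remaining
  minimal scenarios are returned sorted by serialised form, and no single
  "true" history is claimed.
* **WGD is never searched.** Ploidy change is observed, not inferred; it
  enters scenarios only as an explicit prefix.

Soundness is checked by converting every token-level solution back into
model events and replaying it. On this machine the full search from the
post-WGD complement to the painted karyotype (depth 5) expands about 7000
states in under half a minute.

# Ploidy inference

Alternate-allele frequencies of biallelic SNPs in (0,1) are modelled as
one-dimensional Gaussian mixtures. Fixed models represent the *ideal*
distribution of a ploidy level: means pinned at the dosage expectations
(1/2; 1/3, 2/3; 1/4, 1/2, 3/4) **with uniform dosage-class weights**, only
the per-component standard deviations fitted (floor 1e-3; EM tolerance 1e-8,
at most 500 iterations; deterministic initialisation, so fits are
reproducible without a seed). The free model fits means, weights and
standard deviations of three components. The delta log-likelihood (free
minus fixed) is smallest for the ploidy whose ideal distribution the data
match. Freeing the fixed models' weights would let the tetraploid model —
whose mean set contains 1/2 — collapse onto diploid data and always undercut
the diploid model's delta; pinning the weights is what makes the lowest-delta
rule identify the generating ploidy across all three levels, and it also
defines the "ideal histogram" that the histogram criterion compares against.

The four decision criteria of `callPloidy()`:

1. *Histogram shape* — operationalised as the delta-logL candidate also
   maximising the histogram R-squared (the visual comparison itself is
   served by `plotAlleleFrequencyHistogram()`; no automatic shape classifier
   is invented).
2. *Lowest delta log-likelihood* across the three fixed models.
3. *Histogram fit quality* of the candidate: ordinary least squares of
   empirical on expected bin heights (30 equal bins on (0,1); expectations
   integrated per bin from the fitted fixed model) must show a positive
   slope and R-squared at or above 0.8 (default).
4. *Median allele ratio* (per-site max/min read count; scale-free) within
   the limits set by the lowest and highest medians of known-ploidy
   reference samples.

A call is made only when criteria 2 and 4 agree (candidate matches the
reference ploidy and the median falls inside the limits, or both point away
from the reference ploidy); otherwise the sample is `ambiguous`.

Default site filters — coverage at least 10 and minor-allele read count at
least 2 (which also removes sites monoallelic in-sample) — are package
choices; the published workflow does not state its thresholds. Every
filtered count is logged. The optional uniform-noise mixture component
(off by default) mirrors the published tool's denoising step.

# ABBA-BABA

For a quartet (((P1, P2), P3), O) the outgroup defines the ancestral state
per site. Binary mode (default; one haplotype per taxon, matching a
consensus-supercontig alignment) scores a site 1 for ABBA when (P1, P2, P3)
read (A, B, B) and for BABA when (B, A, B); frequency mode contributes
(1 − p1) p2 p3 and p1 (1 − p2) p3 with derived-allele frequencies,
polarised by the outgroup major allele. Sites the outgroup cannot polarise
are skipped and counted. D = (nABBA − nBABA) / (nABBA + nBABA); a zero
denominator yields a flagged NA rather than an error, so batch runs never
stop.

Significance uses a delete-one block jackknife over contiguous site blocks
(default 2000 sites, approximating per-locus linkage blocks in
target-enrichment data; at least 20 non-empty blocks are required),
SE from the jackknife variance, Z = D/SE and a one-sided normal p-value;
the significance rule is p < 0.01 and Z > 3. A constant D across blocks is
flagged as infinite Z. The study's printed D values (e.g. D > 0.315,
Z > 6.07 in the ingroup trios showing gene flow) depend on the full
deposited Hyb-Seq data and are context, not desk-reproducible targets.

# SNP partitioning

Given per-sample alternate-allele presence and a sample-to-cluster table
(assignments are inputs; no clustering is performed here, and samples with
more than 10% admixture are excluded as admixed), `partitionSnps()`
subsamples an equal number of samples per cluster — seeded from each
cluster's member set, so relabeling clusters permutes the result without
changing it — removes singletons, and classifies each SNP by the set of
clusters carrying it. "Singleton" is read as: alternate allele observed in
exactly one sample of the analysis set. With more than two clusters, SNPs
present in several but not all clusters form a mixed residual category
(empty at two clusters). Cluster membership of a SNP is presence-based (at
least one carrier in the subsample); frequency thresholds are deliberately
not imposed. `placeOnBlocks()` places genes carrying cluster-specific SNPs
through their genomic block onto the chromosomes carrying that block,
flagging placements on chromosomes that are rearranged relative to a
reference complement — supporting the display convention of showing SNPs
only on unrearranged chromosomes. The headline counts of the study
(56 169 shared; 9 331 and 3 738 cluster-unique SNPs) require the deposited
reads and are out of desk scope.

# Synthetic data

* **Read counts** (`simulateAlleleCounts`): depth is negative binomial
  (mean 40, dispersion 5 by default) rather than Poisson, matching the
  overdispersion of capture data; the alternate read count is binomial with
  p = (d/ploidy)(1−e) + (1 − d/ploidy)e, i.e. base error e (default 0.01)
  shrinks frequencies symmetrically. Tetraploid dosage classes default to
  0.4/0.2/0.4 for 1:3 / 2:2 / 3:1 — balanced dosages are the rarest class
  at randomly ascertained loci. These defaults are the package's study
  conditions for all ploidy tests.
* **Quartet sites** (`simulateQuartetSnps`): a site-pattern multinomial,
  not a coalescent. With probability g (default 0.3) a site is informative
  and is ABBA with probability (b + γ)/(2b + γ), BABA with b/(2b + γ)
  (b default 0.1); hence the closed form E[D] = γ/(2b + γ) recorded in the
  truth record. This suffices to calibrate D and its jackknife; it does not
  emulate linkage, so the jackknife's robustness to linked sites is not
  exercised by the generator.
* **Cluster genotypes** (`makeClusterGenotypes`): constructs exactly the
  requested shared/unique/singleton counts (unique SNPs get at least two
  carriers so they survive singleton filtering); `partitionSnps` recovers
  the construction exactly when subsampling uses whole clusters.
* **Random scenarios** (`randomScenario`): k valid random events with
  rejection sampling (invalid or no-op events are redrawn), for search
  recovery tests.

All generators are byte-deterministic under their seed. What passing tests
show about real data is limited by what the generators emulate: no mapping
bias, no allele-specific error, no linkage, no reference bias in the
frequency distributions — the statistical shapes are right, the artefact
structure of real capture data is not.

# Problem sizes and runtimes

The test suite uses the sizes at which the methods' claims are stated:
5000 sites at mean depth 40 with 20 replicates per ploidy for model
recovery; 40 replicates of 20 000 sites for the null calibration of D;
depth-5 search against the painted karyotype plus 50 seeded random-scenario
recoveries at k ≤ 3; ten seeded partition configurations. These are the
package's chosen study conditions; each completes in seconds to a few
minutes on a single CPU.

# Known limitations

* The search's adjacency-guided completeness caveat (above).
* Gaussian components approximate binomially sampled frequencies; at low
  depth the approximation coarsens, which is why coverage filtering
  precedes fitting.
* Block-level karyotypes carry no physical coordinates: megabase sizes and
  gene-level breakpoints remain annotations, and rDNA loci are not
  modelled.
* Homeolog copy indices are bookkeeping; no phasing is claimed, and all
  fixture comparisons are copy-blind.
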