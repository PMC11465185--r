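---
title: "Screening, dereplication and spatiotemporal dynamics of lake giant-virus MAGs"
author: "stratovir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, dereplication and spatiotemporal dynamics of lake giant-virus MAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratovir)
```

## The scientific problem

Giant viruses (phyla *Nucleocytoviricota* and *Mirusviricota*) are large DNA
viruses that infect microbial eukaryotes and shape plankton dynamics. In a
deep monomictic lake the water column stratifies thermally for part of the
year into a sunlit epilimnion and a dark hypolimnion, and microbial
communities partition between the two layers. Genome-resolved metagenomics
of such a system asks, in order:

1. Which assembled sequences and bins are giant-virus genomes (and which
   are fragmented cellular genomes masquerading as bins)?
2. How good are the genomes (contiguity, completeness, complete linear
   genomes with terminal inverted repeats)?
3. Which genomes are the same species, and how much of the in-lake virus
   diversity does the catalogue capture?
4. How do the species distribute over depth and season — which are
   epilimnion specialists, hypolimnion specialists, or generalists, and how
   persistent is each group?

`stratovir` implements this workflow as small composable functions, and
ships a synthetic lake-community generator with planted ground truth so
every stage can be exercised and tested end to end without any sequencing
data. The `analysis/` directory of the source repository runs the stages in
order as a narrative.

## Screening rules

A bin or contig is a giant-virus candidate when it exceeds **50 kb** and
shows a virus signal: at least one of the seven nucleocytovirus marker
genes (MCP, PolB, TFIIB, TopoII, A32, SFII, VLTF3), or — for mirusviruses —
an HK97-fold major capsid protein hit with bit score **> 100**
(`is_gv_candidate()`). Bins with CheckM-style completeness **> 15**
(bacterial) or **> 20** (archaeal) are excluded as prokaryotes
(`exclude_prokaryote()`); both cutoffs are strict inequalities.

Nucleocytovirus identity is confirmed with a core-gene density index
(`core_gene_density()`): the number of *distinct* core genes (of a panel of
20) per 100 kb of genome. The index itself is only cited, not defined, in
the study this package reconstructs, so the implementation here is a
documented proxy: density = distinct core genes / (length / 100 kb), with a
configurable acceptance cutoff defaulting to 0.5. The rationale is that
viral genomes are marker-dense, while megabase-scale cellular sequences
collect only sporadic spurious hits, so any cutoff of this order separates
the two cleanly; the exact value matters little and is exposed as a
parameter.

Marker hits enter the package as *tables* (sequence id, gene, bit score),
never as raw HMM searches: profile searches are external tools, and all
downstream decisions consume their tabular output.

## Quality metrics

`quality_summary()` reports the completeness tier ("high" strictly above
90% completeness; "medium" at or above 50%, following MIMAG convention for
the boundary the study leaves undefined; otherwise "low"), the N50, the
contig count and the number of distinct nucleocytovirus markers (of 7).
`find_tir()` scans a single-contig genome for a terminal inverted repeat —
a genome prefix whose reverse complement matches the same-length suffix —
the signature of a complete linear genome. The scan exploits the fact that
prefix position $i$ always pairs with the complement of position
$n + 1 - i$, so one mismatch profile serves every candidate repeat length;
an exhaustive quadratic oracle confirms it in the tests. Defaults: minimum
length 20 bp, search window 5 kb, mismatch fraction at most 0.05, strict
ACGT alphabet, 0-based half-open coordinates.

`poa90()` is the share of per-protein alignment coverages at or above 0.90,
a proxy for unpolished indel errors. Like the density index, the original
metric is defined in an external reference; this package accepts the
per-gene coverage list (or a precomputed table) and documents the
operationalization, leaving ORF prediction and the reference search out of
scope. `fragmentation_compare()` contrasts any per-genome metric between
two catalogues with medians and a two-sided Mann–Whitney U test; the study
reports fragmentation p-values without naming a test, and Mann–Whitney is
the standard choice for skewed count metrics such as contigs per genome.

## Dereplication and diversity capture

`cluster_species()` collapses genomes to species at **ANI ≥ 95%** by greedy
centroid clustering over a supplied ANI table: genomes are visited in
decreasing quality score (default `completeness + 10·log10(N50)`,
dRep-inspired), each joins the first representative at or above the
threshold, otherwise founds a cluster. This replaces dRep's two-stage
Mash/ANIm machinery deliberately: the ANI table, not the estimator, carries
the decision rule, and sparse tables are allowed (missing pairs mean
"below threshold"). Representatives get four-digit serial IDs ordered by
maximum per-sample coverage (`assign_serial_ids()`; ties break
lexicographically).

Diversity capture asks what fraction of assembly-wide polB representatives
(polB is single-copy and universal in nucleocytoviruses) is present in the
MAG catalogue. A representative is captured when some MAG polB matches it
at the operational species boundary — identity **> 96%** over **> 60%** of
the shorter sequence, both strict (`species_match()`). Identities come from
a precomputed alignment table or from the built-in exact Needleman–Wunsch
aligner (match +1, mismatch −1, gap −2; identity = matches / alignment
columns), which is intended for fixture-scale sequences only — genome-scale
search (blastn, fastANI) stays out of scope.

## Abundance and community structure

RPKM is reads / (genome kb × million mapped reads) (`rpkm()`,
`rpkm_matrix()`). A toy k-mer-seeded ungapped mapper (`toy_map_reads()`)
exists so end-to-end fixture tests can exercise the mapping identity rule —
reads below **92% identity** are discarded, both strands are searched, ties
break uniformly at random under the seed — while real mapping at study
scale is an external concern; count tables are first-class inputs.

Community structure uses Bray–Curtis dissimilarity
$\mathrm{BC}(x,y) = \sum_i |x_i - y_i| \,/\, \sum_i (x_i + y_i)$
(`bray_curtis()`; defined as 0 for two all-zero profiles, logged when
triggered) and nonmetric multidimensional scaling (`nmds()`). The NMDS is
implemented directly: Kruskal stress-1 is minimized by alternating a
monotone (isotonic) regression of configuration distances on dissimilarity
ranks — ties handled by the secondary approach, tied dissimilarities
sharing one fitted value — with a Guttman-transform update of the
configuration. The first start is the classical (Torgerson) metric
solution, the remaining restarts (default 10) are random under the seed,
and a step that would increase stress is discarded, so the stress trace is
non-increasing by construction. Defaults: $k = 2$ dimensions (the study's
ordination is planar), tolerance $10^{-6}$ on the stress decrease, 500
iterations. `vegan::vegdist` serves as an independent cross-check of
Bray–Curtis in the tests, never as the implementation.

`within_layer_dispersion()` collects all within-layer pairwise
dissimilarities over the stratified months (8 stratified months give
$\binom{8}{2} = 28$ pairs per layer) and compares layers with a two-sided
Mann–Whitney test.

## Habitat preference and persistence

The habitat-preference index is
$$P_{epi} = \frac{\sum_{\text{stratified}} \mathrm{RPKM}_{epi}}
{\sum_{\text{stratified}} (\mathrm{RPKM}_{epi} + \mathrm{RPKM}_{hypo})},$$
undefined when the genome was never detected during stratification.
$P_{epi} > 0.95$ is epilimnion-specific, $P_{epi} < 0.05$
hypolimnion-specific, anything between is a generalist, and an undefined
index is "unclassified" (`p_epi()`, `classify_habitat()`). Report
denominators include unclassified genomes by default — matching the
published totals — with an explicit switch to exclude them, since the study
does not state its convention.

Persistence is the longest run of consecutive stratified months with
covered fraction **> 20%** (`persistence()`), computed for each specialist
in its own layer only (`persistence_cohort()`); generalists are excluded by
default and, when requested, are scored in their higher-RPKM layer. Group
mean persistence is compared with Welch's unequal-variance t-test
(`welch_t()`), implemented from the closed form with Welch–Satterthwaite
degrees of freedom and checked against `stats::t.test` to $10^{-10}$ in the
tests. Degenerate inputs are defined explicitly: two zero-variance groups
with equal means give $p = 1$; unequal means give an underflow-safe
minimal $p$.

`gene_sharing_partition()` implements the annotation-sharing bookkeeping
across habitat classes. "Shared" is deliberately isolated in one function
because its natural-language definition is ambiguous: here it means terms
present both in at least one specialist class and in the generalist class,
while "exclusive to class L" means present in L and absent from every other
class. `summary_percentages()` reproduces the catalogue report arithmetic
with half-up rounding to one decimal — base `round()` rounds half to even,
which would mis-round some printed values.

## The synthetic community

`community_config()` encodes the study design: 12 monthly samples
(May–April) at 2 depths (24 samples), stratification May–December, and
three virus guilds plus cellular decoys. Defaults: 60 epilimnion
specialists, 30 hypolimnion specialists, 30 generalists, 6 decoys;
epilimnion peaks last 2 months; hypolimnion specialists occupy each
stratified month with probability 0.95; lognormal multiplicative noise with
sdlog 0.5 (the field reports no abundance distribution for these viruses;
lognormal is the conventional assumption for microbial abundances and is
flagged as such); 2×10⁵ reads of 150 bp per sample; virus genomes 80–250
kb, decoys 300–600 kb; 8% mirusviruses.

The guild templates are sharp: epilimnion specialists get one contiguous
epilimnion peak during stratification and are absent from the stratified
hypolimnion (and vice versa), generalists sit in both layers. During the
four mixing months each layer moves linearly toward the mean of the two
layers' last stratified values, reaching the fully mixed state in the
second mixing month — the study observes well-mixed communities in the
second month after overturn begins. Read counts are Poisson with mean
proportional to abundance × genome length (normalized per sample);
overdispersion, when wanted, comes from the lognormal abundance noise —
the Poisson choice keeps the count model analytically checkable. Covered
fraction uses the Lander–Waterman approximation $1 - e^{-d}$ from the mean
depth $d$.

What the generator does *not* emulate — realistic sequence evolution,
indels, read errors, assembly artefacts, shared k-mer content between
genomes, uneven coverage — bounds what the passing tests demonstrate: they
validate the decision rules, statistics and their wiring, not robustness to
messy real assemblies. On the template side the separation is intentionally
ideal (a specialist's off-layer stratified abundance is exactly zero), so
near-perfect label recovery is the designed property being verified, not an
empirical discovery about real lakes.

## Numerical choices and degenerate inputs

* All thresholds are strict inequalities exactly where the published rules
  print them as strict (">50 kb", ">0.95", ">20%", ">96%", ">15/>20").
* Sequence alphabet is strict uppercase ACGT; anything else errors.
* Coordinates are 0-based half-open.
* Ties: serial IDs and clustering visit order break ties lexicographically;
  the toy mapper breaks identity ties uniformly at random under the seed;
  the NMDS monotone regression uses the secondary (tie-averaging) approach.
* Empty inputs are distinguished from zero: POA90 of an empty coverage list
  is missing, not 0; an empty MAG polB set gives capture 0 with a warning;
  an all-zero dissimilarity matrix embeds at stress 0.
* Every stochastic function takes a seed and restores the caller's RNG
  state; identical configuration and seed give byte-identical outputs.

## Problem sizes

The test-suite and acceptance runs use the default 120-virus community
(24 samples), exhaustive oracle sweeps over all contig multisets of size
≤ 8, all binary occupancy series of length ≤ 12, TIR scans on sequences
≤ 5 kb, and 100-pair oracle comparisons for the statistical kernels —
sizes at which the independent brute-force oracles are exact and fast.

## Known limitations

* The core-gene density index and POA90 are documented proxies for metrics
  defined in external references; their cutoffs are configurable.
* The toy aligner and toy mapper are quadratic/linear-scan tools for
  fixture-scale data; genome-scale homology search is out of scope.
* The greedy ANI clustering consumes a provided ANI table; it does not
  estimate ANI from sequence.
* Real-data idiosyncrasies (months with zero mapped reads, partially
  covered genomes near the 20% boundary) are handled by the stated rules
  but not calibrated against real mapping output.
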