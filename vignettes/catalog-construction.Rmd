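---
title: "Constructing and evaluating species-level genome catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and evaluating species-level genome catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catforge)
options(catforge.verbose = FALSE)
```

## The problem

Shotgun metagenomics of a gut community yields thousands of
metagenome-assembled genomes (MAGs) of uneven quality, many of them
near-duplicates of one another. Turning that pile into a *reference
catalog* — one representative genome per bacterial species, with the
redundant conspecific genomes identified and the species delineated at
the conventional 95% average nucleotide identity (ANI) boundary — is the
foundation for everything downstream: taxonomic profiling, pangenome
analysis, and cross-host functional comparison. `catforge` implements
that catalog construction end to end at desk scale, together with the
evaluation machinery used to judge taxonomic profilers against a catalog
and the statistics used to compare two catalogs functionally.

## Quality gating

MAG quality is consumed, not estimated: completeness and contamination
come from an upstream assessment tool, the clade separation score (CSS,
a chimerism indicator) from another. The gates are:

* **MQ** (medium quality): completeness ≥ 50%, contamination ≤ 5%;
* **NC** (near complete): completeness ≥ 90%, contamination ≤ 5%;
* **CSS**: genomes with CSS strictly greater than 0.45 are excluded.

All boundaries are inclusive at the stated value; only the CSS rule is
strictly-greater, because the convention for that score excludes only
values *above* its default cutoff. Genomes missing a CSS are dropped
with a warning by default — a catalog of only chimerism-screened genomes
is the safer default — with `missing = "keep"` available.

## The intactness score

Within a species cluster the representative genome maximizes

$$S = \text{completeness} - 5 \times \text{contamination} + 0.5 \times f(N50).$$

Taken literally with $f$ the identity, the N50 term (tens of kilobases
and up) swamps the two quality terms (at most 100), reducing the score
to an assembly-contiguity contest. The package therefore defaults to
$f = \log_{10}$, the convention of widely used dereplication tools,
which keeps the three terms on comparable scales; `transform =
"identity"` restores the literal form. Ties are broken by the
lexicographically smaller genome id so selection is deterministic.

## Two-tier species clustering

Computing alignment-based ANI for all genome pairs is quadratic and
wasteful; almost all pairs are obviously different species. The pipeline
therefore clusters in two tiers:

1. **Preliminary.** Genomes are partitioned by their taxonomic order
   (genomes without an order form singleton groups and can never merge
   here). Within each order, MinHash sketches (k = 21, sketch size
   10,000, canonical k-mers, seeded 64-bit hashing) give Mash-style
   distances $d = -\tfrac1k \ln\frac{2j}{1+j}$, and average-linkage
   clusters are cut at d = 0.2.
2. **Secondary.** Within each preliminary cluster, fragment-based ANI is
   computed for every pair: the smaller genome is cut into 1 kb
   fragments (tails dropped), each fragment is seeded by exact 15-mers
   into the larger genome and aligned with a banded gapped alignment;
   per-fragment identity is matching bases over aligned non-gap columns,
   fragments at identity ≥ 0.8 count as matched, ANI is the mean matched
   identity, and coverage the matched fraction of fragments. Pairs with
   coverage < 0.6 (or no measurable ANI) get the maximal distance —
   local-alignment ANI over a sliver of a genome says nothing about
   species identity. Average-linkage trees on $1 - \text{ANI}/100$ are
   cut at 0.05, so the 95% ANI species boundary maps exactly onto the
   cut height.

The two tiers refine independently: the order gate forbids a global
re-merge across preliminary clusters, which matches the two-tier design
and keeps the procedure deterministic. Whether the secondary pass should
use average or single linkage is genuinely open; average linkage is used
for consistency with the preliminary tier.

Defining per-fragment identity over aligned non-gap columns (rather than
over fragment length) has a useful consequence: for genomes diverged by
point substitutions at rate $r$ plus a small indel component, measured
ANI converges to $100(1-r)$ exactly, which is what makes the parameter
recovery tests sharp.

**Conspecific dereplication.** Within a species cluster, members are
re-clustered at 99.9% ANI with a coverage floor of 0.81 and one genome
per subcluster (the intactness argmax) is kept as non-redundant. The
0.81 is not arbitrary: two NC genomes each at least 90% complete can
share at most ~0.9 × 0.9 of their content, so the floor is recomputed as
the squared NC completeness fraction if the NC threshold is
reconfigured.

## Marker-gene selection

Species-specific marker genes enable marker-based profiling. Selection
proceeds in two stages over per-species pangenome matrices (gene-family
presence/absence and copy counts across conspecific genomes):

* **Candidates.** Keep families with protein length 150–1500 aa, mean
  copies per containing genome < 1.5 (paralog guard), coreness ≥ 0.5
  for species with more than 100 conspecific genomes and ≥ 0.6
  otherwise, and uniqueness ≤ 10 species; at most 800 per species. For
  a single-genome species every family is trivially core. The ranking
  before the 800 cap (uniqueness ascending, coreness descending, length
  descending, family id) is this package's choice; only the cap itself
  is canonical.
* **Refinement.** Candidate genes are fragmented into consecutive
  150 bp segments (tails dropped) and remapped against every genome at
  ≥ 95% identity over the full fragment on either strand (ungapped
  near-exact matching by pigeonhole seeding: with at most 7 mismatches
  over 150 bp, one of 8 equal chunks must be exact). A genome counts as
  containing the gene when at least half of the gene's fragments hit
  it — robust to one diverged fragment. Remapped coreness must reach
  0.6 and remapped uniqueness must be exactly 1 (for species with more
  than 100 conspecific genomes, another species counts against
  uniqueness only when more than 1% of its genomes are hit). The 200
  longest surviving genes per species form the marker set; ordering by
  length with family-id tie-break is total, so exports are
  deterministic.

Whether mean copies should average over containing genomes or all
conspecific genomes is ambiguous; containing genomes is implemented
(the alternative only weakens the paralog guard for accessory genes).
Final-stage coreness is recomputed from fragment hits rather than
carried over from stage one.

## Profiling evaluation

DNA-based profilers assign reads in proportion to genome size as well as
abundance, so raw read counts overstate large-genome species.
Genome-size normalization divides counts by representative genome length
before renormalizing: $a_i = (r_i/L_i)/\sum_j (r_j/L_j)$. The read
simulator deliberately draws reads with probability ∝ abundance ×
length, so normalization is *required* to recover planted truth — the
tests close that loop at $10^5$ reads within ±2%.

Presence is strict (`abundance > 1e-6`), prevalence surveys drop samples
below 100 Mbp, and profiles are compared by recall, precision and
Bray-Curtis similarity $1 - \tfrac12\sum_i |p_i - q_i|$ over the union
of species (the species universe for the metric is a package choice).
The centered log-ratio transform uses a configurable pseudocount
(default $10^{-9}$) when zeros are present.

The benchmark designs are pure combinatorics and are enumerated, not
simulated: 3 community sizes (40, 150, 600 genomes) × 3
genome-selection strategies (representative / one random conspecific per
species / five random conspecifics per species, species count = size/5)
× 3 replicates = 27 samples, and 10 samples × 8 read-pair depths
(0.5–125 million pairs at 300 bp per pair, 150 Mbp–37.5 Gbp) = 80
datasets. Community sizes count genomes (not species) under the
five-per-species strategy, which is why those sizes must divide by 5.

## Functional comparison

Between two catalogs, per-term enrichment uses the two-sided Fisher
exact test computed by direct hypergeometric enumeration, with
Bonferroni correction over the terms actually tested (present in at
least one species of either group). The reported effect sizes are the
sample odds ratio and the log2 fold change of carrier proportions with a
shift of $1/(2 \times \text{group size})$ per group to avoid logs of
zero; raw proportions are reported alongside. Taxonomic homogeneity of
GO-profile clusters is size-weighted purity (the modal-label fraction),
the simplest metric consistent with "label consistency within clusters";
no GO-graph ancestor propagation is performed before Jaccard distances
are taken, and the Jaccard distance of two empty annotation sets is 0 by
convention so unannotated genomes cluster together rather than error.

## The synthetic-data generator

The generator plants truth at every level: species (independent random
ancestors, conspecific genomes evolved at half the target within-species
divergence so pairwise ANI lands on target), pangenome architecture
(unique-core families at 95% presence in exactly one species, shared
families split with ring-neighbouring species, accessory families below
50% presence, optional two-copy paralogs), communities (equal-abundance
designs) and reads (length-weighted sampling, uniform positions, either
strand, optional substitution errors). Everything is deterministic under
a seed and emits truth tables alongside the data.

What it does **not** emulate: real base-composition and repeat
structure, strain-level microdiversity gradients, quality-score-shaped
error profiles, incomplete assemblies (completeness and contamination
are assigned metadata by default, not physically simulated truncations),
and horizontal transfer. Passing tests therefore demonstrate
correctness of the algorithms under clean planted conditions, not
robustness to every pathology of real MAGs.

## Numerical choices and problem sizes

* Missing or coverage-gated ANI comparisons become maximal distance
  (never merge), and cluster numbering follows the smallest
  lexicographic member id, so clustering is invariant to input order.
* The indel component of the evolver defaults to one tenth of the
  substitution rate, keeping the ANI ↔ substitution-rate mapping
  simple.
* The test suite runs the full pipeline on 30 genomes in 3 planted
  species of 20 kb (adjusted Rand index 1 required), marker recovery on
  5 species × 20 genomes with 50/20/30 unique-core/shared/accessory
  families, evolver recovery on 50 kb genomes across targets
  {90, 95, 99, 99.9}% × 20 seeds (±0.5 tolerance), and normalization
  closure at $10^5$ reads. These sizes make the planted signals several
  standard errors wider than the asserted tolerances.

## Limitations

Fragment ANI approximates alignment-tool ANI by best-hit fragment
identity; it is validated against planted mutation rates, not against
any particular aligner's output. MinHash accuracy declines for genomes
with low mutual coverage, and no correction is applied. The greedy
identity clusterer is a fixture-scale stand-in, not a replacement for
linear-time clustering at catalog scale. Archaeal marker sets,
phylogenetic placement, and profiler execution are all out of scope:
the package consumes upstream quality scores and annotation tables and
exports marker databases and normalized profiles.
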