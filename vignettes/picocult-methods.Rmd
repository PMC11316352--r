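---
title: "Methods: culture genomics of non-axenic picocyanobacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: culture genomics of non-axenic picocyanobacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Freshwater picocyanobacteria (*Synechococcus*/*Cyanobium*, subclusters
SC5.2 and SC5.3) are usually isolated as *non-axenic* cultures: the
phototroph grows together with heterotrophic bacteria that persist in media
without any added carbon source. Shotgun sequencing of such a culture
therefore yields a small metagenome. Turning a collection of these cultures
into genome-resolved biology requires a chain of decisions — which contigs
belong to which organism, which genomes are "the same" population, which
organisms are genuinely present in which culture, which co-occurrences
repeat often enough to suggest symbiosis, and which gene repertoires
separate the ecotypes. `picocult` implements that chain as small, testable
operations with explicit boundary semantics.

# Bin decontamination

Per-gene class-level taxonomy calls are consumed as a table (gene
prediction and homology search are upstream tools and out of scope). The
bin consensus is the plurality class over all classified genes, computed
once on the full bin; ties break lexicographically so results are
deterministic. A contig is removed when

* strictly more than 30% of its genes are off-target (`no_hit`,
  `eukaryote`, `virus`), or
* the plurality class of its own classified genes disagrees with the bin
  consensus.

A contig with zero classified genes cannot "disagree" — disagreement is
undefined without a class — so it is judged by the fraction rule alone.
Both filters are applied in one pass against the pre-removal consensus (the
procedure describes a single removal step, not an iteration); the
single-pass rule is idempotent on its own output, which the test-suite
checks. The quality gate is inclusive on both printed comparators:
completeness ≥ 80%, contamination ≤ 5%.

# Fragment ANI and population structure

No specific ANI algorithm is prescribed by convention at these scales, so
the package defines a deterministic, oracle-checkable estimator:

* the query is cut into non-overlapping 1000 bp fragments (trailing partial
  fragment dropped);
* each fragment is placed on the reference (either strand) by exact 16-mer
  seeding followed by ungapped extension over the full fragment; identity is
  `matches / fragment_length` at the best placement;
* fragments with identity ≥ 0.80 count as aligned; the directed ANI is the
  mean identity of aligned fragments, reported missing when the aligned
  fraction falls below 0.20;
* the two directions are symmetrized by arithmetic mean, giving the single
  symmetric matrix clustering needs.

Because the synthetic mutator introduces substitutions only, the realized
identity of a simulated pair is known exactly from the returned position
list, and the estimator can be validated against it to ±0.005 at 100 kb.
One boundary effect is worth knowing: when the true identity sits *at* the
0.80 fragment cutoff, the "aligned" condition truncates the lower half of
the fragment-identity distribution and biases the mean upward by about
+0.01 (exactly computable from the binomial fragment distribution). The
estimator is still within a 0.01 tolerance in the tested configurations,
but estimates at the aligned-fraction boundary should be read with that
bias in mind.

Clustering at a cutoff is single linkage: pairs at or above the cutoff are
edges and clusters are connected components, so chains merge by transitive
closure — the reproducible reading of "a cutoff", and the reason partitions
at 85% (population boundaries) are always coarsenings of partitions at 95%
(species). A greedy-centroid alternative is available behind
`cluster_at(..., method = "greedy")`. Heatmap ordering uses average-linkage
leaf order on `1 - ANI`, a deterministic stand-in for ordering by a
phylogenomic tree (tree inference stays with external tools).

# Read recruitment and presence

Reads are mapped by exact 15-mer seeding on both strands plus ungapped
extension, clipped at genome ends; an alignment is kept iff identity
≥ 0.95, aligned length / read length ≥ 0.90 and aligned length ≥ 50 bp; at
most one alignment per read is retained (best identity, ties to the
leftmost placement, plus strand first). Identity is computed over the
extended ungapped alignment — the synthetic reads carry substitutions only,
which keeps the accounting exact and lets a brute-force all-position
exact-match scan (via `Biostrings` `matchPDict`) serve as an independent
oracle for error-free reads.

rRNA intervals are inputs (BED dialect, 0-based half-open, consistent with
all coordinates in the package); masked positions become `N`, which removes
them from seeding (no k-mer containing `N` is indexed), from the breadth
numerator and from the effective genome length.

Coverage bookkeeping: `depth = aligned_bases / effective_length`,
`breadth` = fraction of unmasked positions covered at least once, and
`coverage_per_gb = depth / (total sampled bases / 1e9)` — the per-Gb
normalization is stated here because no closed formula is conventional; it
is invariant to duplicating the read set while doubling the sampled bases.
"Genome coverage above 95%" is interpreted as *breadth*, strictly greater
than 0.95: mean depth above 95% is not a presence criterion, breadth is the
standard reading. Subsampling keeps the first `n` of a seeded random
permutation (exactly `n` reads without replacement, deterministic per
seed).

# Co-occurrence

The prevalence filter retains genomes present in strictly more than 5% of
the cultures; the denominator is all cultures with sequencing data. In the
simulated study the filter is applied to the heterotroph genomes — the
symbiont candidates — because each culture's picocyanobacterium is a
per-culture resident, not a candidate symbiont. Counting is culture-level
throughout: a taxon present as two genomes in one culture counts once.
Heat-tree rows aggregate counts upward through the lineage as unions of the
contributing culture sets, so a parent taxon's count is at least each
child's but can be less than their sum. The aggregation needs the per-taxon
culture sets, so `heat_tree_table()` takes the presence matrix plus the
taxonomy rather than a pre-collapsed count table. No null model is offered:
the upstream analysis asserts non-randomness without a test, and this
package exposes prevalence only.

# Marker panels, pigmentation, ordination

The default panel groups the genes that separate the ecotypes: nitrogen
assimilation (narB, nirA, nrtABC, amt, urtA), assimilatory sulfate
reduction (cysDNC, cysH, sir), ROS detoxification (katE, sod1),
phycoerythrin (cpeA/cpeB), pili-mediated chemotaxis (pilA, cheB, cheR),
trehalose biosynthesis (treS, otsA, otsB) and lactone degradation (mlhB).
KO-identifier mapping is configurable (the panel asset encodes gene names).

A strain is called red iff both cpeA *and* cpeB are present — pigmentation
is attributed to the complete phycoerythrin operon, so a single subunit
does not make a red call.

"Selective presence" is formalized as: present in ≥ 80% of focal-ecotype
genomes and ≤ 20% of the genomes of *each* other ecotype. The 0.8/0.2
thresholds are this package's choice and are recorded in output headers.

The gene-content ordination uses Jaccard distance on binarized profiles and
classical PCoA instead of NMDS: NMDS stress optimization is stochastic and
the ordination is used only descriptively, while PCoA is deterministic once
each axis's sign is fixed (largest-magnitude loading positive).

# CRISPR-Cas profiling

Locus tables from an external subtyping tool are consumed as input. The
adaptation module is cas1/cas2; interference gene sets are a shipped,
editable JSON schema per subtype (I-E, I-G, III-B) because cas gene
nomenclature is contested and must not be hard-coded. Low-quality gene
matches count towards completeness but stay flagged — they are displayed,
not discarded. A locus lacking cas1 but holding at least one spacer is
flagged `cas1_less_with_spacers`, the signature of a decaying adaptation
module in front of a maintained array. Reported percentages round half-up
to one decimal (so 27 positives of 170 genomes print 15.9%, and 11 of 27
cas1-less positives print 40.7%); raw fractions are retained alongside.

The Cas1 curation chain is: keep hits with p < 0.01 (strict) and length
> 80 aa (strict); keep the top-10 scoring neighbors per query (ties at the
k-th rank to the lexicographically smaller id); collapse at 90% identity by
greedy length-sorted clustering with bidirectional coverage ≥ 0.80.
Alignment identity is matches over alignment columns excluding terminal
gaps under global alignment (match 1, mismatch 0, gap open −11, extend −1);
the implementation delegates the alignment to `Biostrings`, and an
independent hand-rolled Needleman–Wunsch in the test-suite verifies the
identities.

# The synthetic world

The generator states a world and the tests measure it; none of its
parameters were adjusted after seeing test outcomes.

* **Genomes** are i.i.d. base draws at a requested GC (default range
  0.52–0.72, mirroring the 51.8–72.5% span of real freshwater
  picocyanobacteria). Lengths default to 25–40 kb for culture simulations
  and 100 kb for ANI fixtures — deliberately scaled down from the real
  1.9–4.2 Mb so the full suite runs in minutes on one CPU; every operation
  is length-agnostic.
* **Divergence** is substitution-only (no indels), so realized identity is
  exact from the mutated-position list, and mapping/ANI oracles are exact.
  This is the one deliberate unrealism that buys exactness.
* **Cultures** hold one picocyanobacterium (five ecotype genomes, round
  robin) plus 0–3 heterotrophs from a pool of 8: one symbiont planted in 8%
  of 100 cultures, decoys in at most 4 cultures each (≤ 4%, below the 5%
  prevalence bar). Reads are allocated multinomially by abundance × length
  (shotgun sampling), sampled from both strands, sized for ~6× member depth
  (comfortably above the 5× the recovery criterion needs; breadth at 6×
  is ≈ 1 − e⁻⁶ minus small edge effects), with 0.5% substitution errors —
  read origin is recorded in the read name for oracle tests.
* **Marker tables** plant each ecotype's diagnostic genes and add 5%
  background presence elsewhere, emulating annotation noise. The pigment
  genes are exempt from background noise: pigmentation is
  genotype-determined, a green strain simply lacks the operon. Fixtures use
  34 genomes per ecotype (a 170-genome catalogue over five ecotypes), large
  enough that 5% noise stays below the 20% contrast bar with high
  probability.
* **Bin tables** guarantee clean contigs ≥ 90% consensus-class genes;
  planted contaminants carry a requested off-target fraction or a foreign
  class.

What a green test therefore establishes: the *logic* of every rule
(boundaries, tie-breaks, aggregation), and the recovery of planted truth in
a substitution-only, repeat-free, uniform-coverage world. What it does not
establish: robustness to indels, repeats, strain mixtures, uneven coverage,
or real annotation pipelines; the ANI/mapper implementations are meant for
desk-scale validation and synthetic benchmarking, not as replacements for
production aligners on megabase genomes.

# Numerical choices and degenerate inputs

* Coordinates 0-based half-open everywhere; 1-based only inside R
  position vectors (documented per function).
* Plurality/consensus ties: lexicographic. Mapping ties: best identity,
  then leftmost start, then plus strand. Top-k ties: smaller id.
* All-off-target bins raise a no-consensus error; all-zero gene profiles
  raise a degenerate-ordination error; zero effective genome length raises
  an error; an empty read set maps to an empty table, not an error.
* Reported percentages round half **up** (`round_half_up()`), not
  half-even, matching how such tables are conventionally printed.
* Seeds: every stochastic operation takes an explicit seed; collection
  simulation derives per-culture seeds from one master seed, and fixed
  seeds give byte-identical outputs.

# Known limitations

* The ANI estimator's aligned-fraction and fragment-identity boundary
  behavior near 0.80–0.85 differs between published estimators; population
  boundaries near 85% should not be compared across tools without
  calibration.
* The prevalence filter has no null model for "non-random" co-occurrence.
* The CRISPR completeness logic is only as good as the schema asset; it
  intentionally refuses unknown subtypes instead of guessing.
* The supplementary-table consistency checks (catalogue shares, size/GC
  extrema, CRISPR prevalence recomputed from published tables) require
  those tables; offline, the recomputation functions are exercised on
  synthetic stand-ins only, and the corresponding acceptance test stays
  red by design.
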