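---
title: "Profiling cell-wall gene families across stem internodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling cell-wall gene families across stem internodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemwall)
```

## The biological model

Grass stems elongate from the base upward: at peak elongation, lower
internodes have ceased growing and their rind cells deposit lignified
secondary walls, while upper internodes still elongate under primary-wall
synthesis. Sampling the rind of internodes 4, 5 (older, secondary-wall
forming) and 6, 8 (younger, elongating) of a maize stem therefore turns one
RNA-seq time point into a developmental contrast. Internode 7 is excluded
by design — it failed a housekeeping-gene quality control in the underlying
experimental series — so the internode set is hard-coded to {4, 5, 6, 8}
and any `i7` column is a schema error, not data.

The package's unit of inference is the *expression class* of a gene:

* **elongation** (primary-wall context): expression concentrated in the
  upper internodes, ratio `(n4+n5)/(n6+n8) < 1`;
* **secondary**: ratio `>= 2`;
* **transitional**: ratio in `[1, 2)`.

The boundary placement is inherited from the criteria as stated — "2 or
higher" is secondary and "< 1" is primary — so a ratio of exactly 1 is
transitional and exactly 2 is secondary. Both cut points are fields of
`thresholds()` and can be moved.

## Thresholds and their units

All criteria act on reads per 20 M (i.e. counts rescaled by
`2e7 / library size`), the scale on which the original cutoffs were
expressed:

| parameter | default | unit | meaning |
|---|---|---|---|
| `detect_per_million` | 1 | reads/M | per-internode detection (= 20 per 20 M) |
| `expressed_min` | 95 | reads/20 M | summed over 4 internodes, inclusive |
| `ratio_min` | 500 | reads/20 M | summed, inclusive; qualifies for a ratio |
| `secondary_min_ratio` | 2 | — | inclusive lower bound of secondary |
| `primary_max_ratio` | 1 | — | exclusive upper bound of elongation |

Two readings of "95 reads per 20 M from the four internodes" are possible:
a per-internode minimum or a four-internode sum. The package uses the sum.
The aggregate reading keeps the 95/500 hierarchy coherent (both are totals
on the same scale, 95 gating "expressed" and 500 gating "evaluable") and
matches the family tables this pipeline reproduces, in which class counts
among evaluable genes are strictly fewer than expressed genes.

Whether the original criteria were applied to raw or normalized sums is
not stated in the source material; the package normalizes first, which is
the only order that remains correct when library sizes differ. With equal
library sizes the two are identical. Likewise, ambiguous reads are split
*before* normalization: a read is a unit of library mass regardless of
how many loci it matches, so apportionment belongs on the raw scale.

## Duplicated loci and ambiguous reads

Maize's recent genome duplication leaves many paralog pairs so similar
that reads map exactly to the two loci. Such reads arrive as per-pair,
per-internode counts and are apportioned by `split_ambiguous()`:

* `"even"` (default): half to each locus — fractional halves are carried
  through deliberately rather than rounded, so totals are conserved to
  machine precision;
* `"proportional"`: by the two loci's unique counts at that internode,
  falling back to even when both are zero.

Even splitting is the default because the apportionment rule used
originally is not specified beyond "split between the two loci", and an
even split adds no assumption. Proportional splitting is strictly more
adaptive but estimates the mixing proportion from the very counts it
corrects, which is circular at low coverage. Conservation of per-internode
totals is asserted in the test suite on randomized fixtures.

## Distances, trees and supports

Protein alignments are consumed as given (multiple alignment itself is out
of scope). Distances are p-distances with pairwise gap deletion: the
proportion of differing residues over sites where neither sequence is
gapped. A pair with no comparable site gets distance 1 with a warning. The
distance model behind the original ClustalW trees is not documented;
p-distance was chosen because it is transparent, parameter-free, and
exactly testable (its expected values can be counted by hand).

`nj_tree()` is a textbook Saitou–Nei implementation with two documented
determinism/robustness rules:

* **ties** in the Q-criterion are broken toward the lowest (row, column)
  pair in the current working matrix, making output invariant across runs;
* **negative branch estimates** are clamped to zero with the deficit
  transferred to the sister branch, the standard practical remedy.

On additive matrices the implementation recovers the generating topology
and all path lengths to machine precision; this oracle equivalence, plus
agreement with an independent NJ implementation on noisy distances, is
pinned in the tests.

Bootstrap supports resample alignment columns with replacement
(`n_reps = 1000` by default, the conventional depth; tests use 100 for
speed), rebuild the tree per replicate, and report for each internal edge
of the full-alignment tree the percentage of replicates containing the
same leaf bipartition.

### Subgroup assignment

Anchor genes — reference-species members with known subgroup labels —
polarize the tree: a query gene is assigned label `L` if the smallest
bipartition side containing the gene and at least one anchor (i) contains
anchors of only label `L` and (ii) has bootstrap support at or above
`min_support` (default 50%; no acceptance threshold was stated originally,
and 50% is the weakest level at which a bipartition is better supported
than not). Mixed-label clades and unsupported clades yield `"unassigned"`;
anchors are never relabeled.

One numerical subtlety: a family of identical sequences yields an
arbitrary but deterministic NJ resolution whose replicates all agree, so
raw bootstrap support would be 100 despite zero signal. The package
therefore treats internal edges of zero branch length as unresolved
(support 0) — the usual polytomy-collapse convention — so degenerate
families return all-unassigned rather than confidently wrong subgroups.

Subgroups missing all members of a species are flagged by
`flag_species_absent()`; this is the pattern of grass-only and
eudicot-only subgroups familiar from the cellulose-synthase-like family.

### Closest homologs

`closest_homolog()` maximizes alignment identity (1 − p-distance) over
reference-species sequences, breaking ties lexicographically with a
warning. This deliberately diverges from BLAST expect values used in the
original scripts: identity over a curated alignment is deterministic,
database-free, and consistent with the distances used for the trees.

## Orthology by developmental context

The ortholog criterion is deliberately *not* best-reciprocal-hit: a query
gene and its closest reference-species homolog are putative orthologs only
when the query's expression class matches the homolog's annotated wall
context (elongation ↔ primary, secondary ↔ secondary). Opposite contexts
are `context_mismatch`. Transitional queries give `indeterminate`: such
gene pairs are homologous, but a transitional profile neither confirms nor
refutes shared context, and forcing either verdict would over-read the
evidence. Reference wall-context labels are an input annotation — the
established reference-species discriminations — and are never recomputed.
`ortholog_fraction()` reports numerator and denominator and can include or
exclude indeterminate calls from the denominator, since the original
"one quarter" summary does not state how transitional genes entered it.

## The synthetic-data generator

The generator exists so that every downstream stage has ground truth. Its
defaults are the study conditions and are not adjusted per analysis:

* four internode libraries of 2e7 reads (the per-20M scale's natural size);
* `effect_size = 4`: expected lower/upper ratio of secondary-class genes
  (reciprocal for elongation) — comfortably beyond the 2-fold class
  boundary, as expected for strongly secondary-wall-associated genes like
  lignin biosynthesis enzymes;
* `class_mix = (0.3, 0.2, 0.3, 0.2)` over elongation / transitional /
  secondary / not-expressed;
* `dispersion = 0.05` (negative-binomial, variance `mu + 0.05 mu^2`,
  i.e. a ~22% biological-plus-technical CV). The original design pooled
  three biological replicates before sequencing, so no empirical
  within-class variance exists; 0.05 is a realistic magnitude for pooled
  technical material and is documented as a free parameter, not an
  estimate;
* `ortholog_concordance = 0.25`: the probability that a query gene's
  designated reference anchor carries the concordant wall context,
  matching the reported order of magnitude for secondary-wall genes;
* `mutation_rate = 0.03` per site per unit branch length over alignments
  of 200 residues.

Families are assembled from *units*: one or two query-species genes
(two = a duplicated paralog pair on a short cherry) sister to a designated
reference anchor, with intermediate-species genes between. Units are
joined into subgroups, and subgroups are separated by long stem branches
(3 branch-length units against 0.3–1 within subgroups), so subgroup clades
are recoverable while within-unit proximity makes each query's closest
reference sequence its designated anchor. The last subgroup of each family
can be generated without reference-species members
(`species_absent_subgroup = TRUE`), emulating lineage-specific subgroups;
those query genes have no designated anchor and are excluded from
homolog-recovery scoring.

Counts: expressed genes draw a lognormal total (median 2000 reads per
20 M, floor 600 so the class machinery is exercised above the
ratio threshold), split between lower and upper internodes according to
the class ratio — transitional expectations are drawn uniformly in (1, 2).
Duplicated partners share their expected total and ratio (equal-expression
paralogs), which also makes the even ambiguous split exact in the
noise-free limit. A binomial `ambig_fraction = 0.3` of each duplicated
gene's reads is diverted into the pair's ambiguous counts; conservation of
unique + ambiguous = simulated reads holds by construction and is
asserted per internode in the tests. With `dispersion = 0` the generator
is fully deterministic (rounded means), so realized ratios equal the
configured expectations up to count rounding — exactly, when means are
rounding-compatible integers.

### What the generator does and does not emulate

It emulates: known subgroup clades with anchors, species-specific
subgroups, duplicated pairs sharing ambiguous reads, class-structured
count profiles with overdispersion, and sub-threshold genes. It does not
emulate: alignment error or gaps (generated alignments are gap-free;
p-distance's gap handling is tested on hand-built cases), read-level
artifacts (FASTQ/mapping are out of scope end to end), rate heterogeneity
across sites, or correlated expression between families. Passing recovery
tests on synthetic data therefore validates the pipeline's logic and
numerics, not the adequacy of NJ or of the ratio classifier for any
particular real family.

## Problem sizes and observed behavior

The reference recovery fixture is 10 families × 20 genes (≈ 90
query-species genes, ~70 of them ratio-evaluable) at `effect_size = 4`;
across seeds, class recovery among evaluable genes runs ≈ 90–99%, with
errors concentrated in true-transitional genes whose expected ratios lie
near the 1 and 2 boundaries — the unavoidable failure mode of any
threshold classifier under count noise. In the noise-free limit recovery
is 100%. Subgroup recovery on bootstrapped trees (`min_support = 50`)
and designated-anchor recovery both run ≥ 95% at moderate mutation rates,
reaching 100% with longer alignments (400 residues). Unit tests use
bootstrap depths of 25–100 replicates and families of 6–20 genes to keep
the default test run under a minute; none of these sizes is a statistical
claim.

## Known limitations

* The ratio collapses four internodes into one contrast; profiles that
  peak in the middle internodes are summarized as transitional.
* p-distance ignores multiple substitutions; for deeply diverged families
  a corrected distance would be preferable (the NJ machinery is
  distance-agnostic, so a corrected matrix can be supplied directly to
  `nj_tree()`).
* Subgroup assignment trusts the anchor labels; a mislabeled anchor
  propagates to its clade.
* The orthology criterion identifies shared-context closest homologs, not
  evolutionary orthology; tree-reconciliation methods answer a different,
  stricter question.
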