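---
title: "Detecting horizontally transferred plastid sequences in plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontally transferred plastid sequences in plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant mitochondrial genomes (chondromes) routinely absorb DNA from the
plastid of the same cell — intracellular gene transfer (IGT) — and,
less famously, from the mitochondria of *other* plant species —
horizontal gene transfer (HGT).  A plastid-derived region found in a
mitochondrial genome (an **MTPT**) can therefore have two very
different histories:

* **native**: copied from the species' own plastome by IGT;
* **foreign**: acquired from an unrelated species by HGT.

And a foreign MTPT can itself have travelled by two routes:

1. **pt-to-mt**: foreign plastid DNA integrated directly into the
   recipient chondrome;
2. **mt-to-mt**: the plastid sequence first hopped into the *donor's*
   mitochondrion by ordinary IGT, and later the donor's mitochondrial
   DNA — MTPT included — recombined into the recipient's chondrome
   during a mitochondrial fusion event.

The two routes leave different scars.  Under route 2 the foreign MTPT
should be *embedded in a foreign mitochondrial tract*: its flanking
sequence should match the donor's chondrome, not the recipient's.
Under route 1 the flanks are plain recipient DNA.  This package
implements the full decision procedure — detection, phylogenetic
origin classification, and flank interrogation — together with a
synthetic-corpus generator that makes every stage testable against a
known ground truth.

## The detection chain

### 1. MTPT calling (`call_mtpts`)

The chondrome is searched against a panel of plastomes with the
package's seed-and-extend local aligner (`find_hits`; word size 20,
E-value ceiling 1e-10, classic +2/−3 with 5/2 affine gaps and
Karlin–Altschul bitscores, all adjustable via `search_params()`).
Hits are kept when their mitochondrial span exceeds **200 bp** and
their identity exceeds **70%** (both strict), hits overlapping the
ancient cross-compartment homologies *atp1*, *rrn18*, *rrn26* (a
configurable locus list) are excluded, and surviving hits separated by
gaps **< 100 bp** are merged transitively into calls.  Filtering
precedes merging; since every merged call contains at least one
filtered hit, a post-merge length re-check is a no-op by construction.
Merging considers the mitochondrial coordinate only; the plastid-side
intervals of all supporting hits are retained.  Two reading choices
are deliberate and documented: "larger than 200 bp" is interpreted as
the *query span* (not the gapped alignment length), and merged hits
are not required to share a best subject genome.

### 2. Origin classification (`classify_origin`)

Calls whose best-scoring plastome belongs to a lineage related to the
recipient — sharing the leading taxonomy ranks down to order level
(rank depth 3, configurable) — are screened out as native.  The rest
are confirmed phylogenetically:

* a homolog panel is built by searching the focal sequence against
  every panel genome (`build_panel`); regions extracted from
  mitochondrial genomes are tagged `mtpt`, because their sisterhood to
  the focal tip is the signature that the sequence travelled inside a
  mitochondrion (the donor-sister flag);
* the panel is aligned (`build_alignment`, MAFFT FFT-NS-2);
* a tree is inferred (`infer_tree`): neighbor joining on TN93
  maximum-likelihood distances with a seeded nonparametric bootstrap,
  supports as integer percentages;
* `classify_placement` midpoint-roots the tree and finds the smallest
  focal-containing clade with bipartition support **> 70%** whose
  non-focal members share a lineage prefix.  If that prefix is
  unrelated to the recipient at the configured depth the verdict is
  *foreign* and the prefix is the donor lineage; if related, *native*;
  with no such clade, *unresolved* — never foreign at support ≤ 70.
  Donor identity within a clade is certified by its plastome tips: an
  MTPT tip carries its host genome's lineage, which can itself be
  foreign to the plastid sequence it contains (exactly the
  donor-sister situation), so mtpt tips inform the donor-sister flag
  but do not veto clade coherence when plastome tips are present.

Externally computed trees (e.g. a published ML tree) can be supplied
via the `tree` argument as a drop-in.

### 3. Flank evidence (`classify_flanks_record`)

For each foreign MTPT both 1 kb windows (`extract_flanks`; circular
coordinates by default, truncation in linear mode, untestable windows
become NA) are searched against the mitochondrial panel (word size 11,
a sensitivity compromise between the two published word sizes) and
categorized by the lineage affinity of their hits:

| category | meaning | supports mt-to-mt? |
|---|---|---|
| 1 | no hit | no |
| 2 | all hits recipient-related | no |
| 3 | hits only to unrelated lineages | no |
| 4 | all hits donor-related | **yes** |
| 5 | diverse lineages | phylogeny decides |
| 6 | external published evidence | **yes** (input annotation) |

Category 5 triggers the placement classifier on the flank itself;
support requires a foreign verdict with a donor-matching lineage above
the bootstrap threshold.  When the diverse panel has fewer than four
usable tips a tree is impossible and the verdict falls back to the
lineage of the strongest hit.  Category 6 is never computed — it is
carried through the packaged table as an annotation.  A record
supports the mt-to-mt hypothesis when either flank does.

### 4. Reverse direction (`call_ptmts`)

Plastomes are searched against the mitochondrial panel with word size
7.  Hits landing on mitochondrial regions annotated as plastid-derived,
or on the ancient-homology loci, are excluded; surviving plastid
regions are cross-checked against the other plastomes and reported
only when the best mitochondrial bitscore strictly exceeds the best
plastid bitscore.  The published protocol corroborated candidates
against the nr database; that step is not reproducible offline and is
replaced by the plastome-panel cross-check.  A 30 bp reporting floor
(configurable) suppresses the tiny hits word size 7 produces.
Symmetrically, the MTPT caller ignores hits whose plastid subject is
annotated as mitochondrion-derived, so a transferred segment is only
ever reported in its true direction.

## The synthetic world

`sim_config()` states the world the tests live in; its defaults are
the conditions under which every advertised number was measured, and
they are not tuned per test.

* **Species sample**: 20 species on a Yule tree of height 0.2
  substitutions/site, rejection-sampled so both root clades hold at
  least a quarter of the species (donor and recipient pools must both
  exist; the published donors are order-level or deeper, here they are
  always drawn from the opposite root clade).  Taxonomic ranks are
  divergence-time bands: the order groups species whose common
  ancestor is younger than 0.35 x the tree height, the subclade 0.7 x,
  the major clade is the root split.  This ties "order-level related"
  to divergence time, which is also roughly the horizon at which
  fast-evolving mitochondrial intergenic homology fades — so flank
  hits fall overwhelmingly inside the correct rank group, as they do
  for real chondromes.
* **Genomes**: circular, 60 kb chondrome / 15 kb plastome (scaled-down
  stand-ins for the real 200–2,000 kb / 120–160 kb).  Three conserved
  loci (*atp1*, *rrn18*, *rrn26*) are planted with identical sequence
  in both compartments to exercise the ancient-homology exclusion, at
  rate multiplier 0.15.
* **Rates**: mitochondrial intergenic sequence evolves at multiplier 6
  — so intergenic homology fades beyond roughly order-level
  divergence, as in real chondromes — while plastid sequence evolves
  at 0.8, keeping plastid homolog panels alignable across the whole
  tree, as in real plastomes.  Substitutions are HKY-like (kappa 2,
  event-based so expected counts are exactly rate x length x branch);
  indels are geometric (mean 2 bp) at 0.02 of the substitution rate
  and avoid gene features, with annotations lifted through every
  indel.  Generation is HKY while inference assumes TN93/GTR-family
  distances — a deliberate mild model mismatch that avoids the
  generator confirming itself.
* **Events**: 20 native IGTs, 30 mt-to-mt HGTs, 30 pt-to-mt HGTs per
  corpus; transferred segments of 400–1,500 bp diverged by 0.05
  substitutions/site from their source at transfer time
  (substitutions only).  An mt-to-mt event first performs the IGT in
  the donor (that copy is logged as a detectable native MTPT of the
  donor), then co-transfers 1,500 bp of donor chondrome on each side —
  enough that both 1 kb flank windows lie wholly inside donor
  sequence.  Insertions land in intergenic sequence at least 1,100 bp
  from any gene (so flank windows stay gene-free) and 1,500 bp apart
  (so calls stay separate and flank windows never touch a neighboring
  event).  Two further placement rules keep every flank window
  attributable to a single event: donor-side IGT insertions are spaced
  at least 2 x padding + 1 kb apart, making co-transferred tracts
  disjoint in donor coordinates, and later insertions keep padding +
  1 kb clear of existing MTPT annotations, so the flank of one event
  never samples tract material belonging to another.
* **Truth log**: every implanted base is traceable to its source
  interval; recovery is scored at 50% reciprocal overlap.

What a green test does **not** establish: performance on real
assemblies with repeats, chimeric contigs or recombined isoforms;
detection of transfers older than the simulated divergences; correct
donor assignment when the true donor lineage is unsampled (the
published cases with unavailable donor chondromes could not be flank
tested either); multi-contig recipients.

## Numerical choices

* Bootstrap default is 1,000 replicates (`infer_tree`); the pipeline
  runs 200 by default and the acceptance corpus 100, which moves
  integer supports by a few points at most — observed supports at true
  events sit at 95–100, far from the 70 threshold.  Alignment rows are
  canonically sorted before seeding the resampler, so supports are
  invariant to input order.
* The aligner's two-hit-like anchor (`min_anchor`, default
  `max(word_size, 12)`) suppresses random seed noise at small word
  sizes; a single-diagonal Kadane pre-score skips gapped extension of
  clusters that cannot reach the E-value ceiling.  Low-complexity
  masking (DUST) is deliberately not re-implemented; the generator
  avoids low-complexity tracts instead.
* Saturated pairwise distances in bootstrap replicates (infinite or
  undefined TN93) are replaced by twice the largest finite distance —
  they occur only in resampled replicates of already-deep pairs.
* Spearman rho is Pearson on mid-ranks; p-values use the
  t-approximation on n − 2 degrees of freedom, with exact permutation
  enumeration available for n ≤ 10.  Zero rank variance is flagged
  undefined rather than silently returning NA.
* Ties in the smallest-supported-clade search are broken by clade
  size; the support certifying a foreign verdict is the bipartition
  support of that clade, looked up from the unrooted tree so midpoint
  rooting cannot relabel it.

## Open design points, resolved

* *Which branch's support certifies "unexpected"?*  The published
  criterion names no specific edge.  This package uses the smallest
  supported focal-containing clade, evaluated as a bipartition, which
  is the weakest claim consistent with "placed inside the donor clade
  with BS > 70".
* *Internal aligner.*  The multiple alignment step is infrastructure,
  not the contribution; it is delegated to MAFFT (deterministic
  FFT-NS-2) rather than re-implemented, with the module contract and
  tests unchanged.
* *Distance model.*  Pairwise ML GTR distances are not available in
  the installed toolchain; TN93 (the closest closed-form model) is
  used and documented.  At the simulated divergences (< 0.5) the
  choice does not move any quartet.
* *Event counts.*  Stated per corpus (20/30/30), matching the
  acceptance wording; recipients are recycled across the appropriate
  clade so no genome overflows.
* *Flank hit thresholds.*  The publication states no E-value or
  identity floor for flank hits; the module applies the same E-value
  ceiling as the main search and no length filter (flanks are short).

## Limitations

The aligner is a desk-scale tool: correct on organellar-scale inputs,
not performance-comparable to BLAST, and unindexed.  The classifier
assumes every non-focal panel tip carries a lineage; unannotated tips
make a clade incoherent and push the verdict toward unresolved, which
is conservative.  Circular wrap-around is supported for flank windows
but implanted events avoid the origin entirely, so wrap handling is
exercised only by unit tests.  Host–parasite annotation is an input
(as in the published table), never inferred.
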