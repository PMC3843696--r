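---
title: "Detecting reticulate ancestry in a selfing crop: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reticulate ancestry in a selfing crop: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmernet)
```

## The scientific problem

Domesticated emmer wheat (*Triticum turgidum* subsp. *dicoccum*) is a
predominantly self-pollinating annual, yet different parts of its genome
tell different stories about its origin: haplotype sequences,
retrotransposon insertion markers and per-locus gene trees disagree with
one another in ways a single bifurcating tree cannot explain. The natural
summary of such data is a *network*, not a tree. This package implements
the full desk-side toolkit for that style of analysis:

1. **Split encoding** — alignments, binary insertion markers and gene
   trees are dissolved into *splits* (bipartitions of taxa), the atomic
   units of phylogenetic signal.
2. **Median-joining haplotype networks** for allele sequences.
3. **Filtered supernetworks** — Z-closure extension of partial splits to
   the full taxon set, support counting, and a minSupportingTrees-style
   threshold that removes low-support conflict before drawing the
   splits graph; retained incompatibilities appear as boxes
   (reticulations).
4. **Parsimony incongruence diagnostics** — concatenated-matrix MP score
   versus the sum of per-locus MP scores, with bootstrap and consensus.
5. **Minimum hybridization counting** — exact maximum-acyclic-agreement-
   forest search on rooted tree pairs.
6. **A mixing simulation** quantifying how quickly founder genotypes
   disappear from a cultivated stand under rare outcrossing.
7. **Synthetic-data generators** with planted, fully recorded truth, so
   every stage can be validated without external data.

## Split algebra

A split `A | B` partitions a subset of the taxa (its *support domain*);
partial gene trees and markers with missing calls yield partial splits.
Two splits are compatible — can coexist on one tree — iff at least one of
the four side intersections on their common domain is empty (the
four-point condition; for binary characters this is the classic
four-gamete test). Design choices worth knowing:

* Multi-state alignment columns are decomposed state-versus-rest, one
  split per state, keeping every position representable and matching the
  binary-marker pathway.
* Taxa with missing symbols are excluded from a column's split rather
  than imputed; downstream support counting restricts to each split's
  domain.
* Gap columns count as a 5th character state for split extraction (the
  indel signal is real), but as missing for nucleotide diversity and, by
  default, for parsimony scoring (matching the usual treatment in MP
  programs; `gap_as_state = TRUE` switches both scorers).
* Canonical form: sides sorted, the side holding the lexicographically
  smallest taxon first. All deduplication and comparison work on this
  form.
* Insertions observed in a single accession are flagged uninformative and
  dropped from marker split sets, since a singleton split carries no
  grouping information.

## Curation rules

`curate_alignment()` applies, in a fixed order: removal of sequences and
then columns with more than `max_unrecognized` symbols outside
`{A,C,G,T,-}` (default 1, i.e. "multiple" read as at least two; sequences
first so one bad sequence cannot drag whole columns down), extraction of
polymorphic positions, and reduction of indels longer than 1 bp to single
positions. Indel reduction merges only *maximal runs of adjacent columns
sharing an identical gapped-taxon set* — the conservative reading: a
k-bp deletion event contributes one inferred change, while overlapping
but distinct gap patterns stay separate.

Nucleotide diversity uses the unbiased estimator
\(\hat\pi = \frac{n}{n-1}\binom{n}{2}^{-1}\sum_{i<j} d_{ij}\)
with pairwise deletion. It is computed over all sequences (one per
accession); computing it over distinct alleles weighted by frequency is a
caller-side option via `collapse_haplotypes()`.

## Median-joining networks

`median_joining()` follows the classic two-phase scheme: a minimum
spanning network (all edges on any minimum spanning tree under Hamming
distance; `epsilon` relaxes the connection criterion) is repeatedly
augmented with per-position majority medians of node triples that are
mostly adjacent, keeping only medians that strictly reduce the network's
spanning cost, and pruning inferred medians that stop paying for
themselves. Determinism: ties among equally good medians break on the
lexicographic state vector; within-position majority ties resolve to the
first-listed node's state. Default `epsilon = 0`, uniform character
weights — the defaults of the program this construction is modeled on;
neither is data-dependent here. On small instances (at most 5 observed
haplotypes, 6 positions) the output's spanning cost equals a brute-force
Dreyfus–Wagner Steiner minimum in the test suite; on larger instances
median joining is, like the original algorithm, a heuristic.

## Parsimony machinery

Small parsimony uses Hartigan's generalization of the Fitch pass, exact
on multifurcating trees, with missing symbols as full-state wildcards.
Tree search is exact — all unrooted topologies — up to
`exhaustive_limit = 9` taxa ((2n-5)!! = 135,135 topologies), and above
that a heuristic of `n_jumbles` random-addition-order stepwise insertions
each refined by nearest-neighbour-interchange hill climbing. NNI rather
than SPR refinement is deliberate: at the taxon counts this package
targets it is adequate and far easier to verify against the exhaustive
oracle (the suite requires agreement on at least 95% of random
fixtures). All co-optimal trees are kept, deduplicated by canonical
split-set keys.

Bootstrap resampling exploits the linearity of parsimony scores in
column weights: in the exhaustive regime, per-pattern costs of every
topology are computed once and each replicate is a reweighting — one
matrix product per replicate — which makes 1000-replicate runs cheap and
exactly equivalent to the naive loop. One best tree per replicate (first
in canonical order) enters the majority-rule consensus; supports are
replicate percentages.

The incongruence diagnostic is the ratio of the concatenated-matrix MP
score to the sum of per-locus MP scores. Because any single tree must
absorb every locus's changes, the concatenated score can never fall below
the per-locus sum (superadditivity — property-tested); values above 1
indicate conflicting gene histories.

## Filtered supernetworks

`zclosure()` implements the pairwise Z extension rule: for partial splits
\(A_1|B_1\) and \(A_2|B_2\) with \(A_1\cap A_2\neq\emptyset\),
\(B_1\cap B_2\neq\emptyset\) and \(A_2\cap B_1=\emptyset\), the pair is
replaced by \((A_1\cup A_2)|B_1\) and \(A_2|(B_1\cup B_2)\). Sweeps run
in randomized order to a fixed point; the union of distinct full splits
over several randomized runs is kept (the rule is order-dependent, and
multiple runs recover splits a single order misses). Splits still partial
at the fixed point are completed by assigning absent taxa to the
canonical second side — a documented convention, with `"discard"`
exposed as the alternative. The behavioural contract, enforced in the
tests, is *no signal loss on clean data*: with mutually compatible
inputs, the closure restricted to any input's taxa contains all of that
input's splits.

Support counting unifies the two published filtering modes (raw splits
as inputs; partial trees as inputs): an input supports a full split iff
the split restricted to the input's taxa is empty (vacuous support,
counted by default and switchable off), trivial, or exactly one of the
input's own splits. The filter keeps nontrivial splits supported by more
than `min_supporting` inputs (strictly greater by default, matching the
published "> 31" phrasing; presets 31/8/6 are available via
`pipeline_preset()`). Filtering is antitone in the threshold —
property-tested.

The splits graph is the Buneman construction: vertices are coherent
side assignments (pairwise intersecting chosen sides), edges join
assignments differing in one split. Compatible systems give their tree;
k mutually incompatible splits give a 2^k hypercube face, so retained
conflict displays as boxes. Deleting one split's edge class bipartitions
the graph exactly by that split (tested). A `node_cap` guards against
under-filtered systems.

## Minimum hybridization numbers

For a rooted tree pair, the minimum number of hybridization events
equals the size of a maximum *acyclic* agreement forest minus one. The
search adds a root leaf above both trees, then iteratively deepens over
the number of edges cut in the first tree; each candidate partition is
checked for agreement (identical restricted cluster sets), node-disjoint
spanning subtrees in both trees, and acyclicity of the component
inheritance digraph. This exact small-instance search replaces the
published large-scale algorithm for nonbinary partial trees; on the
instances where both are exact they compute the same quantity, and the
test suite verifies equality with an independent exhaustive
enumeration over all leaf-set partitions at up to 7 taxa. The exact
limit is 12 common taxa (the combinatorics beyond that call for the
specialised algorithms this package deliberately does not reimplement);
soft polytomies are handled by a bounded sample of binary resolutions
(degree at most 5), harder ones raise an error.

## The mixing simulation

The simulation asks: if genetically distinct founder populations of a
selfing annual are grown intermixed, how fast do the original multilocus
genotypes disappear under rare cross-pollination, with no selection?
Lines are modeled as effectively haploid multilocus genotypes — full
selfing keeps lines homozygous, so an outcross is collapsed into a
single free-recombination mosaic of the two parents, absorbing the
heterozygous-then-segregating generations. Founders are fixed for
population-diagnostic alleles at all `L` loci, so "retains a founder
genotype" means every locus traces to one founder.

The outcross frequency `c` is the expected number of outcross events per
line per generation (events per generation ~ Binomial(N, c)). Two
mating schemes are implemented because the main-text description of the
underlying model leaves the bookkeeping open:

* **maternal-only** — an event re-derives a single line from itself and
  a random pollen parent; a fraction c of lines is affected, giving the
  closed-form envelope \((1-c)^t\) when founders are all distinct
  (verified within Monte-Carlo error in the tests). At c = 0.01 this
  envelope is \(0.99^{200}\approx 0.134\): it cannot fall below 10% in
  200 generations.
* **symmetric-pair** (default) — an event replaces the succession of
  *both* participants with independent recombinant mosaics, affecting a
  fraction of roughly 2c of lines. This is the scheme consistent with
  the headline behaviour (frequency below 10% after 200 generations at
  c = 0.01), and with k = 2 equal founder populations the simulated mean
  frequency at generation 200 is about 4% (same-population outcrosses
  reproduce the founder genotype, which slows the early decay relative
  to \((1-2c)^t\approx 0.018\)).

Defaults N = 1000 lines, L = 20 loci, 20 replicates: N and L only enter
through the (negligible at L = 20) probability that a mosaic recreates a
founder genotype and through Monte-Carlo noise, so results are flat in
both — the invariants suite checks expectation-level conservation of
allele frequencies and monotone decay. Frequencies are exact counts, not
approximations, so `c = 0` preserves frequency 1 forever.

## Synthetic data: what it does and does not emulate

* `gen_alignment_on_tree()` uses infinite-sites generation (each variable
  site mutates exactly once, on an edge drawn proportionally to length):
  clean-data invariants — every column split is a tree split, parsimony
  recovers the generating topology — are then *exact*, which is what
  makes them usable as tests. A finite-sites mode with homoplasy exists
  for stress testing only. Real amplicon data of course contain
  homoplasy, sequencing error and alignment artifacts; passing tests on
  generator output validates the algorithms, not those error processes.
* `gen_hybrid_markers()` plants population-diagnostic marker blocks and
  mosaic hybrids that carry at least one marker from each parental
  block, creating marker *combinations* absent from any parent while
  every individual marker exists in a parent — the fingerprint the
  marker analysis looks for. The default is three populations: with
  only two uniform populations the hybrid's two marker classes are
  mutually compatible (they fit a path-shaped tree) and no box can
  exist; a third population makes them incompatible, which is the
  minimal realistic design (two parental gene pools plus an outgroup
  population).
* `gen_discordant_trees()` plants hybridization as single-leaf rooted
  SPR moves — one accession's lineage reattached elsewhere — which
  models introgression into a single sampled lineage and makes the
  per-move minimum hybridization count exactly 1; taxon dropout
  emulates partial per-locus accession coverage.

## Numerical and scale choices

Exhaustive parsimony search is the default up to 9 taxa; the test suite
exercises exhaustive-versus-heuristic agreement at 7 taxa (945
topologies per fixture, 40 fixtures), the agreement-forest oracle at 5–6
taxa, and the Steiner oracle at up to 5 haplotypes and 6 positions —
sizes chosen so that each brute-force oracle enumerates its full space
in well under a minute while still covering every code path. The
mixing simulation runs at its full stated size (N = 1000, 200
generations, 20 replicates) in under a minute.

## Limitations

* Split weights are uniform; weighted (least-squares or distance-based)
  split systems and circular systems (NeighborNet) are out of scope.
* The supernetwork graph is abstract — node and edge structure, not a
  drawing.
* The heuristic MP search uses NNI only; pathological landscapes that
  require SPR to escape are not handled (and are flagged by the
  oracle-agreement property when they matter at test scale).
* `min_hybridization()` is exact but exponential: 12 common taxa is the
  hard limit, and the reported mean over pairs of larger trees must rely
  on subsampling.
* The mixing model has no selection, mutation, seed banks or overlapping
  generations, and treats lines as haploid genotypes.
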