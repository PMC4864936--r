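---
title: "Exact repeat-aware scaffolding: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact repeat-aware scaffolding: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafex)
```

# The scaffolding problem

A draft assembly consists of contigs whose order, orientation and spacing
along the chromosomes are unknown. Mate-pair ("jumping") libraries constrain
them: a read pair whose two mates map to different contigs implies a
relative orientation and an approximate distance between those contigs.
`scafex` builds a *scaffold graph* — contigs as nodes, bundled pair
constraints as edges — and searches for a scaffold (a signed permutation of
contig instances plus gap sizes) that **globally minimizes the number of
discordant edges**, i.e. edges whose distance or orientation constraint no
placed instance pair satisfies. This is a clear combinatorial objective
rather than a greedy heuristic: when the returned scaffold has `k`
discordant edges, no scaffold with fewer exists (under the package's
deterministic placement rule, below).

Repeat contigs — identified by read coverage above 1.5x the length-weighted
genome mean — may occur multiple times in a scaffold. The optimum sought is
*minimal-repeat*: among discordance-minimizing scaffolds, one from which no
repeat instance can be deleted without increasing discordance. Two standing
assumptions make repeats tractable: (1) edges emanating from placed repeat
instances never propose further extensions (avoiding ambiguous walks through
repeat space), and (2) concordance of repeat-repeat edges is ignored, since
it cannot be verified without assuming all instances were placed.

# From mappings to edges

**Library estimation.** Each library's orientation (inward / outward /
same-strand) is the majority class over same-contig pairs; ties follow the
fixed preference inward > outward > same-strand. Insert mean and SD come
from pair spans (outermost coordinates, both read lengths included) on
contigs longer than twice a preliminary estimate (the mean span of the
first 1000 same-contig pairs), after discarding spans outside
`[Q1 - 3 IQR, Q3 + 3 IQR]` (type-7 quartiles; the method's standard
outlier rule). The SD is floored at 1 bp so concordance windows stay
positive, and the library span bound is `L = mu + 6 sigma`.

**Truncation-corrected edge lengths.** Pairs linking two contigs are
bundled per (contig pair, orientation class). Each pair contributes one
observation of `S`, the contig sequence overlapped by its insert (the sum
of the two within-contig overhangs). Because a pair spanning a gap `g`
between flanks of total length `l` is only observed when its insert lies in
`[g, g + l]`, the observed insert distribution is truncated, and the naive
estimate `g = mu - mean(S)` systematically under-estimates long gaps. The
package instead tabulates `E(S | gap = g) = E(I | g <= I <= g + l) - g`
for every `g` in `[0, L]` (linear time via cumulative sums over the insert
histogram; tables cached per 500-bp bucket of `l`, ties rounding down) and
inverts the table at the observed mean of `S`. `E(S)` is non-increasing in
`g`, so the inversion is unique up to table resolution. Values falling
outside the table are clamped and the edge flagged. The edge SD is
`sigma / sqrt(n)` over `n` supporting pairs — the standard error of the
bundled estimate; a single-pair edge keeps the full library SD. The insert
histogram may be empirical (from the library's filtered same-contig spans)
or a discretized Normal when parameters are known; empirical tails carry
little mass far from the mean, so simulation studies use the parametric
form.

**Multi-library merging.** Edges from different libraries connecting the
same oriented contig pair are clustered: the largest-SD unmerged edge seeds
a cluster, absorbing edges whose means lie within 6 seed-SDs; clusters are
combined by inverse-variance weighting (`sd = (sum sd_i^-2)^-1/2`,
supports summed). If several merged edges survive between two unique
contigs, only the best-supported is kept; pairs involving a repeat retain
all of them. Libraries can also be grouped into insert-size *stages*
(`(0,1k]`, `(1k,10k]`, `(10k,Inf)` by default, upper-inclusive), each stage
scaffolding the previous stage's output as units.

**Filters.** Contigs shorter than `max(500, 2 x paired-end insert)` are set
aside as singletons (their position is typically under-constrained), and
edges with fewer than 5 supporting pairs are dropped (1 in long-read mode).

# The exact search

An edge is *concordant* under a placement when some ordered instance pair
matches its relative orientation with an implied gap inside
`[g - 6 sd, g + 6 sd]`. The search grows a partial scaffold rightward
only. Its bookkeeping is three-state: each edge is *satisfied*, *open*
(undecided), or *dead* — provably unsatisfiable by any extension, either
because both unique endpoints are placed incompatibly or because the tail
has moved beyond the edge's reach window. The dead count `k` is the
lower bound driving iterative deepening: levels `p = 0, 1, 2, ...` are
searched in turn and the first completed scaffold (all unique contigs
placed) with final discordance at most `p` is returned, which makes the
returned `k` minimal and the tie-break deterministic ("first found" under
the fixed exploration order).

**Deterministic placement.** The abstract objective treats gap sizes as
free; to make search and validation oracle optimize the *identical*
computable objective, the package fixes a deterministic placement rule:
a newly appended instance is positioned at the candidate coordinate —
among the gap estimates and lower window endpoints of all in-reach
matching anchored edges, plus the gap-0 tail fallback, floored at 500 bp
of overlap — that satisfies the most of its own constraints (ties prefer
estimate centers, then higher support, then smaller edge id, then the
smaller coordinate). Considering lower window endpoints matters: a maximal
satisfiable set of interval constraints can always be met at one of their
lower endpoints.

**Candidates and ordering.** Extensions are proposed by open edges
anchored at placed *unique* instances within reach; each proposal carries
the orientation the edge demands. Candidates are ordered by estimated
distance from the scaffold tail, propagated breadth-first through the
graph visiting each edge once; a candidate reachable by several paths gets
a weighted mean distance, down-weighting longer paths by their edge count.
If nothing is proposed while unique contigs remain (possible only in
heavily discordant regions), the remaining unique contigs are offered
directly so the search space stays complete.

**Repeats.** A repeat instance is proposed like any other candidate (up to
a parsimony cap of 2 instances per repeat per component) but proposes
nothing itself. Once an unconfirmed instance falls out of the tail's reach
window it is tested: if no currently satisfied edge depends on it, it is
deleted (coordinates of everything else fixed); otherwise it is confirmed
and kept. A final sweep applies the same test to the completed scaffold,
so every surviving instance is essential — deleting it strictly increases
discordance.

**Memoization.** Search states are memoized on the *active region* — the
suffix of instances within the maximal edge reach window of the tail,
which by construction contains every unconfirmed repeat and every open
edge's anchor — together with the open-edge set, the unplaced unique set
and per-repeat instance counts; with repeats present a state is pruned
when an equal key was reached with no more discordance (dominance on `k`),
and in unique-only mode keys are exact on (active region, discordant set).
The key is deliberately finer than the minimal equivalence class the
theory allows: because the placement rule consults anchor offsets, equal
keys must also guarantee equal geometry. A finer key only reduces pruning,
never correctness. The memo table is a hashed environment keyed on the
canonical state encoding; lookup cost is proportional to the key length.
Memoization on or off returns byte-identical scaffolds, never more
explored states with it on.

**Hybrid-exact fallback.** If a subgraph's explored-state count exceeds
the cap (10^6 by default), the edge-support threshold is raised by 1,
weakly supported edges dropped, and the search restarted; the resulting
scaffolds are flagged in the AGP output and the run log. The rationale:
edges with few supporting pairs are the least reliable, so the fallback
trades the exactness guarantee on that subgraph for tractability in a
conservative, visible way.

# Contraction and stitching

A unique contig at least as long as the largest library span bound `L` is
a *border*: no concordant edge can span it. Removing borders splits the
unique-contig graph into components; each component plus its adjacent
borders and linked repeat contigs forms a *fenced subgraph* that can be
searched independently without losing global optimality (every external
edge passes through a border). Adjacent borders flanking an empty junction
form pair subgraphs (with their linked repeats) so junction repeats are
still placed. Per-subgraph scaffolds are stitched at shared borders,
flipping the later scaffold when orientations disagree; repeat instances
hanging past a border (the neighbouring subgraph places those
authoritatively) are trimmed before joining, and a *unique* contig beyond
a border is treated as an invariant breach.

# Gap sizing

With order and orientation fixed, every satisfied edge constrains the
distance it spans: `D_e(gaps) = sum(interior contig lengths) +
sum(spanned gaps)` should be close to its estimate `g_e` with SD
`sigma_e`. The Gaussian maximum-likelihood gap vector minimizes
`sum_e n_e (D_e - g_e)^2 / sigma_e^2` subject to box bounds
(`-500` bp, allowing modest overlap, up to the largest library bound).
The pair-support weight `n_e` can be switched off
(`use_support_weights = FALSE`). The solver is projected coordinate
descent with deterministic sweeps and a `1e-8` relative tolerance on the
objective — the problem is a small convex QP per scaffold, and the
unconstrained solution (checked against the normal equations in the test
suite) is recovered to `1e-6` relative whenever it is interior. Gaps
covered by no constraint keep their placement value (or the lower bound).

```{r gap-example}
sys <- gap_system(c(2000, 3000),
                  data.frame(i = c(1, 1), j = c(2, 2),
                             gap = c(500, 800), sd = c(50, 100),
                             support = c(1, 1)))
estimate_gap_sizes(sys)$gaps   # inverse-variance weighted mean: 560
```

# Long-read links

Contig links inferred from long reads (a 6-column TSV: contigs,
orientations, distance, support) become scaffold edges with
`sd = max(0.1 x distance, 30)` — the 10% rule reflects indel noise in
long reads; the 30-bp floor (10% of the smallest bin's upper edge) keeps
windows positive for zero-distance links. Links are grouped into synthetic
libraries by fixed lower-inclusive distance bins `[0,300), [300,1000),
[1000,2000), [2000,5000), [5000,15000), [15000,40000]`; longer links are
discarded rather than clamped. Duplicate links for an oriented pair merge
first (supports summed, inverse-variance mean distance). The edge-support
threshold defaults to 1 in this mode, as chimeric links are rare. Feeding
the resulting edges to the scaffolder is exactly equivalent to supplying
the same constraints natively.

# The synthetic-data generator, and what passing tests mean

The simulator emulates the data a scaffolder sees, not a sequencer: a
uniform-random genome with planted repeat families (copies of a template,
optionally mutated, at non-overlapping positions), contigs tiling the
genome broken at repeat boundaries and at random unique-region breakpoints
(mean unique contig ~20 kbp), each repeat family collapsed to a single
contig with coverage multiplied by its copy number (Poisson-jittered, so
classification is exercised near its threshold), and mate pairs drawn with
Normal(mu, sigma) inserts at uniform genome positions, mapped directly
onto the containing contig copies. Default validation conditions: a 1-Mbp
genome with ~10% repeat content in 10 families of 2-3 copies of 3-5 kbp —
enough copies to confound a repeat-naive scaffolder while keeping the
exact search's subgraphs small — and two inward libraries, 3 kbp +/- 300
and 10 kbp +/- 1000 at 2x base-pair coverage each (about 20,000 pairs per
library), mirroring the common mate-pair complement of a large-genome
project at desk scale.

Deliberately *not* modeled: base-call errors and mis-mapping (mappings are
generated, not aligned), chimeric pairs, GC- or mappability-dependent
coverage, heterozygosity and structural variation between repeat copies.
Passing the end-to-end checks therefore shows the graph construction,
search, contraction and gap sizing are correct and calibrated on clean
data of realistic geometry; it does not certify robustness to alignment
artifacts — on real data the IQR filter, support threshold and edge
clustering carry that burden, and they are exercised here only at their
defaults. Separate generators produce small random scaffold *graphs*
directly (planted layouts with corrupted extra edges, repeats collapsed
into junction gaps) for the exactness and contraction checks against a
brute-force oracle; their corrupted edges are confined to unique-unique
pairs, matching the search's standing assumptions about repeat edges.

# Validation problem sizes

The test suite verifies exactness on 200 random graphs of up to 7 unique
plus 2 repeat contigs and 12 edges against exhaustive enumeration
(branch-and-bound-pruned but exact), contraction soundness on 50 graphs
with planted borders, estimator calibration on a 10 kbp +/- 1 kbp library
with 100-pair edges over true gaps of 2-12 kbp, library recovery at
10,000 pairs across 10 seeds, and the 1-Mbp end-to-end assembly above.
These sizes keep the brute-force oracle exact — its cost grows
factorially, so it is the oracle that bounds graph size, not the search.
`scripts/acceptance.R` recomputes all of it from scratch for any seed.

# Numerical and design choices

* Coordinates are 0-based half-open internally; SAM's 1-based positions
  convert at the boundary. Reverse-strand positions are leftmost aligned
  bases; pair spans use outermost coordinates.
* Edges are canonicalized (lexicographically smaller contig first, using
  the reversal identity), so a scaffold and its mirror image are the same
  solution; starts are explored in both orientations.
* AGP gap records must be positive, so non-positive estimated gaps render
  as one `N` with the raw estimate preserved in a trailing `est_gap=`
  column; the FASTA writer renders `max(1, round(gap))` Ns.
* Degenerate inputs: an empty edge set yields singletons; a subgraph of
  only repeats yields one singleton per repeat; zero same-contig pairs is
  an error advising manual library parameters; an SD of zero is floored.
* The evaluator classifies adjacent unique-contig joins with precedence
  translocation > inversion > relocation > scaffold indel; the relocation
  distance tolerance is `max(1 kbp, 6 x join SD)` (default join SD 500 bp,
  standing in for the supporting edge's SD), while the indel threshold is
  the standard 1 kbp. Corrected N50 breaks scaffolds at every error join
  and asks for the fragment length at which cumulative coverage strictly
  exceeds half the genome.
* The lookup-table domain for the contig-length sum runs from 0 to
  `Q3 + 3 IQR`; buckets of 500 bp, ties rounding down.
* The repeat copy cap (2 per component) matches the parsimony criterion
  and the oracle's enumeration bound; raise `max_repeat_copies` for
  genomes with high local copy numbers.
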