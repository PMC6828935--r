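---
title: "Inferring genome rearrangements on a phylogeny from signed block orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring genome rearrangements on a phylogeny from signed block orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgrpt)
```

## The model

A genome is a set of linear chromosomes; each chromosome is a signed
permutation of syntenic-block labels, and a chromosome `X` is identified
with its reverse complement `−X` (read from the other end, all signs
flipped). Every block occurs exactly once per genome: the model assumes
equal block content across all genomes, with no duplications or losses,
and no circular chromosomes. Five operators act on genomes:

* **reversal** `r(i, j)`: a segment is reversed in place with signs
  flipped (≤ 2 adjacencies destroyed, ≤ 2 created);
* **translocation** `tl(i, j)`: two chromosomes exchange end segments,
  either prefix-for-prefix (`Y1 X2` / `X1 Y2`) or prefix-for-suffix
  (`−Y2 X2` / `X1 −Y1`); all four exchanged segments must be non-empty —
  an exchange that empties a chromosome is a fusion or fission, which
  are kept as separate operators so that simulation logs are
  unambiguous;
* **transposition** `tp(i, j, k)`: a fragment is excised and reinserted,
  orientation preserved, immediately after another block (or at a
  chromosome head), intra- or inter-chromosomally (≤ 3 adjacencies
  each way);
* **fusion / fission**: two chromosomes joined end-to-end (optionally
  with the second flipped), or one chromosome split at an internal
  junction.

The observable consequence of every operator is a change in the
*adjacency set*: the canonical pairs `a(x, y) ≡ a(−y, −x)` of
consecutive blocks. All bookkeeping in this package is done on
adjacency sets; every operator returns an event record whose
`destroyed`/`created` sets exactly update the genome's (telomere-capped)
adjacency set, a property asserted by the test suite across random
operator applications.

**Telomere caps.** Events that touch a chromosome end are invisible in
plain adjacency terms (a reversal of a prefix destroys only one internal
adjacency). The RGRPT convention adds a sentinel `0` at each chromosome
end, so a chromosome `1 2 3` carries `a(0,1), a(1,2), a(2,3), a(3,0)`.
Event records are always stored in capped terms; candidate sets carry
caps only in RGRPT mode.

## Candidate adjacency sets

For a rooted tree with genomes at the leaves, removing an edge
`e = (A, B)` bisects the leaves into `S_A` and `S_B`. The candidate set
`Ca(e, A)` collects adjacencies attributable to A's side:

* **step a**: adjacencies in *every* genome of `S_A` and in *no* genome
  of `S_B`;
* **step b** (internal endpoints): adjacencies in ≥ 1 genome of *each*
  subtree hanging off `A` away from `e`, and in no genome of `S_B`;
* **step c**: recursive propagation. For each sub-edge `e_i` with far
  endpoint `u_i`, an adjacency `a1 ∈ Ca(e_i, u_i)` is admitted into
  `Ca(e, A)` when (i) it shares no block with the near set `Ca(e_i, A)`
  (if it did, the event that made it likely happened on `e_i` itself),
  and (ii) every other subtree `e_j` contains a block-sharing partner
  `a2 ∈ Ca(e_j, u_j)` that itself shares a block with `Ca(e_j, A)`;
* **RGRPT extension**: as (ii) alone — a sub-edge candidate is admitted
  whenever every other subtree echoes one of its blocks, with the
  blocking conditions waived.

"Sharing a block" means sharing an absolute label; caps never count.

Three design decisions deserve record:

1. **The recursion is cyclic as stated and is resolved as a least
   fixpoint.** The near sets `Ca(e_i, A)` that step c consults would, if
   fully recursive, need `Ca(e, A)` back (the sub-edges of `(e_i, A)`
   include `e` itself). We pin the near sets to their direct (a+b)
   evidence and sweep the far sets to convergence; with the near sets
   fixed every admission condition is monotone, so the sweeps reach a
   unique fixpoint. On caterpillar topologies one pass already is the
   fixpoint.
2. **Candidate sets live on the unrooted tree.** A rooted binary tree
   has a degree-2 root whose two child edges cut the leaf set
   identically; they are merged into a single inference unit whose
   endpoints are the two root children (computing step b at the
   artificial root would degenerate to "present anywhere on this
   side"). Consequently, events on the two root branches are pooled and
   their direction on that unit is not identifiable.
3. **Post-filter.** Steps a and b guarantee by construction that a
   candidate occurs on its own side and nowhere on the far side;
   step c and the extension assert this as an explicit filter.

Step b's quantifier is read as "at least one genome of each subtree";
in step c any block-sharing witness suffices (uniqueness is not
required). Both are deliberate readings of ambiguous prose, chosen once
and covered by tests.

## Inference rules

Each canonical adjacency has two oriented readings under
`a(x, y) ≡ a(−y, −x)`. Writing `a1 = (p, q) = a(c_{i−1}, c_i)` and
`a2 = (r, s) = a(c_j, c_{j+1})` from `Ca(e, A)`, a reversal `r(i, j)`
predicts `b1 = a(p, −r)` and `b2 = a(−q, s)` in `Ca(e, B)`. The same
quadruple signature read on two chromosomes is a prefix–suffix
translocation, and the prefix–prefix exchange signature
(`b1 = a(p, s)`, `b2 = a(r, q)`) is this very pattern applied to the
flipped reading of `a2` — so a single matcher over both readings of
every candidate covers all published patterns at once.

Which type to emit is decided by chromosome context:

* if all genomes are uni-chromosomal, the signature is a **reversal**;
* otherwise the quadruple is a **reversal** if some witness-bearing
  genome on each side (one carrying both of that side's witnesses)
  places all their blocks on one chromosome, and a **translocation** if
  witness-bearing genomes on both sides show the two-chromosome
  exchange configuration (each witness on its own chromosome);
* a quadruple with no coherent configuration is not called. The bare
  alternative — calling every non-co-chromosomal quadruple a
  translocation — emits two to three times the true translocation
  count in mixed simulations, assembled from breakpoint-reuse leftovers
  of co-edge events.

The matcher runs in two passes (reversal calls first, then
translocations from the remainder), then the transposition sextuple
(`b1 = a(p, s)`, `b2 = a(t, q)`, `b3 = a(r, u)` for a third ancestor
adjacency `a3 = (t, u)`), gated in multi-chromosomal data by the
majority test: among the `m ≥ 1` ancestor-side genomes carrying both
`a1` and `a2`, at least `m/2` genomes must place the blocks of `a1`+`a2`
(or of `a2`+`a3`) on one chromosome (exact integer comparison, no
rounding).

**Fissions and fusions.** In RGRPT mode the exact capped signature is
tried first: an interior adjacency `a(x, y)` on one side paired with the
two caps `a(x, 0)`, `a(0, y)` on the other. Remaining single candidates
use a *sign-compatibility* test, which we formalize as the split's
actual postcondition: `a(x, y)` is sign-compatible with a genome `G`
iff `a(x, 0)` and `a(0, y)` are capped adjacencies of `G` — that is,
`x` can close a chromosome and `y` can open one with the signs the
split implies, up to whole-chromosome flips. A fission is called for an
ancestor-side candidate that is sign-compatible with *every*
descendant-side genome; a fusion is the same rule read from the other
side. Weaker formalizations (e.g. per-chromosome sign consistency,
which renders every cross-chromosome pair compatible) flood
multi-chromosomal simulations with spurious calls — up to thirty
predicted fissions against one true — and were rejected.

Rule families run in fixed order (reversal/translocation →
transposition → fusion/fission); candidates are enumerated in canonical
sort order; the first match consumes its witnesses, and no adjacency
witnesses two events on the same edge. Events are reported
ancestor → descendant; on the merged root unit the direction is a
convention, and the evaluation layer treats it as unoriented (fusions
and fissions, which are direction-conjugate, are pooled there and in
all scoring).

## The simulator

`simulate_evolution()` walks the tree in preorder; each edge receives
`k ~ Uniform{k_min..k_max}` events drawn from a weighted type mix, with
all placements uniform among valid ones and infeasible draws resampled.
Identity events are never drawn: a whole-chromosome reversal (equal to
its reverse complement), a one-block reversal on a length-1 chromosome,
a whole-chromosome transposition fragment, and reinsertion at the
excision site all leave the genome unchanged and would make sensitivity
denominators meaningless. Reversals span a single block with
probability 0.25 (a 1 : 3 one-block : multi-block ratio, applied in
expectation, not as a quota) and otherwise a uniformly drawn multi-block
segment — the span distribution is a modelling choice; real inversion
lengths are strongly skewed short, so uniform spans make co-edge events
interfere more than short-biased spans would. Chromosomes are chosen
proportionally to their number of valid placements. Two packaged
protocols fix the study conditions:

* **reversal-only**: uni-chromosomal ancestors of `m = 50, 60, …, 150`
  blocks (11 datasets per leaf count), caterpillar topologies with 3–10
  leaves, `k ~ U{3..10}` reversals per edge;
* **mixed-event**: a 5-chromosome × 100-block ancestor on a 4-leaf
  caterpillar, mix reversal : translocation : transposition :
  fusion/fission = 10 : 2 : 2 : 0.1 (the joint 0.1 split evenly), with
  `k ~ U{1..μ}` for `μ ∈ {6, 12, 18, 24}`, 10 replicates each.

The caterpillar is the simplest topology family parameterized by leaf
count alone; any rooted newick can be substituted. Every applied event
is logged per edge, and `replay_truth()` re-derives the leaves from the
log — byte-equality is asserted in the tests, as are seed determinism,
block conservation, and the empirical type frequencies (chi-square).

What the simulator does **not** emulate: unequal block content (gain,
loss, duplication), breakpoint reuse hotspots, branch-length-scaled
event counts, and block-boundary uncertainty from real synteny calls.
Passing simulation benchmarks therefore says nothing about
block-calling robustness on real genome alignments — only about the
inference rules under the stated generative model.

## Scoring

"Correctly predicted" needs a definition because the same physical
event admits several index descriptions. A prediction matches a true
event when both lie on the same inference unit, have the same type
class (fusion/fission pooled), and their created-adjacency sets
intersect (`criterion = "overlap"`, the default) or are equal
(`"strict"`). Matching is a maximum one-to-one bipartite matching with
deterministic order, so two predictions can never both claim one true
event. Sensitivity is correct/true, specificity correct/predicted;
empty denominators give `NA`, never 0. Because the reversal-only study
concerns reversal prediction and its genomes are uni-chromosomal (the
translocation and fission branches cannot fire there),
`benchmark_reversal_only()` runs only the reversal rule family;
`benchmark_all_events()` runs all families.

With the default seeds the two benchmark drivers land, over three
independent batches, at grand means of roughly 66 % sensitivity /
95 % specificity for RGRPT and 51 % / 96 % for EMRAE on the
reversal-only study (RGRPT's sensitivity advantage of ~15 points holds
in every batch and traces to the caps plus the extension rule), and
roughly 74 % / 89 % for RGRPT on the mixed study, with sensitivity
decreasing monotonically in μ — run `scripts/acceptance.R` to
regenerate these numbers from scratch. These operating points are a
property of the reading documented above: the candidate-propagation and
rule prose admits a family of implementations, with stricter readings
trading sensitivity for specificity, and the numbers here come from the
single reading fixed in this section, not from per-benchmark switches.

## Numerical and degenerate-input choices

* Adjacencies are encoded as single 32-bit integers
  (`(x+20000)·40001 + (y+20000)`, canonical form the smaller of the two
  readings); block labels are validated to |label| ≤ 20000.
* Indices are 1-based inclusive; chromosome orientation ties
  (palindromic under reverse complement) keep the input orientation.
* Genomes are compared after normalizing each chromosome to the
  lexicographically smaller of `X`/`−X` (by |label|, then sign) and
  sorting chromosomes by first absolute label.
* A two-leaf tree is the smallest valid input; both endpoints of its
  single unit are leaves, so only step a applies.
* Trees whose root has three or more children are handled without
  merging (no unit is unoriented then).

## Known limitations

* Equal block content is assumed, not checked against biology: blocks
  missing from one genome must be removed upstream.
* Events on the two root branches cannot be told apart; per-edge counts
  for those branches are reported jointly.
* At high per-edge event counts the adjacency evidence of earlier
  events is progressively overwritten; no candidate scheme can recover
  an event whose destroyed and created adjacencies survive in no leaf.
  The benchmarks quantify exactly this decay.
* Greedy witness consumption makes prediction sets order-dependent in
  principle; the canonical enumeration order makes them deterministic,
  but composite signatures assembled from co-edge leftovers can still
  be called as single events.
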