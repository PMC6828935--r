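# rgrpt

Identify genome rearrangement events — reversals, translocations,
transpositions, fusions and fissions — on the edges of a rooted
phylogenetic tree, given only the signed syntenic-block orders of the
leaf genomes.

## The problem and the method

Comparative maps reduce each genome to an ordering of conserved syntenic
blocks: a chromosome is a signed permutation `X = c1 c2 … cn`, identical
to its reverse complement `−X`. An *adjacency* `a(ci, ci+1)` is a pair of
consecutive blocks, with `a(x, y) ≡ a(−y, −x)`; an adjacency is
*effective* for a genome set when some but not all genomes carry it —
the raw footprint of rearrangement.

For each tree edge `e = (A, B)`, the package assembles candidate
adjacency sets `Ca(e, A)` and `Ca(e, B)`: adjacencies attributable to
each side of the edge, collected by

* **step a** — present in every genome of one side, absent from every
  genome of the other;
* **step b** — present in ≥ 1 genome of each subtree hanging off the
  endpoint, absent from the far side;
* **step c** — propagated up from sub-edge candidate sets through
  block-sharing ("overlap gene") links.

Typed events are then read off the candidate pair by inference rules:
a reversal `r(i, j)` converts `a(c_{i−1}, c_i), a(c_j, c_{j+1})` into
`a(c_{i−1}, −c_j), a(−c_i, c_{j+1})`; the same signature on two
chromosomes is a translocation; a sextuple pattern identifies
transpositions; single split/joined adjacencies identify fissions and
fusions.

Two modes are provided:

* **EMRAE** — the baseline: uncapped adjacencies, steps a–c;
* **RGRPT** — adds a telomere cap `0` at every chromosome end, so events
  at chromosome frontiers leave detectable candidates, plus an extended
  propagation rule that admits a sub-edge candidate whenever every other
  subtree echoes one of its blocks.

A forward simulator evolves an ancestral genome along a tree under a
configurable event mix and logs every applied event per edge, and the
evaluation layer scores predictions against such truth logs
(sensitivity = correct/true, specificity = correct/predicted, maximum
one-to-one matching by edge, type and adjacency signature).

## Worked example

The classic quartet: two leaves carry `1 2 3 4`, two carry `1 −3 −2 4`.

```r
library(rgrpt)
genomes <- list(
  A1 = genome(list(1:4), "A1"), A2 = genome(list(1:4), "A2"),
  B1 = genome(list(c(1,-3,-2,4)), "B1"), B2 = genome(list(c(1,-3,-2,4)), "B2"))
res <- identify_rearrangements(genomes, "((A1,A2),(B1,B2));", method = "rgrpt")
as.data.frame(res)
#>   edge_id ancestor descendant     type       destroyed           created method
#> 1       1       N1         N2 reversal a(-4,2);a(1,-3) a(-4,-3);a(-2,-1)  RGRPT
```

One reversal on the internal edge, nothing anywhere else. The witnesses
are the four effective adjacencies, printed in canonical form
(`a(-4,-3) ≡ a(3,4)`, `a(-2,-1) ≡ a(1,2)`, `a(-4,2) ≡ a(-2,4)`): the
reversal `r(2,3)` destroyed `a(1,2)` and `a(3,4)` on one side of the
edge and created `a(1,-3)` and `a(-2,4)` on the other. Segment ends are
reported in `params`; `tabulate_predictions(res)` gives per-edge,
per-type count tables.

Simulation with ground truth and scoring:

```r
set.seed(7)
sim <- simulate_evolution(caterpillar_newick(5), ancestor_genome(1, 80),
                          k_range = c(3, 10))          # reversals only
sc  <- score_predictions(infer_all(sim$tree, "rgrpt"), sim$truth)
#> true=48 predicted=43 correct=37 sens=0.771 spec=0.860
```

A thin command-line front end lives in `inst/cli/rgrpt.R`
(`simulate`, `infer`, `evaluate` subcommands over GRIMM genome files and
newick trees).

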