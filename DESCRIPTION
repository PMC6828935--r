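Package: rgrpt
Title: Identify Genome Rearrangement Events on a Phylogeny from Signed
    Gene Orders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers reversal, translocation, transposition, fusion and
    fission events on each edge of a rooted phylogenetic tree from the
    signed syntenic-block orders of the leaf genomes.  Implements the
    RGRPT algorithm (telomere-capped candidate adjacencies with an
    extended propagation rule) alongside its EMRAE baseline, a forward
    simulator of genome evolution along a tree with ground-truth event
    logs, GRIMM-format genome I/O, and sensitivity/specificity scoring
    of predicted against simulated events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
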