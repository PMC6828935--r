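# Shared fixtures and independent oracles used across the suite.

# The quartet of the worked reversal example: two leaves carry the
# ancestral order 1 2 3 4, two carry 1 -3 -2 4 (one reversal apart).
quartet_tree <- function() {
  rearr_tree("((A1,A2),(B1,B2));",
             list(A1 = genome(list(1:4), "A1"),
                  A2 = genome(list(1:4), "A2"),
                  B1 = genome(list(c(1L, -3L, -2L, 4L)), "B1"),
                  B2 = genome(list(c(1L, -3L, -2L, 4L)), "B2")))
}

# Two-leaf frontier-reversal instance: B = -2 -1 3 4 is one reversal
# r(1,2) away from C = 1 2 3 4; the event touches the chromosome head.
frontier_pair_tree <- function() {
  rearr_tree("(B,C);",
             list(B = genome(list(c(-2L, -1L, 3L, 4L)), "B"),
                  C = genome(list(1:4), "C")))
}

# Quartet with a mutated clade: leaves P,Q carry the ancestor, R,S the
# mutated genome; the single event separating them sits on the internal
# (root-merged) unit.
planted_quartet <- function(ancestor, mutated) {
  rearr_tree("((P,Q),(R,S));",
             list(P = ancestor, Q = ancestor, R = mutated, S = mutated))
}

adj_codes <- function(pairs) {
  # pairs: list of c(x, y)
  sort(vapply(pairs, function(p) canonical_adjacency(p[1L], p[2L]), 0L))
}

# Random genome: n blocks in random signed order over n_chrom chromosomes.
random_genome <- function(n, n_chrom = 1L, name = "g") {
  v <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
  if (n_chrom == 1L) return(genome(list(v), name))
  cuts <- sort(sample(seq_len(n - 1L), n_chrom - 1L))
  genome(split(v, findInterval(seq_len(n), cuts + 1L)), name)
}

# Brute-force enumeration of every single rearrangement operation
# applicable to g; returns a list of list(type, genome, event).  Used as
# the independent oracle for single-operation inference: it enumerates
# operator applications exhaustively instead of running any candidate or
# rule machinery.  Because the edge between the two quartet clades is
# unoriented, oracle checks enumerate the operations of both endpoint
# genomes and compare signatures in either direction (a fission of one
# genome is a fusion of the other; a rotation-type transposition at a
# chromosome end is, uncapped, exactly a fission+fusion pair).
oracle_all_ops <- function(g) {
  out <- list()
  add <- function(res, type) out[[length(out) + 1L]] <<- list(
    type = type, genome = res$genome, event = res$event)
  lens <- lengths(g$chromosomes)
  for (ci in seq_along(lens)) {
    L <- lens[ci]
    for (i in seq_len(L)) for (j in i:L) {
      if (i == 1L && j == L) next # identity under X == -X
      add(apply_reversal(g, ci, i, j), "reversal")
    }
    for (pos in seq_len(max(L - 1L, 0L)))
      add(apply_fission(g, ci, pos), "fission")
  }
  nc <- length(lens)
  if (nc >= 2L) {
    for (c1 in seq_len(nc)) for (c2 in seq_len(nc)) {
      if (c1 == c2) next
      for (orient in c("same", "flip"))
        add(apply_fusion(g, c1, c2, orient), "fusion")
      for (i in 2:max(lens[c1], 2L)) for (j in 2:max(lens[c2], 2L)) {
        if (lens[c1] < 2L || lens[c2] < 2L) next
        if (i > lens[c1] || j > lens[c2]) next
        if (c1 < c2) {
          add(apply_translocation(g, c1, c2, i, j, "prefix-prefix"),
              "translocation")
        }
        add(apply_translocation(g, c1, c2, i, j, "prefix-suffix"),
            "translocation")
      }
    }
  }
  for (ci in seq_along(lens)) {
    L <- lens[ci]
    if (L < 2L) next
    for (i in seq_len(L)) for (j in i:L) {
      if (i == 1L && j == L) next
      for (di in seq_along(lens)) {
        ks <- 0:lens[di]
        if (di == ci) ks <- setdiff(ks, (i - 1L):j)
        for (k in ks)
          add(apply_transposition(g, ci, i, j, dest = di, k = k),
              "transposition")
      }
    }
  }
  out
}

type_class <- function(type) {
  ifelse(type %in% c("fusion", "fission"), "fusfis", type)
}
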