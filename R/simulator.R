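## Forward simulation of genome evolution along a tree ------------------------

#' Caterpillar (ladder) tree in newick
#'
#' @param n number of leaves (>= 2).
#' @param labels leaf labels (default `L1..Ln`).
#' @return newick string, e.g. `"(((L1,L2),L3),L4);"`.
#' @export
caterpillar_newick <- function(n, labels = paste0("L", seq_len(n))) {
  if (n < 2L) stop("need at least 2 leaves")
  s <- sprintf("(%s,%s)", labels[1L], labels[2L])
  for (i in seq_len(n)[-(1:2)]) s <- sprintf("(%s,%s)", s, labels[i])
  paste0(s, ";")
}

#' Ancestral genome with consecutive block labels
#'
#' @param n_chrom number of chromosomes.
#' @param genes_per_chrom blocks per chromosome.
#' @param name genome name.
#' @return a [genome]; chromosome `c` carries labels
#'   `(c-1)*genes_per_chrom + 1 .. c*genes_per_chrom`, all positive.
#' @export
ancestor_genome <- function(n_chrom = 1L, genes_per_chrom = 100L,
                            name = "ancestor") {
  chrs <- lapply(seq_len(n_chrom), function(c)
    seq.int((c - 1L) * genes_per_chrom + 1L, c * genes_per_chrom))
  genome(chrs, name = name)
}

.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

## Uniform (i, j) with i < j over 1..n, excluding the whole-chromosome pair
## (1, n) which is the identity under X == -X.
.sample_span <- function(n) {
  repeat {
    ij <- sort(sample.int(n, 2L))
    if (!(ij[1L] == 1L && ij[2L] == n)) return(ij)
  }
}

## Uniform (i, j) with i <= j, excluding (1, n).
.sample_fragment <- function(n) {
  total <- n * (n + 1L) / 2L
  repeat {
    r <- .sample1(seq_len(total))
    i <- 1L
    while (r > n - i + 1L) { r <- r - (n - i + 1L); i <- i + 1L }
    j <- i + r - 1L
    if (!(i == 1L && j == n)) return(c(i, j))
  }
}

#' Draw and apply one random rearrangement event
#'
#' The event type is drawn with probability proportional to `mix` and
#' resampled (bounded) when structurally impossible for the current
#' genome.  Reversals span a single block with probability
#' `one_gene_ratio` and otherwise a uniform multi-block segment; all
#' placements are uniform among valid ones.  Identity events
#' (whole-chromosome reversals, whole-chromosome transposition fragments,
#' reinsertion at the excision site) are never drawn.
#'
#' @param g a [genome].
#' @param mix named non-negative weights over
#'   `c("reversal","translocation","transposition","fusion","fission")`
#'   (absent names = weight 0).
#' @param one_gene_ratio probability that a reversal spans one block.
#' @return `list(genome =, event =)`.
#' @export
sample_event <- function(g, mix = c(reversal = 1), one_gene_ratio = 0.25) {
  types <- names(mix)[mix > 0]
  if (!length(types)) stop("event mix has no positive weight")
  for (try in seq_len(200L)) {
    type <- if (length(types) == 1L) types else
      sample(types, 1L, prob = mix[types])
    lens <- lengths(g$chromosomes)
    res <- switch(type,
      reversal = {
        if (stats::runif(1L) < one_gene_ratio) {
          elig <- which(lens >= 2L) # a lone flipped block is X == -X
          if (!length(elig)) NULL else {
            ci <- .sample1(rep(elig, lens[elig]))
            pos <- .sample1(seq_len(lens[ci]))
            apply_reversal(g, ci, pos, pos)
          }
        } else {
          npairs <- ifelse(lens >= 3L, lens * (lens - 1L) / 2L - 1L, 0L)
          if (!any(npairs > 0L)) NULL else {
            ci <- .sample1(rep(seq_along(lens), npairs))
            ij <- .sample_span(lens[ci])
            apply_reversal(g, ci, ij[1L], ij[2L])
          }
        }
      },
      translocation = {
        elig <- which(lens >= 2L)
        if (length(elig) < 2L) NULL else {
          cc <- sample(elig, 2L)
          i <- .sample1(2:lens[cc[1L]])
          j <- .sample1(2:lens[cc[2L]])
          mode <- sample(c("prefix-prefix", "prefix-suffix"), 1L)
          apply_translocation(g, cc[1L], cc[2L], i, j, mode)
        }
      },
      transposition = {
        nfrag <- ifelse(lens >= 2L, lens * (lens + 1L) / 2L - 1L, 0L)
        if (!any(nfrag > 0L)) NULL else {
          ci <- .sample1(rep(seq_along(lens), nfrag))
          ij <- .sample_fragment(lens[ci])
          slots <- lapply(seq_along(lens), function(d) {
            ks <- 0:lens[d]
            if (d == ci) ks <- setdiff(ks, (ij[1L] - 1L):ij[2L])
            if (length(ks)) cbind(d, ks) else NULL
          })
          slots <- do.call(rbind, slots)
          if (is.null(slots) || !nrow(slots)) NULL else {
            pick <- slots[.sample1(seq_len(nrow(slots))), ]
            apply_transposition(g, ci, ij[1L], ij[2L],
                                dest = pick[1L], k = pick[2L])
          }
        }
      },
      fusion = {
        if (length(lens) < 2L) NULL else {
          cc <- sample(seq_along(lens), 2L)
          apply_fusion(g, cc[1L], cc[2L], sample(c("same", "flip"), 1L))
        }
      },
      fission = {
        if (!any(lens >= 2L)) NULL else {
          ci <- .sample1(rep(seq_along(lens), pmax(lens - 1L, 0L)))
          apply_fission(g, ci, .sample1(seq_len(lens[ci] - 1L)))
        }
      })
    if (!is.null(res)) return(res)
  }
  stop("no feasible rearrangement event for this genome/mix")
}

#' Simulate genome evolution along a rooted tree
#'
#' Traverses the tree in preorder; on each edge draws
#' `k ~ Uniform{k_min..k_max}` and applies `k` random events drawn from
#' `mix`.  Leaves receive the final genomes and every applied event is
#' logged per edge (the ground truth for scoring predictions).
#'
#' @param topology newick string/file or `phylo`; rooted.
#' @param ancestor the root [genome].
#' @param k_range integer vector `c(k_min, k_max)` of events per edge.
#' @param mix event-type weights, see [sample_event()].
#' @param one_gene_ratio probability of a single-block reversal.
#' @return list with `tree` (a [rearr_tree] with simulated leaf genomes
#'   bound), `truth` (per-edge lists of events, names = edge ids),
#'   `ancestor`.
#' @examples
#' sim <- simulate_evolution(caterpillar_newick(4), ancestor_genome(1, 50),
#'                           k_range = c(3, 10))
#' @export
simulate_evolution <- function(topology, ancestor, k_range = c(3L, 10L),
                               mix = c(reversal = 1),
                               one_gene_ratio = 0.25) {
  t <- rearr_tree(topology)
  nedge <- nrow(t$edge)
  node_genomes <- vector("list", max(t$edge))
  node_genomes[[t$root]] <- ancestor
  truth <- vector("list", nedge)
  names(truth) <- as.character(seq_len(nedge))
  for (e in seq_len(nedge)) { # cladewise rows: parents before children
    g <- node_genomes[[t$edge[e, 1L]]]
    k <- .sample1(seq.int(k_range[1L], k_range[2L]))
    evs <- vector("list", if (k > 0L) k else 0L)
    if (k > 0L) for (s in seq_len(k)) {
      res <- sample_event(g, mix = mix, one_gene_ratio = one_gene_ratio)
      g <- res$genome
      ev <- res$event
      ev$edge_id <- e
      evs[[s]] <- ev
    }
    truth[[e]] <- evs
    child <- t$edge[e, 2L]
    g$name <- t$node_names[child]
    node_genomes[[child]] <- g
  }
  leaf_genomes <- node_genomes[seq_len(t$ntip)]
  names(leaf_genomes) <- t$node_names[seq_len(t$ntip)]
  list(tree = bind_genomes(t, leaf_genomes), truth = truth,
       ancestor = ancestor)
}

#' Replay a truth log
#'
#' Re-applies every logged event from the ancestor down the tree and
#' returns the resulting leaf genomes; used to assert log soundness.
#'
#' @param sim result of [simulate_evolution()].
#' @return named list of leaf [genome]s.
#' @export
replay_truth <- function(sim) {
  t <- sim$tree
  node_genomes <- vector("list", max(t$edge))
  node_genomes[[t$root]] <- sim$ancestor
  apply_event <- function(g, ev) {
    p <- ev$params
    switch(ev$type,
      reversal = apply_reversal(g, p$chrom, p$i, p$j),
      translocation = apply_translocation(g, p$c1, p$c2, p$i, p$j, p$mode),
      transposition = apply_transposition(g, p$chrom, p$i, p$j, p$dest, p$k),
      fusion = apply_fusion(g, p$c1, p$c2, p$orient),
      fission = apply_fission(g, p$chrom, p$pos))$genome
  }
  for (e in seq_len(nrow(t$edge))) {
    g <- node_genomes[[t$edge[e, 1L]]]
    for (ev in sim$truth[[e]]) g <- apply_event(g, ev)
    g$name <- t$node_names[t$edge[e, 2L]]
    node_genomes[[t$edge[e, 2L]]] <- g
  }
  out <- node_genomes[seq_len(t$ntip)]
  names(out) <- t$node_names[seq_len(t$ntip)]
  out
}

#' Reversal-only simulation protocol
#'
#' For one leaf count, generates the 11-dataset group: uni-chromosomal
#' ancestors of `m = 50, 60, ..., 150` blocks evolving along a caterpillar
#' topology with `k ~ Uniform{3..10}` reversals per edge and a 1:3
#' one-block : multi-block reversal ratio.
#'
#' @param n_leaves number of leaves (3..10 in the study design).
#' @param seed RNG seed for the whole group.
#' @param m_values ancestor sizes (blocks).
#' @return list of 11 simulation results (see [simulate_evolution()]).
#' @export
protocol_reversal_only <- function(n_leaves, seed = 1L,
                                   m_values = seq(50L, 150L, by = 10L)) {
  set.seed(seed)
  lapply(m_values, function(m)
    simulate_evolution(caterpillar_newick(n_leaves),
                       ancestor_genome(1L, m),
                       k_range = c(3L, 10L),
                       mix = c(reversal = 1),
                       one_gene_ratio = 0.25))
}

#' Mixed-event simulation protocol
#'
#' Ancestor of 5 chromosomes x 100 blocks evolving along a 4-leaf
#' caterpillar with `k ~ Uniform{1..mu}` events per edge drawn from the
#' mix reversal : translocation : transposition : fusion/fission =
#' 10 : 2 : 2 : 0.1 (the fusion/fission weight split evenly).
#'
#' @param mu upper bound of the per-edge event count (6, 12, 18 or 24 in
#'   the study design).
#' @param replicates number of independent datasets.
#' @param seed RNG seed for the whole replicate set.
#' @return list of `replicates` simulation results.
#' @export
protocol_all_events <- function(mu, replicates = 10L, seed = 1L) {
  set.seed(seed)
  mix <- c(reversal = 10, translocation = 2, transposition = 2,
           fusion = 0.05, fission = 0.05)
  lapply(seq_len(replicates), function(r)
    simulate_evolution(caterpillar_newick(4L),
                       ancestor_genome(5L, 100L),
                       k_range = c(1L, mu),
                       mix = mix,
                       one_gene_ratio = 0.25))
}
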