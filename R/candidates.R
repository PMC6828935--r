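## Candidate adjacency sets Ca(e, N) ------------------------------------------
##
## For an edge e = (A, B) and endpoint A, the candidate set Ca(e, A)
## collects adjacencies attributable to A's side of the tree:
##
##   step a: adjacencies in every genome of S_A and in no genome of S_B;
##   step b: adjacencies in >= 1 genome of each subtree hanging off A
##           (away from e) and in no genome of S_B;
##   step c: adjacencies propagated from the sub-edge candidate sets
##           Ca(e_i, u_i): an adjacency a1 is admitted when it shares no
##           block with the near set of its own sub-edge but is echoed
##           (by shared blocks) through every other subtree;
##   RGRPT extension: like step c with the blocking conditions waived --
##           a1 only needs a block-sharing partner in every other subtree.
##
## In RGRPT mode all leaf adjacency sets carry telomere caps (0 at each
## chromosome end), so events at chromosome frontiers leave detectable
## candidates; EMRAE mode is uncapped.
##
## The far sets Ca(e_i, u_i) referenced by step c recurse fully (the
## subtree below u_i shrinks strictly, so the recursion is well-founded);
## the near sets Ca(e_i, u) are evaluated with steps a+b only, because a
## fully recursive near set would need Ca(e, A) back.  Results are
## memoized per (edge, endpoint).

.candidate_env <- function(t, mode = c("rgrpt", "emrae")) {
  mode <- match.arg(mode)
  if (is.null(t$genomes)) stop("tree has no bound genomes")
  capped <- mode == "rgrpt"
  env <- new.env(parent = emptyenv())
  env$mode <- mode
  env$leaf_adjs <- lapply(t$genomes, adjacencies, capped = capped)
  env$ab <- new.env(parent = emptyenv())
  env$full <- new.env(parent = emptyenv())
  env$tree <- t
  env
}

.union_over <- function(env, leaves) {
  if (!length(leaves)) return(integer(0))
  sort(unique(unlist(env$leaf_adjs[leaves], use.names = FALSE)))
}

.intersect_over <- function(env, leaves) {
  Reduce(intersect, env$leaf_adjs[leaves])
}

## Absolute non-cap labels occurring in a code set.
.label_union <- function(codes) {
  if (!length(codes)) return(integer(0))
  m <- abs(decode_adjacency(codes))
  unique(m[m != 0L])
}

## Steps a + b for (edge, node) in the unrooted view; returns list(codes, step).
.ab_set <- function(env, edge_id, node) {
  t <- env$tree
  edge_id <- .resolve_edge(t, edge_id)
  key <- paste0(edge_id, "|", node)
  hit <- env$ab[[key]]
  if (!is.null(hit)) return(hit)
  side_node <- .uside_leaves(t, edge_id, node)
  side_far <- setdiff(t$leaves, side_node)
  far_union <- .union_over(env, side_far)
  a_codes <- sort(setdiff(.intersect_over(env, side_node), far_union))
  b_codes <- integer(0)
  sub <- .uincident_excluding(t, node, edge_id)
  if (length(sub)) {
    per_sub <- lapply(sub, function(ei) {
      ui <- setdiff(.unrooted_ends(t, ei), node)
      .union_over(env, .uside_leaves(t, ei, ui))
    })
    b_codes <- sort(setdiff(setdiff(Reduce(intersect, per_sub), far_union),
                            a_codes))
  }
  res <- list(codes = c(a_codes, b_codes),
              step = c(rep("a", length(a_codes)), rep("b", length(b_codes))))
  env$ab[[key]] <- res
  res
}

## Full candidate sets (steps a, b, c and, in RGRPT mode, the extension)
## for every (edge, endpoint) pair of the unrooted tree, computed jointly
## as a least fixpoint: the near sets Ca(e_i, u) referenced by the
## admission conditions stay pinned to their direct (a+b) evidence, the
## far sets Ca(e_i, u_i) start from a+b and are swept repeatedly so that
## admissions can propagate along arbitrarily long paths.  With the near
## sets fixed, every admission condition is monotone in the far sets, so
## the sweeps converge.
.compute_full_sets <- function(env) {
  t <- env$tree
  pairs <- list()
  for (e in t$inference_edges)
    for (node in .unrooted_ends(t, e))
      pairs[[paste0(e, "|", node)]] <- list(edge = e, node = node)
  sets <- lapply(pairs, function(p) .ab_set(env, p$edge, p$node))
  meta <- lapply(pairs, function(p) {
    side_node <- .uside_leaves(t, p$edge, p$node)
    sub <- .uincident_excluding(t, p$node, p$edge)
    list(sub = sub,
         subkey = vapply(sub, function(ei)
           paste0(ei, "|", setdiff(.unrooted_ends(t, ei), p$node)), ""),
         near_labels = lapply(sub, function(ei)
           .label_union(.ab_set(env, ei, p$node)$codes)),
         side_union = .union_over(env, side_node),
         far_union = .union_over(env, setdiff(t$leaves, side_node)))
  })
  repeat {
    changed <- FALSE
    for (key in names(pairs)) {
      mt <- meta[[key]]
      k <- length(mt$sub)
      if (!k) next
      cur <- sets[[key]]
      info <- lapply(seq_len(k), function(i) {
        far <- sets[[mt$subkey[i]]]$codes
        far_lab <- .adj_block_labels(far)
        qualified <- if (length(far))
          vapply(far_lab, function(l) any(l %in% mt$near_labels[[i]]), TRUE)
        else logical(0)
        list(far = far, far_lab = far_lab,
             qual_labels = unique(unlist(far_lab[qualified], use.names = FALSE)),
             all_labels = unique(unlist(far_lab, use.names = FALSE)))
      })
      for (i in seq_len(k)) {
        fi <- info[[i]]
        for (idx in seq_along(fi$far)) {
          a1 <- fi$far[idx]
          if (a1 %in% cur$codes) next
          ## post-filter: a candidate must occur on this side and nowhere
          ## on the far side of e (holds by construction for steps a/b)
          if (!(a1 %in% mt$side_union) || a1 %in% mt$far_union) next
          lab1 <- fi$far_lab[[idx]]
          others <- setdiff(seq_len(k), i)
          c_ok <- !any(lab1 %in% mt$near_labels[[i]]) &&
            all(vapply(others, function(j) any(lab1 %in% info[[j]]$qual_labels),
                       TRUE))
          if (c_ok) {
            cur$codes <- c(cur$codes, a1); cur$step <- c(cur$step, "c")
            changed <- TRUE
          } else if (env$mode == "rgrpt") {
            ext_ok <- all(vapply(others,
                                 function(j) any(lab1 %in% info[[j]]$all_labels),
                                 TRUE))
            if (ext_ok) {
              cur$codes <- c(cur$codes, a1)
              cur$step <- c(cur$step, "rgrpt-b-extension")
              changed <- TRUE
            }
          }
        }
      }
      sets[[key]] <- cur
    }
    if (!changed) break
  }
  for (key in names(sets)) {
    ord <- order(sets[[key]]$codes)
    env$full[[key]] <- list(codes = sets[[key]]$codes[ord],
                            step = sets[[key]]$step[ord])
  }
  env$full_done <- TRUE
}

.full_set <- function(env, edge_id, node) {
  t <- env$tree
  edge_id <- .resolve_edge(t, edge_id)
  key <- paste0(edge_id, "|", node)
  if (!isTRUE(env$full_done)) .compute_full_sets(env)
  res <- env$full[[key]]
  if (is.null(res)) stop("no candidate set for edge ", edge_id, ", node ", node)
  res
}

#' Candidate adjacency set for one edge endpoint
#'
#' Computes `Ca(e, N)`: the adjacencies attributed to node `N`'s side of
#' edge `e` by the candidate-selection steps (a, b, c and, in RGRPT mode,
#' the extended propagation rule over telomere-capped adjacencies).
#'
#' @param t a [rearr_tree] with bound genomes.
#' @param edge_id edge id.
#' @param node node id (an endpoint of `edge_id`).
#' @param mode `"rgrpt"` (telomere caps, extended rule) or `"emrae"`.
#' @param env optional precomputed environment from repeated calls (used
#'   internally by [infer_all()]); pass the same `env` to share memoized
#'   results across edges.
#' @return list with `edge_id`, `node`, `adjacencies` (sorted canonical
#'   codes) and `step` (the first-admitting step per adjacency, one of
#'   `"a"`, `"b"`, `"c"`, `"rgrpt-b-extension"`).
#' @export
candidates <- function(t, edge_id, node, mode = c("rgrpt", "emrae"), env = NULL) {
  mode <- match.arg(mode)
  if (is.null(env)) env <- .candidate_env(t, mode)
  node <- .resolve_node(t, edge_id, node)
  edge_id <- .resolve_edge(t, edge_id)
  fs <- .full_set(env, edge_id, node)
  list(edge_id = edge_id, node = node, adjacencies = fs$codes, step = fs$step)
}

#' All candidate sets of a tree
#'
#' Computes `Ca(e, N)` for every edge and both endpoints (the two root
#' child edges are merged into one inference unit).
#'
#' @inheritParams candidates
#' @return a data.frame with one row per admitted adjacency: `edge_id`,
#'   `node` (node name), `adjacency` (formatted), `code`, `step`.
#' @export
candidate_sets <- function(t, mode = c("rgrpt", "emrae")) {
  mode <- match.arg(mode)
  env <- .candidate_env(t, mode)
  rows <- list()
  for (e in t$inference_edges) {
    for (node in .unrooted_ends(t, e)) {
      fs <- .full_set(env, e, node)
      if (!length(fs$codes)) next
      rows[[length(rows) + 1L]] <- data.frame(
        edge_id = e, node = t$node_names[node],
        adjacency = format_adjacency(fs$codes),
        code = fs$codes, step = fs$step, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(edge_id = integer(0), node = character(0),
                      adjacency = character(0), code = integer(0),
                      step = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
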