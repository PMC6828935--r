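## Rooted phylogeny with genome-bearing leaves --------------------------------
##
## Thin wrapper around an ape "phylo" object.  Edges get stable integer ids
## (rows of the cladewise/preorder edge matrix), every edge knows the leaf
## set below its child, and leaves are bound to genomes by name.
##
## A rooted binary tree always has a degree-2 root, so its two root child
## edges cut the leaf set identically and are indistinguishable as
## inference units; they are merged into a single unrooted edge represented
## by the first of the two (the other id aliases to it).

#' Build a phylogeny for rearrangement inference
#'
#' @param tree a newick string, a path readable by [ape::read.tree()], or a
#'   `phylo` object.  Must be rooted with at least 2 uniquely-named leaves;
#'   branch lengths are ignored; internal labels are honored when present,
#'   otherwise nodes are auto-named deterministically.
#' @param genomes optional named list of [genome] objects covering every
#'   leaf name (can be bound later with [bind_genomes()]).
#' @return an object of class `"rearr_tree"`.
#' @examples
#' tr <- rearr_tree("((L1,L2),(L3,L4));")
#' @export
rearr_tree <- function(tree, genomes = NULL) {
  if (inherits(tree, "phylo")) {
    phy <- tree
  } else if (is.character(tree) && length(tree) == 1L) {
    phy <- if (grepl("\\(", tree)) ape::read.tree(text = tree)
           else ape::read.tree(tree)
  } else stop("tree must be a newick string, a file path, or a phylo object")
  if (is.null(phy)) stop("failed to parse newick tree")
  if (length(phy$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  phy <- stats::reorder(phy, "cladewise") # preorder; stable edge ids
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root <- ntip + 1L
  node_names <- character(ntip + nnode)
  node_names[seq_len(ntip)] <- phy$tip.label
  auto <- paste0("N", seq_len(nnode))
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    auto[nzchar(lab)] <- lab[nzchar(lab)]
  }
  node_names[ntip + seq_len(nnode)] <- auto
  E <- phy$edge
  nedge <- nrow(E)
  ## leaf sets below each edge's child, by postorder accumulation
  below <- vector("list", ntip + nnode)
  for (v in seq_len(ntip)) below[[v]] <- v
  po <- rev(seq_len(nedge)) # cladewise rows reversed ~ children before parents
  for (r in po) below[[E[r, 1L]]] <- c(below[[E[r, 1L]]], below[[E[r, 2L]]])
  leaves_below <- lapply(seq_len(nedge), function(r)
    sort(node_names[below[[E[r, 2L]]][below[[E[r, 2L]]] <= ntip]]))
  root_edges <- which(E[, 1L] == root)
  merged_alias <- integer(0)
  inference_edges <- seq_len(nedge)
  if (length(root_edges) == 2L) {
    rep_edge <- min(root_edges)
    merged_alias <- stats::setNames(rep_edge, max(root_edges))
    inference_edges <- setdiff(inference_edges, max(root_edges))
  }
  t <- structure(list(
    phy = phy, ntip = ntip, root = root, edge = E,
    node_names = node_names, leaves = sort(phy$tip.label),
    leaves_below = leaves_below,
    root_edges = root_edges, merged_alias = merged_alias,
    inference_edges = inference_edges,
    genomes = NULL), class = "rearr_tree")
  if (!is.null(genomes)) t <- bind_genomes(t, genomes)
  t
}

#' Bind leaf genomes to a phylogeny
#'
#' @param t a `rearr_tree`.
#' @param genomes named list of [genome] objects; names must cover every
#'   leaf of the tree.
#' @return the tree with genomes bound.
#' @export
bind_genomes <- function(t, genomes) {
  if (is.null(names(genomes)) || !all(nzchar(names(genomes))))
    names(genomes) <- vapply(genomes, function(g) g$name, "")
  missing <- setdiff(t$leaves, names(genomes))
  if (length(missing))
    stop("no genome bound for leaf/leaves: ", paste(missing, collapse = ", "))
  t$genomes <- genomes[t$leaves]
  t
}

#' @export
print.rearr_tree <- function(x, ...) {
  cat(sprintf("Rearrangement phylogeny: %d leaves, %d edges (%d inference units)%s\n",
              x$ntip, nrow(x$edge), length(x$inference_edges),
              if (is.null(x$genomes)) ", genomes unbound" else ""))
  invisible(x)
}

#' Number of edges and edge endpoints
#'
#' @param t a `rearr_tree`.
#' @param edge_id edge id (row of the preorder edge matrix).
#' @return `edge_endpoints()`: named integer vector with `parent` and
#'   `child` node ids.
#' @export
edge_endpoints <- function(t, edge_id) {
  if (edge_id < 1L || edge_id > nrow(t$edge)) stop("unknown edge: ", edge_id)
  c(parent = t$edge[edge_id, 1L], child = t$edge[edge_id, 2L])
}

#' Leaf bipartition induced by removing an edge
#'
#' @param t a `rearr_tree`.
#' @param edge_id edge id.
#' @return list with `side_A` (leaves on the parent side) and `side_B`
#'   (leaves below the child), both character vectors of leaf names.
#' @export
edge_partition <- function(t, edge_id) {
  if (edge_id < 1L || edge_id > nrow(t$edge)) stop("unknown edge: ", edge_id)
  below <- t$leaves_below[[edge_id]]
  list(side_A = setdiff(t$leaves, below), side_B = below)
}

## Leaves on `node`'s side of edge `edge_id` (node must be an endpoint).
.side_leaves <- function(t, edge_id, node) {
  ends <- t$edge[edge_id, ]
  below <- t$leaves_below[[edge_id]]
  if (node == ends[2L]) below
  else if (node == ends[1L]) setdiff(t$leaves, below)
  else stop("node ", node, " is not an endpoint of edge ", edge_id)
}

#' Edges incident to a node, excluding one
#'
#' Lists the edges meeting `node` other than `edge_id`, in increasing edge
#' id order (deterministic).  Leaves have no other incident edges.
#'
#' @param t a `rearr_tree`.
#' @param node node id (an endpoint of `edge_id`).
#' @param edge_id the excluded edge.
#' @return integer vector of edge ids.
#' @export
incident_edges_excluding <- function(t, node, edge_id) {
  ends <- t$edge[edge_id, ]
  if (!(node %in% ends)) stop("node ", node, " is not an endpoint of edge ", edge_id)
  inc <- which(t$edge[, 1L] == node | t$edge[, 2L] == node)
  sort(setdiff(inc, edge_id))
}

## Resolve an edge id through the root merge (events logged on either root
## child edge belong to the same unrooted inference unit).
.resolve_edge <- function(t, edge_id) {
  a <- t$merged_alias[as.character(edge_id)]
  if (length(a) == 1L && !is.na(a)) unname(a) else edge_id
}

## Unrooted view: a degree-2 root is suppressed, so the merged root unit's
## endpoints are the two root children.  Candidate-set construction and
## inference work on this view; node "A" is the ancestor-ish endpoint.
.unrooted_ends <- function(t, edge_id) {
  edge_id <- .resolve_edge(t, edge_id)
  if (length(t$merged_alias) && edge_id == unname(t$merged_alias))
    c(A = t$edge[as.integer(names(t$merged_alias)), 2L],
      B = t$edge[edge_id, 2L])
  else c(A = t$edge[edge_id, 1L], B = t$edge[edge_id, 2L])
}

## Map a rooted endpoint query to the unrooted view: the root stands for
## the far root child of whichever root edge is queried.
.resolve_node <- function(t, edge_id, node) {
  if (length(t$merged_alias) && node == t$root) {
    if (!(edge_id %in% t$root_edges))
      stop("node ", node, " is not an endpoint of edge ", edge_id)
    other <- setdiff(t$root_edges, edge_id)
    t$edge[other, 2L]
  } else node
}

## Leaves on `node`'s side of the (unrooted) edge.
.uside_leaves <- function(t, edge_id, node) {
  ends <- .unrooted_ends(t, edge_id)
  below <- t$leaves_below[[.resolve_edge(t, edge_id)]]
  if (node == ends["B"]) below
  else if (node == ends["A"]) setdiff(t$leaves, below)
  else stop("node ", node, " is not an endpoint of edge ", edge_id)
}

## Edges incident to `node` in the unrooted view, excluding `edge_id`
## (ids resolved through the root merge, deduplicated, sorted).
.uincident_excluding <- function(t, node, edge_id) {
  inc <- which(t$edge[, 1L] == node | t$edge[, 2L] == node)
  inc <- unique(vapply(inc, function(e) .resolve_edge(t, e), 0L))
  sort(setdiff(inc, .resolve_edge(t, edge_id)))
}

#' Human-readable edge names
#'
#' Edges are named after their child endpoint (the descendant), matching
#' the per-edge rows of rearrangement tables.
#'
#' @param t a `rearr_tree`.
#' @param edge_id integer vector of edge ids.
#' @return character vector.
#' @export
edge_name <- function(t, edge_id) {
  t$node_names[t$edge[edge_id, 2L]]
}
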