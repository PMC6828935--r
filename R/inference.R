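## Event inference from candidate-set pairs -----------------------------------
##
## For each edge e = (A, B) with A the ancestor endpoint, destroyed
## adjacencies are looked up in Ca(e, A) and created adjacencies in
## Ca(e, B).  Rule families run in fixed order (reversal/translocation,
## then transposition, then fusion/fission); candidates are enumerated in
## canonical sort order, each match consumes its witnesses, and no
## adjacency witnesses two events on the same edge.
##
## Writing an adjacency in an oriented reading (p, q) -- each canonical
## code has two readings under a(x,y) == a(-y,-x) -- the reversal r(i,j)
## signature is
##   a1 = (p, q) = a(c_{i-1}, c_i),  a2 = (r, s) = a(c_j, c_{j+1})
##   b1 = a(p, -r),                  b2 = a(-q, s)
## which also covers the prefix-suffix translocation exchange; the
## prefix-prefix exchange (b1 = a(p, s), b2 = a(r, q)) is this same
## signature applied to the flipped reading of a2, so one matcher over
## both readings of every adjacency covers both published patterns.
## Reversal vs translocation is decided by the co-chromosome test.

## Per-leaf block location index: chromosome id and signed value per label.
.block_locations <- function(g) {
  labs <- abs(unlist(g$chromosomes, use.names = FALSE))
  mx <- max(labs)
  chrom <- integer(mx); val <- integer(mx)
  for (ci in seq_along(g$chromosomes)) {
    v <- g$chromosomes[[ci]]
    chrom[abs(v)] <- ci
    val[abs(v)] <- v
  }
  list(chrom = chrom, val = val)
}

.infer_context <- function(t) {
  list(loc = lapply(t$genomes, .block_locations),
       capped_adjs = lapply(t$genomes, adjacencies, capped = TRUE),
       all_uni = all(vapply(t$genomes, function(g)
         length(g$chromosomes) == 1L, TRUE)))
}

## Do all labels sit on one chromosome in at least one of `leaves`?
.co_chromosomal <- function(labels, leaves, ctx) {
  labels <- labels[labels != 0L]
  if (length(labels) < 2L) return(TRUE)
  for (lf in leaves) {
    ch <- ctx$loc[[lf]]$chrom
    if (max(labels) > length(ch)) next
    cc <- ch[labels]
    if (all(cc != 0L) && all(cc == cc[1L])) return(TRUE)
  }
  FALSE
}

## Do the two label groups sit on two different chromosomes (each group
## on one) in at least one of `leaves`?  The exchange configuration of a
## genuine translocation.
.on_two_chromosomes <- function(lab1, lab2, leaves, ctx) {
  lab1 <- lab1[lab1 != 0L]; lab2 <- lab2[lab2 != 0L]
  if (!length(lab1) || !length(lab2)) return(FALSE)
  for (lf in leaves) {
    ch <- ctx$loc[[lf]]$chrom
    if (max(lab1, lab2) > length(ch)) next
    c1 <- ch[lab1]; c2 <- ch[lab2]
    if (all(c(c1, c2) != 0L) && all(c1 == c1[1L]) && all(c2 == c2[1L]) &&
        c1[1L] != c2[1L]) return(TRUE)
  }
  FALSE
}

## Sign compatibility of a split adjacency a(x, y) with a leaf genome.
## Splitting a(x, y) leaves x at the tail of one fragment and y at the
## head of the other, orientation preserved; under X == -X that is
## exactly "the capped adjacencies a(x, 0) and a(0, y) are adjacencies of
## the genome".  A genome is sign-compatible with the fission when both
## caps are present, i.e. x can close a chromosome and y can open one
## with the signs the split implies.
.sign_compatible <- function(x, y, caps) {
  (canonical_adjacency(x, 0L) %in% caps) &&
    (canonical_adjacency(0L, y) %in% caps)
}

## Oriented lookup index for a candidate code set.
.ori_index <- function(codes) {
  if (!length(codes))
    return(list(m = NULL, by_left = list(), by_right = list()))
  m <- .adj_orientations(codes)
  list(m = m,
       by_left = split(seq_len(nrow(m)), m[, "p"]),
       by_right = split(seq_len(nrow(m)), m[, "q"]))
}

.idx_rows <- function(index, key) {
  r <- index[[as.character(key)]]
  if (is.null(r)) integer(0) else r
}

.new_prediction <- function(type, edge_id, params, destroyed, created, method) {
  ev <- .new_event(type, params, destroyed, created, edge_id = edge_id)
  ev$method <- method
  ev
}

## One edge; returns list of prediction events.
.infer_one_edge <- function(t, edge_id, mode, cenv, ctx,
                            rules = c("reversal", "transposition", "fusfis")) {
  ends <- .unrooted_ends(t, edge_id)
  anc <- ends[["A"]]; desc <- ends[["B"]]
  caA <- .full_set(cenv, edge_id, anc)$codes
  caB <- .full_set(cenv, edge_id, desc)$codes
  preds <- list()
  if (!length(caA) && !length(caB)) return(preds)
  sideA <- .uside_leaves(t, edge_id, anc)
  sideB <- .uside_leaves(t, edge_id, desc)
  consA <- new.env(parent = emptyenv())
  consB <- new.env(parent = emptyenv())
  used <- function(envc, code) isTRUE(envc[[as.character(code)]])
  consume <- function(envc, code) assign(as.character(code), TRUE, envir = envc)
  idxA <- .ori_index(caA)
  idxB <- .ori_index(caB)
  method <- toupper(cenv$mode)

  ## Reversal when the witnesses are co-chromosomal on both sides (or the
  ## data are uni-chromosomal throughout); translocation when they show
  ## the two-chromosome exchange configuration on both sides; a quadruple
  ## showing neither coherent configuration is not an event call.
  ## The configuration tests presuppose a genome that carries both
  ## witnesses of a side, so they are evaluated within witness-bearing
  ## genomes; a quadruple with no coherent configuration on both sides
  ## (co-chromosomal = reversal, two-chromosome exchange = translocation)
  ## is not an event call.
  pair_config <- function(x1, x2, leaves) {
    lab12 <- .label_union(c(x1, x2))
    l1 <- .label_union(x1); l2 <- .label_union(x2)
    co <- FALSE; two <- FALSE
    for (lf in leaves) {
      adj <- cenv$leaf_adjs[[lf]]
      if (!((x1 %in% adj) && (x2 %in% adj))) next
      if (!co) co <- .co_chromosomal(lab12, lf, ctx)
      if (!two) two <- .on_two_chromosomes(l1, l2, lf, ctx)
      if (co && two) break
    }
    c(co = co, two = two)
  }
  decide_rt <- function(a1, a2, b1, b2) {
    if (ctx$all_uni) return("reversal")
    cfA <- pair_config(a1, a2, sideA)
    cfB <- pair_config(b1, b2, sideB)
    if (cfA[["co"]] && cfB[["co"]]) return("reversal")
    if (cfA[["two"]] && cfB[["two"]]) return("translocation")
    NA_character_
  }

  ## -- reversals / translocations -------------------------------------------
  ## Two passes over the same signature: the rule's primary branch
  ## (reversal) consumes its witnesses first, then the remaining
  ## candidates may pair into two-chromosome exchanges (translocations).
  if ("reversal" %in% rules) for (want in c("reversal", "translocation")) {
    if (want == "translocation" && ctx$all_uni) break
    for (a1 in caA) {
      if (used(consA, a1)) next
      done <- FALSE
      oris1 <- which(idxA$m[, "code"] == a1)
      for (o1 in oris1) {
        p <- idxA$m[o1, "p"]; q <- idxA$m[o1, "q"]
        if (q == 0L) next # c_i is a real block
        for (ob1 in .idx_rows(idxB$by_left, p)) {
          b1 <- idxB$m[ob1, "code"]
          if (used(consB, b1)) next
          z <- idxB$m[ob1, "q"]
          if (z == 0L) next # -c_j is a real block
          r <- -z
          for (oa2 in .idx_rows(idxA$by_left, r)) {
            a2 <- idxA$m[oa2, "code"]
            if (a2 == a1 || used(consA, a2)) next
            s <- idxA$m[oa2, "q"]
            if (q == 0L && s == 0L) next
            b2 <- canonical_adjacency(-q, s)
            if (b2 == b1 || !(b2 %in% caB) || used(consB, b2)) next
            type <- decide_rt(a1, a2, b1, b2)
            if (is.na(type) || type != want) next
            preds[[length(preds) + 1L]] <- .new_prediction(
              type, edge_id, list(ci = q, cj = r),
              destroyed = c(a1, a2), created = c(b1, b2), method = method)
            consume(consA, a1); consume(consA, a2)
            consume(consB, b1); consume(consB, b2)
            done <- TRUE
            break
          }
          if (done) break
        }
        if (done) break
      }
    }
  }

  ## -- transpositions --------------------------------------------------------
  if ("transposition" %in% rules) for (a1 in caA) {
    if (used(consA, a1)) next
    done <- FALSE
    oris1 <- which(idxA$m[, "code"] == a1)
    for (o1 in oris1) {
      p <- idxA$m[o1, "p"]; q <- idxA$m[o1, "q"]
      if (q == 0L) next # c_i real
      for (ob1 in .idx_rows(idxB$by_left, p)) {
        b1 <- idxB$m[ob1, "code"]
        if (used(consB, b1)) next
        s <- idxB$m[ob1, "q"] # c_{j+1}
        for (oa2 in .idx_rows(idxA$by_right, s)) {
          a2 <- idxA$m[oa2, "code"]
          if (a2 == a1 || used(consA, a2)) next
          r <- idxA$m[oa2, "p"] # c_j
          if (r == 0L) next
          for (ob2 in .idx_rows(idxB$by_right, q)) {
            b2 <- idxB$m[ob2, "code"]
            if (b2 == b1 || used(consB, b2)) next
            tt <- idxB$m[ob2, "p"] # c_k (0 = head insertion)
            for (oa3 in .idx_rows(idxA$by_left, tt)) {
              a3 <- idxA$m[oa3, "code"]
              if (a3 == a1 || a3 == a2 || used(consA, a3)) next
              u <- idxA$m[oa3, "q"] # c_{k+1}
              if (r == 0L && u == 0L) next
              b3 <- canonical_adjacency(r, u)
              if (b3 == b1 || b3 == b2 || !(b3 %in% caB) || used(consB, b3)) next
              ok <- ctx$all_uni
              if (!ok) {
                ## m genomes of S_A carry a1 and a2; >= m/2 of the leaf
                ## genomes must place the blocks of a1+a2 (or a2+a3) on one
                ## chromosome
                la12 <- .label_union(c(a1, a2))
                la23 <- .label_union(c(a2, a3))
                have12 <- vapply(sideA, function(lf) {
                  adj <- cenv$leaf_adjs[[lf]]
                  (a1 %in% adj) && (a2 %in% adj)
                }, TRUE)
                m <- sum(have12)
                n12 <- sum(vapply(sideA, function(lf)
                  .co_chromosomal(la12, lf, ctx), TRUE))
                n23 <- sum(vapply(sideA, function(lf)
                  .co_chromosomal(la23, lf, ctx), TRUE))
                ok <- m >= 1L && ((2L * n12 >= m) || (2L * n23 >= m))
              }
              if (!ok) next
              preds[[length(preds) + 1L]] <- .new_prediction(
                "transposition", edge_id, list(ci = q, cj = r, ck = tt),
                destroyed = c(a1, a2, a3), created = c(b1, b2, b3),
                method = method)
              consume(consA, a1); consume(consA, a2); consume(consA, a3)
              consume(consB, b1); consume(consB, b2); consume(consB, b3)
              done <- TRUE
              break
            }
            if (done) break
          }
          if (done) break
        }
        if (done) break
      }
      if (done) break
    }
  }

  ## -- fusions / fissions ----------------------------------------------------
  ## RGRPT first pairs an interior adjacency on one side with its two
  ## telomere caps on the other (the exact capped signature of a fission
  ## or fusion); remaining single candidates use the sign-compatibility
  ## rule, additionally requiring the two blocks to be separated onto
  ## different chromosomes in at least one far-side genome.
  fifu <- function(codes_from, cons_from, cons_to, set_to, type, far_leaves) {
    for (a in codes_from) {
      if (used(cons_from, a)) next
      m <- decode_adjacency(a)
      x <- m[1L]; y <- m[2L]
      if (x == 0L || y == 0L) next
      capL <- canonical_adjacency(x, 0L)
      capR <- canonical_adjacency(0L, y)
      hit <- FALSE
      if (cenv$mode == "rgrpt" &&
          (capL %in% set_to) && !used(cons_to, capL) &&
          (capR %in% set_to) && !used(cons_to, capR)) {
        hit <- TRUE
        consume(cons_to, capL); consume(cons_to, capR)
      } else {
        ok <- all(vapply(far_leaves, function(lf)
          .sign_compatible(x, y, ctx$capped_adjs[[lf]]), TRUE))
        if (ok) hit <- TRUE
      }
      if (hit) {
        consume(cons_from, a)
        if (type == "fission")
          preds[[length(preds) + 1L]] <<- .new_prediction(
            "fission", edge_id, list(cx = x, cy = y),
            destroyed = a, created = c(capL, capR), method = method)
        else
          preds[[length(preds) + 1L]] <<- .new_prediction(
            "fusion", edge_id, list(cx = x, cy = y),
            destroyed = c(capL, capR), created = a, method = method)
      }
    }
  }
  if ("fusfis" %in% rules) {
    fifu(caA, consA, consB, caB, "fission", sideB)
    fifu(caB, consB, consA, caA, "fusion", sideA)
  }
  preds
}

#' Infer rearrangement events on one edge
#'
#' @param t a [rearr_tree] with bound genomes.
#' @param edge_id edge id (one of `t$inference_edges`).
#' @param mode `"rgrpt"` or `"emrae"`.
#' @return list of prediction events (class `rearrangement_event` with a
#'   `method` field); `destroyed` adjacencies come from the ancestor-side
#'   candidate set and `created` from the descendant side.
#' @export
infer_edge <- function(t, edge_id, mode = c("rgrpt", "emrae")) {
  mode <- match.arg(mode)
  cenv <- .candidate_env(t, mode)
  .infer_one_edge(t, edge_id, mode, cenv, .infer_context(t))
}

#' Infer rearrangement events on every edge
#'
#' Runs the inference rules over all inference units of the tree (the two
#' root child edges count as one unrooted unit).
#'
#' @param t a [rearr_tree] with bound genomes.
#' @param mode `"rgrpt"` or `"emrae"`.
#' @param rules rule families to run, a subset of
#'   `c("reversal", "transposition", "fusfis")` (`"reversal"` covers the
#'   joint reversal/translocation rule).  Restricting the families is
#'   useful for studies of a single event class.
#' @return object of class `rearrangement_predictions`: list with
#'   `predictions` (per-edge lists of events), `tree`, `mode`.
#' @export
infer_all <- function(t, mode = c("rgrpt", "emrae"),
                      rules = c("reversal", "transposition", "fusfis")) {
  mode <- match.arg(mode)
  rules <- match.arg(rules, several.ok = TRUE)
  if (is.null(t$genomes)) stop("tree has unbound leaves; use bind_genomes()")
  cenv <- .candidate_env(t, mode)
  ctx <- .infer_context(t)
  preds <- lapply(t$inference_edges, function(e)
    .infer_one_edge(t, e, mode, cenv, ctx, rules))
  names(preds) <- as.character(t$inference_edges)
  structure(list(predictions = preds, tree = t, mode = mode),
            class = "rearrangement_predictions")
}

#' @export
print.rearrangement_predictions <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("%s predictions: %d events on %d edges\n", toupper(x$mode),
              nrow(df), length(x$predictions)))
  if (nrow(df)) print(utils::head(df, 20L))
  invisible(x)
}

#' @export
as.data.frame.rearrangement_predictions <- function(x, ...) {
  rows <- list()
  t <- x$tree
  for (e in names(x$predictions)) {
    eid <- as.integer(e)
    anc <- t$node_names[t$edge[eid, 1L]]
    desc <- t$node_names[t$edge[eid, 2L]]
    for (ev in x$predictions[[e]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        edge_id = eid, ancestor = anc, descendant = desc, type = ev$type,
        destroyed = paste(format_adjacency(ev$destroyed), collapse = ";"),
        created = paste(format_adjacency(ev$created), collapse = ";"),
        method = ev$method, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(edge_id = integer(0), ancestor = character(0),
                      descendant = character(0), type = character(0),
                      destroyed = character(0), created = character(0),
                      method = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Per-edge, per-type prediction counts
#'
#' Tabulates an [infer_all()] result in the layout of published per-edge
#' rearrangement tables (fusions and fissions pooled).
#'
#' @param x a `rearrangement_predictions` object.
#' @return data.frame with one row per edge plus a `Total` row.
#' @export
tabulate_predictions <- function(x) {
  t <- x$tree
  types <- c(reversal = "Rev", translocation = "Tloc",
             transposition = "Tran", fusion = "FusFis", fission = "FusFis")
  eids <- as.integer(names(x$predictions))
  out <- data.frame(edge = edge_name(t, eids),
                    Rev = 0L, Tloc = 0L, Tran = 0L, FusFis = 0L,
                    Total = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(eids)) {
    for (ev in x$predictions[[i]]) {
      col <- types[[ev$type]]
      out[i, col] <- out[i, col] + 1L
      out[i, "Total"] <- out[i, "Total"] + 1L
    }
  }
  total <- data.frame(edge = "Total", Rev = sum(out$Rev), Tloc = sum(out$Tloc),
                      Tran = sum(out$Tran), FusFis = sum(out$FusFis),
                      Total = sum(out$Total), stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Identify rearrangements from genomes and a newick tree
#'
#' Convenience wrapper: binds genomes to the tree and runs [infer_all()].
#'
#' @param genomes named list of [genome] objects (or a GRIMM file path).
#' @param tree newick string/file or `phylo` object.
#' @param method `"rgrpt"` or `"emrae"`.
#' @return a `rearrangement_predictions` object.
#' @export
identify_rearrangements <- function(genomes, tree,
                                    method = c("rgrpt", "emrae")) {
  method <- match.arg(method)
  if (is.character(genomes)) genomes <- read_grimm(genomes)
  infer_all(rearr_tree(tree, genomes), mode = method)
}
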