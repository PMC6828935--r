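## Scoring predictions against simulation truth logs --------------------------
##
## "Correctly predicted" is not something the truth log hands us directly:
## the same physical event can be described by different index tuples, so
## predictions and true events are compared by (edge, event type,
## adjacency signature).  A prediction matches a true event when both sit
## on the same inference unit, have the same type (fusions and fissions
## pooled), and their created-adjacency sets intersect (criterion
## "overlap", the default) or are equal (criterion "strict").  On the
## merged root unit event direction is unobservable, so a prediction's
## destroyed set may stand in for its created set there.  Each true event
## matches at most one prediction and vice versa (maximum bipartite
## matching, deterministic order).

.type_class <- function(type) {
  ifelse(type %in% c("fusion", "fission"), "fusfis", type)
}

## Kuhn's augmenting-path maximum bipartite matching on a logical matrix.
.max_bipartite <- function(compat) {
  np <- nrow(compat); nt <- ncol(compat)
  match_t <- integer(nt) # truth -> pred (0 = unmatched)
  augment <- function(p, seen) {
    for (tt in seq_len(nt)) {
      if (compat[p, tt] && !seen[tt]) {
        seen[tt] <- TRUE
        if (match_t[tt] == 0L || Recall(match_t[tt], seen)$ok) {
          match_t[tt] <<- p
          return(list(ok = TRUE))
        }
      }
    }
    list(ok = FALSE)
  }
  for (p in seq_len(np)) augment(p, logical(nt))
  match_t
}

#' Match predictions against a truth log
#'
#' @param preds a `rearrangement_predictions` object (from [infer_all()]).
#' @param truth per-edge truth log from [simulate_evolution()] (the `truth`
#'   element), logged on the same tree.
#' @param criterion `"overlap"` (created sets intersect) or `"strict"`
#'   (created sets equal).
#' @return data.frame of matched pairs: `edge_id`, `type`, `pred_index`,
#'   `truth_index` (indices within the per-unit lists).
#' @export
match_events <- function(preds, truth, criterion = c("overlap", "strict")) {
  criterion <- match.arg(criterion)
  t <- preds$tree
  if (length(truth) != nrow(t$edge))
    stop("truth log and tree disagree on the number of edges")
  ## pool truth events onto inference units through the root merge
  units <- as.character(t$inference_edges)
  tr_units <- stats::setNames(vector("list", length(units)), units)
  for (e in seq_along(truth)) {
    u <- as.character(.resolve_edge(t, e))
    tr_units[[u]] <- c(tr_units[[u]], truth[[e]])
  }
  merged_unit <- if (length(t$merged_alias)) as.character(unname(t$merged_alias))
                 else ""
  pairs <- list()
  for (u in units) {
    pl <- preds$predictions[[u]]
    tl <- tr_units[[u]]
    if (!length(pl) || !length(tl)) next
    symmetric <- identical(u, merged_unit)
    compat <- matrix(FALSE, length(pl), length(tl))
    for (ip in seq_along(pl)) for (it in seq_along(tl)) {
      p <- pl[[ip]]; tv <- tl[[it]]
      if (.type_class(p$type) != .type_class(tv$type)) next
      hit <- if (criterion == "overlap")
        length(intersect(p$created, tv$created)) > 0L
      else setequal(p$created, tv$created)
      if (!hit && symmetric) {
        hit <- if (criterion == "overlap")
          length(intersect(p$destroyed, tv$created)) > 0L
        else setequal(p$destroyed, tv$created)
      }
      compat[ip, it] <- hit
    }
    m <- .max_bipartite(compat)
    for (it in which(m > 0L))
      pairs[[length(pairs) + 1L]] <- data.frame(
        edge_id = as.integer(u), type = .type_class(tl[[it]]$type),
        pred_index = m[it], truth_index = it, stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(data.frame(edge_id = integer(0), type = character(0),
                      pred_index = integer(0), truth_index = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}

#' Sensitivity and specificity of predictions
#'
#' Sensitivity is the fraction of true events correctly predicted;
#' specificity the fraction of predictions that are correct.  Undefined
#' ratios (zero denominator) are reported as `NA`, not 0.
#'
#' @inheritParams match_events
#' @return list with `n_true`, `n_predicted`, `n_correct`, `sensitivity`,
#'   `specificity` and a per-type breakdown data.frame `by_type`.
#' @export
score_predictions <- function(preds, truth,
                              criterion = c("overlap", "strict")) {
  criterion <- match.arg(criterion)
  matched <- match_events(preds, truth, criterion)
  all_truth <- unlist(truth, recursive = FALSE)
  all_pred <- unlist(preds$predictions, recursive = FALSE)
  tr_types <- .type_class(vapply(all_truth, function(e) e$type, ""))
  pr_types <- .type_class(vapply(all_pred, function(e) e$type, ""))
  n_true <- length(all_truth)
  n_pred <- length(all_pred)
  n_corr <- nrow(matched)
  classes <- sort(unique(c(tr_types, pr_types)))
  by_type <- data.frame(
    type = classes,
    n_true = vapply(classes, function(cl) sum(tr_types == cl), 0L),
    n_predicted = vapply(classes, function(cl) sum(pr_types == cl), 0L),
    n_correct = vapply(classes, function(cl) sum(matched$type == cl), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(n_true = n_true, n_predicted = n_pred, n_correct = n_corr,
       sensitivity = if (n_true > 0L) n_corr / n_true else NA_real_,
       specificity = if (n_pred > 0L) n_corr / n_pred else NA_real_,
       by_type = by_type)
}

.score_sim <- function(sim, methods, criterion,
                       rules = c("reversal", "transposition", "fusfis")) {
  rows <- lapply(methods, function(me) {
    sc <- score_predictions(infer_all(sim$tree, mode = me, rules = rules),
                            sim$truth, criterion)
    data.frame(method = me, n_true = sc$n_true, n_predicted = sc$n_predicted,
               n_correct = sc$n_correct, sensitivity = sc$sensitivity,
               specificity = sc$specificity, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reversal-only benchmark (leaf counts 3..10)
#'
#' Runs the reversal-only protocol for every leaf count and scores both
#' methods on every dataset.  Since this study predicts reversal events,
#' only the reversal rule family is run (the genomes are uni-chromosomal,
#' so the translocation and fission branches cannot fire anyway and the
#' transposition family would only contribute noise predictions).
#'
#' @param leaves integer vector of leaf counts.
#' @param seed RNG seed (one derived seed per leaf count).
#' @param methods methods to score.
#' @param criterion matching criterion, see [match_events()].
#' @return data.frame with one row per dataset x method: `leaves`, `m`,
#'   `method`, counts and the two metrics.
#' @export
benchmark_reversal_only <- function(leaves = 3:10, seed = 1L,
                                    methods = c("emrae", "rgrpt"),
                                    criterion = "overlap") {
  out <- list()
  m_values <- seq(50L, 150L, by = 10L)
  for (nl in leaves) {
    sims <- protocol_reversal_only(nl, seed = seed + nl)
    for (d in seq_along(sims)) {
      df <- .score_sim(sims[[d]], methods, criterion, rules = "reversal")
      df$leaves <- nl
      df$m <- m_values[d]
      out[[length(out) + 1L]] <- df
    }
  }
  df <- do.call(rbind, out)
  df[, c("leaves", "m", "method", "n_true", "n_predicted", "n_correct",
         "sensitivity", "specificity")]
}

#' Mixed-event benchmark (mu = 6, 12, 18, 24)
#'
#' @param mu_values upper bounds of the per-edge event count.
#' @param replicates datasets per `mu`.
#' @param seed RNG seed (one derived seed per `mu`).
#' @inheritParams benchmark_reversal_only
#' @return data.frame with one row per dataset x method.
#' @export
benchmark_all_events <- function(mu_values = c(6L, 12L, 18L, 24L),
                                 replicates = 10L, seed = 1L,
                                 methods = c("emrae", "rgrpt"),
                                 criterion = "overlap") {
  out <- list()
  for (mu in mu_values) {
    sims <- protocol_all_events(mu, replicates = replicates, seed = seed + mu)
    for (d in seq_along(sims)) {
      df <- .score_sim(sims[[d]], methods, criterion)
      df$mu <- mu
      df$replicate <- d
      out[[length(out) + 1L]] <- df
    }
  }
  df <- do.call(rbind, out)
  df[, c("mu", "replicate", "method", "n_true", "n_predicted", "n_correct",
         "sensitivity", "specificity")]
}

#' Group means and grand means of a benchmark table
#'
#' Averages sensitivity/specificity per group (leaf count or `mu`) and
#' method, then averages the group means (the layout of the published
#' simulation tables).
#'
#' @param df output of [benchmark_reversal_only()] or
#'   [benchmark_all_events()].
#' @param by grouping column, `"leaves"` or `"mu"`.
#' @return list with `groups` (per-group means) and `grand` (per-method
#'   means over groups).
#' @export
benchmark_summary <- function(df, by = intersect(c("leaves", "mu"),
                                                 names(df))[1L]) {
  agg <- stats::aggregate(df[, c("n_true", "sensitivity", "specificity")],
                          by = list(group = df[[by]], method = df$method),
                          FUN = mean, na.rm = TRUE)
  names(agg)[1L] <- by
  agg <- agg[order(agg$method, agg[[by]]), ]
  grand <- stats::aggregate(agg[, c("sensitivity", "specificity")],
                            by = list(method = agg$method),
                            FUN = mean, na.rm = TRUE)
  rownames(agg) <- rownames(grand) <- NULL
  list(groups = agg, grand = grand)
}

#' Per-edge rearrangement tables for a set of real genomes
#'
#' Driver for block-order datasets on disk: expects
#' `file.path(data_dir, resolution)` to contain `genomes.txt` (GRIMM
#' format, one record per species) and `data_dir` to contain `tree.nwk`
#' (newick, leaf names matching the genome names).  Runs both methods and
#' tabulates per-edge, per-type counts.
#'
#' @param data_dir dataset directory.
#' @param resolution subdirectory name, e.g. `"10kb"` or `"50kb"`.
#' @return list with per-method tables (see [tabulate_predictions()]).
#' @export
benchmark_mammals <- function(data_dir, resolution = c("10kb", "50kb")) {
  resolution <- match.arg(resolution)
  gen_file <- file.path(data_dir, resolution, "genomes.txt")
  tree_file <- file.path(data_dir, "tree.nwk")
  if (!file.exists(gen_file) || !file.exists(tree_file))
    stop("dataset not found; expected layout:\n  ", gen_file,
         "  (GRIMM block orders, one '>' record per species)\n  ",
         tree_file, "  (rooted newick, leaf names matching genome names)")
  genomes <- read_grimm(gen_file)
  t <- rearr_tree(tree_file, genomes)
  list(emrae = tabulate_predictions(infer_all(t, "emrae")),
       rgrpt = tabulate_predictions(infer_all(t, "rgrpt")))
}
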