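test_that("the quartet yields exactly one reversal r(2,3) on its internal unit", {
  t <- quartet_tree()
  for (mode in c("emrae", "rgrpt")) {
    res <- infer_all(t, mode)
    df <- as.data.frame(res)
    expect_identical(nrow(df), 1L)
    expect_identical(df$type, "reversal")
    expect_identical(df$edge_id, min(t$root_edges))
    ev <- res$predictions[[as.character(min(t$root_edges))]][[1]]
    # the four witnesses are the diagnostic adjacencies; segment ends are
    # blocks 2 and 3 (the planted r(2,3)); direction on the merged unit
    # is unoriented, so accept either reading
    sig <- list(sort(ev$destroyed), sort(ev$created))
    expect_true(setequal(sig[[1]], adj_codes(list(c(1, 2), c(3, 4)))) ||
                  setequal(sig[[2]], adj_codes(list(c(1, 2), c(3, 4)))))
    expect_true(setequal(sig[[1]], adj_codes(list(c(1, -3), c(-2, 4)))) ||
                  setequal(sig[[2]], adj_codes(list(c(1, -3), c(-2, 4)))))
    expect_setequal(abs(unlist(ev$params)), c(2, 3))
  }
})

test_that("the frontier reversal is found by RGRPT and missed by EMRAE", {
  t <- frontier_pair_tree()
  dfr <- as.data.frame(infer_all(t, "rgrpt"))
  expect_identical(nrow(dfr), 1L)
  expect_identical(dfr$type, "reversal")
  expect_identical(nrow(as.data.frame(infer_all(t, "emrae"))), 0L)
})

test_that("identical leaves produce no predictions", {
  g <- genome(list(1:8), "g")
  t <- rearr_tree("((P,Q),(R,S));", list(P = g, Q = g, R = g, S = g))
  expect_identical(nrow(as.data.frame(infer_all(t, "rgrpt"))), 0L)
})

test_that("each planted event type is recovered with its type and signature", {
  base <- genome(list(1:10, 11:20), "anc")
  plant <- function(res) planted_quartet(base, res$genome)
  cases <- list(
    reversal = apply_reversal(base, 1, 3, 6),
    translocation = apply_translocation(base, 1, 2, 4, 5, "prefix-prefix"),
    transposition = apply_transposition(base, 1, 2, 3, k = 6),
    fusion = apply_fusion(base, 1, 2, "same"),
    fission = apply_fission(base, 1, 5))
  for (nm in names(cases)) {
    t <- plant(cases[[nm]])
    truth_ev <- cases[[nm]]$event
    for (mode in c("rgrpt", "emrae")) {
      res <- infer_all(t, mode)
      df <- as.data.frame(res)
      expect_identical(nrow(df), 1L)
      # fusion vs fission flips with the unoriented merged-unit direction
      expect_identical(type_class(df$type), type_class(nm))
      ev <- res$predictions[[as.character(df$edge_id[1])]][[1]]
      expect_true(setequal(c(ev$destroyed, ev$created),
                           c(truth_ev$destroyed, truth_ev$created)))
    }
  }
})

test_that("RGRPT recovers a frontier event on the quartet that EMRAE cannot", {
  base <- genome(list(1:10), "anc")
  mut <- apply_reversal(base, 1, 1, 2) # touches the chromosome head
  t <- planted_quartet(base, mut$genome)
  expect_identical(nrow(as.data.frame(infer_all(t, "rgrpt"))), 1L)
  expect_identical(nrow(as.data.frame(infer_all(t, "emrae"))), 0L)
})

test_that("two independent reversals on one edge are both recovered", {
  base <- genome(list(1:20), "anc")
  m1 <- apply_reversal(base, 1, 3, 5)
  m2 <- apply_reversal(m1$genome, 1, 12, 16)
  t <- planted_quartet(base, m2$genome)
  df <- as.data.frame(infer_all(t, "rgrpt"))
  expect_identical(nrow(df), 2L)
  expect_identical(df$type, c("reversal", "reversal"))
})

test_that("no adjacency witnesses two predictions on the same edge", {
  set.seed(21)
  for (rep in 1:3) {
    sim <- simulate_evolution(caterpillar_newick(5),
                              ancestor_genome(2, 25), k_range = c(2, 6),
                              mix = c(reversal = 10, translocation = 2,
                                      transposition = 2, fusion = 0.05,
                                      fission = 0.05))
    res <- infer_all(sim$tree, "rgrpt")
    for (pl in res$predictions) {
      if (length(pl) < 2) next
      dest <- unlist(lapply(pl, `[[`, "destroyed"))
      crea <- unlist(lapply(pl, `[[`, "created"))
      expect_false(anyDuplicated(dest) > 0)
      expect_false(anyDuplicated(crea) > 0)
    }
  }
})

test_that("single-operation predictions agree with brute-force enumeration", {
  set.seed(22)
  for (rep in 1:8) {
    nb <- sample(6:8, 1)
    nc <- sample(1:2, 1)
    anc <- random_genome(nb, nc, "anc")
    planted <- oracle_all_ops(anc)
    op <- planted[[sample(length(planted), 1)]]
    ops <- c(planted, oracle_all_ops(op$genome))
    t <- planted_quartet(anc, op$genome)
    for (mode in c("rgrpt", "emrae")) {
      res <- infer_all(t, mode)
      for (pl in res$predictions) for (ev in pl) {
        # every emitted prediction must correspond to some single
        # operation with the same type class whose adjacency signature
        # covers the prediction's (either orientation of the unit)
        hit <- any(vapply(ops, function(o) {
          type_class(o$type) == type_class(ev$type) &&
            (all(ev$destroyed %in% o$event$destroyed) &&
               all(ev$created %in% o$event$created) ||
               all(ev$destroyed %in% o$event$created) &&
               all(ev$created %in% o$event$destroyed))
        }, TRUE))
        expect_true(hit, info = sprintf(
          "rep %d mode %s type %s", rep, mode, ev$type))
      }
    }
  }
})

test_that("per-edge totals add up in the prediction table", {
  set.seed(23)
  sim <- simulate_evolution(caterpillar_newick(4), ancestor_genome(2, 20),
                            k_range = c(1, 3))
  res <- infer_all(sim$tree, "rgrpt")
  tab <- tabulate_predictions(res)
  body <- tab[tab$edge != "Total", ]
  tot <- tab[tab$edge == "Total", ]
  for (col in c("Rev", "Tloc", "Tran", "FusFis", "Total"))
    expect_identical(tot[[col]], sum(body[[col]]))
  expect_identical(sum(body$Total), nrow(as.data.frame(res)))
})
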