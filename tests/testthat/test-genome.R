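test_that("canonical adjacency identifies a(x,y) with a(-y,-x)", {
  expect_identical(canonical_adjacency(2, 3), canonical_adjacency(-3, -2))
  expect_identical(canonical_adjacency(0, 1), canonical_adjacency(-1, 0))
  expect_identical(canonical_adjacency(1, -3), canonical_adjacency(3, -1))
  expect_error(canonical_adjacency(0, 0), "both sides")
  # idempotence/symmetry over random signed pairs
  set.seed(1)
  for (rep in 1:50) {
    x <- sample(c(-50:-1, 1:50), 1)
    y <- sample(c(-50:-1, 1:50, 0), 1)
    c1 <- canonical_adjacency(x, y)
    expect_identical(c1, canonical_adjacency(-y, -x))
    m <- decode_adjacency(c1)
    expect_identical(canonical_adjacency(m[1], m[2]), c1)
  }
})

test_that("genome validation enforces non-empty unique-label chromosomes", {
  expect_error(genome(list(integer(0))), "empty")
  expect_error(genome(list(c(1, 0, 2))), "reserved")
  expect_error(genome(list(1:3, c(4, -2))), "duplicated")
  g <- genome(list(1:3, 4:6), name = "g")
  expect_s3_class(g, "genome")
  expect_length(g$chromosomes, 2)
})

test_that("adjacency sets match the worked examples and counting identities", {
  g <- genome(list(1:4))
  expect_identical(adjacencies(g),
                   adj_codes(list(c(1, 2), c(2, 3), c(3, 4))))
  expect_identical(adjacencies(g, capped = TRUE),
                   adj_codes(list(c(1, 2), c(2, 3), c(3, 4), c(0, 1), c(4, 0))))
  # capped sets of X and Y share a(4,0) but differ in the head cap
  y <- genome(list(c(-2L, -1L, 3L, 4L)))
  expect_true(canonical_adjacency(0, 1) %in% adjacencies(g, capped = TRUE))
  expect_true(canonical_adjacency(0, -2) %in% adjacencies(y, capped = TRUE))
  # single-block chromosome
  s <- genome(list(5L))
  expect_identical(adjacencies(s), integer(0))
  expect_identical(adjacencies(s, capped = TRUE),
                   adj_codes(list(c(0, 5), c(5, 0))))
  # |adjacencies| = sum(len-1); capped adds 2 per chromosome; X == -X
  set.seed(2)
  for (rep in 1:20) {
    nc <- sample(1:3, 1)
    g <- random_genome(sample(5:20, 1), nc)
    lens <- lengths(g$chromosomes)
    expect_length(adjacencies(g), sum(lens - 1L))
    expect_length(adjacencies(g, capped = TRUE), sum(lens + 1L))
    flipped <- genome(lapply(g$chromosomes, function(v) -rev(v)))
    expect_identical(adjacencies(g, capped = TRUE),
                     adjacencies(flipped, capped = TRUE))
  }
})

test_that("effective adjacencies are union minus intersection in canonical form", {
  g1 <- genome(list(1:4), "G1")
  g2 <- genome(list(c(1L, -3L, -2L, 4L)), "G2")
  # the canonical classes of a(1,2), a(3,4), a(1,-3), a(-2,4); a(2,3) is
  # carried by both genomes (as a(-3,-2) in G2) and so is not effective
  expect_identical(effective_adjacencies(list(g1, g2)),
                   adj_codes(list(c(1, 2), c(3, 4), c(1, -3), c(-2, 4))))
  expect_identical(effective_adjacencies(list(g1, g1)), integer(0))
  expect_error(effective_adjacencies(list(g1)), "at least two")
  # g3 = 1 2 3 -4: a(1,2) in 2 of 3 genomes -> effective; a(2,3) in all
  # three (g2 carries it as a(-3,-2)) -> not effective
  g3 <- genome(list(c(1L, 2L, 3L, -4L)), "G3")
  eff <- effective_adjacencies(list(g1, g2, g3))
  expect_true(canonical_adjacency(1, 2) %in% eff)
  expect_true(canonical_adjacency(3, -4) %in% eff)
  expect_false(canonical_adjacency(2, 3) %in% eff)
})

test_that("reversal reverses, flips signs, and is an involution", {
  g <- genome(list(1:4))
  r <- apply_reversal(g, 1, 2, 3)
  expect_identical(r$genome$chromosomes[[1]], c(1L, -3L, -2L, 4L))
  expect_identical(sort(r$event$destroyed), adj_codes(list(c(1, 2), c(3, 4))))
  expect_identical(sort(r$event$created), adj_codes(list(c(1, -3), c(-2, 4))))
  # one-gene reversal flips a single sign
  r1 <- apply_reversal(g, 1, 2, 2)
  expect_identical(r1$genome$chromosomes[[1]], c(1L, -2L, 3L, 4L))
  # involution
  back <- apply_reversal(r$genome, 1, 2, 3)
  expect_true(genomes_equal(back$genome, g))
  expect_error(apply_reversal(g, 1, 3, 5), "range")
})

test_that("translocation exchanges segments in both modes and conserves blocks", {
  g <- genome(list(1:3, 4:6))
  pp <- apply_translocation(g, 1, 2, 2, 2, "prefix-prefix")
  expect_identical(pp$genome$chromosomes[[1]], c(4L, 2L, 3L))
  expect_identical(pp$genome$chromosomes[[2]], c(1L, 5L, 6L))
  g2 <- genome(list(1:2, 3:4))
  ps <- apply_translocation(g2, 1, 2, 2, 2, "prefix-suffix")
  expect_identical(ps$genome$chromosomes[[1]], c(-4L, 2L))
  expect_identical(ps$genome$chromosomes[[2]], c(1L, -3L))
  # block conservation
  expect_setequal(abs(unlist(pp$genome$chromosomes)), 1:6)
  expect_setequal(abs(unlist(ps$genome$chromosomes)), 1:4)
  # empty-side splits rejected
  expect_error(apply_translocation(g, 1, 2, 1, 2), "empty")
  expect_error(apply_translocation(g, 1, 1, 2, 2), "distinct")
})

test_that("transposition excises and reinserts after the target block", {
  g <- genome(list(1:5))
  tp <- apply_transposition(g, 1, 2, 3, k = 5)
  expect_identical(tp$genome$chromosomes[[1]], c(1L, 4L, 5L, 2L, 3L))
  expect_length(tp$event$destroyed, 3)
  expect_length(tp$event$created, 3)
  # inter-chromosomal move conserves blocks
  g2 <- genome(list(1:4, 5:8))
  tp2 <- apply_transposition(g2, 1, 2, 3, dest = 2, k = 2)
  expect_identical(tp2$genome$chromosomes[[1]], c(1L, 4L))
  expect_identical(tp2$genome$chromosomes[[2]], c(5L, 6L, 2L, 3L, 7L, 8L))
  expect_setequal(abs(unlist(tp2$genome$chromosomes)), 1:8)
  # target inside the fragment (or the identity slot) is an error
  expect_error(apply_transposition(g, 1, 2, 3, k = 2), "inside")
  expect_error(apply_transposition(g, 1, 2, 3, k = 1), "inside")
  expect_error(apply_transposition(g, 1, 1, 5, k = 0), "whole chromosome")
})

test_that("fusion and fission are mutual inverses with capped event records", {
  g <- genome(list(1:2, 3:4))
  fu <- apply_fusion(g, 1, 2, "same")
  expect_identical(fu$genome$chromosomes[[1]], 1:4)
  fl <- apply_fusion(g, 1, 2, "flip")
  expect_identical(fl$genome$chromosomes[[1]], c(1L, 2L, -4L, -3L))
  expect_error(apply_fusion(g, 1, 1), "distinct")
  fi <- apply_fission(genome(list(1:4)), 1, 2)
  expect_identical(fi$genome$chromosomes[[1]], 1:2)
  expect_identical(fi$genome$chromosomes[[2]], 3:4)
  expect_identical(fi$event$destroyed, canonical_adjacency(2, 3))
  expect_identical(sort(fi$event$created), adj_codes(list(c(2, 0), c(0, 3))))
  expect_error(apply_fission(genome(list(1:4)), 1, 4), "non-empty")
  # inverse pair: fission at the fused junction recovers the originals
  refi <- apply_fission(fu$genome, 1, 2)
  expect_true(genomes_equal(refi$genome, g))
  refu <- apply_fusion(fi$genome, 1, 2, "same")
  expect_true(genomes_equal(refu$genome, genome(list(1:4))))
})

test_that("every operator's event record updates the capped adjacency set exactly", {
  set.seed(3)
  s1 <- function(x) if (length(x) == 1) x else sample(x, 1)
  for (rep in 1:40) {
    g <- random_genome(sample(6:15, 1), sample(1:3, 1))
    before <- adjacencies(g, capped = TRUE)
    lens <- lengths(g$chromosomes)
    op <- sample(c("rev", "tp", "tl", "fu", "fi"), 1)
    res <- switch(op,
      rev = {
        ci <- sample(seq_along(lens), 1)
        ij <- sort(sample(lens[ci], 2, replace = TRUE))
        if (ij[1] == 1 && ij[2] == lens[ci]) next
        apply_reversal(g, ci, ij[1], ij[2])
      },
      tp = {
        ci <- which(lens >= 2)[1]
        if (is.na(ci)) next
        ij <- sort(sample(lens[ci], 2, replace = TRUE))
        if (ij[1] == 1 && ij[2] == lens[ci]) next
        ks <- setdiff(0:lens[ci], (ij[1] - 1):ij[2])
        if (!length(ks)) next
        apply_transposition(g, ci, ij[1], ij[2], k = s1(ks))
      },
      tl = {
        el <- which(lens >= 2)
        if (length(el) < 2) next
        cc <- sample(el, 2)
        apply_translocation(g, cc[1], cc[2], s1(2:lens[cc[1]]),
                            s1(2:lens[cc[2]]),
                            sample(c("prefix-prefix", "prefix-suffix"), 1))
      },
      fu = {
        if (length(lens) < 2) next
        cc <- sample(seq_along(lens), 2)
        apply_fusion(g, cc[1], cc[2], sample(c("same", "flip"), 1))
      },
      fi = {
        ci <- which(lens >= 2)[1]
        if (is.na(ci)) next
        apply_fission(g, ci, s1(seq_len(lens[ci] - 1)))
      })
    after <- adjacencies(res$genome, capped = TRUE)
    expect_identical(after,
                     sort(union(setdiff(before, res$event$destroyed),
                                res$event$created)))
    expect_length(intersect(res$event$destroyed, res$event$created), 0)
    expect_identical(sort(abs(unlist(res$genome$chromosomes, use.names = FALSE))),
                     sort(abs(unlist(g$chromosomes, use.names = FALSE))))
  }
})

test_that("GRIMM files round-trip bit-stably", {
  gs <- list(A = genome(list(c(1L, -3L, 2L), c(4L, 5L)), "A"),
             B = genome(list(c(-5L, -4L, -3L, 2L, 1L)), "B"))
  path <- tempfile(fileext = ".txt")
  write_grimm(gs, path)
  back <- read_grimm(path)
  expect_identical(lapply(back, `[[`, "chromosomes"),
                   lapply(gs, `[[`, "chromosomes"))
  path2 <- tempfile(fileext = ".txt")
  write_grimm(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # comments and format errors
  writeLines(c("# header comment", ">G", "1 2 3 $"), path)
  expect_identical(read_grimm(path)$G$chromosomes[[1]], 1:3)
  writeLines(c(">G", "1 2 3"), path)
  expect_error(read_grimm(path), "terminated")
  writeLines(c("1 2 $"), path)
  expect_error(read_grimm(path), "header")
})
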