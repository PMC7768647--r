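test_that("classic PageRank handles degenerate and symmetric graphs", {
  # single node, no edges: all mass on the node
  one <- pagerankClassic(matrix(0, 1, 1))
  expect_equal(unname(rankValues(one)), 1)

  # two nodes linking to each other: symmetry
  A <- matrix(0, 2, 2); A[1, 2] <- A[2, 1] <- 1
  expect_equal(unname(rankValues(pagerankClassic(A))), c(0.5, 0.5))

  expect_error(pagerankClassic(matrix(0, 0, 0)), "square")
  expect_error(pagerankClassic(matrix(1, 2, 2), damping = 1), "damping")
})

test_that("the power iteration matches the dense eigenvector oracle", {
  # 3-node chain with a dangling sink
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 3] <- 1
  pr <- pagerankClassic(A, maxIter = 1000L)
  expect_equal(unname(rankValues(pr)), eigenPagerank(A), tolerance = 1e-8)

  # random directed graphs up to 6 nodes
  set.seed(101)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    A <- randomDigraph(n, runif(1, 0.2, 0.8))
    pr <- pagerankClassic(A, maxIter = 2000L)
    expect_equal(sum(rankValues(pr)), 1, tolerance = 1e-12)
    expect_lt(max(abs(unname(rankValues(pr)) - eigenPagerank(A))), 1e-8)
  }
})

test_that("literal (unnormalized) teleport form sums to the node count", {
  set.seed(5)
  A <- randomDigraph(5, 0.5)
  pr <- pagerankClassic(A, maxIter = 2000L, normalized = FALSE)
  expect_equal(sum(rankValues(pr)), 5, tolerance = 1e-6)
})

test_that("non-convergence within the cap warns and flags the state", {
  set.seed(2)
  A <- randomDigraph(6, 0.5)
  expect_warning(pr <- pagerankClassic(A, maxIter = 2L, tol = 1e-15),
                 "converge")
  expect_false(isConverged(pr))
  expect_equal(iterations(pr), 2L)
})

test_that("rank initialization is seeded, renormalized and deterministic", {
  a <- initializeRanks(c("P1", "P2", "P3"), seed = 7)
  b <- initializeRanks(c("P1", "P2", "P3"), seed = 7)
  expect_identical(rankValues(a), rankValues(b))
  expect_equal(sum(rankValues(a)), 1)
  expect_true(all(rankValues(a) > 0))

  c_ <- initializeRanks(c("P1", "P2", "P3"), seed = 8)
  expect_false(identical(rankValues(a), rankValues(c_)))

  solo <- initializeRanks("P1", seed = 1)
  expect_equal(unname(rankValues(solo)), 1)
})

test_that("phenolic score is gene-weighted normalized edge mass over degree", {
  # single edge with norm weight 1 and gw 1
  net1 <- buildNetwork(makeRecords("P1", c("G1", "G2"), c(1L, 3L)))
  expect_equal(unname(phenolicScores(net1, c(G1 = 1, G2 = 1))[1]), 1)

  # hand case: norm weights {1,1}, gws {0.2, 0.8} -> (0.2 + 0.8)/2
  s <- phenolicScores(net1, c(G1 = 0.2, G2 = 0.8))
  expect_equal(unname(s), 0.5)

  # all-zero gene weights annihilate the score
  expect_equal(unname(phenolicScores(net1, c(G1 = 0, G2 = 0))), 0)

  expect_error(phenolicScores(net1, c(G1 = 1)), "G2")
})

test_that("uninformative score vectors collapse to a uniform lexicographic ranking", {
  # identical edges and gene weights for every phenolic
  rec <- makeRecords(rep(c("Pb", "Pa", "Pc"), each = 2),
                     rep(c("G1", "G2"), 3),
                     rep(c(1L, 3L), 3))
  net <- buildNetwork(rec)
  expect_warning(
    st <- rankPhenolics(net, c(G1 = 0.4, G2 = 0.6), seed = 3),
    "equal|zero")
  expect_equal(unname(rankValues(st)), rep(1 / 3, 3))
  expect_equal(rankOrder(st), c("Pa", "Pb", "Pc"))

  # all-zero gene weights degrade the same way
  expect_warning(st0 <- rankPhenolics(net, c(G1 = 0, G2 = 0)), "zero")
  expect_equal(unname(rankValues(st0)), rep(1 / 3, 3))
})

test_that("a dominant multiplier wins from any seed and mass is conserved", {
  # s = {0.9, 0.1} via one edge each: norm weights are 1 (two equal
  # groups), gene weights set the multipliers directly
  rec <- makeRecords(c("P1", "P2"), c("Ghi", "Glo"), c(2L, 2L))
  net <- buildNetwork(rec)
  for (seed in 1:10) {
    st <- rankPhenolics(net, c(Ghi = 0.9, Glo = 0.1), seed = seed,
                        maxIter = 2000L)
    expect_equal(rankOrder(st), c("P1", "P2"))
    expect_true(isConverged(st))
    expect_equal(sum(rankValues(st)), 1, tolerance = 1e-12)
  }
})

test_that("the converged order equals the descending s(p) order on random instances", {
  set.seed(202)
  for (i in 1:8) {
    m <- sample(4:8, 1); g <- sample(6:12, 1)
    pid <- sprintf("P%02d", 1:m)
    gid <- sprintf("G%02d", 1:g)
    grid <- expand.grid(phenolic = pid, gene = gid,
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < 0.6, ]
    grid <- grid[!duplicated(grid), ]
    # ensure every phenolic keeps at least one edge
    missing <- setdiff(pid, grid$phenolic)
    if (length(missing))
      grid <- rbind(grid, data.frame(phenolic = missing, gene = gid[1]))
    rec <- makeRecords(grid$phenolic, grid$gene,
                       rpois(nrow(grid), 3) + 1L)
    net <- buildNetwork(rec)
    gw <- setNames(runif(length(genes(net))), genes(net))

    s <- phenolicScores(net, gw)
    oracle <- names(s)[order(-s, names(s))]
    st <- rankPhenolics(net, gw, seed = i, maxIter = 1e9)
    expect_equal(rankOrder(st), oracle)

    # the final order is seed-independent when the s(p) are distinct
    if (!anyDuplicated(s)) {
      for (seed in c(11, 99)) {
        st2 <- rankPhenolics(net, gw, seed = seed, maxIter = 1e9)
        expect_equal(rankOrder(st2), oracle)
      }
    }
  }
})

test_that("rescaling all gene weights leaves the final order unchanged", {
  set.seed(33)
  rec <- makeRecords(rep(sprintf("P%d", 1:5), each = 4),
                     sprintf("G%d", rep(1:4, 5)),
                     rpois(20, 5) + 1L)
  net <- buildNetwork(rec)
  gw <- setNames(runif(4), sprintf("G%d", 1:4))
  base <- rankPhenolics(net, gw, seed = 1, maxIter = 1e9)
  for (c_ in c(0.01, 3, 250)) {
    scaled <- rankPhenolics(net, gw * c_, seed = 1, maxIter = 1e9)
    expect_equal(rankOrder(scaled), rankOrder(base))
  }
})

test_that("RankState accessors and show method expose the run", {
  rec <- makeRecords(c("P1", "P2"), c("G1", "G2"), c(1L, 4L))
  net <- buildNetwork(rec)
  st <- rankPhenolics(net, c(G1 = 0.9, G2 = 0.2), seed = 1,
                      maxIter = 2000L)
  expect_s4_class(st, "RankState")
  expect_named(sScores(st))
  expect_true(is.numeric(iterations(st)))
  expect_output(show(st), "RankState")
  expect_output(show(net), "InteractionNetwork")
})
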