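test_that("subnetwork extraction keeps exactly the edges into the DEG list", {
  g <- toyGRN()
  s <- extractSubnetwork(g, c("A", "B"), label = "toy")
  # brute-force filter on the toy instance
  expected <- edges(g)[edges(g)$target %in% c("A", "B"), ]
  rownames(expected) <- NULL
  expect_identical(edges(s), expected)
  expect_identical(nrow(edges(s)), 4L)
  # identity case: DEGs cover all targets
  sAll <- extractSubnetwork(g, c("A", "B", "C", "D"), label = "toy")
  expect_identical(edges(sAll), edges(g))
  # disjoint DEG list: empty subnetwork with a warning
  expect_warning(sEmpty <- extractSubnetwork(g, "ZZZ", label = "toy"),
                 "no edges")
  expect_identical(nrow(edges(sEmpty)), 0L)
  expect_error(extractSubnetwork(g, character()), "empty")
  # idempotence
  s2 <- extractSubnetwork(s, c("A", "B"), label = "toy")
  expect_identical(edges(s2), edges(s))
})

test_that("regulator ranking sums weights and orders deterministically", {
  g <- new("GRNetwork",
           edges = data.frame(regulator = c("R1", "R1", "R2"),
                              target = c("A", "B", "C"),
                              weight = c(0.5, 0.3, 0.6)),
           regulatorUniverse = c("R1", "R2"))
  s <- extractSubnetwork(g, c("A", "B", "C"), label = "x")
  rk <- rankingTable(rankRegulators(s))
  expect_identical(rk$regulator, c("R1", "R2"))
  expect_equal(rk$weightSum, c(0.8, 0.6), tolerance = 1e-12)
  expect_identical(rk$rank, 1:2)
  # equal weights: more edges wins
  gEq <- new("GRNetwork",
             edges = data.frame(regulator = c("R1", "R1", "R1", "R2", "R2"),
                                target = paste0("T", 1:5),
                                weight = 0.2),
             regulatorUniverse = c("R1", "R2"))
  rkEq <- rankingTable(rankRegulators(extractSubnetwork(gEq, paste0("T", 1:5),
                                                        "x")))
  expect_identical(rkEq$regulator[1], "R1")
  # shuffling edge order changes nothing
  gShuf <- new("GRNetwork", edges = edges(g)[c(3, 1, 2), ],
               regulatorUniverse = c("R1", "R2"))
  expect_identical(rankingTable(rankRegulators(gShuf)), rk)
  expect_error(rankRegulators(suppressWarnings(
    extractSubnetwork(g, "ZZZ", "x"))), "empty")
})

test_that("ranking conserves total subnetwork weight", {
  set.seed(42)
  for (i in 1:20) {
    nr <- sample(3:8, 1)
    ne <- sample(5:40, 1)
    ed <- unique(data.frame(
      regulator = paste0("R", sample(nr, ne, replace = TRUE)),
      target = paste0("T", sample(12, ne, replace = TRUE))))
    ed$weight <- runif(nrow(ed))
    g <- new("GRNetwork", edges = ed,
             regulatorUniverse = unique(ed$regulator))
    rk <- rankingTable(rankRegulators(g))
    expect_equal(sum(rk$weightSum), sum(ed$weight), tolerance = 1e-9)
    # brute-force recomputation per regulator
    brute <- vapply(rk$regulator,
                    function(r) sum(ed$weight[ed$regulator == r]),
                    numeric(1))
    expect_equal(rk$weightSum, unname(brute), tolerance = 1e-12)
  }
})

test_that("class filtering preserves order, truncates, and keeps global ranks", {
  rk <- mkRanking(paste0("G", 1:5), c(5, 4, 3, 2, 1))
  rs <- new("RegulatorSet", records = data.frame(
    gene = paste0("G", 1:5), symbol = "",
    regClass = c("TF", "EPIGENETIC", "TF", "EPIGENETIC", "TF"),
    category = c("NONE", "SIRNA", "NONE", "DNA_METHYLATION", "NONE")))
  epi <- rankingTable(filterRanking(rk, rs, "EPIGENETIC", topN = 10))
  expect_identical(epi$regulator, c("G2", "G4"))
  expect_identical(epi$rank, 1:2)
  expect_identical(epi$globalRank, c(2L, 4L))
  all25 <- rankingTable(filterRanking(rk, rs, "ALL", topN = 25))
  expect_identical(all25$regulator, paste0("G", 1:5))
  top2 <- rankingTable(filterRanking(rk, rs, "ALL", topN = 2))
  expect_identical(top2$regulator, c("G1", "G2"))
})

test_that("rank-sum aggregation matches hand enumeration and is symmetric", {
  a <- mkRanking(c("X", "Y", "Z"), c(3, 2, 1))
  b <- mkRanking(c("Y", "X", "Z"), c(3, 2, 1))
  cum <- rankSumAggregate(list(a, b), topN = 3)
  ct <- rankingTable(cum)
  expect_identical(setNames(ct$rankSum, ct$regulator),
                   c(X = 3L, Y = 3L, Z = 6L))
  # X/Y tie resolved by total weight sum: X has 3+2=5, Y has 2+3=5 -> gene id
  expect_identical(ct$regulator, c("X", "Y", "Z"))
  # list order must not matter
  ct2 <- rankingTable(rankSumAggregate(list(b, a), topN = 3))
  expect_identical(ct, ct2)
  # identical lists reproduce the input order
  same <- rankingTable(rankSumAggregate(list(a, a), topN = 3))
  expect_identical(same$regulator, c("X", "Y", "Z"))
  expect_identical(same$rankSum, c(2L, 4L, 6L))
  # absence from one top-n contributes rank topN + 1
  c3 <- mkRanking(c("X", "Y", "W"), c(3, 2, 1))
  ct3 <- rankingTable(rankSumAggregate(list(a, c3), topN = 3))
  expect_identical(ct3$rankSum[ct3$regulator == "Z"], 3L + 4L)
  expect_identical(ct3$rankSum[ct3$regulator == "W"], 4L + 3L)
  expect_error(rankSumAggregate(list(a), topN = 3), "at least 2")
})

test_that("target retrieval matches an exhaustive scan of the toy network", {
  g <- toyGRN()
  for (r in c("R1", "R2", "R3")) {
    ts <- getTargets(g, r)
    expect_identical(targets(ts),
                     sort(unique(edges(g)$target[edges(g)$regulator == r])))
  }
  expect_warning(none <- getTargets(g, "R9"), "no edges")
  expect_identical(targets(none), character())
})

test_that("weight fractions are proper proportions that sum to one", {
  g <- new("GRNetwork",
           edges = data.frame(regulator = c("R1", "R2"),
                              target = c("A", "B"),
                              weight = c(0.75, 0.25)),
           regulatorUniverse = c("R1", "R2"))
  s <- extractSubnetwork(g, c("A", "B"), "x")
  expect_equal(weightFraction(s, "A"), 0.75, tolerance = 1e-12)
  expect_equal(weightFraction(s, c("A", "B")), 1.0, tolerance = 1e-12)
  expect_identical(weightFraction(s, character()), 0)
  set.seed(1)
  for (i in 1:10) {
    tg <- unique(edges(toyGRN())$target)
    sub <- sample(tg, sample(0:4, 1))
    s2 <- extractSubnetwork(toyGRN(), tg, "toy")
    expect_equal(weightFraction(s2, sub) + weightFraction(s2, setdiff(tg, sub)),
                 1, tolerance = 1e-12)
  }
})
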