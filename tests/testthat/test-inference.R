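test_that("normalization centres, scales, flags constants, and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = rnorm(3))
  colnames(m) <- paste0("s", 1:3)
  n1 <- normalizeExpression(m)
  expect_equal(unname(rowMeans(n1)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(epigrn:::.rowVar(n1)[c("a", "c")]), c(1, 1),
               tolerance = 1e-12)
  expect_identical(unname(n1["b", ]), c(0, 0, 0))
  expect_identical(attr(n1, "constantGenes"),
                   c(a = FALSE, b = TRUE, c = FALSE))
  n2 <- normalizeExpression(n1)
  expect_equal(unname(n2), unname(n1), tolerance = 1e-12)
})

test_that("stump importances match the exhaustive split-enumeration oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 8
    m <- rbind(R1 = rnorm(n), R2 = rnorm(n), T1 = rnorm(n))
    colnames(m) <- sprintf("s%02d", seq_len(n))
    rs <- new("RegulatorSet", records = data.frame(
      gene = c("R1", "R2"), symbol = "", regClass = "TF", category = "NONE"))
    cfg <- inferenceConfig(nTrees = 4, seed = rep, bootstrap = FALSE,
                           minLeaf = 1, maxDepth = 1)
    g <- inferNetwork(m, rs, cfg)
    yn <- drop(scale(m["T1", ]))
    red <- stumpOracle(t(m[c("R1", "R2"), ]), yn)
    expected <- ifelse(seq_along(red) == which.max(red), max(red), 0)
    e <- edges(g)
    got <- setNames(rep(0, 2), c("R1", "R2"))
    hit <- e[e$target == "T1", ]
    got[hit$regulator] <- hit$weight
    expect_equal(unname(got), expected, tolerance = 1e-9)
  }
})

test_that("a perfect predictor dominates the importance of its target", {
  set.seed(11)
  n <- 50
  r1 <- rnorm(n)
  m <- rbind(R1 = r1, R2 = rnorm(n), T1 = r1)
  colnames(m) <- sprintf("s%02d", seq_len(n))
  rs <- new("RegulatorSet", records = data.frame(
    gene = c("R1", "R2"), symbol = "", regClass = "TF", category = "NONE"))
  g <- inferNetwork(m, rs, inferenceConfig(nTrees = 100, seed = 1))
  e <- edges(g)
  wT <- setNames(rep(0, 2), c("R1", "R2"))
  hit <- e[e$target == "T1", ]
  wT[hit$regulator] <- hit$weight
  expect_gt(wT["R1"], wT["R2"])
  expect_gt(wT["R1"] / sum(wT), 0.9)
})

test_that("constant targets receive no edges and constant predictors are dropped", {
  set.seed(3)
  m <- rbind(R1 = rnorm(20), R2 = rnorm(20), C1 = rep(2, 20), T1 = rnorm(20))
  colnames(m) <- sprintf("s%02d", 1:20)
  rs <- new("RegulatorSet", records = data.frame(
    gene = c("R1", "R2", "C1"), symbol = "", regClass = "TF",
    category = "NONE"))
  g <- inferNetwork(m, rs, inferenceConfig(nTrees = 20, seed = 1))
  expect_false("C1" %in% edges(g)$target)
  expect_false("C1" %in% edges(g)$regulator)
})

test_that("incoming weight sums equal the per-tree variance reduction", {
  set.seed(5)
  n <- 30
  m <- rbind(R1 = rnorm(n), R2 = rnorm(n), R3 = rnorm(n), T1 = rnorm(n))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  rs <- new("RegulatorSet", records = data.frame(
    gene = c("R1", "R2", "R3"), symbol = "", regClass = "TF",
    category = "NONE"))
  # without bootstrap and grown to purity every tree removes all of the
  # target's (population) variance: sum of importances = SS/n = (n-1)/n
  g <- inferNetwork(m, rs, inferenceConfig(nTrees = 7, seed = 2,
                                           bootstrap = FALSE, minLeaf = 1))
  wT <- sum(edges(g)$weight[edges(g)$target == "T1"])
  expect_equal(wT, (n - 1) / n, tolerance = 1e-9)
})

test_that("inference is seed-deterministic and invariant to row/column order", {
  set.seed(9)
  m <- matrix(rnorm(8 * 25), 8, 25,
              dimnames = list(paste0("G", 1:8), sprintf("s%02d", 1:25)))
  rs <- new("RegulatorSet", records = data.frame(
    gene = paste0("G", 1:3), symbol = "", regClass = "TF",
    category = "NONE"))
  cfg <- inferenceConfig(nTrees = 30, seed = 4)
  g1 <- inferNetwork(m, rs, cfg)
  g2 <- inferNetwork(m, rs, cfg)
  expect_identical(edges(g1), edges(g2))
  gPermSamples <- inferNetwork(m[, sample(ncol(m))], rs, cfg)
  expect_identical(edges(g1), edges(gPermSamples))
  gPermGenes <- inferNetwork(m[sample(nrow(m)), ], rs, cfg)
  expect_identical(edges(g1), edges(gPermGenes))
  gOther <- inferNetwork(m, rs, inferenceConfig(nTrees = 30, seed = 5))
  expect_false(identical(edges(g1), edges(gOther)))
  # worker count cannot change the result
  g4 <- inferNetwork(m, rs, cfg, nCores = 2L)
  expect_identical(edges(g1), edges(g4))
})

test_that("importances agree qualitatively with an independent forest", {
  skip_if_not_installed("ranger")
  set.seed(21)
  n <- 120
  x <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("R", 1:5), sprintf("s%03d", 1:n)))
  y <- 1.5 * x["R2", ] - 1.2 * x["R4", ] + rnorm(n, 0, 0.3)
  m <- rbind(x, T1 = y)
  rs <- new("RegulatorSet", records = data.frame(
    gene = paste0("R", 1:5), symbol = "", regClass = "TF",
    category = "NONE"))
  g <- inferNetwork(m, rs, inferenceConfig(nTrees = 200, seed = 1))
  e <- edges(g)
  ours <- e[e$target == "T1", ]
  ours <- setNames(ours$weight, ours$regulator)[paste0("R", 1:5)]
  ours[is.na(ours)] <- 0
  rf <- ranger::ranger(y = y, x = as.data.frame(t(x)), num.trees = 200,
                       mtry = 5, importance = "impurity", seed = 1)
  theirs <- rf$variable.importance[paste0("R", 1:5)]
  expect_identical(names(sort(ours, decreasing = TRUE))[1:2],
                   names(sort(theirs, decreasing = TRUE))[1:2])
  expect_gt(cor(ours, theirs), 0.9)
})

test_that("trimming keeps exactly the ceiling fraction with deterministic ties", {
  g20 <- new("GRNetwork",
             edges = data.frame(regulator = rep("R1", 20),
                                target = sprintf("T%02d", 1:20),
                                weight = seq(0.05, 1, by = 0.05)),
             regulatorUniverse = "R1")
  t2 <- trimTopFraction(g20, 0.1)
  expect_identical(nrow(edges(t2)), 2L)
  expect_setequal(edges(t2)$target, c("T20", "T19"))
  g25 <- new("GRNetwork",
             edges = data.frame(regulator = rep("R1", 25),
                                target = sprintf("T%02d", 1:25),
                                weight = (1:25) / 25),
             regulatorUniverse = "R1")
  expect_identical(nrow(edges(trimTopFraction(g25, 0.1))), 3L)
  gTies <- new("GRNetwork",
               edges = data.frame(regulator = rep(c("R1", "R2"), 5),
                                  target = rep(sprintf("T%d", 1:5), each = 2),
                                  weight = 0.5),
               regulatorUniverse = c("R1", "R2"))
  kept <- edges(trimTopFraction(gTies, 0.3))
  expect_identical(nrow(kept), 3L)
  expect_identical(kept$regulator, c("R1", "R1", "R1"))
  expect_identical(kept$target, c("T1", "T2", "T3"))
  expect_error(trimTopFraction(g20, 0), "fraction")
  expect_error(trimTopFraction(g20, 1.2), "fraction")
  full <- edges(g20)[order(-edges(g20)$weight), , drop = FALSE]
  rownames(full) <- NULL
  expect_identical(edges(trimTopFraction(g20, 1.0)), full)
})
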