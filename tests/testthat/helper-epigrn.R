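# Shared fixtures and independent oracles.

# A small fixed network: 3 regulators, 4 targets, 6 edges.
toyGRN <- function() {
  ed <- data.frame(
    regulator = c("R1", "R1", "R2", "R2", "R3", "R3"),
    target    = c("A",  "B",  "A",  "C",  "B",  "D"),
    weight    = c(0.50, 0.30, 0.60, 0.20, 0.10, 0.40))
  new("GRNetwork", edges = ed, regulatorUniverse = c("R1", "R2", "R3"))
}

# Build a ranking with prescribed weight sums through the public path:
# one edge per regulator into a private target.
mkRanking <- function(ids, weightSums, label = "test") {
  ed <- data.frame(regulator = ids,
                   target = paste0("T_", ids),
                   weight = weightSums)
  g <- new("GRNetwork", edges = ed, regulatorUniverse = ids)
  s <- extractSubnetwork(g, ed$target, label = label)
  rankRegulators(s, label = label)
}

# Upper-tail hypergeometric by direct summation of the pmf from binomial
# coefficients (independent of phyper).
hyperOracle <- function(N, K, n, k) {
  j <- seq(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exhaustive best-split search for a depth-1 regression tree: for every
# feature and every threshold between distinct sorted values, the
# sum-of-squares reduction of the split; returns the per-feature maximum
# divided by n (the stump importance convention).
stumpOracle <- function(X, y) {
  n <- length(y)
  ss <- function(v) sum(v^2) - sum(v)^2 / length(v)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    cuts <- sort(unique(x))
    best <- 0
    for (c in cuts[-length(cuts)]) {
      l <- y[x <= c]; r <- y[x > c]
      red <- ss(y) - ss(l) - ss(r)
      if (red > best) best <- red
    }
    best / n
  }, numeric(1))
}

# Numeric PR-curve integration: expand tied blocks into fine linear steps of
# (TP, FP) and integrate precision over recall with the trapezoid rule.
auprNumericOracle <- function(scores, positive, stepsPerBlock = 20000) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; ypos <- positive[o]
  P <- sum(positive)
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(ypos)[ends]; nn <- ends
  recall <- 0; prec <- NULL; tp0 <- 0; n0 <- 0; auc <- 0
  for (b in seq_along(ends)) {
    dtp <- tp[b] - tp0; dn <- nn[b] - n0
    if (dtp > 0) {
      t <- seq(0, 1, length.out = stepsPerBlock)
      tpt <- tp0 + t * dtp
      nt <- n0 + t * dn
      pr <- tpt / nt
      pr[nt == 0] <- dtp / dn
      rc <- tpt / P
      auc <- auc + sum(diff(rc) * (pr[-1] + pr[-length(pr)]) / 2)
    }
    tp0 <- tp[b]; n0 <- nn[b]
  }
  auc
}

# Write a regulator TSV with arbitrary content (for loader error tests).
writeRegTsv <- function(lines, dir = tempdir()) {
  f <- tempfile("regs", fileext = ".tsv", tmpdir = dir)
  writeLines(c("gene\tsymbol\tcategory", lines), f)
  f
}

# Shared cache so expensive benchmark runs are computed once per session.
.benchCache <- new.env(parent = emptyenv())

benchmarkRun <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.benchCache[[key]])) return(.benchCache[[key]])
  spec <- syntheticGRNSpec(seed = seed)
  truth <- generateTrueNetwork(spec)
  expr <- simulateExpression(truth, spec)
  rs <- regulatorSetFromTruth(truth)
  grn <- inferNetwork(expr, rs, inferenceConfig(nTrees = 500, seed = seed))
  res <- list(spec = spec, truth = truth, rs = rs, grn = grn,
              trimmed = trimTopFraction(grn, 0.1))
  .benchCache[[key]] <- res
  res
}
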