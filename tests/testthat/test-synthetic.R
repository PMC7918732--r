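test_that("network generation is a pure function of the spec", {
  spec <- syntheticGRNSpec(nTF = 12, nEpi = 4, nTargets = 50, nSamples = 40,
                           nProcessRegulators = 2, processModuleSize = 20,
                           seed = 7)
  n1 <- generateTrueNetwork(spec)
  n2 <- generateTrueNetwork(spec)
  expect_identical(edges(n1), edges(n2))
  expect_identical(processModule(n1), processModule(n2))
  n3 <- generateTrueNetwork(syntheticGRNSpec(nTF = 12, nEpi = 4,
                                             nTargets = 50, nSamples = 40,
                                             nProcessRegulators = 2,
                                             processModuleSize = 20,
                                             seed = 8))
  expect_false(identical(edges(n1), edges(n3)))
})

test_that("planted hubs drive the stated share of module in-edges", {
  spec <- syntheticGRNSpec(nTF = 10, nEpi = 5, nTargets = 60, nSamples = 40,
                           nProcessRegulators = 2, processModuleSize = 20,
                           hubConcentration = 0.8, seed = 3)
  net <- generateTrueNetwork(spec)
  hubs <- processRegulators(net)
  expect_identical(length(hubs), 2L)
  # at least one hub is epigenetic when epigenetic regulators exist
  expect_true(any(regulatorClasses(net)[hubs] == "EPIGENETIC"))
  ed <- edges(net)
  inMod <- ed[ed$target %in% processModule(net), ]
  expect_gte(sum(inMod$regulator %in% hubs), 16L)
  # effects respect the configured magnitude range
  expect_true(all(abs(ed$effect) >= spec@effectLow - 1e-12))
  expect_true(all(abs(ed$effect) <= spec@effectHigh + 1e-12))
})

test_that("a spec without process regulators still fills the module", {
  spec <- syntheticGRNSpec(nTF = 8, nEpi = 0, nTargets = 30, nSamples = 20,
                           nProcessRegulators = 0, processModuleSize = 10,
                           seed = 2)
  net <- generateTrueNetwork(spec)
  expect_identical(processRegulators(net), character())
  expect_identical(length(processModule(net)), 10L)
  # every module gene still has an in-edge
  expect_true(all(processModule(net) %in% edges(net)$target))
})

test_that("infeasible module sizes are rejected", {
  expect_error(syntheticGRNSpec(nTargets = 10, processModuleSize = 30),
               "module")
  expect_error(syntheticGRNSpec(nTF = 1, nEpi = 0, nProcessRegulators = 3),
               "process regulators")
})

test_that("expression follows the linear-Gaussian structural model", {
  # noiseless copy: child equals parent exactly
  net <- new("TrueNetwork",
             edges = data.frame(regulator = "G000001", target = "G000002",
                                effect = 1),
             genes = c("G000001", "G000002"),
             regulatorClasses = c(G000001 = "TF"),
             processRegulators = character(),
             processModule = character())
  spec0 <- syntheticGRNSpec(nTF = 1, nEpi = 0, nTargets = 1,
                            nProcessRegulators = 0, processModuleSize = 0,
                            noiseSD = 0, nSamples = 50, seed = 1)
  m <- simulateExpression(net, spec0)
  expect_equal(m["G000002", ], m["G000001", ], tolerance = 1e-12)
  # two independent parents with beta = (1, -1), noise sd 0.5:
  # Var(child) = 1 + 1 + 0.25 within 3 standard errors at n = 2000
  net2 <- new("TrueNetwork",
              edges = data.frame(regulator = c("G000001", "G000002"),
                                 target = "G000003", effect = c(1, -1)),
              genes = c("G000001", "G000002", "G000003"),
              regulatorClasses = c(G000001 = "TF", G000002 = "TF"),
              processRegulators = character(),
              processModule = character())
  spec2 <- syntheticGRNSpec(nTF = 2, nEpi = 0, nTargets = 1,
                            nProcessRegulators = 0, processModuleSize = 0,
                            noiseSD = 0.5, nSamples = 2000, seed = 4)
  m2 <- simulateExpression(net2, spec2)
  v <- var(m2["G000003", ])
  se <- 2.25 * sqrt(2 / (2000 - 1))
  expect_lt(abs(v - 2.25), 3 * se)
  # determinism
  expect_identical(simulateExpression(net2, spec2), m2)
})

test_that("simulated matrices satisfy the inference preconditions", {
  spec <- syntheticGRNSpec(nTF = 10, nEpi = 3, nTargets = 40, nSamples = 30,
                           nProcessRegulators = 2, processModuleSize = 10,
                           seed = 11)
  net <- generateTrueNetwork(spec)
  m <- simulateExpression(net, spec)
  expect_identical(dim(m), c(53L, 30L))
  expect_false(anyNA(m))
  expect_true(all(epigrn:::.rowVar(m) > 1e-12))
})

test_that("DEG lists contaminate the module tail reproducibly", {
  spec <- syntheticGRNSpec(nTF = 10, nEpi = 5, nTargets = 80, nSamples = 30,
                           nProcessRegulators = 2, processModuleSize = 20,
                           seed = 5)
  net <- generateTrueNetwork(spec)
  module <- sort(processModule(net))
  expect_identical(makeDegList(net, 0), module)
  d1 <- makeDegList(net, 0.5, seed = 1)
  expect_identical(length(d1), 20L)
  expect_identical(sum(d1 %in% module), 10L)
  d2 <- makeDegList(net, 0.5, seed = 2)
  # true core identical across seeds, decoys differ
  expect_identical(intersect(d1, module), intersect(d2, module))
  expect_false(setequal(setdiff(d1, module), setdiff(d2, module)))
  # exclusion forces disjoint decoys
  d3 <- makeDegList(net, 0.5, seed = 3, exclude = setdiff(d1, module))
  expect_identical(intersect(setdiff(d1, module), setdiff(d3, module)),
                   character())
  expect_error(makeDegList(net, 1), "contamination")
})
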