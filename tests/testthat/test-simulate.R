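test_that("simulation is deterministic and leaves global RNG state alone", {
  cfg <- simulationConfig(60, 20, groups = list(plantedGroup(5, 8)),
                          nConfounders = 4, seed = 11)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  a <- simulateCompendium(cfg)
  b <- simulateCompendium(cfg)
  expect_identical(SummarizedExperiment::assay(a$exprs),
                   SummarizedExperiment::assay(b$exprs))
  expect_identical(groupMembers(a$truth), groupMembers(b$truth))
  expect_identical(runif(1), before)  # global stream untouched
})

test_that("a structure-free configuration yields near-zero correlations", {
  cfg <- simulationConfig(30, 150, seed = 5)
  sim <- simulateCompendium(cfg)
  cc <- corValues(correlateAllPairs(sim$exprs, "pearson"))
  off <- cc[upper.tri(cc)]
  expect_lt(max(abs(off)), 0.4)
  expect_lt(mean(abs(off)), 0.1)
})

test_that("high-SNR planted group members are near-collinear", {
  cfg <- simulationConfig(
    120, 100, groups = list(plantedGroup(5, 50, signalMean = 10,
                                         signalSd = 0.5)),
    baselineMean = 4, baselineSd = 0.5, seed = 3)
  sim <- simulateCompendium(cfg)
  members <- groupMembers(sim$truth)[[1]]
  cc <- corValues(correlateAllPairs(sim$exprs, "pearson"))
  within <- cc[members, members][upper.tri(diag(5))]
  expect_true(all(within > 0.9))
})

test_that("regulator profiles track their target groups", {
  cfg <- simulationConfig(
    80, 100,
    groups = list(plantedGroup(6, 40), plantedGroup(6, 40)),
    globalRegulators = list(c(1L, 2L)),
    residentRegulators = list(list(home = 1L, targets = 1L)),
    seed = 21)
  sim <- simulateCompendium(cfg)
  tr <- sim$truth
  regs <- regulatorTargets(tr)
  expect_length(regs, 2)
  cc <- corValues(correlateAllPairs(sim$exprs, "pearson"))
  for (reg in names(regs)) {
    targets <- unlist(groupMembers(tr)[regs[[reg]]])
    expect_gt(mean(cc[reg, targets]), 0.3)
  }
})

test_that("invalid configurations fail naming the violated constraint", {
  expect_error(simulationConfig(10, 2), "nSamples")
  expect_error(
    simulationConfig(10, 20, groups = list(plantedGroup(8, 30))),
    "activeSamples")
  expect_error(
    simulationConfig(5, 20, groups = list(plantedGroup(10, 5))),
    "exceed nGenes")
  expect_error(
    simulationConfig(10, 20, groups = list(plantedGroup(3, 5,
                                                        signalSd = -1))),
    "signalSd")
  expect_error(
    simulationConfig(50, 20, nConfounders = 5),
    "at least one planted group")
  expect_error(
    simulationConfig(50, 20, groups = list(plantedGroup(3, 5)),
                     globalRegulators = list(2L)),
    "out of range")
})

test_that("within-group correlation exceeds between-group correlation", {
  cfg <- simulationConfig(
    100, 120,
    groups = list(plantedGroup(6, 1:40), plantedGroup(6, 61:100)),
    seed = 13)
  sim <- simulateCompendium(cfg)
  gm <- groupMembers(sim$truth)
  cc <- corValues(correlateAllPairs(sim$exprs, "pearson"))
  within <- mean(c(cc[gm[[1]], gm[[1]]][upper.tri(diag(6))],
                   cc[gm[[2]], gm[[2]]][upper.tri(diag(6))]))
  between <- mean(cc[gm[[1]], gm[[2]]])
  expect_gt(within, between)
  expect_gt(within, 0.8)
})

test_that("rare-cluster scenario has the documented planted structure", {
  fx <- scenarioFixture()
  tr <- fx$truth
  sizes <- lengths(groupActiveSamples(tr))
  expect_gte(sum(sizes <= 5), 2)              # rarely expressed groups
  expect_gte(length(confounderIds(tr)), 20)   # sparse confounders
  expect_gte(ncol(fx$exprs), 150)
  expect_length(intersect(unlist(groupMembers(tr)), confounderIds(tr)), 0)
  # determinism of the canned scenario
  again <- rareClusterScenario(1)
  expect_identical(SummarizedExperiment::assay(again$exprs), fx$exprs)
})

test_that("every scenario confounder spuriously correlates with a planted gene", {
  fx <- scenarioFixture()
  members <- unlist(groupMembers(fx$truth))
  cc <- corValues(fx$pcc)
  maxR <- apply(abs(cc[confounderIds(fx$truth), members, drop = FALSE]),
                1, max)
  expect_true(all(maxR >= 0.5))
})

test_that("confounders have fewer MR-top-10 partners in planted groups than members", {
  fx <- scenarioFixture()
  mr <- mrValues(fx$mr)
  gm <- groupMembers(fx$truth)
  allMembers <- unlist(gm)
  top10InGroups <- function(gene) {
    o <- order(mr[gene, ], na.last = NA)[1:10]
    sum(colnames(mr)[o] %in% allMembers)
  }
  memberMean <- mean(vapply(allMembers, top10InGroups, numeric(1)))
  confMean <- mean(vapply(confounderIds(fx$truth), top10InGroups,
                          numeric(1)))
  expect_gt(memberMean, confMean)
})
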