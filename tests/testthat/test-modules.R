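triangleNet <- function() toyNetwork(cliqueEdges(c("a", "b", "c")))

test_that("cohesiveness matches its defining formula on hand-computed cases", {
  tri <- triangleNet()
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 0), 1)
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 2), 1 / 3)
  expect_equal(cohesiveness(tri, "a", penalty = 0), 0)  # no internal weight
  expect_equal(cohesiveness(tri, c("a", "b"), penalty = 0), 1 / 3)
  expect_error(cohesiveness(tri, character()), "empty")
  ## agreement with the edge-list oracle on an irregular weighted graph
  e <- data.frame(from = c("a", "a", "b", "c", "d"),
                  to   = c("b", "c", "c", "d", "e"),
                  weight = c(0.9, 0.4, 0.7, 0.2, 0.8))
  net <- toyNetwork(e)
  for (genes in list(c("a", "b"), c("a", "b", "c"), c("c", "d", "e"),
                     c("a", "b", "c", "d", "e")))
    expect_equal(cohesiveness(net, genes), bruteCohesiveness(net, genes))
})

test_that("growth from a seed reaches the locally optimal set", {
  ## isolated seed: nothing to do
  net <- toyNetwork(cliqueEdges(c("a", "b", "c")), nodes = c("a", "b", "c",
                                                             "iso"))
  m <- growModule(net, "iso")
  expect_identical(moduleGenes(m, 1), "iso")
  expect_equal(cohesivenessScores(m), 0)
  ## seed inside a 5-clique attached to the rest by one light edge
  e <- rbind(cliqueEdges(paste0("c", 1:5)),
             data.frame(from = "c5", to = "z1", weight = 0.05),
             cliqueEdges(paste0("z", 1:4), weight = 0.3))
  net2 <- toyNetwork(e)
  m2 <- growModule(net2, "c2")
  expect_identical(moduleGenes(m2, 1), paste0("c", 1:5))
  expect_true(bruteLocallyOptimal(net2, moduleGenes(m2, 1)))
  ## determinism
  expect_identical(moduleGenes(growModule(net2, "c2"), 1),
                   moduleGenes(m2, 1))
})

test_that("two bridged cliques are detected as two modules", {
  e <- rbind(cliqueEdges(paste0("a", 1:5)),
             cliqueEdges(paste0("b", 1:5)),
             data.frame(from = "a5", to = "b1", weight = 0.05))
  net <- toyNetwork(e)
  mods <- detectModules(net)
  expect_equal(moduleCount(mods), 2)
  expect_setequal(vapply(moduleGenes(mods), moduleKey, character(1)),
                  c(moduleKey(paste0("a", 1:5)),
                    moduleKey(paste0("b", 1:5))))
  ## both are genuine local optima and pass the filters
  for (g in moduleGenes(mods)) {
    expect_true(bruteLocallyOptimal(net, g))
    expect_gte(bruteDensity(net, g), 0.3)
  }
})

test_that("small prototype graphs match the exhaustive-search oracle", {
  graphs <- list(
    clique4 = toyNetwork(cliqueEdges(paste0("k", 1:4))),
    path4 = toyNetwork(data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "d"), weight = 1)),
    star = toyNetwork(data.frame(from = "hub", to = c("t1", "t2", "t3"),
                                 weight = 1)),
    weighted = toyNetwork(rbind(
      cliqueEdges(paste0("u", 1:4), weight = 0.9),
      cliqueEdges(paste0("v", 1:3), weight = 0.8),
      data.frame(from = "u4", to = "v1", weight = 0.1)))
  )
  for (nm in names(graphs)) {
    net <- graphs[[nm]]
    mods <- detectModules(net)
    oracle <- vapply(bruteEnumerateModules(net), moduleKey, character(1))
    got <- vapply(moduleGenes(mods), moduleKey, character(1))
    ## everything emitted is a locally optimal filter-passing set...
    expect_true(all(got %in% oracle), label = nm)
    ## ...and verifies single-move local optimality directly
    for (g in moduleGenes(mods))
      expect_true(bruteLocallyOptimal(net, g), label = nm)
  }
  ## the 4-clique is recovered exactly as one module covering all nodes
  expect_identical(moduleGenes(detectModules(graphs$clique4), 1),
                   paste0("k", 1:4))
})

test_that("identical grown candidates merge into one module", {
  net <- toyNetwork(cliqueEdges(paste0("k", 1:4)))
  ## seeding every node grows the same clique four times; the omega >= 0.8
  ## merge collapses the duplicates
  mods <- detectModules(net, seedMode = "all")
  expect_equal(moduleCount(mods), 1)
  expect_identical(moduleGenes(mods, 1), paste0("k", 1:4))
})

test_that("module detection is deterministic", {
  fx <- scenarioFixture()
  again <- detectModules(fx$nets$NET10)
  expect_identical(moduleGenes(again), moduleGenes(fx$modules10))
  expect_identical(cohesivenessScores(again),
                   cohesivenessScores(fx$modules10))
})

test_that("detected modules on the scenario network are locally optimal", {
  fx <- scenarioFixture()
  mods <- fx$modules10
  for (i in seq_len(moduleCount(mods)))
    expect_true(bruteLocallyOptimal(fx$nets$NET10, moduleGenes(mods, i)))
})

test_that("metamodule collapse takes the union of anchor-containing modules", {
  ms <- methods::new("ModuleSet",
    genes = list(c("A", "B", "C"), c("B", "D"), c("X", "Y", "Z")),
    cohesiveness = c(0.9, 0.8, 0.7), density = c(1, 1, 1),
    sourceNetwork = "NET10", params = list())
  mm <- collapseMetamodule(ms, "B")
  expect_identical(metamoduleGenes(mm), c("A", "B", "C", "D"))
  expect_equal(nrow(contributingModules(mm)), 2)
  ## anchors in no module: empty metamodule with a warning, not an error
  expect_warning(empty <- collapseMetamodule(ms, "missing"), "empty")
  expect_length(metamoduleGenes(empty), 0)
  expect_error(collapseMetamodule(ms, character()), "non-empty")
  ## pooling across module sets from several networks
  ms2 <- methods::new("ModuleSet",
    genes = list(c("D", "E")), cohesiveness = 0.5, density = 1,
    sourceNetwork = "NET25", params = list())
  mm2 <- collapseMetamodule(list(ms, ms2), c("B", "E"))
  expect_identical(metamoduleGenes(mm2), c("A", "B", "C", "D", "E"))
  expect_setequal(contributingModules(mm2)$source_network,
                  c("NET10", "NET10", "NET25"))
})
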