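test_that("MR network edges require both the PCC and the weight filter", {
  ## gA-gB strongly correlated mutual best partners; gC anti-correlated
  ## with gA (high |r| but signed r < 0.3 must be excluded)
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  set.seed(1)
  m <- rbind(gA = a + rnorm(8, 0, 0.01), gB = a + rnorm(8, 0, 0.01),
             gC = -a + rnorm(8, 0, 0.01), gD = c(3, 1, 4, 1, 5, 9, 2, 6))
  colnames(m) <- paste0("s", 1:8)
  net <- buildMRNetwork(m, x = 10)
  e <- networkEdges(net)
  expect_true(any(e$from == "gA" & e$to == "gB"))
  expect_false(any((e$from == "gA" & e$to == "gC") |
                   (e$from == "gC" & e$to == "gA")))
  ## a high-PCC pair with a large MR is excluded by the weight filter
  w <- decayWeight(60, 10)
  expect_lt(w, 0.1)
})

test_that("network nesting: NET05 within NET10 within NET25", {
  fx <- scenarioFixture()
  key <- function(net) {
    e <- networkEdges(net)
    paste(e$from, e$to)
  }
  e05 <- key(fx$nets$NET05)
  e10 <- key(fx$nets$NET10)
  e25 <- key(fx$nets$NET25)
  expect_true(all(e05 %in% e10))
  expect_true(all(e10 %in% e25))
  expect_lte(length(e05), length(e10))
  expect_lte(length(e10), length(e25))
  ## shared edges keep a larger weight under a larger x
  expect_true(all(networkEdges(fx$nets$NET25)$weight[
    match(e10, e25)] >= networkEdges(fx$nets$NET10)$weight))
})

test_that("SCC network keeps signed rho and applies the absolute threshold", {
  a <- c(5, 1, 4, 2, 8, 3, 9, 7)
  set.seed(2)
  m <- rbind(gA = a, gB = a^3, gC = -2 * a + rnorm(8, 0, 0.01),
             gD = rnorm(8))
  colnames(m) <- paste0("s", 1:8)
  net <- buildSCCNetwork(m, rhoMin = 0.5)
  e <- networkEdges(net)
  ab <- e[e$from == "gA" & e$to == "gB", ]
  expect_equal(ab$rho, 1)            # monotone pair
  ac <- e[e$from == "gA" & e$to == "gC", ]
  expect_equal(ac$rho, -1)           # anti-monotone pair kept with sign
  expect_equal(ac$weight, 1)         # weight is |rho|
  expect_true(all(abs(e$rho) >= 0.5))
})

test_that("independent noise genes produce essentially no SCC edges", {
  set.seed(99)
  m <- matrix(rnorm(30 * 150, 5, 1), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30),
                              sprintf("s%03d", 1:150)))
  net <- buildSCCNetwork(m, rhoMin = 0.5)
  expect_lte(nrow(networkEdges(net)), 1)
})

test_that("the Spearman network is invariant under monotone per-gene transforms", {
  set.seed(17)
  m <- matrix(rnorm(20 * 40, 6, 1.5), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:40)))
  m[1:5, 1:20] <- m[1:5, 1:20] + 4   # some real structure
  net1 <- buildSCCNetwork(m, rhoMin = 0.4)
  m2 <- m
  m2[1, ] <- exp(m2[1, ] / 3)        # strictly increasing
  m2[2, ] <- m2[2, ]^3 / 100
  m2[3, ] <- 5 * m2[3, ] - 2
  net2 <- buildSCCNetwork(m2, rhoMin = 0.4)
  expect_identical(networkEdges(net1)[c("from", "to")],
                   networkEdges(net2)[c("from", "to")])
  expect_equal(networkEdges(net1)$rho, networkEdges(net2)$rho,
               tolerance = 1e-12)
})

test_that("subnetworkContaining returns the components of the query genes", {
  e <- rbind(cliqueEdges(c("a1", "a2", "a3")),
             cliqueEdges(c("b1", "b2", "b3")))
  net <- toyNetwork(e, nodes = c("a1", "a2", "a3", "b1", "b2", "b3",
                                 "iso"))
  sub <- subnetworkContaining(net, "a1")
  expect_setequal(networkNodes(sub), c("a1", "a2", "a3"))
  ## two query genes in one component: returned once
  sub2 <- subnetworkContaining(net, c("a1", "a2"))
  expect_setequal(networkNodes(sub2), c("a1", "a2", "a3"))
  ## isolated query gene gives a single-node component
  sub3 <- subnetworkContaining(net, "iso")
  expect_identical(networkNodes(sub3), "iso")
  expect_equal(nrow(networkEdges(sub3)), 0)
  ## query absent from the network: empty result tolerated
  expect_length(networkNodes(subnetworkContaining(net, "zz")), 0)
  lc <- largestComponent(net)
  expect_setequal(networkNodes(lc), c("a1", "a2", "a3"))  # id tie-break
})

test_that("a regulator's SCC component contains most of its regulon", {
  fx <- compendiumFixture()
  reg <- fx$pc$globalRegulator
  regulon <- groupMembers(fx$truth)[[regulatorTargets(fx$truth)[[reg]]]]
  sub <- subnetworkContaining(fx$scc, reg)
  expect_gte(mean(regulon %in% networkNodes(sub)), 0.8)
})
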