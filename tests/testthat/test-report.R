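miniCatalog <- function() {
  bgcCatalog(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "tfX", "tfY"),
    bgc_id = c("B1", "B1", "B1", "B2", "B2", "B1", NA),
    role = c("core", "tailoring", "transporter", "core", "tailoring",
             "TF", "TF"),
    core_type = c("PKS", "none", "none", "NRPS", "none", "none", "none"),
    chromosome = "chr1", start = c(1, 100, 200, 300, 400, 500, 600),
    end = c(50, 150, 250, 350, 450, 550, 650),
    stringsAsFactors = FALSE))
}

test_that("catalog TSV round-trips and malformed input is rejected", {
  cat1 <- miniCatalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCatalog(cat1, path)
  back <- loadCatalog(path)
  expect_equal(catalogTable(back), catalogTable(cat1))
  ## start > end
  bad <- catalogTable(cat1)
  bad$start[1] <- 999
  expect_error(bgcCatalog(bad), "start > end")
  ## duplicate gene id
  dup <- catalogTable(cat1)
  dup$gene_id[2] <- "g1"
  expect_error(bgcCatalog(dup), "duplicate")
  ## catalog without coordinates is accepted with NA coordinates
  slim <- catalogTable(cat1)[, c("gene_id", "bgc_id", "role", "core_type")]
  noCoord <- bgcCatalog(slim)
  expect_true(all(is.na(catalogTable(noCoord)$start)))
  ## malformed row gets a line number
  lines <- readLines(path)
  writeLines(c(lines, "broken\trow"), path)
  expect_error(loadCatalog(path), "line")
})

test_that("BGC-module overlap counts genes and flags shared modules", {
  cat1 <- miniCatalog()
  ms <- methods::new("ModuleSet",
    genes = list(c("g1", "g2", "g3", "other"), c("g4", "noise1", "noise2")),
    cohesiveness = c(0.8, 0.6), density = c(0.9, 0.5),
    sourceNetwork = "NET10", params = list())
  rep <- bgcModuleOverlap(ms, cat1)
  tab <- bgcTable(rep)
  b1 <- tab[tab$bgc_id == "B1", ]
  expect_equal(b1$n_recovered, 3)
  expect_true(b1$coexpressed)       # g1, g2, g3 share module 1
  b2 <- tab[tab$bgc_id == "B2", ]
  expect_equal(b2$n_recovered, 1)
  expect_false(b2$coexpressed)      # only one B2 gene in any module
  ## counts equal brute-force recomputation from the same inputs
  pool <- moduleGenes(ms)
  for (bgc in tab$bgc_id) {
    gs <- catalogTable(cat1)$gene_id[
      !is.na(catalogTable(cat1)$bgc_id) & catalogTable(cat1)$bgc_id == bgc]
    expect_equal(tab$n_recovered[tab$bgc_id == bgc],
                 sum(vapply(gs, function(g)
                   any(vapply(pool, function(p) g %in% p, logical(1))),
                   logical(1))))
    expect_equal(tab$coexpressed[tab$bgc_id == bgc],
                 any(vapply(pool, function(p) sum(gs %in% p) >= 2,
                            logical(1))))
  }
  ## pure function: repeated calls identical
  expect_equal(bgcTable(bgcModuleOverlap(ms, cat1)), tab)
})

test_that("TF coexpression counts follow the SCC-edge and shared-module rules", {
  cat1 <- miniCatalog()
  scc <- toyNetwork(data.frame(
    from = c("tfX", "tfX", "g1", "tfY"),
    to = c("g1", "g4", "g2", "g5"),
    weight = c(0.8, 0.6, 0.9, 0.7)), name = "SCC")
  ms <- methods::new("ModuleSet",
    genes = list(c("tfX", "g4", "noise"), c("g1", "g2")),
    cohesiveness = c(0.7, 0.6), density = c(0.8, 0.9),
    sourceNetwork = "NET10", params = list())
  rep <- tfCoreCoexpressionCounts(scc, ms, cat1, c("tfX", "tfY"))
  tab <- tfTable(rep)
  x <- tab[tab$tf_id == "tfX", ]
  expect_equal(x$scc_count, 2)   # adjacent cores g1 and g4
  expect_equal(x$mr_count, 1)    # shares a module with core g4 only
  expect_true(x$clustered)
  y <- tab[tab$tf_id == "tfY", ]
  expect_equal(y$scc_count, 0)   # g5 is not a core gene
  expect_equal(y$mr_count, 0)
  expect_false(y$clustered)
  expect_error(tfCoreCoexpressionCounts(scc, ms, cat1, "nope"), "unknown")
  ## details allow recomputing every count
  det <- reportDetails(rep)
  expect_identical(det$tfSccCores$tfX, c("g1", "g4"))
  expect_identical(det$tfMrCores$tfX, "g4")
})

test_that("shortlisting labels global and pathway-specific regulators", {
  cat1 <- miniCatalog()
  mkRep <- function(scc, mrCores) {
    tfTab <- data.frame(tf_id = "tfX", scc_count = scc,
                        mr_count = length(mrCores), clustered = TRUE,
                        bgc_id = "B1", stringsAsFactors = FALSE)
    methods::new("CoexpressionReport", bgcTable = data.frame(),
                 tfTable = tfTab,
                 details = list(tfSccCores = list(tfX = character()),
                                tfMrCores = list(tfX = mrCores)),
                 params = list())
  }
  ## high SCC count: global
  sl <- shortlistTFs(mkRep(14, character()), cat1)
  expect_equal(sl$category, "global (SCC)")
  expect_equal(sl$clustered, "clustered")
  ## shares modules with cores of two distinct BGCs: pathway-specific
  sl2 <- shortlistTFs(mkRep(0, c("g1", "g4")), cat1)
  expect_equal(sl2$category, "pathway-specific (MR-PCC)")
  expect_equal(sl2$mr_bgcs, "B1,B2")
  ## cores of a single BGC and low SCC count: not shortlisted
  sl3 <- shortlistTFs(mkRep(3, "g1"), cat1)
  expect_equal(nrow(sl3), 0)
  ## empty report: empty shortlist
  empty <- methods::new("CoexpressionReport", bgcTable = data.frame(),
                        tfTable = mkRep(0, character())@tfTable[0, ],
                        details = list(tfMrCores = list()), params = list())
  expect_equal(nrow(shortlistTFs(empty, cat1)), 0)
})

test_that("no silent BGC is flagged coexpressed on the planted compendium", {
  fx <- compendiumFixture()
  rep <- bgcModuleOverlap(unname(fx$modules), fx$catalog)
  tab <- bgcTable(rep)
  silent <- c("BGC09", "BGC10", "BGC11")
  expect_false(any(tab$coexpressed[tab$bgc_id %in% silent]))
  ## at most a stray singleton straggler; never two genes sharing a module
  expect_lte(max(tab$n_recovered[tab$bgc_id %in% silent]), 1)
  ## every transcribed BGC is flagged
  expect_true(all(tab$coexpressed[!tab$bgc_id %in% silent]))
})

test_that("the BGC correlation submatrix extracts the catalog members", {
  fx <- compendiumFixture()
  pcc <- correlateAllPairs(fx$exprs[1:60, ], "pearson")
  sub <- bgcCorrelationSubmatrix(pcc, fx$catalog, "BGC01")
  inB1 <- catalogTable(fx$catalog)
  inB1 <- inB1$gene_id[!is.na(inB1$bgc_id) & inB1$bgc_id == "BGC01"]
  expect_setequal(rownames(sub), intersect(inB1, rownames(fx$exprs)[1:60]))
  expect_error(bgcCorrelationSubmatrix(pcc, fx$catalog, "nope"), "unknown")
})
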