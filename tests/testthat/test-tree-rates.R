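test_that("root-to-anchor distances are hand-computable and additive", {
  sp <- SpeciesPhylogeny("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1):0.0;",
                         cladeMembers = c("A", "B"))
  ts <- new("OrthologTreeSet",
            trees = list(og1 = speciesTree(sp)), phylogeny = sp)
  d <- rootToAnchorDistances(ts)
  expect_equal(d$clade_dist[d$species %in% c("A", "B")], c(0.1, 0.1))
  expect_equal(d$base_dist, rep(0.1, 4))
  ## additivity for clade members
  cm <- d[!is.na(d$clade_dist), ]
  expect_equal(cm$order_dist, cm$clade_dist + cm$base_dist,
               tolerance = 1e-9)
})

test_that("distances on simulated trees match the generator ground truth in the degenerate case", {
  cfg <- simulationConfig(seed = 4, nOrthologs = 5,
                          baselineRateShape = Inf,
                          branchNoiseShape = Inf)
  sim <- simulateGeneTrees(cfg)
  d <- rootToAnchorDistances(sim$trees)
  cm <- d[!is.na(d$clade_dist), ]
  expect_equal(
    as.numeric(tapply(cm$clade_dist, cm$species, unique)[
      names(sim$truth$expected_clade_dist)]),
    unname(sim$truth$expected_clade_dist), tolerance = 1e-12)
  ## additivity holds across a noisy simulated set too
  simN <- simulateGeneTrees(simulationConfig(seed = 9, nOrthologs = 30))
  dn <- rootToAnchorDistances(simN$trees)
  cn <- dn[!is.na(dn$clade_dist), ]
  expect_equal(cn$order_dist, cn$clade_dist + cn$base_dist,
               tolerance = 1e-9)
})

test_that("place assignment ranks longest branch first with deterministic ties", {
  sp <- chalcidPhylogeny()
  d <- data.frame(
    ortholog = "og1", species = c("TPRE", "CSOL", "CFLO", "NVIT"),
    clade_dist = c(0.5, 0.3, 0.2, 0.1), order_dist = NA, base_dist = 0.1)
  pt <- placeTable(d)
  expect_equal(placeMatrix(pt)["og1", c("TPRE", "CSOL", "CFLO", "NVIT")],
               c(TPRE = 1L, CSOL = 2L, CFLO = 3L, NVIT = 4L))
  expect_length(pt@tied, 0L)
  ## ties broken by species-name order and flagged
  d$clade_dist <- c(0.5, 0.3, 0.3, 0.1)
  pt2 <- placeTable(d)
  expect_equal(pt2@tied, "og1")
  expect_lt(placeMatrix(pt2)["og1", "CFLO"], placeMatrix(pt2)["og1", "CSOL"])
})

test_that("place table marginals sum to the ortholog count and match a sort oracle", {
  sim <- simulateGeneTrees(simulationConfig(seed = 21, nOrthologs = 200))
  d <- rootToAnchorDistances(sim$trees)
  pt <- placeTable(d)
  n <- length(sim$trees)
  expect_equal(unname(rowSums(placeCounts(pt))), rep(n, 4))
  expect_equal(unname(colSums(placeCounts(pt))), rep(n, 4))
  ## independent repeated-max oracle, every ortholog
  cm <- d[!is.na(d$clade_dist), ]
  for (og in unique(cm$ortholog)) {
    rows <- cm[cm$ortholog == og, ]
    expect_equal(
      placeMatrix(pt)[og, names(oraclePlaces(setNames(rows$clade_dist,
                                                      rows$species)))],
      oraclePlaces(setNames(rows$clade_dist, rows$species)))
  }
})

test_that("expected place count is n/k with nearest-integer rendering", {
  e <- expectedPlaceCount(1311, 4)
  expect_equal(e$expected, 327.75)
  expect_identical(e$rounded, 328L)
  expect_equal(expectedPlaceCount(100, 4)$expected, 25)
  expect_equal(expectedPlaceCount(1311, 7)$expected, 1311 / 7,
               tolerance = 1e-12)
  expect_error(expectedPlaceCount(100, 0), "kSpecies")
})

test_that("branch-length normalization is a ratio, excludes zero bases, and is scale invariant", {
  d <- data.frame(ortholog = c("a", "a", "b"),
                  species = c("X", "Y", "X"),
                  clade_dist = c(0.2, 0, 0.3),
                  order_dist = NA, base_dist = c(0.1, 0.1, 0))
  expect_warning(nb <- normalizeBranch(d), "base_dist = 0")
  expect_equal(nb$normalized_length, c(2, 0))
  expect_equal(attr(nb, "excluded"), "b")
  ## scaling every branch of one gene tree leaves normalization, places
  ## and ranks unchanged
  sim <- simulateGeneTrees(simulationConfig(seed = 2, nOrthologs = 20))
  ts <- sim$trees
  scaled <- ts
  scaled@trees[[3L]]$edge.length <- scaled@trees[[3L]]$edge.length * 7.5
  d1 <- rootToAnchorDistances(ts); d2 <- rootToAnchorDistances(scaled)
  n1 <- normalizeBranch(d1); n2 <- normalizeBranch(d2)
  expect_equal(n1$normalized_length, n2$normalized_length,
               tolerance = 1e-9)
  expect_identical(placeMatrix(placeTable(d1)),
                   placeMatrix(placeTable(d2)))
  ## within-genome ranks are invariant when every gene tree is scaled by
  ## the same constant (ranks compare orthologs within one species)
  all2 <- ts
  for (i in seq_along(all2@trees))
    all2@trees[[i]]$edge.length <- all2@trees[[i]]$edge.length * 3.1
  dAll <- rootToAnchorDistances(all2)
  tp1 <- d1$clade_dist[d1$species == "TPRE" & !is.na(d1$clade_dist)]
  tpA <- dAll$clade_dist[dAll$species == "TPRE" & !is.na(dAll$clade_dist)]
  expect_identical(assignRanks(tp1), assignRanks(tpA))
})

test_that("rank assignment yields a deterministic permutation", {
  expect_equal(assignRanks(c(0.1, 0.3, 0.2)), c(1L, 3L, 2L))
  expect_equal(assignRanks(c(0.1, 0.3, 0.2), "decreasing"), c(3L, 1L, 2L))
  ## ties broken by input (ortholog-id) order
  expect_equal(assignRanks(c(0.2, 0.2, 0.1)), c(2L, 3L, 1L))
  set.seed(1)
  for (i in 1:20) {
    v <- sample(c(runif(30), runif(5)))  # may contain near-ties
    r <- assignRanks(v)
    expect_setequal(r, seq_along(v))
  }
  expect_error(assignRanks(c(1, NA)), "non-finite")
})

test_that("rank-discrepancy scores match the worked convention", {
  expect_identical(rankChangeScore(10, 1000), 990L)
  expect_identical(rankChangeScore(42, 42), 0L)
  expect_identical(rankChangeScore(1000, 10), -990L)
  ## half-integer comparison ranks round half away from zero
  expect_identical(rankChangeScore(10, 15.5), 6L)
  expect_identical(rankChangeScore(16, 10.5), -6L)
  expect_error(rankChangeScore(0, 5), ">= 1")
  expect_error(rankChangeScore(5, 2000, nProteins = 1311), "exceeds")
})

test_that("median rank follows the even-count convention", {
  expect_equal(medianRank(c(10, 20, 30)), 20)
  expect_equal(medianRank(c(10, 20)), 15)
  expect_equal(medianRank(c(5, 5, 5, 5)), 5)
  expect_error(medianRank(numeric()), "at least one")
})

test_that("binned selection partitions 1311 proteins as 13 full bins plus a remainder", {
  set.seed(42)
  n <- 1311
  scores <- setNames(sample(-500:500, n, replace = TRUE),
                     sprintf("p%04d", 1:n))
  sel <- binAndSelect(scores, baseRanks = sample(n), binSize = 100,
                      fraction = 0.10)
  expect_equal(nrow(sel$bins), 14L)
  expect_equal(sel$bins$occupancy, c(rep(100L, 13L), 11L))
  expect_equal(sel$bins$selected, c(rep(10L, 13L), 1L))
  expect_length(sel$fast, 131L)
  expect_length(sel$slow, 131L)
})

test_that("binned selection agrees with a brute-force oracle and flags ties", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(30:200, 1)
    scores <- setNames(sample(-20:20, n, replace = TRUE),
                       sprintf("g%03d", 1:n))
    base <- sample(n)
    got <- binAndSelect(scores, base, binSize = 25, fraction = 0.10)
    exp <- oracleBinSelect(scores, base, binSize = 25, fraction = 0.10)
    expect_setequal(got$fast, exp$fast)
    expect_setequal(got$slow, exp$slow)
  }
  allEq <- setNames(rep(0, 40), sprintf("g%02d", 1:40))
  tied <- binAndSelect(allEq, seq_len(40), binSize = 20, fraction = 0.10)
  expect_true(all(tied$tiedBins))
})

test_that("three-set overlap partition covers the union exactly", {
  ov <- overlapPartition(c("1", "2"), c("2", "3"), "2")
  expect_equal(ov[["A"]], 1L)
  expect_equal(ov[["B"]], 1L)
  expect_equal(ov[["ABC"]], 1L)
  expect_equal(sum(ov), 3L)
  same <- overlapPartition(letters[1:4], letters[1:4], letters[1:4])
  expect_equal(same[["ABC"]], 4L)
  expect_equal(sum(same), 4L)
  set.seed(3)
  for (i in 1:20) {
    a <- sample(letters, sample(5:15, 1))
    b <- sample(letters, sample(5:15, 1))
    c_ <- sample(letters, sample(5:15, 1))
    expect_equal(sum(overlapPartition(a, b, c_)),
                 length(unique(c(a, b, c_))))
  }
})

test_that("gene-tree reading validates taxa, lengths and topology", {
  sp <- chalcidPhylogeny()
  f <- tempfile()
  sim <- simulateGeneTrees(simulationConfig(seed = 1, nOrthologs = 3))
  writeGeneTrees(sim$trees, f)
  rt <- readGeneTrees(f, sp)
  expect_length(rt, 3L)
  ## re-reading gives identical distances
  expect_equal(rootToAnchorDistances(rt), rootToAnchorDistances(sim$trees),
               tolerance = 1e-9)
  ## missing leaf
  tr <- speciesTree(sp)
  writeLines(paste0("bad1\t", ape::write.tree(ape::drop.tip(tr, "TPRE"))), f)
  expect_error(readGeneTrees(f, sp), "missing leaf TPRE")
  ## extra leaf
  writeLines("bad2\t((AROS:1,XXX:1):1,(OABI:0.9,(MDEM:0.8,(AMEL:0.7,(TPRE:0.55,(CSOL:0.4,(CFLO:0.25,NVIT:0.25):0.15):0.15):0.15):0.1):0.1):0.1);",
             f)
  expect_error(readGeneTrees(f, sp), "unexpected leaf XXX")
  ## malformed newick aborts unless skipBad
  ok <- paste0("good\t", ape::write.tree(tr))
  writeLines(c(ok, "bad3\t((A:1,B:1"), f)
  expect_error(readGeneTrees(f, sp), "bad3")
  expect_warning(part <- readGeneTrees(f, sp, skipBad = TRUE), "bad3")
  expect_length(part, 1L)
})
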