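test_that("dinucleotide O/E follows the windowed formula", {
  r <- dinucleotideOE("CGCGCG")
  expect_equal(r$oe, 2.0)
  expect_equal(r$n_xy, 3L)
  ## C and G present but no CG dinucleotide
  expect_equal(dinucleotideOE("CCCGGG")$oe > 0, TRUE)
  expect_equal(dinucleotideOE("GGGCCC", "CG")$oe, 0)
  ## undefined when a base is absent
  expect_false(dinucleotideOE("AAAA")$defined)
  ## windows containing N are skipped with the length adjusted
  withN <- dinucleotideOE("CGNCG")
  expect_equal(withN$n_xy, 2L)
  expect_equal(withN$length, 3L)  # two valid windows + 1
})

test_that("CpG O/E is reverse-complement invariant and GpC mirrors the C/G swap", {
  set.seed(51)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    expect_equal(dinucleotideOE(s, "CG")$oe, dinucleotideOE(rc, "CG")$oe,
                 tolerance = 1e-12)
    expect_equal(dinucleotideOE(s, "GC")$oe, dinucleotideOE(rc, "GC")$oe,
                 tolerance = 1e-12)
    swapped <- chartr("CG", "GC", s)
    expect_equal(dinucleotideOE(s, "GC")$oe,
                 dinucleotideOE(swapped, "CG")$oe, tolerance = 1e-12)
  }
})

test_that("gene fractional methylation is read-weighted with coverage filters", {
  sites <- data.frame(seqid = "c1", pos = c(10, 20, 30), strand = "+",
                      context = "CpG",
                      meth_reads = c(5, 0, 2), total_reads = c(10, 10, 1))
  span <- list(gene = "g1", seqid = "c1", start = 1, end = 25)
  r <- geneFractionalMethylation(sites, span, minCoverage = 1,
                                 minSites = 2)
  expect_equal(r$fraction, 5 / 20)  # positions 10 and 20 only
  expect_equal(r$n_sites, 2L)
  ## all sites fully methylated
  full <- data.frame(seqid = "c1", pos = c(5, 6), strand = "+",
                     context = "CpG", meth_reads = c(8, 12),
                     total_reads = c(8, 12))
  expect_equal(geneFractionalMethylation(full,
    list(gene = "g", seqid = "c1", start = 1, end = 10),
    minSites = 1)$fraction, 1)
  ## weighted equals unweighted only at equal totals
  uneq <- data.frame(seqid = "c1", pos = c(1, 2), strand = "+",
                     context = "CpG", meth_reads = c(1, 5),
                     total_reads = c(2, 10))
  sp <- list(gene = "g", seqid = "c1", start = 1, end = 2)
  expect_equal(geneFractionalMethylation(uneq, sp, minSites = 1)$fraction,
               geneFractionalMethylation(uneq, sp, minSites = 1,
                                         weighted = FALSE)$fraction)
  uneq2 <- uneq; uneq2$meth_reads <- c(2, 5)
  expect_false(isTRUE(all.equal(
    geneFractionalMethylation(uneq2, sp, minSites = 1)$fraction,
    geneFractionalMethylation(uneq2, sp, minSites = 1,
                              weighted = FALSE)$fraction)))
  ## weighted fraction bounded by per-site extremes
  set.seed(52)
  for (i in 1:10) {
    tot <- sample(5:30, 6, replace = TRUE)
    met <- rbinom(6, tot, runif(1))
    st <- data.frame(seqid = "c1", pos = 1:6, strand = "+",
                     context = "CpG", meth_reads = met, total_reads = tot)
    fr <- geneFractionalMethylation(st,
      list(gene = "g", seqid = "c1", start = 1, end = 6),
      minSites = 1)$fraction
    expect_gte(fr, min(met / tot))
    expect_lte(fr, max(met / tot))
  }
  ## zero covered sites
  none <- geneFractionalMethylation(sites,
    list(gene = "g", seqid = "c9", start = 1, end = 5))
  expect_equal(none$status, "no_data")
})

test_that("the 0.01 status threshold is strict", {
  expect_equal(classifyMethylated(0.005), "unmethylated")
  expect_equal(classifyMethylated(0.0100), "unmethylated")
  expect_equal(classifyMethylated(0.5), "methylated")
})

test_that("positional profiles recover a planted 5' gradient", {
  cfg <- simulationConfig(seed = 61, nOrthologs = 40, fivePrimeBias = 0.4,
                          methClassProportions = c(methylated = 1,
                                                   unmethylated = 0))
  sim <- simulateMethylome(cfg)
  mt <- methylationTable(sim$sites, sim$models)
  status <- setNames(mt$status, mt$gene)
  prof <- positionalProfile(sim$models, sim$sites, status)
  firstExon <- prof[prof$feature == "exon" & prof$end == "first" &
                      prof$group == "methylated", ]
  firstExon <- firstExon[order(firstExon$slot), ]
  expect_true(all(diff(firstExon$mean_fraction) < 0))
  ## unmethylated genes profile near zero
  cfgU <- simulationConfig(seed = 62, nOrthologs = 15,
                           methClassProportions = c(methylated = 0,
                                                    unmethylated = 1))
  simU <- simulateMethylome(cfgU)
  mtU <- methylationTable(simU$sites, simU$models)
  profU <- positionalProfile(simU$models, simU$sites,
                             setNames(mtU$status, mtU$gene))
  expect_true(all(profU$mean_fraction < 0.05))
  ## single-exon gene contributes only its one exon slot
  one <- new("GeneModel", geneId = "solo", txId = "solo.t1",
             seqid = "c1", strand = "+",
             exons = IRanges::IRanges(1, 50),
             cds = IRanges::IRanges(1, 50), phase = 0L)
  sites1 <- data.frame(seqid = "c1", pos = c(5, 10), strand = "+",
                       context = "CpG", meth_reads = c(9, 9),
                       total_reads = c(10, 10))
  p1 <- positionalProfile(list(one), sites1, c(solo = "methylated"))
  expect_true(all(p1$slot == 1L))
  expect_setequal(p1$end, c("first", "last"))
})

test_that("conservation labels partition complete orthologs", {
  st <- rbind(c("methylated", "methylated", "methylated"),
              c("methylated", "unmethylated", "unmethylated"),
              c("unmethylated", "methylated", "methylated"),
              c("unmethylated", "unmethylated", "unmethylated"),
              c("methylated", "methylated", "unmethylated"),
              c("no_data", "methylated", "methylated"))
  rownames(st) <- paste0("og", 1:6)
  colnames(st) <- c("TPRE", "NVIT", "AMEL")
  ct <- conservationTable(st, focal = "TPRE")
  expect_equal(unname(ct$counts[c("conserved_methylated", "focal_gain",
                                  "focal_loss", "conserved_unmethylated",
                                  "other", "excluded")]),
               rep(1L, 6), ignore_attr = TRUE)
  expect_equal(sum(ct$counts), nrow(st))
  expect_error(conservationTable(st[, 1:2], "TPRE"), "three species")
})

test_that("synthetic bimodal methylome supports accurate status recovery and O/E separation", {
  cfg <- simulationConfig(seed = 63, nOrthologs = 120)
  sim <- simulateMethylome(cfg)
  oe <- cdsDinucleotideOE(sim$cds)
  mMeth <- mean(oe$cpg_oe[sim$truth$class == "methylated"])
  mUn <- mean(oe$cpg_oe[sim$truth$class == "unmethylated"])
  expect_lt(mMeth, mUn - 0.2)
  ## true class associates with called status
  mt <- methylationTable(sim$sites, sim$models)
  tab <- table(sim$truth$class, mt$status)
  expect_lt(chisq2x2(unclass(tab))$p, 1e-6)
})

test_that("ortholog methylation correlation recovers planted dependence", {
  f <- runif(50)
  r <- orthologMethylationCorrelation(f, f)
  expect_equal(r$r, 1, tolerance = 1e-12)
  set.seed(64)
  ## planted bivariate log-normal with rho = 0.5, n = 2000
  z1 <- rnorm(2000); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(2000)
  x <- pmin(1, exp(-2 + z1) / 10); y <- pmin(1, exp(-2 + z2) / 10)
  pr <- orthologMethylationCorrelation(x, y, floor = 1e-6)
  expect_equal(pr$r, 0.5, tolerance = 0.06)
  ## independent vectors: near-zero correlation
  ind <- orthologMethylationCorrelation(runif(500), runif(500))
  expect_lt(abs(ind$r), 0.12)
  expect_error(orthologMethylationCorrelation(c(0.1, 0.2), c(0.1, 0.2)),
               "three")
})
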