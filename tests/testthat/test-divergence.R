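test_that("identical and symmetric pairs behave as expected", {
  set.seed(71)
  s <- randomCodingSeq(100)
  r <- neiGojobori(s, s)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_equal(r$N + r$S, 3 * r$codons, tolerance = 1e-6)
  ## symmetry
  t <- randomCodingSeq(100)
  a <- neiGojobori(s, t); b <- neiGojobori(t, s)
  expect_equal(a[c("N", "S", "Nd", "Sd", "pN", "pS", "dN", "dS")],
               b[c("N", "S", "Nd", "Sd", "pN", "pS", "dN", "dS")],
               tolerance = 1e-9)
})

test_that("codon difference counting matches a recursive pathway oracle", {
  set.seed(72)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  n <- 0
  while (n < 120) {
    c1 <- sample(codons, 1); c2 <- sample(codons, 1)
    if (c1 == c2) next
    n <- n + 1
    got <- chalcidEvo:::codonDifferences(c1, c2)
    exp <- oracleCodonDiff(c1, c2)
    expect_equal(unname(got), unname(exp), tolerance = 1e-9,
                 info = paste(c1, c2))
    expect_equal(sum(got), sum(strsplit(c1, "")[[1]] !=
                                 strsplit(c2, "")[[1]]))
  }
  ## whole-pair equivalence on a constructed 100-codon pair
  s1 <- randomCodingSeq(100)
  s2 <- s1
  idx <- sample(100, 30)
  spl <- substring(s2, 3 * (idx - 1) + 1, 3 * idx)
  repl <- sample(codons, 30, replace = TRUE)
  for (j in seq_along(idx))
    substr(s2, 3 * (idx[j] - 1) + 1, 3 * idx[j]) <- repl[j]
  got <- neiGojobori(s1, s2)
  c1s <- substring(s1, 3 * (1:100) - 2, 3 * (1:100))
  c2s <- substring(s2, 3 * (1:100) - 2, 3 * (1:100))
  oracle <- rowSums(vapply(seq_len(100), function(i)
    oracleCodonDiff(c1s[i], c2s[i]), c(syn = 0, nonsyn = 0)))
  expect_equal(got$Sd, oracle[["syn"]], tolerance = 1e-9)
  expect_equal(got$Nd, oracle[["nonsyn"]], tolerance = 1e-9)
})

test_that("site counts and the Jukes-Cantor correction obey their invariants", {
  set.seed(73)
  for (i in 1:10) {
    a <- randomCodingSeq(60); b <- randomCodingSeq(60)
    r <- neiGojobori(a, b)
    expect_equal(r$N + r$S, 3 * r$codons, tolerance = 1e-6)
  }
  ## JC: d >= p, d -> p as p -> 0, undefined at p >= 3/4
  p <- c(1e-4, 0.01, 0.1, 0.5)
  d <- jukesCantor(p)
  expect_true(all(d >= p))
  expect_lt(abs(jukesCantor(1e-4) - 1e-4), 1e-6)
  expect_true(is.na(jukesCantor(0.75)))
  ## ambiguity codons are skipped and counted
  s1 <- "ATGNNNAAA"; s2 <- "ATGCCCAAA"
  r <- neiGojobori(s1, s2)
  expect_equal(r$codons, 2L)
  expect_equal(r$skipped, 1L)
})

test_that("simulated coding pairs recover their divergence targets", {
  cfg <- simulationConfig(seed = 74, nOrthologs = 6,
                          alignmentLength = 3000,
                          dsTarget = 0.05, dnTarget = 0.05)
  sim <- simulateCodingPairs(cfg)
  stats <- do.call(rbind, lapply(seq_along(sim$seq1), function(i)
    neiGojobori(sim$seq1[[i]], sim$seq2[[i]], id = names(sim$seq1)[i])))
  agg <- aggregateDivergence(stats)
  expect_equal(agg$mean_dS, 0.05, tolerance = 0.01)
  expect_equal(agg$mean_dN, 0.05, tolerance = 0.01)
  ## dn/ds target 1 gives ratio near 1
  expect_equal(mean(stats$dnds), 1, tolerance = 0.2)
  ## zero targets give identical sequences
  z <- simulateCodingPairs(simulationConfig(seed = 75, nOrthologs = 3,
                                            alignmentLength = 200,
                                            dsTarget = 0, dnTarget = 0))
  expect_identical(as.character(z$seq1), as.character(z$seq2))
  zs <- neiGojobori(z$seq1[[1]], z$seq2[[1]])
  expect_equal(zs$dS, 0)
  ## aggregate on identical pairs: mean zero, no ratio > 1
  zstats <- do.call(rbind, lapply(1:3, function(i)
    neiGojobori(z$seq1[[i]], z$seq2[[i]], id = i)))
  zagg <- aggregateDivergence(zstats)
  expect_equal(zagg$mean_dS, 0)
  expect_length(zagg$ratio_gt1, 0L)
})

test_that("standard errors shrink like one over the square root of gene count", {
  cfg <- simulationConfig(seed = 76, nOrthologs = 40,
                          alignmentLength = 300)
  sim <- simulateCodingPairs(cfg)
  stats <- do.call(rbind, lapply(seq_along(sim$seq1), function(i)
    neiGojobori(sim$seq1[[i]], sim$seq2[[i]], id = i)))
  se10 <- aggregateDivergence(stats[1:10, ])$se_dS
  se40 <- aggregateDivergence(stats)$se_dS
  ## expect roughly a factor 2 reduction; allow slack for sampling
  expect_lt(se40, se10)
})

test_that("variants are classified by region precedence and codon effect", {
  ## genome: one gene at 11..40 (+), CDS 11..28, UTR 29..40, intron none
  cds <- "ATGGCTGCAAAACCCTAG"  # M A A K P *
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0("GGGGGGGGGG", cds, "AAAAAAAAAAAA", strrep("T", 30))))
  m <- new("GeneModel", geneId = "g1", txId = "g1.t1", seqid = "chr1",
           strand = "+", exons = IRanges::IRanges(11, 40),
           cds = IRanges::IRanges(11, 28), phase = 0L)
  ## silent: third position of the GCT (Ala) codon, genome pos 16 T>C
  v <- data.frame(CHROM = "chr1", POS = c(16L, 15L, 35L, 5L, 20L),
                  REF = c("T", "C", "A", "G", "AAA"),
                  ALT = c("C", "G", "G", "T", "A"),
                  stringsAsFactors = FALSE)
  av <- classifyVariant(v, list(m), genome)
  expect_equal(av$region, c("coding", "coding", "UTR", "intergenic",
                            "coding"))
  expect_equal(av$effect[1], "silent")     # GCT -> GCC, Ala
  expect_equal(av$effect[2], "missense")   # GCT -> GGT, Ala -> Gly
  expect_equal(av$effect[3], "none")
  expect_equal(av$class[5], "indel")
  expect_equal(av$effect[5], "frameshift") # 2-bp net deletion
  ## in-frame indel
  v2 <- data.frame(CHROM = "chr1", POS = 19L, REF = "AAAA", ALT = "A",
                   stringsAsFactors = FALSE)
  expect_equal(classifyVariant(v2, list(m), genome)$effect,
               "in_frame_indel")
  ## REF mismatch names the site
  v3 <- data.frame(CHROM = "chr1", POS = 16L, REF = "G", ALT = "A",
                   stringsAsFactors = FALSE)
  expect_error(classifyVariant(v3, list(m), genome), "chr1:16")
  ## intron classification on a two-exon gene
  m2 <- new("GeneModel", geneId = "g2", txId = "g2.t1", seqid = "chr1",
            strand = "+", exons = IRanges::IRanges(c(41, 51), c(45, 55)),
            cds = IRanges::IRanges(c(41, 51), c(45, 55)),
            phase = c(0L, 0L))
  v4 <- data.frame(CHROM = "chr1", POS = 48L,
                   REF = substr(as.character(genome[[1]]), 48, 48),
                   ALT = "C", stringsAsFactors = FALSE)
  expect_equal(classifyVariant(v4, list(m, m2), genome)$region, "intron")
})

test_that("missense/silent ratio and top-divergence selection behave", {
  av <- data.frame(effect = c(rep("missense", 3), rep("silent", 6),
                              "none"))
  expect_equal(missenseSilentRatio(av), 0.5)
  expect_equal(missenseSilentRatio(data.frame(effect = "silent")), 0)
  expect_warning(r <- missenseSilentRatio(data.frame(effect = "missense")),
                 "no silent")
  expect_true(is.na(r))
  ## top 5% of 100 genes
  set.seed(77)
  cnt <- setNames(sample(0:1000, 100), sprintf("g%03d", 1:100))
  len <- setNames(rep(100, 100), names(cnt))
  sel <- topDivergenceGenes(cnt, len)
  expect_length(sel, 5L)
  ## sort oracle
  rate <- cnt / len
  expect_setequal(sel, names(sort(rate, decreasing = TRUE))[1:5])
  ## all tied
  tied <- setNames(rep(5, 10), paste0("t", 1:10))
  expect_warning(all10 <- topDivergenceGenes(tied, setNames(rep(10, 10),
                                                            names(tied))),
                 "tied")
  expect_length(all10, 10L)
  expect_error(topDivergenceGenes(c(a = 1), c(a = 0)), "positive")
})
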