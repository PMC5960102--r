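## Synthetic-data generators with recorded ground truth. One master
## seed determines every output; each generator draws from a private
## stream derived from the seed plus the generator name, so adding a
## generator never perturbs the others.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build a simulation configuration
#'
#' Central parameter object for all generators; see
#' [SimulationConfig-class] for the slots. Defaults describe the study
#' conditions the analyses assume: an ultrametric eight-taxon wasp
#' phylogeny, gamma rate heterogeneity across orthologs (shape 2,
#' typical of protein rate variation) with milder per-branch noise
#' (shape 5), a bimodal methylome with 37.4% methylated genes at
#' gene-body fractions 0.9 vs 0.001 and 20x bisulfite coverage, and
#' coding pairs at per-site divergence targets dS 0.013, dN 0.0075.
#'
#' @param seed master RNG seed.
#' @param nOrthologs records per generator (default 200).
#' @param phylogeny a [SpeciesPhylogeny-class]; default
#'   [chalcidPhylogeny()].
#' @param baselineRateShape,branchNoiseShape gamma shapes of the mean-1
#'   per-ortholog rate and per-branch noise (`Inf` = no variation).
#' @param lineageMultipliers named multipliers on terminal branches.
#' @param alignmentLength columns per triple alignment / codons per
#'   coding pair.
#' @param tripleRates per-site substitution probabilities on the `A`,
#'   `B`, `O` and internal `AB` branches.
#' @param methClassProportions,methClassFractions,depletionStrength
#'   methylome class structure (named `methylated`, `unmethylated`).
#' @param coverageMean mean bisulfite reads per CpG site.
#' @param fivePrimeBias geometric decay of methylation across
#'   successive transcript features (0 = flat).
#' @param dsTarget,dnTarget per-site divergence targets of the
#'   coding-pair generator.
#' @param clusterCounts named category counts for the cluster-table
#'   generator (`single_copy_core`, `variable_copy_core`,
#'   `dispensable` are family counts; `species_specific`, `singleton`
#'   are per-species counts).
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nOrthologs = 200L,
                             phylogeny = chalcidPhylogeny(),
                             baselineRateShape = 2,
                             branchNoiseShape = 5,
                             lineageMultipliers = numeric(),
                             alignmentLength = 500L,
                             tripleRates = c(A = 0.02, B = 0.02,
                                             O = 0.04, AB = 0.02),
                             methClassProportions = c(
                               methylated = 0.374, unmethylated = 0.626),
                             methClassFractions = c(
                               methylated = 0.9, unmethylated = 0.001),
                             depletionStrength = c(
                               methylated = 0.6, unmethylated = 0),
                             coverageMean = 20,
                             fivePrimeBias = 0,
                             dsTarget = 0.013, dnTarget = 0.0075,
                             clusterCounts = c(
                               single_copy_core = 10,
                               variable_copy_core = 5, dispensable = 5,
                               species_specific = 2, singleton = 3)) {
  new("SimulationConfig", seed = as.integer(seed),
      nOrthologs = as.integer(nOrthologs), phylogeny = phylogeny,
      baselineRateShape = baselineRateShape,
      branchNoiseShape = branchNoiseShape,
      lineageMultipliers = lineageMultipliers,
      alignmentLength = as.integer(alignmentLength),
      tripleRates = tripleRates,
      methClassProportions = methClassProportions,
      methClassFractions = methClassFractions,
      depletionStrength = depletionStrength,
      coverageMean = coverageMean, fivePrimeBias = fivePrimeBias,
      dsTarget = dsTarget, dnTarget = dnTarget,
      clusterCounts = clusterCounts)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, ",", object@nOrthologs,
      "orthologs,", length(object@phylogeny@tree$tip.label), "taxa\n")
})

rgammaMean1 <- function(n, shape) {
  if (is.infinite(shape)) rep(1, n) else rgamma(n, shape, rate = shape)
}

#' Simulate per-ortholog gene trees
#'
#' Each gene tree keeps the species-tree topology; branch `e` of
#' ortholog `g` has length `base_e * r_g * u_ge * m_e` with `r_g` a
#' mean-1 gamma ortholog rate (shape `baselineRateShape`), `u_ge`
#' i.i.d. mean-1 gamma branch noise (shape `branchNoiseShape`), and
#' `m_e` the lineage multiplier of the terminal branch (1 elsewhere).
#' With both shapes infinite and all multipliers 1 every gene tree
#' equals the species tree.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `trees` (an [OrthologTreeSet-class]) and `truth`
#'   (per-ortholog rates and the expected distance of each species to
#'   the clade root).
#' @export
simulateGeneTrees <- function(config) {
  validObject(config)
  phy <- config@phylogeny
  tr <- phy@tree
  mult <- config@lineageMultipliers
  if (length(bad <- setdiff(names(mult), tr$tip.label)))
    stop("lineage multiplier names an unknown branch: ",
         paste(bad, collapse = ", "))
  nedge <- nrow(tr$edge)
  edgeMult <- rep(1, nedge)
  tipEdge <- match(seq_along(tr$tip.label), tr$edge[, 2L])
  if (length(mult))
    edgeMult[tipEdge[match(names(mult), tr$tip.label)]] <- mult
  n <- config@nOrthologs
  ids <- sprintf("OG%04d", seq_len(n))
  withStream(config@seed, "trees", {
    rates <- rgammaMean1(n, config@baselineRateShape)
    trees <- vector("list", n)
    for (g in seq_len(n)) {
      gt <- tr
      noise <- rgammaMean1(nedge, config@branchNoiseShape)
      gt$edge.length <- tr$edge.length * rates[g] * noise * edgeMult
      trees[[g]] <- gt
    }
    names(trees) <- ids
    ## analytic expected clade-root-to-species distances (over the
    ## noise, conditional on nothing): E = sum_e base_e * m_e
    depth <- ape::node.depth.edgelength(tr)
    anch <- anchorNodes(tr, phy)
    expDist <- vapply(phy@cladeMembers, function(sp) {
      tip <- match(sp, tr$tip.label)
      d <- depth[tip] - depth[anch$cladeRoot]
      ## only the terminal branch can carry a multiplier
      e <- tipEdge[tip]
      d + tr$edge.length[e] * (edgeMult[e] - 1)
    }, 0)
    list(trees = new("OrthologTreeSet", trees = trees, phylogeny = phy),
         truth = list(rates = setNames(rates, ids),
                      expected_clade_dist = expDist))
  })
}

#' Simulate triple alignments for relative rate testing
#'
#' Sites evolve independently under an equal-exchangeability model over
#' the 20 residues: each column is hit by at most one event, on the
#' A-only, B-only, O-only or shared internal branch, with the per-site
#' probabilities in `tripleRates` (so the expected lineage-unique
#' counts are `length * rate`).
#'
#' @param config a [SimulationConfig-class].
#' @return list with `alignments` (list of
#'   [TripleAlignment-class]) and `truth` (planted per-alignment
#'   unique-substitution counts).
#' @export
simulateTripleAlignments <- function(config) {
  validObject(config)
  L <- config@alignmentLength
  if (L < 1) stop("alignment length must be >= 1")
  r <- config@tripleRates[c("A", "B", "O", "AB")]
  if (anyNA(r)) stop("tripleRates needs entries A, B, O, AB")
  if (sum(r) > 1) stop("tripleRates must sum to at most 1")
  n <- config@nOrthologs
  ids <- sprintf("OG%04d", seq_len(n))
  withStream(config@seed, "alignments", {
    alns <- vector("list", n)
    truth <- data.frame(id = ids, mA = 0L, mB = 0L,
                        stringsAsFactors = FALSE)
    for (g in seq_len(n)) {
      anc <- sample(AA20, L, replace = TRUE)
      cat_ <- sample(c("A", "B", "O", "AB", "none"), L, replace = TRUE,
                     prob = c(r, 1 - sum(r)))
      mutate <- function(res) vapply(res, function(x)
        sample(setdiff(AA20, x), 1L), "")
      a <- b <- o <- anc
      ia <- cat_ == "A"; ib <- cat_ == "B"; io <- cat_ == "O"
      iab <- cat_ == "AB"
      if (any(ia)) a[ia] <- mutate(anc[ia])
      if (any(ib)) b[ib] <- mutate(anc[ib])
      if (any(io)) o[io] <- mutate(anc[io])
      if (any(iab)) { new <- mutate(anc[iab]); a[iab] <- new; b[iab] <- new }
      alns[[g]] <- TripleAlignment(ids[g], paste(a, collapse = ""),
                                   paste(b, collapse = ""),
                                   paste(o, collapse = ""))
      truth$mA[g] <- sum(ia); truth$mB[g] <- sum(ib)
    }
    list(alignments = alns, truth = truth)
  })
}

randomDna <- function(n) paste(sample(NUCS, n, replace = TRUE),
                               collapse = "")

nonStopCodons <- function() {
  gc <- geneticCode()
  names(gc)[gc != "*"]
}

## Deplete CpG dinucleotides: each CpG's C mutates to T with
## probability `strength` (the deamination signature of germline
## methylation).
depleteCpG <- function(seq, strength) {
  if (strength <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  isCpG <- which(chars[-length(chars)] == "C" & chars[-1L] == "G")
  if (length(isCpG)) {
    hit <- isCpG[runif(length(isCpG)) < strength]
    chars[hit] <- "T"
  }
  paste(chars, collapse = "")
}

#' Simulate a methylome: genome, annotation, CDS and bisulfite sites
#'
#' Generates a single-contig genome of multi-exon genes in two latent
#' classes, methylated and unmethylated. CpG depletion of strength
#' `depletionStrength[class]` is applied to gene sequence, giving the
#' CDS population a bimodal CpG O/E structure; per-CpG-site bisulfite
#' counts are binomial draws from the class's true gene-body fraction
#' at Poisson(`coverageMean`) read depth. With `fivePrimeBias > 0` the
#' per-site fraction decays geometrically across successive transcript
#' features, planting a 5'-biased profile.
#'
#' @param config a [SimulationConfig-class].
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `cds.fa`, `sites.tsv` and `truth.tsv` there.
#' @return list with `genome` (`DNAStringSet`), `models` (list of
#'   [GeneModel-class]), `cds` (`DNAStringSet`), `sites` (data.frame)
#'   and `truth` (gene, class, true fraction).
#' @export
simulateMethylome <- function(config, dir = NULL) {
  validObject(config)
  if (config@coverageMean <= 0) stop("coverageMean must be positive")
  n <- config@nOrthologs
  prop <- config@methClassProportions[c("methylated", "unmethylated")]
  fracs <- config@methClassFractions[c("methylated", "unmethylated")]
  depl <- config@depletionStrength[c("methylated", "unmethylated")]
  withStream(config@seed, "methylome", {
    classes <- sample(names(prop), n, replace = TRUE, prob = prop)
    genes <- sprintf("gene%04d", seq_len(n))
    contig <- character()
    pos <- 1L
    models <- vector("list", n)
    siteRows <- list()
    for (g in seq_len(n)) {
      spacer <- randomDna(100L)
      contig <- c(contig, spacer)
      pos <- pos + 100L
      nEx <- sample(2:6, 1L)
      exLens <- 3L * sample(20:60, nEx, replace = TRUE)
      inLens <- sample(40:80, nEx - 1L, replace = TRUE)
      strand <- sample(c("+", "-"), 1L)
      ## plant a stop-free coding sequence; on the minus strand the
      ## genome carries its reverse complement so that spliced,
      ## strand-oriented extraction recovers the planted ORF
      cdsSeq <- paste(sample(nonStopCodons(), sum(exLens) / 3L,
                             replace = TRUE), collapse = "")
      genomicCds <- if (strand == "-")
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cdsSeq))) else cdsSeq
      cut <- c(0L, cumsum(exLens))
      pieces <- character(); exStart <- integer(); exEnd <- integer()
      p <- pos
      for (e in seq_len(nEx)) {
        pieces <- c(pieces, substr(genomicCds, cut[e] + 1L, cut[e + 1L]))
        exStart <- c(exStart, p); exEnd <- c(exEnd, p + exLens[e] - 1L)
        p <- p + exLens[e]
        if (e < nEx) {
          pieces <- c(pieces, randomDna(inLens[e]))
          p <- p + inLens[e]
        }
      }
      geneSeq <- depleteCpG(paste(pieces, collapse = ""),
                            depl[[classes[g]]])
      contig <- c(contig, geneSeq)
      models[[g]] <- new("GeneModel", geneId = genes[g],
                         txId = paste0(genes[g], ".t1"),
                         seqid = "scaffold_1", strand = strand,
                         exons = IRanges::IRanges(exStart, exEnd),
                         cds = IRanges::IRanges(exStart, exEnd),
                         phase = rep(0L, nEx))
      ## per-CpG bisulfite counts over the gene body
      chars <- strsplit(geneSeq, "")[[1L]]
      cpg <- which(chars[-length(chars)] == "C" & chars[-1L] == "G")
      if (length(cpg)) {
        sitePos <- pos + cpg - 1L
        ## feature index (transcript orientation) of each site, for the
        ## optional 5' bias
        nFeat <- 2L * nEx - 1L
        featIdx <- {
          edges <- sort(c(exStart, exEnd + 1L))
          fi <- findInterval(sitePos, edges[-length(edges)])
          if (strand == "-") nFeat - fi + 1L else fi
        }
        w <- (1 - config@fivePrimeBias)^(pmax(featIdx, 1L) - 1L)
        fr <- pmin(1, fracs[[classes[g]]] * w)
        total <- rpois(length(cpg), config@coverageMean)
        meth <- rbinom(length(cpg), total, fr)
        siteRows[[g]] <- data.frame(
          seqid = "scaffold_1", pos = sitePos, strand = "+",
          context = "CpG", meth_reads = meth, total_reads = total,
          stringsAsFactors = FALSE)
      }
      pos <- p
    }
    genome <- Biostrings::DNAStringSet(
      setNames(paste(contig, collapse = ""), "scaffold_1"))
    names(models) <- genes
    sites <- do.call(rbind, siteRows)
    rownames(sites) <- NULL
    cds <- extractCds(genome, models)
    truth <- data.frame(gene = genes, class = classes,
                        fraction = unname(fracs[classes]),
                        stringsAsFactors = FALSE)
    out <- list(genome = genome, models = models, cds = cds,
                sites = sites, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"),
                                  width = 80L)
      Biostrings::writeXStringSet(cds, file.path(dir, "cds.fa"),
                                  width = 80L)
      writeAnnotation(models, file.path(dir, "annotation.gff3"))
      write.table(sites, file.path(dir, "sites.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    out
  })
}

#' Simulate an ortholog cluster table with known composition
#'
#' Builds a [ClusterTable-class] whose classification reproduces the
#' requested per-category counts exactly: `single_copy_core` families
#' (one gene per species), `variable_copy_core` (one random species
#' duplicated), `dispensable` (a random proper subset of >= 2 species),
#' plus per-species `species_specific` clusters (2 genes) and
#' unclustered `singleton` genes.
#'
#' @param config a [SimulationConfig-class].
#' @param species species universe; default the phylogeny leaves.
#' @return list with `clusters` (a `ClusterTable`) and `truth`
#'   (family -> category).
#' @export
simulateClusterTable <- function(config, species = NULL) {
  validObject(config)
  cc <- config@clusterCounts
  if (any(cc < 0)) stop("cluster category counts must be >= 0")
  if (is.null(species)) species <- config@phylogeny@tree$tip.label
  k <- length(species)
  withStream(config@seed, "clusters", {
    rows <- list(); truth <- list()
    fam <- 0L
    gid <- setNames(integer(k), species)
    newGene <- function(sp) {
      gid[sp] <<- gid[sp] + 1L
      sprintf("%s_g%04d", sp, gid[sp])
    }
    addFam <- function(spCounts, category) {
      fam <<- fam + 1L
      fid <- sprintf("FAM%04d", fam)
      for (sp in names(spCounts))
        for (i in seq_len(spCounts[[sp]]))
          rows[[length(rows) + 1L]] <<- data.frame(
            family = fid, species = sp, gene = newGene(sp),
            stringsAsFactors = FALSE)
      truth[[fid]] <<- category
    }
    for (i in seq_len(cc[["single_copy_core"]]))
      addFam(setNames(rep(1L, k), species), "single_copy_core")
    for (i in seq_len(cc[["variable_copy_core"]])) {
      cnt <- setNames(rep(1L, k), species)
      cnt[sample(k, 1L)] <- 2L
      addFam(cnt, "variable_copy_core")
    }
    for (i in seq_len(cc[["dispensable"]])) {
      sub <- sample(species, sample(2:(k - 1L), 1L))
      addFam(setNames(rep(1L, length(sub)), sub), "dispensable")
    }
    for (sp in species)
      for (i in seq_len(cc[["species_specific"]]))
        addFam(setNames(2L, sp), "species_specific")
    tb <- do.call(rbind, rows)
    universes <- split(tb$gene, factor(tb$species, species))
    for (sp in species)
      universes[[sp]] <- c(universes[[sp]],
                           replicate(cc[["singleton"]], newGene(sp)))
    list(clusters = ClusterTable(tb, species, universes),
         truth = unlist(truth))
  })
}

## (position, alternative) choices for a synonymous or nonsynonymous
## single-nucleotide change of a codon; NULL when none exists.
codonChangeOptions <- function(codon, synonymous) {
  gc <- geneticCode()
  opts <- list()
  for (pos in 1:3)
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      alt <- codon; substr(alt, pos, pos) <- nt
      if (gc[[alt]] == "*") next
      if ((gc[[alt]] == gc[[codon]]) == synonymous)
        opts[[length(opts) + 1L]] <- c(pos, nt)
    }
  if (length(opts)) opts else NULL
}

#' Simulate paired coding sequences at target divergence
#'
#' For each gene, draws a stop-free coding sequence and plants
#' `round(p * sites)` synonymous and nonsynonymous single-nucleotide
#' differences at distinct random codons, where `p` is the
#' uncorrected-proportion equivalent of the Jukes-Cantor target
#' (`p = 3/4 (1 - exp(-4 d / 3))`), so Nei-Gojobori estimation on the
#' output recovers the targets within sampling error.
#'
#' @param config a [SimulationConfig-class]; `alignmentLength` is the
#'   codon count per gene.
#' @param nPairs number of gene pairs (default `nOrthologs`).
#' @return list with `seq1`, `seq2` (`DNAStringSet`s) and `truth`
#'   (planted synonymous/nonsynonymous difference counts and site
#'   totals per gene).
#' @export
simulateCodingPairs <- function(config, nPairs = NULL) {
  validObject(config)
  nPairs <- nPairs %||% config@nOrthologs
  ncod <- config@alignmentLength
  pS <- 3 / 4 * (1 - exp(-4 * config@dsTarget / 3))
  pN <- 3 / 4 * (1 - exp(-4 * config@dnTarget / 3))
  if (pS >= 3 / 4 || pN >= 3 / 4)
    stop("divergence targets imply p >= 3/4; correction undefined")
  syn <- synSites()
  pool <- nonStopCodons()
  withStream(config@seed, "pairs", {
    ids <- sprintf("pair%04d", seq_len(nPairs))
    s1 <- s2 <- character(nPairs)
    truth <- data.frame(id = ids, S = 0, N = 0, Sd = 0L, Nd = 0L,
                        stringsAsFactors = FALSE)
    for (g in seq_len(nPairs)) {
      codons <- sample(pool, ncod, replace = TRUE)
      S <- sum(syn[codons]); N <- 3 * ncod - S
      nS <- round(pS * S); nN <- round(pN * N)
      if (nS + nN > ncod)
        stop("divergence targets too large for ", ncod, " codons")
      target <- codons
      avail <- seq_len(ncod)
      plant <- function(count, synonymous) {
        placed <- 0L
        while (placed < count && length(avail)) {
          pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
          opts <- codonChangeOptions(codons[pick], synonymous)
          avail <<- setdiff(avail, pick)
          if (is.null(opts)) next
          ch <- opts[[sample.int(length(opts), 1L)]]
          cd <- codons[pick]
          substr(cd, as.integer(ch[1L]), as.integer(ch[1L])) <- ch[2L]
          target[pick] <<- cd
          placed <- placed + 1L
        }
        placed
      }
      truth$Sd[g] <- plant(nS, TRUE)
      truth$Nd[g] <- plant(nN, FALSE)
      truth$S[g] <- S; truth$N[g] <- N
      s1[g] <- paste(codons, collapse = "")
      s2[g] <- paste(target, collapse = "")
    }
    list(seq1 = Biostrings::DNAStringSet(setNames(s1, ids)),
         seq2 = Biostrings::DNAStringSet(setNames(s2, ids)),
         truth = truth)
  })
}
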