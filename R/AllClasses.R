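## Central S4 containers.

#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom IRanges IRanges CharacterList
#' @importFrom S4Vectors unstrsplit splitAsList
NULL

setOldClass("phylo")

#' Rooted species phylogeny with named clade anchors
#'
#' Wraps a rooted `ape::phylo` tree and records two anchor clades used by
#' the branch-length analyses: the clade of interest (e.g. Chalcidoidea)
#' and the in-group whose ancestor serves as the deeper reference node
#' (e.g. Hymenoptera minus the rooting outgroup). Anchors are resolved as
#' most recent common ancestors of leaf sets, never by node labels, so
#' the same object applies to every gene tree sharing the topology.
#'
#' @slot tree a rooted `phylo` object with branch lengths.
#' @slot cladeMembers leaf names forming the monophyletic clade of
#'   interest.
#' @slot orderMembers leaf names of the in-group whose common ancestor is
#'   the deeper anchor; defaults to all leaves.
#'
#' @examples
#' sp <- chalcidPhylogeny()
#' cladeMembers(sp)
#' @export
setClass("SpeciesPhylogeny",
  representation(tree = "phylo", cladeMembers = "character",
                 orderMembers = "character"))

setValidity("SpeciesPhylogeny", function(object) {
  tr <- object@tree
  msg <- character()
  if (is.null(tr$edge.length)) msg <- c(msg, "tree has no branch lengths")
  else if (any(tr$edge.length < 0)) msg <- c(msg, "negative branch lengths")
  if (!ape::is.rooted(tr)) msg <- c(msg, "tree must be rooted")
  bad <- setdiff(c(object@cladeMembers, object@orderMembers), tr$tip.label)
  if (length(bad))
    msg <- c(msg, paste0("unknown leaves: ", paste(bad, collapse = ", ")))
  if (length(object@cladeMembers) < 2)
    msg <- c(msg, "need at least two clade members")
  if (!length(msg)) {
    node <- ape::getMRCA(tr, object@cladeMembers)
    desc <- tr$tip.label[descendantTips(tr, node)]
    if (!setequal(desc, object@cladeMembers))
      msg <- c(msg, "cladeMembers are not monophyletic in the tree")
  }
  if (length(msg)) msg else TRUE
})

#' Set of per-ortholog gene trees on one fixed topology
#'
#' Gene trees share the topology of a [SpeciesPhylogeny] but carry their
#' own branch lengths (one tree per single-copy ortholog).
#'
#' @slot trees named list of `phylo` objects, names are ortholog ids.
#' @slot phylogeny the reference [SpeciesPhylogeny].
#' @export
setClass("OrthologTreeSet",
  representation(trees = "list", phylogeny = "SpeciesPhylogeny"))

setValidity("OrthologTreeSet", function(object) {
  if (length(object@trees) &&
      (is.null(names(object@trees)) || anyDuplicated(names(object@trees))))
    return("trees must have unique ortholog ids as names")
  TRUE
})

#' Three-sequence amino-acid alignment for relative rate testing
#'
#' Aligned sequences for in-group A, in-group B and out-group O, used to
#' polarize substitutions in Tajima's relative rate test.
#'
#' @slot id ortholog identifier.
#' @slot seqs `Biostrings::AAStringSet` of length 3, names give the
#'   species roles in order A, B, O.
#' @slot masked whether a divergence mask has been applied.
#' @export
setClass("TripleAlignment",
  representation(id = "character", seqs = "AAStringSet", masked = "logical"),
  prototype(masked = FALSE))

setValidity("TripleAlignment", function(object) {
  if (length(object@seqs) != 3L) return("need exactly three sequences")
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) != 1L) return("sequences must be aligned (equal length)")
  TRUE
})

#' Place table of within-ortholog branch-length rankings
#'
#' For each ortholog the clade members are ranked by their root-to-clade
#' branch length; place 1 is the longest branch (most change since the
#' clade ancestor). Stores the per-ortholog places and the per-species
#' tabulation of how often each place is occupied.
#'
#' @slot places integer matrix, orthologs x species; each row is a
#'   permutation of 1..k.
#' @slot counts integer matrix, species x place; column `p` counts the
#'   orthologs in which each species took place `p`.
#' @slot tied ids of orthologs containing tied distances (broken
#'   deterministically by species-name order).
#' @export
setClass("PlaceTable",
  representation(places = "matrix", counts = "matrix", tied = "character"))

setValidity("PlaceTable", function(object) {
  p <- object@places
  k <- ncol(p)
  if (nrow(p) && !all(apply(p, 1L, function(r) setequal(r, seq_len(k)))))
    return("each ortholog row must use each place exactly once")
  if (!identical(dim(object@counts), c(k, k)) && nrow(p))
    return("counts must be a k x k species-by-place matrix")
  TRUE
})

#' Gene model (one representative transcript)
#'
#' Exon/intron/CDS structure for one mRNA in 1-based inclusive
#' coordinates on its contig. Introns are derived as the gaps between
#' consecutive exons.
#'
#' @slot geneId,txId gene and transcript identifiers.
#' @slot seqid contig name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons `IRanges` of exons, sorted by start, non-overlapping.
#' @slot cds `IRanges` of coding segments, sorted by start.
#' @slot phase integer phases of the CDS segments (as in GFF3).
#' @export
setClass("GeneModel",
  representation(geneId = "character", txId = "character", seqid = "character",
                 strand = "character", exons = "IRanges", cds = "IRanges",
                 phase = "integer"))

setValidity("GeneModel", function(object) {
  ex <- object@exons
  msg <- character()
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (length(ex) > 1L) {
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    if (is.unsorted(s)) msg <- c(msg, "exons must be sorted by start")
    else if (any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "exons overlap or abut without an intron")
  }
  if (length(msg)) msg else TRUE
})

#' OrthoMCL-style gene-family cluster table
#'
#' Families of putatively orthologous genes across a declared species
#' universe, plus the full per-species gene universes needed to detect
#' singletons (genes assigned to no family).
#'
#' @slot table data.frame with columns `family`, `species`, `gene`.
#' @slot species declared species universe.
#' @slot geneUniverses named list (by species) of all annotated gene ids.
#' @export
setClass("ClusterTable",
  representation(table = "data.frame", species = "character",
                 geneUniverses = "list"))

setValidity("ClusterTable", function(object) {
  tb <- object@table
  if (!all(c("family", "species", "gene") %in% names(tb)))
    return("table needs columns family, species, gene")
  if (anyDuplicated(paste(tb$species, tb$gene)))
    return("a gene id occurs in more than one family")
  if (length(bad <- setdiff(tb$species, object@species)))
    return(paste0("species outside declared universe: ",
                  paste(unique(bad), collapse = ", ")))
  TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. One master `seed` fully
#' determines every output; each generator draws from its own stream
#' derived from the seed and the generator name.
#'
#' @slot seed master RNG seed.
#' @slot nOrthologs number of orthologs / genes / pairs to simulate.
#' @slot phylogeny the [SpeciesPhylogeny] gene trees are simulated on.
#' @slot baselineRateShape gamma shape of the per-ortholog mean-1 rate.
#' @slot branchNoiseShape gamma shape of the per-branch mean-1 noise.
#' @slot lineageMultipliers named positive multipliers applied to the
#'   terminal branch of the named species (unnamed species get 1).
#' @slot alignmentLength columns per simulated triple alignment.
#' @slot tripleRates named per-site substitution probabilities for the
#'   `A`, `B`, `O` and internal (`AB`) branches of the triple.
#' @slot methClassProportions proportions of the methylated and
#'   unmethylated gene classes (sums to 1).
#' @slot methClassFractions true gene-body fractional methylation of the
#'   two classes.
#' @slot depletionStrength per-class probability that a CpG was lost to
#'   deamination (drives the bimodal CpG O/E structure).
#' @slot coverageMean mean bisulfite read depth per CpG site.
#' @slot fivePrimeBias geometric decay of methylation across successive
#'   features (0 = flat profile).
#' @slot dsTarget,dnTarget per-site synonymous / nonsynonymous divergence
#'   targets of the coding-pair generator.
#' @slot clusterCounts named counts of families/genes per category for
#'   the cluster-table generator.
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nOrthologs = "integer",
                 phylogeny = "SpeciesPhylogeny",
                 baselineRateShape = "numeric", branchNoiseShape = "numeric",
                 lineageMultipliers = "numeric", alignmentLength = "integer",
                 tripleRates = "numeric", methClassProportions = "numeric",
                 methClassFractions = "numeric", depletionStrength = "numeric",
                 coverageMean = "numeric", fivePrimeBias = "numeric",
                 dsTarget = "numeric", dnTarget = "numeric",
                 clusterCounts = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (abs(sum(object@methClassProportions) - 1) > 1e-9)
    msg <- c(msg, "methClassProportions must sum to 1")
  if (length(object@lineageMultipliers)) {
    bad <- names(object@lineageMultipliers)[object@lineageMultipliers <= 0]
    if (length(bad))
      msg <- c(msg, paste0("non-positive lineage multiplier for branch: ",
                           paste(bad, collapse = ", ")))
  }
  if (object@baselineRateShape <= 0 || object@branchNoiseShape <= 0)
    msg <- c(msg, "rate shapes must be positive")
  if (object@coverageMean <= 0) msg <- c(msg, "coverageMean must be positive")
  if (object@alignmentLength < 1) msg <- c(msg, "alignmentLength must be >= 1")
  if (any(object@tripleRates < 0)) msg <- c(msg, "tripleRates must be >= 0")
  if (any(object@depletionStrength < 0 | object@depletionStrength > 1))
    msg <- c(msg, "depletionStrength must lie in [0, 1]")
  for (tg in c(object@dsTarget, object@dnTarget)) {
    p <- 3 / 4 * (1 - exp(-4 * tg / 3))
    if (!is.finite(tg) || tg < 0 || p >= 3 / 4)
      msg <- c(msg, "divergence targets must be finite, >= 0 and imply p < 3/4")
  }
  if (length(msg)) msg else TRUE
})
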