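## SpeciesPhylogeny construction, anchors and accessors.

## Tip indices descending from an internal node (or the tip itself).
descendantTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Construct a SpeciesPhylogeny
#'
#' @param tree a rooted `phylo` object with branch lengths, or a Newick
#'   string.
#' @param cladeMembers leaf names of the monophyletic clade of interest.
#' @param orderMembers leaf names of the in-group whose common ancestor
#'   anchors the deeper reference node; default all leaves.
#' @return a [SpeciesPhylogeny-class] object.
#' @examples
#' sp <- SpeciesPhylogeny("((A:1,B:1):1,(C:1,D:2):1);", c("A", "B"))
#' @export
SpeciesPhylogeny <- function(tree, cladeMembers, orderMembers = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(orderMembers)) orderMembers <- tree$tip.label
  new("SpeciesPhylogeny", tree = tree,
      cladeMembers = as.character(cladeMembers),
      orderMembers = as.character(orderMembers))
}

#' Default eight-taxon hymenopteran phylogeny
#'
#' An ultrametric eight-species wasp phylogeny used as the simulator
#' default: four chalcids (*Trichogramma pretiosum* TPRE, *Ceratosolen
#' solmsi* CSOL, *Copidosoma floridanum* CFLO, *Nasonia vitripennis*
#' NVIT) plus the braconid *Microplitis demolitor* MDEM, the honey bee
#' *Apis mellifera* AMEL, the wood wasp *Orussus abietinus* OABI and the
#' sawfly *Athalia rosae* AROS as the rooting outgroup. The chalcid
#' clade anchors the shallow reference node; the non-sawfly leaves
#' anchor the deeper one.
#'
#' @return a [SpeciesPhylogeny-class] object.
#' @examples
#' chalcidPhylogeny()
#' @export
chalcidPhylogeny <- function() {
  nwk <- paste0(
    "(AROS:1.0,(OABI:0.9,(MDEM:0.8,(AMEL:0.7,(TPRE:0.55,(CSOL:0.4,",
    "(CFLO:0.25,NVIT:0.25):0.15):0.15):0.15):0.1):0.1):0.1);")
  SpeciesPhylogeny(nwk, cladeMembers = c("TPRE", "CSOL", "CFLO", "NVIT"),
                   orderMembers = c("OABI", "MDEM", "AMEL", "TPRE",
                                    "CSOL", "CFLO", "NVIT"))
}

#' @describeIn SpeciesPhylogeny leaf names of the clade of interest.
#' @param object,x a `SpeciesPhylogeny`.
#' @export
cladeMembers <- function(x) x@cladeMembers

#' @describeIn SpeciesPhylogeny leaf names anchoring the deeper node.
#' @export
orderMembers <- function(x) x@orderMembers

#' @describeIn SpeciesPhylogeny the underlying `phylo` tree.
#' @export
speciesTree <- function(x) x@tree

## Anchor nodes of an arbitrary tree sharing the reference leaf set.
anchorNodes <- function(tree, phylogeny) {
  list(cladeRoot = ape::getMRCA(tree, phylogeny@cladeMembers),
       orderRoot = ape::getMRCA(tree, phylogeny@orderMembers))
}

setMethod("show", "SpeciesPhylogeny", function(object) {
  cat("SpeciesPhylogeny with", length(object@tree$tip.label), "leaves\n")
  cat("  clade  :", paste(object@cladeMembers, collapse = ", "), "\n")
  cat("  ingroup:", paste(object@orderMembers, collapse = ", "), "\n")
})

setMethod("show", "OrthologTreeSet", function(object) {
  cat("OrthologTreeSet of", length(object@trees), "gene trees on",
      length(object@phylogeny@tree$tip.label), "taxa\n")
})

setMethod("show", "TripleAlignment", function(object) {
  cat("TripleAlignment", object@id, "(", Biostrings::width(object@seqs)[1L],
      "columns,", if (object@masked) "masked" else "unmasked", ")\n")
})

setMethod("show", "PlaceTable", function(object) {
  cat("PlaceTable:", nrow(object@places), "orthologs x",
      ncol(object@places), "species;", length(object@tied),
      "with ties\n")
  print(object@counts)
})

#' @describeIn OrthologTreeSet number of gene trees.
#' @param x an `OrthologTreeSet`.
#' @export
setMethod("length", "OrthologTreeSet", function(x) length(x@trees))

#' @describeIn OrthologTreeSet the named list of gene trees.
#' @export
geneTrees <- function(x) x@trees

#' @describeIn PlaceTable species-by-place count matrix.
#' @export
placeCounts <- function(x) x@counts

#' @describeIn PlaceTable per-ortholog place matrix.
#' @export
placeMatrix <- function(x) x@places
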