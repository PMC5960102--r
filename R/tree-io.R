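## Reading and writing per-ortholog gene-tree sets.
##
## File format: one tree per line, `ortholog_id<TAB>newick`.

#' Read a set of per-ortholog gene trees
#'
#' Reads a tab-separated multi-tree file (`id<TAB>newick` per line),
#' validates every tree against the reference phylogeny (same leaf set,
#' same topology, no negative branch lengths) and returns an
#' [OrthologTreeSet-class]. Problems are collected per tree; by default
#' any problem aborts the read with the full listing.
#'
#' @param path path to the multi-tree file.
#' @param phylogeny the reference [SpeciesPhylogeny-class].
#' @param skipBad if `TRUE`, offending trees are dropped with a warning
#'   instead of aborting.
#' @return an `OrthologTreeSet`.
#' @export
readGeneTrees <- function(path, phylogeny, skipBad = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate ortholog ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  expected <- phylogeny@tree$tip.label
  trees <- vector("list", length(ids))
  errs <- character()
  for (i in seq_along(ids)) {
    nwk <- if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else ""
    tr <- tryCatch(suppressWarnings(ape::read.tree(text = nwk)),
                   error = function(e) NULL)
    if (is.null(tr)) { errs <- c(errs, paste0(ids[i], ": malformed Newick")); next }
    miss <- setdiff(expected, tr$tip.label)
    extra <- setdiff(tr$tip.label, expected)
    if (length(miss)) {
      errs <- c(errs, paste0(ids[i], ": missing leaf ",
                             paste(miss, collapse = ", ")))
      next
    }
    if (length(extra)) {
      errs <- c(errs, paste0(ids[i], ": unexpected leaf ",
                             paste(extra, collapse = ", ")))
      next
    }
    if (is.null(tr$edge.length) || any(tr$edge.length < 0)) {
      errs <- c(errs, paste0(ids[i], ": missing or negative branch length"))
      next
    }
    if (!isTRUE(ape::all.equal.phylo(tr, phylogeny@tree,
                                     use.edge.length = FALSE))) {
      errs <- c(errs, paste0(ids[i], ": topology mismatch"))
      next
    }
    trees[[i]] <- tr
  }
  names(trees) <- ids
  if (length(errs)) {
    msg <- paste0(length(errs), " bad gene tree(s):\n  ",
                  paste(errs, collapse = "\n  "))
    if (!skipBad) stop(msg)
    warning(msg)
    trees <- trees[!vapply(trees, is.null, TRUE)]
  }
  new("OrthologTreeSet", trees = trees, phylogeny = phylogeny)
}

#' Write a gene-tree set
#'
#' Writes one `id<TAB>newick` line per ortholog; output is byte-stable
#' for a given tree set.
#'
#' @param treeSet an [OrthologTreeSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneTrees <- function(treeSet, path) {
  nwk <- vapply(treeSet@trees, function(tr)
    ape::write.tree(tr, digits = 12), "")
  writeLines(paste(names(treeSet@trees), nwk, sep = "\t"), path)
  invisible(path)
}
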