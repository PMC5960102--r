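## OrthoMCL-style groups parsing, pan-genome gene categories, missing
## families and the family-level annotation-term rule.

#' Construct a ClusterTable
#'
#' @param table data.frame with columns `family`, `species`, `gene`.
#' @param species declared species universe.
#' @param geneUniverses named list (by species) of all annotated gene
#'   ids; defaults to the clustered genes only.
#' @return a [ClusterTable-class].
#' @export
ClusterTable <- function(table, species, geneUniverses = NULL) {
  if (is.null(geneUniverses))
    geneUniverses <- split(table$gene, factor(table$species, species))
  miss <- setdiff(species, names(geneUniverses))
  geneUniverses[miss] <- list(character())
  new("ClusterTable", table = table, species = species,
      geneUniverses = geneUniverses[species])
}

setMethod("show", "ClusterTable", function(object) {
  cat("ClusterTable:", length(unique(object@table$family)), "families,",
      length(object@species), "species,",
      sum(lengths(object@geneUniverses)), "genes in universes\n")
})

#' Read an OrthoMCL-style groups file
#'
#' Parses lines of the form `FAM0001: spA|g1 spB|g2 ...`. Every gene id
#' must occur in at most one family, and every species prefix must be
#' in the declared universe; violations are hard errors naming the
#' offending line.
#'
#' @param path groups file path.
#' @param species declared species universe.
#' @param geneUniverses named list of all gene ids per species (for
#'   singleton detection); defaults to the clustered genes.
#' @return a [ClusterTable-class].
#' @export
readGroups <- function(path, species, geneUniverses = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^(\\S+):\\s*(.*)$", lines[i]))[[1L]]
    if (length(m) != 3L) stop("malformed groups line ", i, ": ", lines[i])
    fam <- m[[2L]]
    toks <- strsplit(trimws(m[[3L]]), "\\s+")[[1L]]
    sp <- sub("\\|.*$", "", toks)
    gene <- sub("^[^|]*\\|", "", toks)
    if (length(bad <- setdiff(sp, species)))
      stop("line ", i, ": unknown species prefix ",
           paste(unique(bad), collapse = ", "))
    rows[[i]] <- data.frame(family = fam, species = sp, gene = gene,
                            stringsAsFactors = FALSE)
  }
  tb <- do.call(rbind, rows)
  dup <- tb[duplicated(paste(tb$species, tb$gene)), ]
  if (nrow(dup))
    stop("gene id in more than one family: ",
         paste(head(paste0(dup$species, "|", dup$gene), 5L), collapse = ", "))
  ClusterTable(tb, species, geneUniverses)
}

#' Write a ClusterTable as a groups file
#'
#' @param clusters a [ClusterTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroups <- function(clusters, path) {
  tb <- clusters@table
  fams <- unique(tb$family)
  lines <- vapply(fams, function(f) {
    sel <- tb[tb$family == f, ]
    paste0(f, ": ", paste(paste0(sel$species, "|", sel$gene),
                          collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Pan-genome gene categories
#'
#' Assigns every gene of every species universe to one of five
#' categories: `single_copy_core` (family with exactly one gene in
#' every species), `variable_copy_core` (in every species, more than
#' one somewhere), `dispensable` (in at least two but not all species),
#' `species_specific` (a cluster of >= 2 genes all from one species),
#' and `singleton` (a gene in no cluster). A one-gene "family" is
#' treated as a singleton.
#'
#' @param clusters a [ClusterTable-class].
#' @return list with `genes` (data.frame `species`, `gene`, `family`,
#'   `category`) and `counts` (species x category matrix).
#' @export
classifyGenes <- function(clusters) {
  validObject(clusters)
  tb <- clusters@table
  species <- clusters@species
  nSp <- length(species)
  famCat <- character()
  if (nrow(tb)) {
    cnt <- table(factor(tb$family), factor(tb$species, species))
    present <- rowSums(cnt > 0)
    size <- rowSums(cnt)
    famCat <- ifelse(present == nSp & apply(cnt, 1L, max) == 1L,
                     "single_copy_core",
              ifelse(present == nSp, "variable_copy_core",
              ifelse(present >= 2L, "dispensable",
              ifelse(size >= 2L, "species_specific", "singleton"))))
    names(famCat) <- rownames(cnt)
  }
  rows <- lapply(species, function(sp) {
    uni <- clusters@geneUniverses[[sp]]
    inTab <- tb[tb$species == sp, ]
    extra <- setdiff(inTab$gene, uni)
    uni <- c(uni, extra)   # clustered genes always belong to the universe
    if (!length(uni)) return(NULL)
    fam <- inTab$family[match(uni, inTab$gene)]
    cat <- ifelse(is.na(fam), "singleton", famCat[fam])
    data.frame(species = sp, gene = uni, family = fam, category = cat,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  cats <- c("single_copy_core", "variable_copy_core", "dispensable",
            "species_specific", "singleton")
  counts <- table(factor(genes$species, species),
                  factor(genes$category, cats))
  list(genes = genes, counts = unclass(counts))
}

#' Per-species missing-family counts
#'
#' A family is "missing" for a species when every other species in the
#' universe has at least one representative gene but that species has
#' none — i.e. the species in question is the sole absentee.
#'
#' @param clusters a [ClusterTable-class].
#' @return named integer vector of missing-family counts per species.
#' @export
missingFamilies <- function(clusters) {
  tb <- clusters@table
  species <- clusters@species
  out <- setNames(integer(length(species)), species)
  if (!nrow(tb)) return(out)
  pres <- table(factor(tb$family), factor(tb$species, species)) > 0
  oneAbsent <- rowSums(pres) == length(species) - 1L
  if (any(oneAbsent)) {
    absentee <- apply(!pres[oneAbsent, , drop = FALSE], 1L, which)
    t <- table(factor(species[absentee], species))
    out[names(t)] <- as.integer(t)
  }
  out
}

#' Family-level annotation terms
#'
#' A term annotates a family when at least `threshold` of the member
#' genes carry it (inclusive boundary: 4 of 10 members passes the
#' default 40% rule).
#'
#' @param memberTerms list of per-gene term vectors, one per family
#'   member (members without annotation contribute empty vectors).
#' @param threshold minimum carrying fraction in `(0, 1]`; default 0.40.
#' @return character vector of family terms.
#' @export
familyTerms <- function(memberTerms, threshold = 0.40) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- length(memberTerms)
  if (!n) stop("empty family")
  tab <- table(unlist(lapply(memberTerms, unique)))
  sort(names(tab)[as.vector(tab) / n >= threshold])
}
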