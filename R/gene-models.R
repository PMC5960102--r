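## GFF3-backed gene models: exon/intron accounting, length comparisons
## and spliced CDS extraction.

#' @describeIn GeneModel exon ranges (1-based inclusive, genomic order).
#' @param x,object a `GeneModel`.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GeneModel intron ranges derived as gaps between
#'   consecutive exons (empty for single-exon genes).
#' @export
intronRanges <- function(x) {
  ex <- x@exons
  if (length(ex) < 2L) return(IRanges::IRanges())
  IRanges::IRanges(start = IRanges::end(ex)[-length(ex)] + 1L,
                   end = IRanges::start(ex)[-1L] - 1L)
}

#' @describeIn GeneModel CDS ranges.
#' @export
cdsRanges <- function(x) x@cds

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "(", object@txId, ")",
      object@seqid, object@strand, ":", length(object@exons), "exons,",
      sum(IRanges::width(object@cds)), "bp CDS\n")
})

#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation (via `rtracklayer`) and assembles one
#' [GeneModel-class] per mRNA from its exon and CDS children. With
#' `representative = TRUE` (default), genes with several mRNAs are
#' reduced to the isoform with the longest CDS, so downstream per-gene
#' summaries see one value per gene. Coordinates stay 1-based
#' inclusive. An exon or CDS without a resolvable mRNA parent, or
#' overlapping exons within one mRNA, are errors naming the feature.
#'
#' @param path GFF3 file.
#' @param representative keep only the longest-CDS isoform per gene?
#' @return named list of `GeneModel`s (by gene id when representative,
#'   else by transcript id).
#' @export
readAnnotation <- function(path, representative = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- gr$ID
  mrna <- which(type %in% c("mRNA", "transcript"))
  mrnaIds <- ids[mrna]
  mrnaGene <- vapply(gr$Parent[mrna], function(p)
    if (length(p)) p[[1L]] else NA_character_, "")
  names(mrnaGene) <- mrnaIds
  models <- vector("list", length(mrna))
  names(models) <- mrnaIds
  for (j in seq_along(mrna)) {
    i <- mrna[j]
    tx <- mrnaIds[j]
    kids <- which(vapply(gr$Parent, function(p) tx %in% p, TRUE))
    exi <- kids[type[kids] == "exon"]
    cdi <- kids[type[kids] == "CDS"]
    ex <- IRanges::IRanges(GenomicRanges::start(gr)[exi],
                           GenomicRanges::end(gr)[exi])
    ex <- ex[order(IRanges::start(ex))]
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      stop("overlapping exons in mRNA ", tx)
    cds <- IRanges::IRanges(GenomicRanges::start(gr)[cdi],
                            GenomicRanges::end(gr)[cdi])
    ord <- order(IRanges::start(cds))
    cds <- cds[ord]
    ph <- as.integer(as.character(gr$phase[cdi]))[ord]
    if (!length(ex) && length(cds)) ex <- cds
    models[[j]] <- new("GeneModel",
      geneId = mrnaGene[[tx]] %||% tx, txId = tx,
      seqid = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = ex, cds = cds, phase = ph)
  }
  ## orphan exon/CDS features: every Parent must name a known mRNA
  childIdx <- which(type %in% c("exon", "CDS"))
  for (i in childIdx) {
    p <- gr$Parent[[i]]
    if (!length(p) || !any(p %in% mrnaIds))
      stop("feature ", type[i], " [", i, "] (",
           ids[i] %||% "unnamed", ") has no mRNA parent")
  }
  if (representative) {
    byGene <- split(models, vapply(models, function(m) m@geneId, ""))
    models <- lapply(byGene, function(ms) {
      len <- vapply(ms, function(m) sum(IRanges::width(m@cds)), 0)
      ms[[which.max(len)]]
    })
  }
  models
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based inclusive) through
#' `rtracklayer`; [readAnnotation()] round-trips the coordinates.
#'
#' @param models list of [GeneModel-class]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m@exons
    introns <- intronRanges(m)
    span <- c(min(IRanges::start(ex)), max(IRanges::end(ex)))
    n <- 2L + length(ex) + length(m@cds)
    data.frame(
      seqid = m@seqid,
      start = c(span[1L], span[1L], IRanges::start(ex),
                IRanges::start(m@cds)),
      end = c(span[2L], span[2L], IRanges::end(ex), IRanges::end(m@cds)),
      type = c("gene", "mRNA", rep("exon", length(ex)),
               rep("CDS", length(m@cds))),
      strand = m@strand,
      phase = c(NA, NA, rep(NA, length(ex)),
                if (length(m@phase)) m@phase else rep(0L, length(m@cds))),
      ID = c(m@geneId, m@txId, paste0(m@txId, ":exon", seq_along(ex)),
             paste0(m@txId, ":cds", seq_along(m@cds))),
      Parent = c(NA, m@geneId, rep(m@txId, length(ex)),
                 rep(m@txId, length(m@cds))),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqid,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$source <- "chalcidEvo"
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr$Parent <- S4Vectors::unstrsplit(S4Vectors::splitAsList(
    gr$Parent, seq_along(gr)))
  gr$Parent <- as(ifelse(nzchar(gr$Parent), gr$Parent, NA_character_),
                  "CharacterList")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Total exon and intron length of a gene model
#'
#' @param model a [GeneModel-class].
#' @return named numeric vector `c(exon_bp, intron_bp)`; single-exon
#'   genes have `intron_bp = 0`.
#' @export
exonIntronTotals <- function(model) {
  c(exon_bp = sum(IRanges::width(model@exons)),
    intron_bp = sum(IRanges::width(intronRanges(model))))
}

#' Per-gene exon/intron totals for a model set
#'
#' @param models list of [GeneModel-class]s.
#' @return data.frame with `gene`, `exon_bp`, `intron_bp`.
#' @export
exonIntronTable <- function(models) {
  tot <- t(vapply(models, exonIntronTotals, c(exon_bp = 0, intron_bp = 0)))
  data.frame(gene = vapply(models, function(m) m@geneId, ""),
             exon_bp = tot[, "exon_bp"], intron_bp = tot[, "intron_bp"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare per-gene length totals across species
#'
#' One-way ANOVA over species groups followed by Tukey's honest
#' significant difference comparisons of all species pairs.
#'
#' @param values per-gene totals (e.g. intron bp).
#' @param groups species labels aligned with `values`.
#' @return list with per-species `means`, `F`, `df`, `p`, and the
#'   `tukey` all-pairs table.
#' @export
lengthComparison <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two species groups")
  if (any(table(groups) < 2)) stop("every group needs at least two genes")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1L]]
  list(means = tapply(values, groups, mean),
       F = an[["F value"]][1L], df = an[["Df"]],
       p = an[["Pr(>F)"]][1L],
       tukey = as.data.frame(TukeyHSD(fit)$groups))
}

#' Extract spliced, strand-oriented CDS sequences
#'
#' Concatenates each model's CDS segments in genomic order and
#' reverse-complements minus-strand genes, yielding translatable coding
#' sequences.
#'
#' @param genome a `Biostrings::DNAStringSet` (or FASTA path).
#' @param models list of [GeneModel-class]s.
#' @return a `DNAStringSet` named by gene id.
#' @export
extractCds <- function(genome, models) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- vapply(models, function(m) {
    if (!m@seqid %in% names(genome)) stop("unknown seqid: ", m@seqid)
    chrom <- genome[[m@seqid]]
    rng <- if (length(m@cds)) m@cds else m@exons
    if (max(IRanges::end(rng)) > length(chrom))
      stop("CDS out of contig bounds for ", m@geneId)
    s <- paste(vapply(seq_along(rng), function(i)
      as.character(Biostrings::subseq(chrom, IRanges::start(rng)[i],
                                      IRanges::end(rng)[i])), ""),
      collapse = "")
    if (m@strand == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    s
  }, "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- vapply(models, function(m) m@geneId, "")
  out
}
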