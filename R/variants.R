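## Variant region and coding-effect classification for the
## reference-vs-resequenced genome comparison, plus the missense/silent
## ratio and top-divergence gene selection.

#' Read a VCF-like variant table
#'
#' Tab-separated with header columns `CHROM POS REF ALT` (1-based
#' positions, REF/ALT on the reference strand).
#'
#' @param path TSV path.
#' @return data.frame of variants.
#' @export
readVariants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(POS = "integer"))
  need <- c("CHROM", "POS", "REF", "ALT")
  if (!all(need %in% names(df)))
    stop("variant table must have columns: ", paste(need, collapse = " "))
  df
}

## CDS-relative coordinate (1-based, transcript orientation) of a
## genomic position inside a model's CDS, or NA.
cdsCoordinate <- function(model, pos) {
  rng <- model@cds
  w <- IRanges::width(rng)
  hit <- which(pos >= IRanges::start(rng) & pos <= IRanges::end(rng))
  if (!length(hit)) return(NA_integer_)
  before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
  fwd <- before + (pos - IRanges::start(rng)[hit]) + 1L
  if (model@strand == "+") fwd else sum(w) - fwd + 1L
}

complementBase <- function(b)
  chartr("ACGTacgt", "TGCAtgca", b)

#' Classify variants by genomic region and coding effect
#'
#' Assigns each variant a class (`SNP` or `indel`), a region with
#' precedence coding > UTR > intron > intergenic (a variant inside any
#' mRNA's CDS is coding; in an exon outside the CDS it is UTR; inside a
#' gene span but no exon it is intron), and for coding variants an
#' effect: SNPs have their codon recomputed and translated
#' (`silent`/`missense`/`nonsense`), indels are `frameshift` when the
#' length difference is not a multiple of 3, else `in_frame_indel`.
#' A REF allele disagreeing with the reference sequence is an error
#' naming the site.
#'
#' @param variants data.frame from [readVariants()].
#' @param models list of [GeneModel-class]s.
#' @param genome `DNAStringSet` (or FASTA path) of the reference.
#' @return `variants` with added `class`, `region`, `effect`, `gene`
#'   columns (`effect = "none"` outside coding regions).
#' @export
classifyVariant <- function(variants, models, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  cdsSeqs <- extractCds(genome, models)
  byChrom <- split(seq_along(models),
                   vapply(models, function(m) m@seqid, ""))
  n <- nrow(variants)
  class <- ifelse(nchar(variants$REF) == 1L & nchar(variants$ALT) == 1L,
                  "SNP", "indel")
  region <- rep("intergenic", n)
  effect <- rep("none", n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    chrom <- variants$CHROM[i]; pos <- variants$POS[i]
    if (!chrom %in% names(genome))
      stop("unknown seqid in variant table: ", chrom)
    refBase <- as.character(Biostrings::subseq(
      genome[[chrom]], pos, pos + nchar(variants$REF[i]) - 1L))
    if (refBase != toupper(variants$REF[i]))
      stop("REF mismatch at ", chrom, ":", pos, " (reference ", refBase,
           ", table ", variants$REF[i], ")")
    hit <- NULL; best <- "intergenic"
    for (j in byChrom[[chrom]] %||% integer()) {
      m <- models[[j]]
      ex <- m@exons
      span <- c(min(IRanges::start(ex)), max(IRanges::end(ex)))
      if (pos < span[1L] || pos > span[2L]) next
      inCds <- length(m@cds) &&
        any(pos >= IRanges::start(m@cds) & pos <= IRanges::end(m@cds))
      inExon <- any(pos >= IRanges::start(ex) & pos <= IRanges::end(ex))
      cand <- if (inCds) "coding" else if (inExon) "UTR" else "intron"
      rankOf <- function(r) match(r, c("coding", "UTR", "intron",
                                       "other_genic", "intergenic"))
      if (rankOf(cand) < rankOf(best)) { best <- cand; hit <- m }
    }
    region[i] <- best
    if (!is.null(hit)) gene[i] <- hit@geneId
    if (best == "coding") {
      if (class[i] == "indel") {
        shift <- abs(nchar(variants$REF[i]) - nchar(variants$ALT[i]))
        effect[i] <- if (shift %% 3L != 0L) "frameshift" else
          "in_frame_indel"
      } else {
        cdsPos <- cdsCoordinate(hit, pos)
        cds <- as.character(cdsSeqs[[hit@geneId]])
        ci <- (cdsPos - 1L) %/% 3L + 1L
        off <- (cdsPos - 1L) %% 3L + 1L
        codon <- substr(cds, 3L * (ci - 1L) + 1L, 3L * ci)
        alt <- toupper(variants$ALT[i])
        if (hit@strand == "-") alt <- complementBase(alt)
        newCodon <- codon
        substr(newCodon, off, off) <- alt
        gc <- geneticCode()
        if (nchar(codon) == 3L && codon %in% names(gc) &&
            newCodon %in% names(gc)) {
          aa0 <- gc[[codon]]; aa1 <- gc[[newCodon]]
          effect[i] <- if (aa0 == aa1) "silent"
                       else if (aa1 == "*") "nonsense" else "missense"
        }
      }
    }
  }
  variants$class <- class
  variants$region <- region
  variants$effect <- effect
  variants$gene <- gene
  variants
}

#' Missense/silent ratio
#'
#' @param variants annotated variants from [classifyVariant()].
#' @return `count(missense) / count(silent)`; `NA` (with a warning)
#'   when there are no silent variants.
#' @export
missenseSilentRatio <- function(variants) {
  nm <- sum(variants$effect == "missense")
  ns <- sum(variants$effect == "silent")
  if (ns == 0L) {
    warning("no silent variants; ratio undefined")
    return(NA_real_)
  }
  nm / ns
}

#' Top-divergence gene selection
#'
#' Ranks genes by missense mutations per amino-acid site and returns
#' the top `fraction` (ceiling), including every gene tied with the
#' cutoff rate (flagged via `attr(, "tied")`).
#'
#' @param missenseCounts named per-gene missense counts.
#' @param proteinLengths named per-gene protein lengths (aa, > 0).
#' @param fraction selected fraction (default 0.05).
#' @return character vector of selected gene ids.
#' @export
topDivergenceGenes <- function(missenseCounts, proteinLengths,
                               fraction = 0.05) {
  genes <- names(missenseCounts)
  stopifnot(!is.null(genes), fraction > 0, fraction <= 1)
  len <- proteinLengths[genes]
  if (any(is.na(len) | len <= 0)) stop("protein lengths must be positive")
  rate <- missenseCounts / len
  nSel <- ceiling(fraction * length(genes))
  ord <- order(-rate, genes)
  cutoff <- rate[ord][nSel]
  sel <- genes[rate >= cutoff]
  tied <- length(sel) > nSel
  if (tied && length(sel) == length(genes))
    warning("all genes tied at the selection cutoff")
  structure(sel[order(-rate[sel], sel)], tied = tied)
}
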