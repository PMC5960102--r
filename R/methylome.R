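## Gene-body methylation: CpG/GpC observed/expected, bisulfite
## fractional methylation with status calls, positional profiles and
## cross-species conservation accounting.

#' Dinucleotide observed/expected ratio
#'
#' Computes `O/E = (N_XY * L) / (N_X * N_Y)` with overlapping
#' dinucleotide windows over the `L - 1` adjacent pairs. Windows
#' containing `N` are skipped and the effective length reduced
#' accordingly; mononucleotide counts ignore `N`. CpG depletion
#' (O/E well below 1) marks historically methylated coding sequence,
#' because methylcytosine deaminates to thymine.
#'
#' @param sequence a DNA string (character or `DNAString`) over
#'   `A,C,G,T,N`, length >= 2.
#' @param dinucleotide two-letter dinucleotide, default `"CG"` (CpG);
#'   use `"GC"` for the GpC control.
#' @return list with `oe` (NA when undefined), `n_xy`, `n_x`, `n_y`,
#'   `length` (effective L) and `defined`.
#' @examples
#' dinucleotideOE("CGCGCG")$oe  # 2.0
#' @export
dinucleotideOE <- function(sequence, dinucleotide = "CG") {
  s <- toupper(as.character(sequence))
  if (nchar(s) < 2) stop("sequence must have length >= 2")
  if (nchar(dinucleotide) != 2) stop("dinucleotide must have 2 letters")
  chars <- strsplit(s, "")[[1L]]
  x <- substr(dinucleotide, 1, 1); y <- substr(dinucleotide, 2, 2)
  first <- chars[-length(chars)]; second <- chars[-1L]
  validWin <- first != "N" & second != "N"
  nXY <- sum(first == x & second == y & validWin)
  nX <- sum(chars == x); nY <- sum(chars == y)
  L <- sum(validWin) + 1L
  if (nX * nY == 0)
    return(list(oe = NA_real_, n_xy = nXY, n_x = nX, n_y = nY,
                length = L, defined = FALSE))
  list(oe = nXY * L / (nX * nY), n_xy = nXY, n_x = nX, n_y = nY,
       length = L, defined = TRUE)
}

#' CpG and GpC O/E per coding sequence
#'
#' @param cds a named `DNAStringSet` (or character vector) of CDS.
#' @return data.frame with `gene`, `cpg_oe`, `gpc_oe`, `defined`.
#' @export
cdsDinucleotideOE <- function(cds) {
  cds <- as.character(cds)
  cpg <- lapply(cds, dinucleotideOE, dinucleotide = "CG")
  gpc <- lapply(cds, dinucleotideOE, dinucleotide = "GC")
  data.frame(gene = names(cds),
             cpg_oe = vapply(cpg, `[[`, 0, "oe"),
             gpc_oe = vapply(gpc, `[[`, 0, "oe"),
             defined = vapply(cpg, `[[`, TRUE, "defined") &
               vapply(gpc, `[[`, TRUE, "defined"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a per-site bisulfite methylation table
#'
#' Tab-separated with header
#' `seqid pos strand context meth_reads total_reads`.
#'
#' @param path TSV path.
#' @return data.frame of sites.
#' @export
readMethylationSites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("seqid", "pos", "strand", "context", "meth_reads",
            "total_reads")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = " "))
  if (any(df$meth_reads > df$total_reads))
    stop("meth_reads exceeds total_reads")
  df
}

#' Gene-body fractional methylation
#'
#' Read-weighted fractional methylation over the covered CpG sites in
#' the gene body (gene span on its contig, exons plus introns):
#' `sum(meth_reads) / sum(total_reads)`. Sites under `minCoverage`
#' reads are excluded. A gene needs `minSites` covered CpG sites for a
#' status call; genes with zero covered sites are `no_data`.
#'
#' @param sites site table (CpG context) as from
#'   [readMethylationSites()].
#' @param model a [GeneModel-class] (or list `seqid`, `start`, `end`).
#' @param minCoverage minimum reads per site (default 1).
#' @param minSites minimum covered sites for a status call (default 3).
#' @param threshold methylation-call threshold (default 0.01).
#' @param weighted read-weighted estimator (default); `FALSE` averages
#'   per-site fractions instead.
#' @return one-row data.frame: `gene`, `fraction`, `n_sites`, `status`.
#' @export
geneFractionalMethylation <- function(sites, model, minCoverage = 1,
                                      minSites = 3, threshold = 0.01,
                                      weighted = TRUE) {
  if (is(model, "GeneModel")) {
    span <- list(gene = model@geneId, seqid = model@seqid,
                 start = min(IRanges::start(model@exons)),
                 end = max(IRanges::end(model@exons)))
  } else span <- model
  sel <- sites$seqid == span$seqid & sites$pos >= span$start &
    sites$pos <= span$end & sites$context == "CpG" &
    sites$total_reads >= minCoverage
  s <- sites[sel, ]
  n <- nrow(s)
  if (n == 0L)
    return(data.frame(gene = span$gene, fraction = NA_real_, n_sites = 0L,
                      status = "no_data", stringsAsFactors = FALSE))
  frac <- if (weighted) sum(s$meth_reads) / sum(s$total_reads)
          else mean(s$meth_reads / s$total_reads)
  status <- if (n < minSites) "no_data"
            else classifyMethylated(frac, threshold)
  data.frame(gene = span$gene, fraction = frac, n_sites = n,
             status = status, stringsAsFactors = FALSE)
}

#' Methylation status call
#'
#' A gene is called methylated when its gene-body fractional
#' methylation strictly exceeds the threshold (default 0.01).
#'
#' @param fraction fractional methylation in `[0, 1]`.
#' @param threshold call threshold (default 0.01).
#' @return `"methylated"` or `"unmethylated"` (vectorized).
#' @export
classifyMethylated <- function(fraction, threshold = 0.01) {
  stopifnot(all(fraction >= 0 & fraction <= 1, na.rm = TRUE))
  ifelse(fraction > threshold, "methylated", "unmethylated")
}

#' Methylation table for a set of gene models
#'
#' @param sites site table.
#' @param models list of [GeneModel-class]s.
#' @param ... passed to [geneFractionalMethylation()].
#' @return data.frame, one row per gene.
#' @export
methylationTable <- function(sites, models, ...) {
  out <- do.call(rbind, lapply(models, geneFractionalMethylation,
                               sites = sites, ...))
  rownames(out) <- NULL
  out
}

## Fractional methylation of the CpG sites inside one interval.
intervalFraction <- function(sites, seqid, start, end, minCoverage = 1) {
  sel <- sites$seqid == seqid & sites$pos >= start & sites$pos <= end &
    sites$context == "CpG" & sites$total_reads >= minCoverage
  if (!any(sel)) return(NA_real_)
  sum(sites$meth_reads[sel]) / sum(sites$total_reads[sel])
}

#' Positional methylation profile over exons and introns
#'
#' Mean fractional methylation in the first and last `nFeatures` exons
#' and introns (transcript orientation) across a gene set, computed
#' separately for methylated and unmethylated genes. Genes with fewer
#' features contribute only to the slots they have; slot means average
#' over contributing genes.
#'
#' @param models list of [GeneModel-class]s.
#' @param sites site table.
#' @param status named status vector per gene
#'   (`"methylated"`/`"unmethylated"`).
#' @param nFeatures slots per end (default 4).
#' @param minCoverage minimum reads per site.
#' @return data.frame: `group`, `feature` (exon/intron), `end`
#'   (first/last), `slot` (1..nFeatures), `mean_fraction`, `n_genes`.
#' @export
positionalProfile <- function(models, sites, status, nFeatures = 4,
                              minCoverage = 1) {
  acc <- list()
  for (m in models) {
    st <- status[[m@geneId]]
    if (is.null(st) || is.na(st) || st == "no_data") next
    for (feat in c("exon", "intron")) {
      rng <- if (feat == "exon") m@exons else intronRanges(m)
      if (!length(rng)) next
      ord <- if (m@strand == "+") seq_along(rng) else rev(seq_along(rng))
      fr <- vapply(ord, function(i)
        intervalFraction(sites, m@seqid, IRanges::start(rng)[i],
                         IRanges::end(rng)[i], minCoverage), 0)
      k <- length(fr)
      for (slot in seq_len(min(nFeatures, k))) {
        for (endLab in c("first", "last")) {
          v <- if (endLab == "first") fr[slot] else fr[k - slot + 1L]
          if (!is.na(v))
            acc[[length(acc) + 1L]] <- data.frame(
              group = st, feature = feat, end = endLab, slot = slot,
              fraction = v, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(acc))
    return(data.frame(group = character(), feature = character(),
                      end = character(), slot = integer(),
                      mean_fraction = numeric(), n_genes = integer()))
  df <- do.call(rbind, acc)
  agg <- aggregate(fraction ~ group + feature + end + slot, df, mean)
  cnt <- aggregate(fraction ~ group + feature + end + slot, df, length)
  names(agg)[names(agg) == "fraction"] <- "mean_fraction"
  agg$n_genes <- cnt$fraction
  agg[order(agg$group, agg$feature, agg$end, agg$slot), ]
}

#' Cross-species methylation conservation table
#'
#' Labels each ortholog from the tuple of per-species status calls:
#' all methylated or all unmethylated are conserved; the focal species
#' differing from a unanimous remainder is a focal-specific gain or
#' loss; every other complete tuple is `other` (non-focal specific
#' changes). Orthologs with any `no_data` status are excluded and
#' counted.
#'
#' @param status data.frame or matrix, orthologs x species, of
#'   `"methylated"`/`"unmethylated"`/`"no_data"`, rownames = ortholog
#'   ids.
#' @param focal focal species column name.
#' @return list with `records` (ortholog, label) and `counts`
#'   (named: conserved_methylated, focal_gain, focal_loss,
#'   conserved_unmethylated, other, excluded).
#' @export
conservationTable <- function(status, focal) {
  status <- as.matrix(status)
  if (ncol(status) < 3) stop("need at least three species")
  if (!focal %in% colnames(status)) stop("unknown focal species: ", focal)
  others <- setdiff(colnames(status), focal)
  lab <- apply(status, 1L, function(s) {
    if (any(s == "no_data" | is.na(s))) return("excluded")
    f <- s[[focal]]; o <- s[others]
    if (all(s == "methylated")) "conserved_methylated"
    else if (all(s == "unmethylated")) "conserved_unmethylated"
    else if (f == "methylated" && all(o == "unmethylated")) "focal_gain"
    else if (f == "unmethylated" && all(o == "methylated")) "focal_loss"
    else "other"
  })
  lev <- c("conserved_methylated", "focal_gain", "focal_loss",
           "conserved_unmethylated", "other", "excluded")
  list(records = data.frame(ortholog = rownames(status), label = lab,
                            row.names = NULL, stringsAsFactors = FALSE),
       counts = table(factor(lab, lev)))
}

#' Correlation of gene-body methylation between two species
#'
#' Product-moment correlation of log10-transformed fractional
#' methylation over paired orthologs; a small positive floor keeps
#' zero fractions finite.
#'
#' @param fractions1,fractions2 paired fractional methylation vectors.
#' @param floor additive floor before log10 (default 1e-4).
#' @return list with `r`, `p`, `n`.
#' @export
orthologMethylationCorrelation <- function(fractions1, fractions2,
                                           floor = 1e-4) {
  stopifnot(length(fractions1) == length(fractions2), floor > 0)
  ok <- is.finite(fractions1) & is.finite(fractions2)
  if (sum(ok) < 3) stop("need at least three complete ortholog pairs")
  ct <- cor.test(log10(fractions1[ok] + floor),
                 log10(fractions2[ok] + floor))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
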