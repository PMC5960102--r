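## Tajima's relative rate test on (in-group A, in-group B, out-group O)
## amino-acid alignments, with a divergence-masking filter and a
## concatenated whole-set test.

#' Construct a TripleAlignment
#'
#' @param id ortholog identifier.
#' @param a,b,o aligned amino-acid sequences (equal length): in-group A,
#'   in-group B and the out-group.
#' @param names species names for the three roles.
#' @return a [TripleAlignment-class].
#' @export
TripleAlignment <- function(id, a, b, o, names = c("A", "B", "O")) {
  seqs <- Biostrings::AAStringSet(c(a, b, o))
  names(seqs) <- names
  new("TripleAlignment", id = as.character(id), seqs = seqs)
}

alnMatrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln@seqs), ""))
}

#' Mask divergent alignment regions
#'
#' A conservative stand-in for external divergence-masking tools: every
#' column containing a gap is removed, and all columns of any sliding
#' window whose mean pairwise identity falls below `minIdentity` are
#' removed. Not byte-compatible with Gblocks; pre-masked alignments can
#' be supplied instead. The retained-column map is attached as
#' `attr(, "columnMap")`.
#'
#' @param aln a [TripleAlignment-class].
#' @param window sliding-window width in columns (default 10).
#' @param minIdentity minimum mean pairwise identity per window
#'   (default 0.5); identities are computed over the three sequence
#'   pairs, gaps never match.
#' @return the masked `TripleAlignment` (possibly zero columns) with
#'   `masked = TRUE`.
#' @export
maskAlignment <- function(aln, window = 10, minIdentity = 0.5) {
  stopifnot(minIdentity >= 0, minIdentity <= 1, window >= 1)
  m <- alnMatrix(aln)
  L <- ncol(m)
  isGap <- m %in% c("-", ".")
  dim(isGap) <- dim(m)
  gapCol <- colSums(isGap) > 0L
  ident <- (( (m[1L, ] == m[2L, ]) & !isGap[1L, ] & !isGap[2L, ]) +
            ( (m[1L, ] == m[3L, ]) & !isGap[1L, ] & !isGap[3L, ]) +
            ( (m[2L, ] == m[3L, ]) & !isGap[2L, ] & !isGap[3L, ])) / 3
  drop <- gapCol
  if (L >= window) {
    for (s in seq_len(L - window + 1L)) {
      w <- s:(s + window - 1L)
      if (mean(ident[w]) < minIdentity) drop[w] <- TRUE
    }
  } else if (L > 0L && mean(ident) < minIdentity) drop[] <- TRUE
  keep <- which(!drop)
  seqs <- Biostrings::AAStringSet(apply(m[, keep, drop = FALSE], 1L, paste,
                                        collapse = ""))
  names(seqs) <- names(aln@seqs)
  out <- new("TripleAlignment", id = aln@id, seqs = seqs, masked = TRUE)
  attr(out, "columnMap") <- keep
  out
}

#' Count lineage-unique substitutions
#'
#' Scans alignment columns and counts `mA`, the sites where A differs
#' while B and O agree (a change on A's branch under parsimony with the
#' out-group as reference), and symmetrically `mB`. Columns with a gap
#' or ambiguity in any sequence are skipped; all other column patterns
#' are ignored by the test.
#'
#' @param aln a [TripleAlignment-class].
#' @return list with counts `mA`, `mB` and `n_used`, the number of
#'   gap-free columns scanned.
#' @export
tajimaCounts <- function(aln) {
  m <- alnMatrix(aln)
  if (ncol(m) == 0L) return(list(mA = 0L, mB = 0L, n_used = 0L))
  ok <- !apply(m, 2L, function(col) any(col %in% c("-", ".", "X", "*")))
  a <- m[1L, ok]; b <- m[2L, ok]; o <- m[3L, ok]
  list(mA = sum(a != b & b == o), mB = sum(b != a & a == o),
       n_used = sum(ok))
}

#' Tajima's relative rate test
#'
#' Tests equality of substitution counts on the two in-group lineages:
#' `chi2 = (mA - mB)^2 / (mA + mB)` on 1 degree of freedom. With
#' `mA + mB = 0` the test is undefined and reported as such (`p = NA`).
#'
#' @param mA,mB lineage-unique substitution counts (non-negative).
#' @param id optional ortholog id carried through.
#' @param nUsed optional number of columns counted.
#' @param masked whether the counts came from a masked alignment.
#' @return a one-row data.frame with `id`, `mA`, `mB`, `chi2`, `p`,
#'   `n_used`, `masked`.
#' @examples
#' tajimaTest(30, 10)  # chi2 = 10, p ~ 1.57e-3
#' @export
tajimaTest <- function(mA, mB, id = NA_character_, nUsed = NA_integer_,
                       masked = FALSE) {
  if (mA < 0 || mB < 0) stop("counts must be non-negative")
  tot <- mA + mB
  chi2 <- if (tot > 0) (mA - mB)^2 / tot else 0
  p <- if (tot > 0) pchisq(chi2, df = 1, lower.tail = FALSE) else NA_real_
  data.frame(id = id, mA = mA, mB = mB, chi2 = chi2, p = p,
             n_used = nUsed, masked = masked, stringsAsFactors = FALSE)
}

#' Relative rate test on one alignment
#'
#' Convenience wrapper: count and test in one step, optionally masking
#' first.
#'
#' @param aln a [TripleAlignment-class].
#' @param mask apply [maskAlignment()] first?
#' @param ... passed to [maskAlignment()].
#' @return as [tajimaTest()].
#' @export
relativeRateTest <- function(aln, mask = FALSE, ...) {
  if (mask) aln <- maskAlignment(aln, ...)
  ct <- tajimaCounts(aln)
  tajimaTest(ct$mA, ct$mB, id = aln@id, nUsed = ct$n_used,
             masked = aln@masked)
}

#' Concatenated relative rate test
#'
#' Sums the lineage-unique substitution counts over a set of alignments
#' sharing the same (A, B, O) species roles and performs one test on the
#' totals — the whole-proteome version of the per-gene test.
#'
#' @param alns list of [TripleAlignment-class] objects.
#' @return as [tajimaTest()], with `id = "concatenated"`.
#' @export
concatenatedTest <- function(alns) {
  if (!length(alns)) stop("empty alignment set")
  roles <- unique(lapply(alns, function(a) names(a@seqs)))
  if (length(roles) != 1L)
    stop("alignments have mixed species roles; cannot concatenate")
  cts <- lapply(alns, tajimaCounts)
  tajimaTest(sum(vapply(cts, `[[`, 0L, "mA")),
             sum(vapply(cts, `[[`, 0L, "mB")),
             id = "concatenated",
             nUsed = sum(vapply(cts, `[[`, 0L, "n_used")))
}

#' Summarize per-gene relative rate tests
#'
#' Applies a multiple-testing correction to the per-gene p-values and
#' counts significant genes by the faster lineage (sign of `mA - mB`).
#'
#' @param results data.frame of [tajimaTest()] rows.
#' @param alpha significance level (default 0.05).
#' @param method correction method for [stats::p.adjust()]; `"BH"` by
#'   default, `"none"` for raw p-values.
#' @return list with `nA` (A faster), `nB` (B faster), `nSignificant`,
#'   and the results with an added `p_adj` column.
#' @export
rateTestSummary <- function(results, alpha = 0.05, method = "BH") {
  stopifnot(alpha > 0, alpha < 1)
  if (!nrow(results))
    return(list(nA = 0L, nB = 0L, nSignificant = 0L, results = results))
  results$p_adj <- p.adjust(results$p, method = method)
  sig <- !is.na(results$p_adj) & results$p_adj < alpha
  list(nA = sum(sig & results$mA > results$mB),
       nB = sum(sig & results$mB > results$mA),
       nSignificant = sum(sig), results = results)
}
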