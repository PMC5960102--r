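## Pairwise coding divergence: Nei-Gojobori synonymous/nonsynonymous
## site and difference counting with pathway averaging and Jukes-Cantor
## correction, plus aggregation and top-divergence selection.

NUCS <- c("A", "C", "G", "T")

.ngCache <- new.env(parent = emptyenv())

geneticCode <- function() Biostrings::GENETIC_CODE

## Per-codon synonymous site counts: each position contributes one site
## split by the fraction of its non-stop single-nucleotide changes that
## are synonymous (changes to stop codons are excluded and the fraction
## renormalized, keeping N + S = 3 per codon).
synSites <- function() {
  if (!is.null(.ngCache$syn)) return(.ngCache$syn)
  gc <- geneticCode()
  codons <- names(gc)
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") { syn[[cd]] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      alt <- vapply(setdiff(NUCS, substr(cd, pos, pos)), function(n) {
        x <- cd; substr(x, pos, pos) <- n; x
      }, "")
      aa <- gc[alt]
      keep <- aa != "*"
      if (any(keep)) s <- s + sum(aa[keep] == gc[[cd]]) / sum(keep)
    }
    syn[[cd]] <- s
  }
  .ngCache$syn <- syn
  syn
}

## Average synonymous/nonsynonymous differences between two codons over
## all mutational pathways; pathways through stop codons are excluded
## (all-blocked pairs fall back to including them).
codonDifferences <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (!is.null(.ngCache[[key]])) return(.ngCache[[key]])
  gc <- geneticCode()
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  res <- if (!length(pos)) c(syn = 0, nonsyn = 0) else {
    perms <- if (length(pos) == 1L) list(pos) else {
      pm <- list()
      for (p in seq_along(pos)) {
        rest <- pos[-p]
        sub <- if (length(rest) == 1L) list(rest) else
          list(rest, rev(rest))
        for (s in sub) pm[[length(pm) + 1L]] <- c(pos[p], s)
      }
      pm
    }
    eval1 <- function(order, allowStop) {
      cur <- c1; s <- 0; n <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (!allowStop && gc[[nxt]] == "*") return(NULL)
        if (gc[[nxt]] == gc[[cur]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    }
    vals <- Filter(Negate(is.null), lapply(perms, eval1, allowStop = FALSE))
    if (!length(vals)) vals <- lapply(perms, eval1, allowStop = TRUE)
    m <- do.call(rbind, vals)
    c(syn = mean(m[, 1L]), nonsyn = mean(m[, 2L]))
  }
  .ngCache[[key]] <- res
  res
}

#' Jukes-Cantor distance correction
#'
#' `d = -3/4 * log(1 - 4p/3)`; undefined (NA) for `p >= 3/4`. Always
#' `d >= p`, with `d -> p` as `p -> 0`.
#'
#' @param p proportion of differing sites in `[0, 1]`.
#' @return corrected per-site distance.
#' @export
jukesCantor <- function(p) {
  ifelse(p >= 3 / 4, NA_real_, -3 / 4 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori divergence statistics for a coding pair
#'
#' Counts synonymous (`S`) and nonsynonymous (`N`) sites (averaged over
#' the two sequences) and observed synonymous (`Sd`) / nonsynonymous
#' (`Nd`) differences, averaging multi-difference codons over all
#' mutational pathways that avoid stop codons. Proportions `pS`, `pN`
#' are Jukes-Cantor corrected to `dS`, `dN`. Codons containing gaps,
#' ambiguity codes or a stop in either sequence are skipped and
#' counted. `N + S = 3 x` (codons used).
#'
#' @param seq1,seq2 aligned coding sequences (character or
#'   `DNAString`), equal length, compared over complete codons.
#' @param id optional gene id.
#' @return one-row data.frame: `id`, `codons`, `skipped`, `N`, `S`,
#'   `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `dnds`.
#' @export
neiGojobori <- function(seq1, seq2, id = NA_character_) {
  s1 <- toupper(as.character(seq1)); s2 <- toupper(as.character(seq2))
  if (nchar(s1) != nchar(s2)) stop("sequences must be aligned")
  ncod <- nchar(s1) %/% 3L
  if (!ncod) stop("need at least one complete codon")
  starts <- 3L * (seq_len(ncod) - 1L) + 1L
  c1 <- substring(s1, starts, starts + 2L)
  c2 <- substring(s2, starts, starts + 2L)
  syn <- synSites()
  gc <- geneticCode()
  valid <- c1 %in% names(gc) & c2 %in% names(gc)
  valid[valid] <- gc[c1[valid]] != "*" & gc[c2[valid]] != "*"
  c1 <- c1[valid]; c2 <- c2[valid]
  used <- length(c1)
  S <- sum(syn[c1] + syn[c2]) / 2
  N <- 3 * used - S
  Sd <- Nd <- 0
  diffIdx <- which(c1 != c2)
  if (length(diffIdx)) {
    keys <- paste0(c1[diffIdx], c2[diffIdx])
    tab <- table(keys)
    for (k in names(tab)) {
      d <- codonDifferences(substr(k, 1, 3), substr(k, 4, 6))
      Sd <- Sd + d[["syn"]] * tab[[k]]
      Nd <- Nd + d[["nonsyn"]] * tab[[k]]
    }
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- if (is.na(pS)) NA_real_ else jukesCantor(pS)
  dN <- if (is.na(pN)) NA_real_ else jukesCantor(pN)
  data.frame(id = id, codons = used, skipped = ncod - used,
             N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
             dN = dN, dS = dS,
             dnds = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS
                    else NA_real_,
             stringsAsFactors = FALSE)
}

#' Aggregate per-gene divergence statistics
#'
#' Means and standard errors of `dS` and `dN` over genes with defined
#' estimates, the subset with `dN/dS > 1`, and the count of undefined
#' estimates.
#'
#' @param stats data.frame of [neiGojobori()] rows.
#' @return list with `mean_dS`, `se_dS`, `mean_dN`, `se_dN`,
#'   `n_defined`, `n_undefined`, `ratio_gt1` (gene ids).
#' @export
aggregateDivergence <- function(stats) {
  okS <- !is.na(stats$dS); okN <- !is.na(stats$dN)
  if (!any(okS)) stop("no defined dS estimates")
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(mean_dS = mean(stats$dS[okS]), se_dS = se(stats$dS[okS]),
       mean_dN = mean(stats$dN[okN]), se_dN = se(stats$dN[okN]),
       n_defined = sum(okS & okN), n_undefined = sum(!okS | !okN),
       ratio_gt1 = stats$id[!is.na(stats$dnds) & stats$dnds > 1])
}
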