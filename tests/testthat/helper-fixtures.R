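## Shared fixtures and independent oracle implementations.

## Symmetric balanced 4-taxon phylogeny: all four leaves exchangeable
## under i.i.d. multiplicative branch noise.
balancedPhylogeny <- function() {
  SpeciesPhylogeny("((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2):0.0;",
                   cladeMembers = c("A", "B", "C", "D"))
}

## Independent place-assignment oracle: repeated max-extraction instead
## of a vectorized order().
oraclePlaces <- function(distances) {
  k <- length(distances)
  nm <- names(distances)
  res <- setNames(integer(k), nm)
  remaining <- nm
  for (p in seq_len(k)) {
    d <- distances[remaining]
    best <- remaining[d == max(d)]
    pick <- sort(best)[1L]
    res[pick] <- p
    remaining <- setdiff(remaining, pick)
  }
  res
}

## Independent bin-selection oracle: explicit per-bin data frame sort.
oracleBinSelect <- function(scores, baseRanks, binSize, fraction) {
  df <- data.frame(id = names(scores), score = scores, base = baseRanks,
                   stringsAsFactors = FALSE)
  df <- df[order(df$base), ]
  df$bin <- ceiling(seq_len(nrow(df)) / binSize)
  fast <- slow <- character()
  for (b in unique(df$bin)) {
    sub <- df[df$bin == b, ]
    nsel <- max(1, sign(fraction * nrow(sub)) *
                  floor(abs(fraction * nrow(sub)) + 0.5))
    sub <- sub[order(-sub$score, sub$id), ]
    fast <- c(fast, sub$id[seq_len(nsel)])
    sub <- sub[order(sub$score, sub$id), ]
    slow <- c(slow, sub$id[seq_len(nsel)])
  }
  list(fast = fast, slow = slow)
}

## Recursive pathway-enumeration oracle for per-codon-pair synonymous /
## nonsynonymous differences (stop-avoiding pathways, uniform average).
oracleCodonDiff <- function(c1, c2, allowStop = FALSE) {
  gc <- Biostrings::GENETIC_CODE
  rec <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allowStop && gc[[nxt]] == "*") next
      step <- if (gc[[nxt]] == gc[[cur]]) c(1, 0) else c(0, 1)
      for (tailRes in rec(nxt, setdiff(remaining, p)))
        out[[length(out) + 1L]] <- step + tailRes
    }
    out
  }
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  paths <- rec(c1, pos)
  if (!length(paths)) return(oracleCodonDiff(c1, c2, allowStop = TRUE))
  m <- do.call(rbind, paths)
  c(syn = mean(m[, 1L]), nonsyn = mean(m[, 2L]))
}

## Exact hypergeometric upper-tail by combinatorial summation.
oracleHyper <- function(x, K, N, n) {
  js <- x:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Random stop-free coding sequence.
randomCodingSeq <- function(ncod) {
  gc <- Biostrings::GENETIC_CODE
  paste(sample(names(gc)[gc != "*"], ncod, replace = TRUE),
        collapse = "")
}

## Tiny GFF3 written to a temp file.
writeTempGff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}
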