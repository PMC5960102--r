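## Chi-squared machinery: goodness of fit against stated proportions,
## 2x2 tests with continuity correction, all-pairs post-hoc comparisons
## with multiple-testing correction, and hypergeometric term
## overrepresentation.

#' Chi-squared goodness-of-fit test
#'
#' Pearson test of observed counts against expected proportions
#' (uniform by default), e.g. species' 1st-place counts against the
#' equal-probability null.
#'
#' @param observed non-negative integer counts (>= 2 cells).
#' @param expectedProportions cell probabilities summing to 1; default
#'   uniform.
#' @return data.frame with `statistic`, `df`, `p`, `comparison`.
#' @export
chisqGof <- function(observed, expectedProportions = NULL) {
  k <- length(observed)
  stopifnot(k >= 2, all(observed >= 0), sum(observed) > 0)
  if (is.null(expectedProportions)) expectedProportions <- rep(1 / k, k)
  if (abs(sum(expectedProportions) - 1) > 1e-9)
    stop("expected proportions must sum to 1")
  if (any(expectedProportions * sum(observed) <= 0))
    stop("zero expected cell count")
  ht <- suppressWarnings(chisq.test(observed, p = expectedProportions))
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, comparison = "goodness-of-fit",
             stringsAsFactors = FALSE)
}

#' 2x2 chi-squared test
#'
#' Pearson test on a 2x2 table, with Yates' continuity correction by
#' default (the corrected statistic never exceeds the uncorrected one).
#' A zero row or column margin makes the test undefined (`p = NA`).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct apply the continuity correction (default `TRUE`).
#' @param comparison optional label.
#' @return data.frame with `statistic`, `df`, `p`, `correction`,
#'   `comparison`.
#' @export
chisq2x2 <- function(table, correct = TRUE, comparison = NA_character_) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  lab <- if (correct) "continuity" else "none"
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(data.frame(statistic = NA_real_, df = 1L, p = NA_real_,
                      correction = lab, comparison = comparison,
                      stringsAsFactors = FALSE))
  ht <- suppressWarnings(chisq.test(table, correct = correct))
  data.frame(statistic = unname(ht$statistic), df = 1L, p = ht$p.value,
             correction = lab, comparison = comparison,
             stringsAsFactors = FALSE)
}

#' All-pairs post-hoc 2x2 comparisons
#'
#' Follows up a goodness-of-fit result by testing every pair of groups
#' with a 2x2 (success vs failure) chi-squared test and adjusting the
#' p-values for multiple comparisons — a reimplementation of the
#' classic post-hoc follow-up to a significant one-way chi-squared.
#'
#' @param counts named per-group success counts (e.g. 1st places).
#' @param totals per-group totals (recycled if length 1).
#' @param method adjustment method: `"BH"` (default), `"bonferroni"` or
#'   `"none"`.
#' @param correct continuity correction for each 2x2 (default `TRUE`).
#' @return data.frame, one row per pair, with raw `p` and adjusted
#'   `p_adj`.
#' @export
pairwisePosthoc <- function(counts, totals, method = c("BH", "bonferroni",
                                                       "none"),
                            correct = TRUE) {
  method <- match.arg(method)
  k <- length(counts)
  stopifnot(k >= 2)
  totals <- rep_len(totals, k)
  if (any(counts > totals)) stop("counts exceed totals")
  grp <- names(counts) %||% paste0("group", seq_len(k))
  pairs <- combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    tb <- matrix(c(counts[i1], totals[i1] - counts[i1],
                   counts[i2], totals[i2] - counts[i2]),
                 2L, 2L, byrow = TRUE)
    chisq2x2(tb, correct = correct,
             comparison = paste(grp[i1], "vs", grp[i2]))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = method)
  out
}

#' Hypergeometric term overrepresentation
#'
#' For each annotation term, tests whether the study set contains more
#' term-annotated genes than expected from the population, with the
#' hypergeometric upper tail, followed by multiple-testing adjustment.
#'
#' @param studyIds study gene ids (must all be in `populationIds`).
#' @param populationIds background gene ids.
#' @param termMap named list: gene id -> character vector of terms.
#' @param method p-value adjustment (default `"BH"`).
#' @param alpha report terms with adjusted p below this (default 0.05);
#'   use 1 to report all.
#' @return data.frame per term: `term`, `study_count`, `study_size`,
#'   `pop_count`, `pop_size`, `p`, `p_adj`, sorted by p.
#' @export
termEnrichment <- function(studyIds, populationIds, termMap,
                           method = "BH", alpha = 0.05) {
  studyIds <- unique(studyIds); populationIds <- unique(populationIds)
  bad <- setdiff(studyIds, populationIds)
  if (length(bad))
    stop("study ids absent from population: ",
         paste(head(bad, 5L), collapse = ", "))
  termMap <- termMap[intersect(names(termMap), populationIds)]
  long <- data.frame(
    gene = rep(names(termMap), lengths(termMap)),
    term = unlist(termMap, use.names = FALSE), stringsAsFactors = FALSE)
  long <- unique(long)
  N <- length(populationIds); n <- length(studyIds)
  terms <- unique(long$term)
  rows <- lapply(terms, function(tm) {
    genes <- long$gene[long$term == tm]
    K <- length(genes)
    x <- sum(genes %in% studyIds)
    p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, study_count = x, study_size = n,
               pop_count = K, pop_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = method)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out[out$p_adj <= alpha | alpha >= 1, ]
}
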