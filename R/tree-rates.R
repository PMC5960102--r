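## Root-to-clade branch-length extraction, place ranking, rank
## discrepancy scoring, binned fast/slow selection and overlap
## accounting for single-copy ortholog gene trees.

#' Root-to-anchor distances for every (ortholog, species) pair
#'
#' For each gene tree, extracts the path length from each clade member
#' to the clade ancestor (`clade_dist`), from each in-group species to
#' the deeper ancestor (`order_dist`), and the path between the two
#' ancestors (`base_dist`). Anchors are located as most recent common
#' ancestors of the reference leaf sets in each gene tree, never by node
#' labels. For clade members `order_dist = clade_dist + base_dist` by
#' tree additivity. Zero-length degenerate trees are allowed (all
#' distances 0).
#'
#' @param treeSet an [OrthologTreeSet-class].
#' @return a data.frame with columns `ortholog`, `species`,
#'   `clade_dist` (NA outside the clade), `order_dist`, `base_dist`.
#' @export
rootToAnchorDistances <- function(treeSet) {
  phy <- treeSet@phylogeny
  out <- vector("list", length(treeSet@trees))
  for (i in seq_along(treeSet@trees)) {
    tr <- treeSet@trees[[i]]
    depth <- ape::node.depth.edgelength(tr)
    anch <- anchorNodes(tr, phy)
    species <- phy@orderMembers
    tipIdx <- match(species, tr$tip.label)
    cladeD <- ifelse(species %in% phy@cladeMembers,
                     depth[tipIdx] - depth[anch$cladeRoot], NA_real_)
    out[[i]] <- data.frame(
      ortholog = names(treeSet@trees)[i], species = species,
      clade_dist = cladeD,
      order_dist = depth[tipIdx] - depth[anch$orderRoot],
      base_dist = depth[anch$cladeRoot] - depth[anch$orderRoot],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate within-ortholog branch-length places
#'
#' Within each ortholog, species are ranked by descending distance:
#' place 1 is the longest branch (most change since the ancestor),
#' place k the shortest. Ties are broken deterministically by
#' species-name order and the affected orthologs flagged.
#'
#' @param records distance records from [rootToAnchorDistances()] (or
#'   any data.frame with `ortholog`, `species` and a distance column).
#' @param members species to rank; defaults to all species with a
#'   non-NA distance in every ortholog.
#' @param distance which distance to rank on, `"clade"` or `"order"`.
#' @return a [PlaceTable-class].
#' @export
placeTable <- function(records, members = NULL,
                       distance = c("clade", "order")) {
  distance <- match.arg(distance)
  col <- paste0(distance, "_dist")
  recs <- records[!is.na(records[[col]]), c("ortholog", "species", col)]
  if (is.null(members)) members <- sort(unique(recs$species))
  recs <- recs[recs$species %in% members, ]
  members <- sort(members)
  k <- length(members)
  ids <- unique(recs$ortholog)
  d <- matrix(NA_real_, length(ids), k, dimnames = list(ids, members))
  d[cbind(match(recs$ortholog, ids), match(recs$species, members))] <-
    recs[[col]]
  if (anyNA(d))
    stop("need one ", col, " per (ortholog, member); missing entries found")
  places <- matrix(0L, length(ids), k, dimnames = dimnames(d))
  tied <- logical(length(ids))
  for (i in seq_len(nrow(d))) {
    ord <- order(-d[i, ], members)   # descending; ties by species name
    places[i, ord] <- seq_len(k)
    tied[i] <- anyDuplicated(d[i, ]) > 0L
  }
  counts <- vapply(seq_len(k), function(p)
    as.integer(colSums(places == p)), integer(k))
  dimnames(counts) <- list(members, paste0("place", seq_len(k)))
  new("PlaceTable", places = places, counts = counts,
      tied = ids[tied])
}

#' Expected place count under the equal-probability null
#'
#' Under the null that each of `k` species is equally likely to carry
#' the longest branch of an ortholog, the expected count of 1st places
#' (or any fixed place) per species is `n / k`.
#'
#' @param nOrthologs number of orthologous groups.
#' @param kSpecies number of competing species.
#' @return list with the exact `expected` value and its nearest-integer
#'   `rounded` rendering.
#' @examples
#' expectedPlaceCount(1311, 4)  # 327.75, rendered 328
#' @export
expectedPlaceCount <- function(nOrthologs, kSpecies) {
  stopifnot(nOrthologs >= 1)
  if (!is.numeric(kSpecies) || kSpecies < 2)
    stop("kSpecies must be at least 2")
  e <- nOrthologs / kSpecies
  list(expected = e, rounded = as.integer(roundHalfAway(e)))
}

#' Normalize species-to-clade branch lengths by the basal distance
#'
#' Divides each clade member's `clade_dist` by the ortholog's
#' `base_dist` (clade ancestor to deeper ancestor), correcting for the
#' protein's background rate of evolution. Orthologs with a zero basal
#' distance are excluded with a warning rather than producing
#' infinities; their ids are attached as `attr(, "excluded")`.
#'
#' @param records distance records from [rootToAnchorDistances()].
#' @return the clade-member records with a `normalized_length` column.
#' @export
normalizeBranch <- function(records) {
  recs <- records[!is.na(records$clade_dist), ]
  bad <- unique(recs$ortholog[recs$base_dist == 0])
  if (length(bad)) {
    warning(length(bad), " ortholog(s) with base_dist = 0 excluded: ",
            paste(head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ...")
    recs <- recs[!recs$ortholog %in% bad, ]
  }
  recs$normalized_length <- recs$clade_dist / recs$base_dist
  attr(recs, "excluded") <- bad
  recs
}

#' Rank values 1..N
#'
#' Deterministic dense ranking: with `direction = "increasing"` (the
#' default) rank 1 is the smallest value and rank N the largest, so for
#' branch lengths a larger rank means a longer branch. Ties are broken
#' by input order (ortholog-id order), making the result a permutation
#' of 1..N.
#'
#' @param values numeric vector (finite).
#' @param direction `"increasing"` (rank 1 = smallest) or
#'   `"decreasing"`.
#' @return integer vector, a permutation of `seq_along(values)`.
#' @export
assignRanks <- function(values, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!length(values)) stop("need at least one value")
  if (any(!is.finite(values))) stop("non-finite values cannot be ranked")
  key <- if (direction == "increasing") values else -values
  r <- integer(length(values))
  r[order(key, seq_along(values))] <- seq_along(values)
  r
}

#' Rank-discrepancy score
#'
#' `score = comparisonRank - baseRank`. With rank 1 = shortest branch, a
#' protein with a low base rank (short basal branch) but a high
#' comparison rank (long within-genome branch) gets a large positive
#' score, marking evolution faster than its baseline predicts; e.g.
#' base rank 10 and median within-clade rank 1000 score +990.
#' Half-integer comparison ranks (even-count medians) are rounded half
#' away from zero after differencing.
#'
#' @param baseRank,comparisonRank ranks in 1..`nProteins`.
#' @param nProteins optional total count for range validation.
#' @return integer score in `[-(N-1), N-1]`.
#' @examples
#' rankChangeScore(10, 1000)  # +990
#' @export
rankChangeScore <- function(baseRank, comparisonRank, nProteins = NULL) {
  if (any(baseRank < 1) || any(comparisonRank < 1))
    stop("ranks must be >= 1")
  if (!is.null(nProteins) &&
      (any(baseRank > nProteins) || any(comparisonRank > nProteins)))
    stop("rank exceeds nProteins")
  as.integer(roundHalfAway(comparisonRank - baseRank))
}

#' Median rank across species
#'
#' Standard median; an even count yields the mean of the two middle
#' ranks (possibly half-integer).
#'
#' @param ranks numeric vector of ranks, length >= 1.
#' @return the median rank.
#' @export
medianRank <- function(ranks) {
  if (!length(ranks)) stop("need at least one rank")
  median(ranks)
}

#' Binned selection of fast and slow proteins
#'
#' Proteins are grouped into consecutive bins of `binSize` by base rank
#' (the final bin holds the remainder). Within each bin the
#' `fraction` of proteins with the most positive rank-discrepancy
#' scores is selected as "fast" and the most negative as "slow"; the
#' per-bin selection count is `round(fraction * occupancy)` with a
#' floor of 1, so small remainder bins still contribute. Bins whose
#' selection boundary falls inside a run of tied scores are flagged
#' (ties broken by protein id).
#'
#' @param scores named rank-discrepancy scores (names = protein ids).
#' @param baseRanks base ranks aligned with `scores`.
#' @param binSize proteins per bin (default 100).
#' @param fraction selected fraction per tail (default 0.10).
#' @return list with `fast` and `slow` id vectors, a per-bin summary
#'   data.frame `bins`, and `tiedBins` flags.
#' @export
binAndSelect <- function(scores, baseRanks, binSize = 100, fraction = 0.10) {
  stopifnot(binSize >= 1, fraction > 0, fraction <= 0.5)
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be named by protein id")
  ord <- order(baseRanks)
  ids <- ids[ord]; sc <- scores[ord]
  n <- length(sc)
  bin <- ((seq_len(n) - 1L) %/% binSize) + 1L
  fast <- slow <- character()
  tiedBins <- logical(max(bin))
  binRows <- vector("list", max(bin))
  for (b in seq_len(max(bin))) {
    idx <- which(bin == b)
    occ <- length(idx)
    nsel <- max(1L, as.integer(roundHalfAway(fraction * occ)))
    o <- order(-sc[idx], ids[idx])
    oS <- order(sc[idx], ids[idx])
    f <- idx[o][seq_len(nsel)]
    s <- idx[oS][seq_len(nsel)]
    cutF <- min(sc[f]); cutS <- max(sc[s])
    outF <- setdiff(idx, f); outS <- setdiff(idx, s)
    tiedBins[b] <- (length(outF) && any(sc[outF] == cutF)) ||
      (length(outS) && any(sc[outS] == cutS))
    fast <- c(fast, ids[f]); slow <- c(slow, ids[s])
    binRows[[b]] <- data.frame(bin = b, occupancy = occ, selected = nsel)
  }
  list(fast = fast, slow = slow, bins = do.call(rbind, binRows),
       tiedBins = tiedBins)
}

#' Three-set overlap partition
#'
#' Counts the seven disjoint Venn regions of three id sets.
#'
#' @param setA,setB,setC character vectors of ids.
#' @return named integer vector over regions `A`, `B`, `C`, `AB`, `AC`,
#'   `BC`, `ABC` (exclusive regions; they sum to the union size).
#' @export
overlapPartition <- function(setA, setB, setC) {
  u <- unique(c(setA, setB, setC))
  inA <- u %in% setA; inB <- u %in% setB; inC <- u %in% setC
  c(A   = sum(inA & !inB & !inC),
    B   = sum(!inA & inB & !inC),
    C   = sum(!inA & !inB & inC),
    AB  = sum(inA & inB & !inC),
    AC  = sum(inA & !inB & inC),
    BC  = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC))
}
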