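#' @include kmer-index.R
NULL

#' Map one read pair by exact 21-mer seeds and a fragment-distance rule
#'
#' Re-implementation of the in-house paired-read placement algorithm used
#' for the transcriptome analysis of the element: the first `k` bases of
#' each mate are looked up in the index at 100% identity on both strands;
#' candidate placements require the two seeds on opposite strands facing
#' inward (the forward-strand mate's 5' end at or left of the
#' reverse-strand mate's 5' end); the end-to-end distance of a placement
#' is `rightmost covered base - leftmost covered base + 1`; placements
#' with distance outside `[minDist, maxDist]` (default 20-2000 bp,
#' inclusive) are discarded and the minimum-distance survivor is chosen.
#'
#' Statuses: `mapped` (unique minimum), `ambiguous` (two or more
#' survivors tie at the minimum distance; excluded from counting),
#' `distance_violation` (orientation-valid placements exist but none is
#' in range), `unmapped` (a seed has no exact hit, or no opposite-strand
#' inward-facing pairing of the hits exists).
#'
#' @param index a [KmerIndex] built with the same `k`.
#' @param seq1,seq2 the two mate sequences (character or DNAString); both
#'   must be at least `k` long.
#' @param minDist,maxDist inclusive end-to-end distance window
#'   (defaults 20 and 2000 bp).
#' @return one-row data.frame: `status`, `span_start`, `span_end`,
#'   `distance` (NA unless mapped), `n_candidates` (count of
#'   distance-valid placements).
#' @details The rule set is deliberately minimal: two initial 21-mers per
#'   pair, exact identity, end-to-end distance 20-2000 bp, shortest
#'   distance on multiple placements, and the spanned range counted as one
#'   transcript fragment downstream (see [countSpans()]).
#' @export
mapPair <- function(index, seq1, seq2, minDist = 20, maxDist = 2000) {
  stopifnot(is(index, "KmerIndex"))
  k <- index@k
  seq1 <- asSeqChar(seq1); seq2 <- asSeqChar(seq2)
  if (nchar(seq1) < k) stop("read 1 is shorter than the seed length k = ", k)
  if (nchar(seq2) < k) stop("read 2 is shorter than the seed length k = ", k)
  res <- .mapPairCore(index, seq1, seq2, minDist, maxDist)
  data.frame(status = res$status, span_start = res$span_start,
             span_end = res$span_end, distance = res$distance,
             n_candidates = res$n_candidates, stringsAsFactors = FALSE)
}

## core placement logic shared by mapPair()/mapPairs(); returns a list
.mapPairCore <- function(index, seq1, seq2, minDist, maxDist) {
  k <- index@k
  len1 <- nchar(seq1); len2 <- nchar(seq2)
  h1 <- .seedHits(index, substr(seq1, 1L, k))
  h2 <- .seedHits(index, substr(seq2, 1L, k))
  if ((!length(h1$fwd) && !length(h1$rev)) ||
      (!length(h2$fwd) && !length(h2$rev)))
    return(list(status = "unmapped", span_start = NA_integer_,
                span_end = NA_integer_, distance = NA_integer_,
                n_candidates = 0L))

  ## orientation A: read1 forward, read2 reverse; orientation B: swapped.
  ## A forward mate seeded at p covers [p, p + len - 1]; a reverse mate
  ## whose seed reverse-complement starts at q has its 5' end at q + k - 1
  ## and covers [q + k - len, q + k - 1].
  a <- .orientCandidates(h1$fwd, len1, h2$rev, len2, k)
  b <- .orientCandidates(h2$fwd, len2, h1$rev, len1, k)
  left <- c(a$left, b$left); right <- c(a$right, b$right)
  if (!length(left))
    return(list(status = "unmapped", span_start = NA_integer_,
                span_end = NA_integer_, distance = NA_integer_,
                n_candidates = 0L))
  dist <- right - left + 1L
  ok <- dist >= minDist & dist <= maxDist
  n_valid <- sum(ok)
  if (n_valid == 0L)
    return(list(status = "distance_violation", span_start = NA_integer_,
                span_end = NA_integer_, distance = NA_integer_,
                n_candidates = 0L))
  left <- left[ok]; right <- right[ok]; dist <- dist[ok]
  dmin <- min(dist)
  best <- which(dist == dmin)
  if (length(best) > 1L)
    return(list(status = "ambiguous", span_start = NA_integer_,
                span_end = NA_integer_, distance = NA_integer_,
                n_candidates = n_valid))
  b <- best[1L]
  list(status = "mapped", span_start = left[b], span_end = right[b],
       distance = dmin, n_candidates = n_valid)
}

## forward/reverse hit positions of one seed (no data.frame overhead)
.seedHits <- function(index, kmer) {
  if (grepl("N", kmer, fixed = TRUE)) return(list(fwd = NULL, rev = NULL))
  rc <- revComp(kmer)
  list(fwd = index@lookup[[kmer]],
       rev = if (identical(rc, kmer)) NULL else index@lookup[[rc]])
}

## all inward-facing placements of a forward mate (starts fp, length lf)
## against a reverse mate (revcomp-seed starts rp, length lr)
.orientCandidates <- function(fp, lf, rp, lr, k) {
  if (!length(fp) || !length(rp)) return(NULL)
  p <- rep(fp, times = length(rp))
  q <- rep(rp, each = length(fp))
  rev5 <- q + k - 1L                 # 5' end of the reverse mate
  keep <- p <= rev5                  # facing inward
  if (!any(keep)) return(NULL)
  p <- p[keep]; q <- q[keep]; rev5 <- rev5[keep]
  list(left = pmin(p, q + k - lr),
       right = pmax(p + lf - 1L, rev5))
}

#' Map many read pairs
#'
#' Vector interface over [mapPair()].
#'
#' @param index a [KmerIndex].
#' @param reads a [SimulatedReads] object, or `seq1`/`seq2` character
#'   vectors of equal length.
#' @param seq2,ids mates and pair identifiers when `reads` is a character
#'   vector.
#' @param minDist,maxDist distance window passed to the placement rule.
#' @return data.frame with one row per pair: `pair_id`, `status`,
#'   `span_start`, `span_end`, `distance`, `n_candidates`.
#' @export
mapPairs <- function(index, reads, seq2 = NULL, ids = NULL,
                     minDist = 20, maxDist = 2000) {
  if (is(reads, "SimulatedReads")) {
    seq1 <- as.character(mateReads(reads, 1))
    seq2 <- as.character(mateReads(reads, 2))
    ids <- truthTable(reads)$pair_id
  } else {
    seq1 <- as.character(reads)
    seq2 <- as.character(seq2)
  }
  n <- length(seq1)
  stopifnot(length(seq2) == n)
  if (is.null(ids)) ids <- sprintf("pair%06d", seq_len(n))
  status <- character(n)
  s0 <- e0 <- d0 <- rep(NA_integer_, n)
  ncand <- integer(n)
  k <- index@k
  for (i in seq_len(n)) {
    if (nchar(seq1[i]) < k || nchar(seq2[i]) < k)
      stop("pair '", ids[i], "': read shorter than the seed length k = ", k)
    r <- .mapPairCore(index, seq1[i], seq2[i], minDist, maxDist)
    status[i] <- r$status
    s0[i] <- r$span_start; e0[i] <- r$span_end; d0[i] <- r$distance
    ncand[i] <- r$n_candidates
  }
  data.frame(pair_id = ids, status = status, span_start = s0, span_end = e0,
             distance = d0, n_candidates = ncand, stringsAsFactors = FALSE)
}

#' Count transcript-spanning fragments per gene feature
#'
#' Each mapped pair's genomic span is counted as one transcript fragment:
#' it increments the count of every gene feature it overlaps by at least
#' one base (a span across two adjacent genes increments both).
#' Ambiguous, unmapped and distance-violating pairs contribute nothing.
#'
#' @param results data.frame from [mapPairs()].
#' @param features a [GenomeRecord], [GenomicRanges::GRanges] or feature
#'   data.frame; rows of kind `gene` are counted (all rows if no `kind`).
#' @param reference optional reference feature name (e.g. `rrn`); when
#'   given, a `normalized` column (count / reference count) is added.
#' @return data.frame `feature`, `count` (and `normalized`), with the
#'   reference name attached as attribute `reference`.
#' @export
countSpans <- function(results, features, reference = NULL) {
  ft <- .asFeatureDf(features)
  if ("kind" %in% names(ft) && any(ft$kind == "gene"))
    ft <- ft[ft$kind == "gene", , drop = FALSE]
  mapped <- results[results$status == "mapped", , drop = FALSE]
  counts <- integer(nrow(ft))
  if (nrow(mapped)) {
    spans <- IRanges::IRanges(start = mapped$span_start, end = mapped$span_end)
    genes <- IRanges::IRanges(start = ft$start, end = ft$end)
    counts <- IRanges::countOverlaps(genes, spans, minoverlap = 1L)
  }
  out <- data.frame(feature = ft$name, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    refc <- out$count[out$feature == reference]
    if (!length(refc)) stop("reference feature '", reference, "' not found")
    if (refc[1L] <= 0L) stop("reference feature '", reference, "' has zero count")
    out$normalized <- out$count / refc[1L]
    attr(out, "reference") <- reference
  }
  out
}

.asFeatureDf <- function(features) {
  if (is(features, "GenomeRecord")) return(featureTable(features))
  if (is(features, "GRanges")) {
    return(data.frame(name = as.character(mcols(features)$name),
                      start = BiocGenerics::start(features),
                      end = BiocGenerics::end(features),
                      kind = if (!is.null(mcols(features)$kind))
                        as.character(mcols(features)$kind) else "gene",
                      stringsAsFactors = FALSE))
  }
  as.data.frame(features, stringsAsFactors = FALSE)
}

#' Reference-normalized fold change between two count tables
#'
#' Expression levels are first normalized to a reference gene (the rRNA
#' gene `rrn` in the study design), then compared between conditions:
#' `fold(g) = (count_b(g) / count_b(ref)) / (count_a(g) / count_a(ref))`.
#' Genes counted in `b` but absent from `a` get `fold = Inf` and are
#' flagged in the `infinite` column; genes absent from both get `NA`.
#'
#' @param tableA,tableB count tables from [countSpans()] (condition A =
#'   baseline, condition B = comparison).
#' @param reference reference feature name; its count must be positive in
#'   both tables.
#' @return data.frame `feature`, `fold`, `infinite`.
#' @export
foldChange <- function(tableA, tableB, reference) {
  refA <- tableA$count[tableA$feature == reference]
  refB <- tableB$count[tableB$feature == reference]
  if (!length(refA) || !length(refB))
    stop("reference feature '", reference, "' missing from a count table")
  if (refA[1L] <= 0L || refB[1L] <= 0L)
    stop("reference feature '", reference, "' has zero count in a table")
  feats <- intersect(tableA$feature, tableB$feature)
  a <- tableA$count[match(feats, tableA$feature)] / refA[1L]
  b <- tableB$count[match(feats, tableB$feature)] / refB[1L]
  fold <- ifelse(a == 0 & b == 0, NA_real_,
                 ifelse(a == 0, Inf, b / a))
  data.frame(feature = feats, fold = fold,
             infinite = is.infinite(fold) & !is.na(fold),
             stringsAsFactors = FALSE)
}
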