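## Independent oracles used to cross-check the package implementations.
## These deliberately take different routes: Biostrings::matchPattern for
## exact seed hits, literal nested loops for the sliding-window scans.

oracleSeedHits <- function(genomeStr, seed) {
  if (grepl("N", seed, fixed = TRUE))
    return(list(fwd = integer(), rev = integer()))
  subj <- Biostrings::DNAString(genomeStr)
  pat <- Biostrings::DNAString(seed)
  list(fwd = BiocGenerics::start(Biostrings::matchPattern(pat, subj)),
       rev = BiocGenerics::start(Biostrings::matchPattern(
         Biostrings::reverseComplement(pat), subj)))
}

## brute-force paired placement under the published rule: exact seeds on
## opposite strands facing inward, end-to-end distance within [minDist,
## maxDist], shortest distance wins, ties are ambiguous
oracleMapPair <- function(genomeStr, s1, s2, k = 21,
                          minDist = 20, maxDist = 2000) {
  h1 <- oracleSeedHits(genomeStr, substr(s1, 1, k))
  h2 <- oracleSeedHits(genomeStr, substr(s2, 1, k))
  none <- list(status = "unmapped", span_start = NA_integer_,
               span_end = NA_integer_, distance = NA_integer_,
               n_candidates = 0L)
  if ((length(h1$fwd) + length(h1$rev)) == 0 ||
      (length(h2$fwd) + length(h2$rev)) == 0) return(none)
  cand <- matrix(numeric(), ncol = 3)
  collect <- function(fp, lf, rp, lr) {
    for (p in fp) for (q in rp) {
      rev5 <- q + k - 1
      if (p <= rev5) {
        left <- min(p, q + k - lr)
        right <- max(p + lf - 1, rev5)
        cand <<- rbind(cand, c(left, right, right - left + 1))
      }
    }
  }
  collect(h1$fwd, nchar(s1), h2$rev, nchar(s2))
  collect(h2$fwd, nchar(s2), h1$rev, nchar(s1))
  if (!nrow(cand)) return(none)
  ok <- cand[, 3] >= minDist & cand[, 3] <= maxDist
  if (!any(ok))
    return(list(status = "distance_violation", span_start = NA_integer_,
                span_end = NA_integer_, distance = NA_integer_,
                n_candidates = 0L))
  cand <- cand[ok, , drop = FALSE]
  dmin <- min(cand[, 3])
  hitmin <- which(cand[, 3] == dmin)
  if (length(hitmin) > 1)
    return(list(status = "ambiguous", span_start = NA_integer_,
                span_end = NA_integer_, distance = NA_integer_,
                n_candidates = nrow(cand)))
  list(status = "mapped", span_start = as.integer(cand[hitmin, 1]),
       span_end = as.integer(cand[hitmin, 2]),
       distance = as.integer(dmin), n_candidates = nrow(cand))
}

revCompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## naive sliding-window Hamming scan for a consensus, both strands
naiveHalfSites <- function(seq, cons, maxMm) {
  out <- NULL
  w <- nchar(cons)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") cons else revCompStr(cons)
    for (i in seq_len(nchar(seq) - w + 1)) {
      sub <- substr(seq, i, i + w - 1)
      mm <- sum(strsplit(pat, "")[[1]] != strsplit(sub, "")[[1]])
      if (mm <= maxMm)
        out <- rbind(out, data.frame(start = i, end = i + w - 1L,
                                     strand = strand, mismatches = mm))
    }
  }
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character(),
                                      mismatches = integer()))
  out[order(out$start, out$strand), ]
}

## naive all-offsets similarity scan (substitutions only, both strands)
naiveSimilarity <- function(query, subject, window, maxMm) {
  out <- NULL
  for (i in seq_len(nchar(query) - window + 1)) {
    qw <- substr(query, i, i + window - 1)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") qw else revCompStr(qw)
      for (j in seq_len(nchar(subject) - window + 1)) {
        sw <- substr(subject, j, j + window - 1)
        mm <- sum(strsplit(pat, "")[[1]] != strsplit(sw, "")[[1]])
        if (mm <= maxMm)
          out <- rbind(out, data.frame(q_offset = i, s_offset = j,
                                       strand = strand, mismatches = mm))
      }
    }
  }
  if (is.null(out)) return(data.frame(q_offset = integer(),
                                      s_offset = integer(),
                                      strand = character(),
                                      mismatches = integer()))
  out[order(out$mismatches, out$s_offset, out$q_offset), ]
}

## exhaustive inverted-repeat scan re-deriving the same definition with
## vectorized mismatch profiles instead of greedy extension
naiveIRScan <- function(seq, minArm, maxLoop, maxMm) {
  ch <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")[ch]
  L <- length(ch)
  rows <- NULL
  for (i in 1:(L - 1)) {
    for (j in (i + 1):min(L, i + 1 + maxLoop)) {
      amax <- min(i, L - j + 1)
      if (amax < 1) next
      mmProfile <- cumsum(ch[i - seq_len(amax) + 1] != comp[j + seq_len(amax) - 1] |
                            is.na(comp[j + seq_len(amax) - 1]))
      within <- which(mmProfile <= maxMm)
      if (!length(within)) next
      a <- max(within)
      ## trim outermost mismatched pairs
      isMm <- c(mmProfile[1], diff(mmProfile)) > 0
      while (a > 0 && isMm[a]) a <- a - 1
      if (a >= minArm)
        rows <- rbind(rows, data.frame(left_start = i - a + 1, left_end = i,
                                       right_start = j, right_end = j + a - 1,
                                       arm_len = a, loop_len = j - i - 1,
                                       mismatches = mmProfile[a]))
    }
  }
  if (is.null(rows)) return(NULL)
  rows <- unique(rows)
  ## containment suppression mirroring the documented rule
  keep <- rep(TRUE, nrow(rows))
  for (a in seq_len(nrow(rows))) for (b in seq_len(nrow(rows))) {
    if (a == b) next
    if (rows$left_start[a] >= rows$left_start[b] &&
        rows$left_end[a] <= rows$left_end[b] &&
        rows$right_start[a] >= rows$right_start[b] &&
        rows$right_end[a] <= rows$right_end[b] &&
        rows$arm_len[a] < rows$arm_len[b] &&
        rows$mismatches[b] <= rows$mismatches[a]) keep[a] <- FALSE
  }
  out <- rows[keep, ]
  rownames(out) <- NULL
  out
}

randomDNAStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
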