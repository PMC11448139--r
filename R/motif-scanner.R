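#' @include utils.R
NULL

#' Published TraR-binding-site sequences
#'
#' The five putative binding sites of the LysR-family regulator TraR:
#' two full TN11A sites in interrupted inverted repeats (upstream of the
#' excisionase gene and of a hypothetical-protein gene) and three
#' half-sites (upstream of the coupling-protein gene `traG`, inside the
#' conserved oriT core, and upstream of `traR` itself).
#'
#' @return named character vector: `BSxis`, `BS15836`, `BStraG`,
#'   `BSoriT`, `BStraR`.
#' @examples
#' findTN11A(traRBindingSites()[["BSxis"]], armLen = 6)
#' @export
traRBindingSites <- function() {
  c(BSxis   = "CGTTTTGATGGAGACGCAAAACG",
    BS15836 = "TTTATTGAATCATTGGCAAAACG",
    BStraG  = "CAAAACG",
    BSoriT  = "CAAAAGG",
    BStraR  = "CAAAA")
}

#' Scan for TN11A LysR-binding motifs in interrupted inverted repeats
#'
#' The LysR-family binding consensus is a conserved T and a conserved A
#' separated by 11 bp (`T-N11-A`), embedded in an inverted repeat whose
#' arms include the T and A as their innermost bases.  A hit is every
#' position pair `(i, i + 12)` with `seq[i] == T`, `seq[i+12] == A`,
#' where the `armLen` bases ending at the T and the `armLen` bases
#' starting at the A are reverse complements with at most
#' `maxArmMismatch` mismatches.
#'
#' Because the arms are an inverted repeat, the reverse complement of a
#' TN11A site is again a TN11A site; a minus-strand scan therefore
#' reports the mirror of the plus-strand hits.  `bothStrands = FALSE`
#' (default) scans the given strand only.  For minus-strand hits, `t_pos`
#' and `a_pos` are the forward-strand coordinates of the bases read as T
#' and A on the minus strand (so `t_pos > a_pos`); the spacer is always
#' `|a_pos - t_pos| - 1 = 11`.
#'
#' @param seq DNA sequence (character or DNAString).
#' @param armLen inverted-repeat arm length, including the conserved
#'   T/A (default 5).
#' @param maxArmMismatch maximum arm mismatches (default 1; the motif is
#'   "interrupted", so perfect arms are not required).
#' @param bothStrands also scan the reverse complement (default FALSE).
#' @param seqId label recorded in the output (default "seq").
#' @return data.frame: `seq_id`, `t_pos`, `a_pos`, `spacer_len`,
#'   `arm_len`, `arm_mismatches`, `strand`, `site_seq` (plus-strand
#'   sequence from the leftmost to the rightmost arm base).
#' @export
findTN11A <- function(seq, armLen = 5, maxArmMismatch = 1,
                      bothStrands = FALSE, seqId = "seq") {
  armLen <- as.integer(armLen)
  if (armLen < 1L) stop("armLen must be >= 1")
  s <- asSeqChar(seq)
  hits <- .tn11aForward(s, armLen, maxArmMismatch, "+", seqId)
  if (bothStrands) {
    L <- nchar(s)
    rc <- .tn11aForward(revComp(s), armLen, maxArmMismatch, "-", seqId)
    if (nrow(rc)) {
      tp <- L - rc$t_pos + 1L
      ap <- L - rc$a_pos + 1L
      rc$t_pos <- tp; rc$a_pos <- ap
      rc$site_seq <- vapply(rc$site_seq, revComp, character(1L), USE.NAMES = FALSE)
      hits <- rbind(hits, rc)
    }
  }
  hits[order(pmin(hits$t_pos, hits$a_pos)), , drop = FALSE]
}

.tn11aForward <- function(s, armLen, maxMm, strand, seqId) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  empty <- data.frame(seq_id = character(), t_pos = integer(),
                      a_pos = integer(), spacer_len = integer(),
                      arm_len = integer(), arm_mismatches = integer(),
                      strand = character(), site_seq = character(),
                      stringsAsFactors = FALSE)
  lo <- armLen; hi <- L - 12L - armLen + 1L
  if (hi < lo) return(empty)
  cand <- which(ch == "T")
  cand <- cand[cand >= lo & cand <= hi & ch[pmin(cand + 12L, L)] == "A"]
  if (!length(cand)) return(empty)
  rows <- lapply(cand, function(i) {
    left <- ch[(i - armLen + 1L):i]
    right <- ch[(i + 12L):(i + 12L + armLen - 1L)]
    rcRight <- rev(unname(.COMP[right]))
    mm <- sum(left != rcRight | is.na(rcRight))
    if (mm > maxMm) return(NULL)
    data.frame(seq_id = seqId, t_pos = i, a_pos = i + 12L, spacer_len = 11L,
               arm_len = armLen, arm_mismatches = mm, strand = strand,
               site_seq = paste(ch[(i - armLen + 1L):(i + 12L + armLen - 1L)],
                                collapse = ""),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Mismatch-tolerant similarity search between two sequences
#'
#' Slides every `window`-length subsequence of `query` along both strands
#' of `subject` and reports all Hamming alignments (substitutions only,
#' no indels) with at most `maxMismatch` mismatches.
#'
#' @param query,subject DNA sequences.
#' @param window alignment window length.
#' @param maxMismatch mismatch budget.
#' @return data.frame `q_offset`, `s_offset`, `strand`, `mismatches`
#'   (1-based offsets; `s_offset` is always the forward-strand start of
#'   the matched window), sorted by mismatches then position.
#' @export
similaritySearch <- function(query, subject, window, maxMismatch) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  q <- asSeqChar(query); s <- asSeqChar(subject)
  if (window > min(nchar(q), nchar(s)))
    stop("window exceeds the length of query or subject")
  subj <- Biostrings::DNAString(s)
  nq <- nchar(q) - window + 1L
  out <- list()
  for (i in seq_len(nq)) {
    pat <- substr(q, i, i + window - 1L)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else revComp(pat)
      m <- Biostrings::matchPattern(p, subj, max.mismatch = maxMismatch,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m)) {
        st <- BiocGenerics::start(m)
        mm <- vapply(st, function(j)
          hamming(p, substr(s, j, j + window - 1L)), numeric(1L))
        out[[length(out) + 1L]] <-
          data.frame(q_offset = i, s_offset = st, strand = strand,
                     mismatches = as.integer(mm), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(q_offset = integer(), s_offset = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$mismatches, res$s_offset, res$q_offset), , drop = FALSE]
}

#' Scan for half-sites of a dyad-symmetric binding consensus
#'
#' A half-site is one arm of a symmetric protein-binding site, potentially
#' bound by one monomer of a dimer.  Reports every occurrence of the
#' consensus on either strand within the mismatch budget, in
#' forward-strand coordinates.
#'
#' @param seq DNA sequence.
#' @param consensus half-site consensus (default `CAAAACG`, the strong
#'   half-site found upstream of the coupling-protein gene).
#' @param maxMismatch mismatch budget (default 1).
#' @param seqId label recorded in the output.
#' @return data.frame `seq_id`, `start`, `end`, `strand`,
#'   `consensus_used`, `mismatches`.
#' @export
findHalfSites <- function(seq, consensus = "CAAAACG", maxMismatch = 1,
                          seqId = "seq") {
  cons <- asSeqChar(consensus)
  if (!grepl("^[ACGT]+$", cons)) stop("consensus must be over A/C/G/T")
  s <- asSeqChar(seq)
  subj <- Biostrings::DNAString(s)
  w <- nchar(cons)
  out <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") cons else revComp(cons)
    m <- Biostrings::matchPattern(p, subj, max.mismatch = maxMismatch,
                                  with.indels = FALSE, fixed = TRUE)
    if (length(m)) {
      st <- BiocGenerics::start(m)
      mm <- vapply(st, function(j) hamming(p, substr(s, j, j + w - 1L)),
                   numeric(1L))
      out[[length(out) + 1L]] <-
        data.frame(seq_id = seqId, start = st, end = st + w - 1L,
                   strand = strand, consensus_used = cons,
                   mismatches = as.integer(mm), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      consensus_used = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}
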