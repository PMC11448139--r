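#' @include utils.R
NULL

## Sigma-70 positional base frequencies (percent) at the -35 and -10
## hexamers, assembled from the classic E. coli promoter compilations
## (consensus TTGACA / TATAAT).  Used as a homology weight table:
## w(pos, base) = ln(f / 25), so the consensus hexamers maximize the
## score and each substitution strictly lowers it.
.SIGMA70_FREQ <- list(
  minus35 = matrix(c(
    ##  A   C   G   T      (columns = hexamer positions 1..6)
    10, 9, 13, 56, 21, 54,
    10, 6, 13, 17, 54, 13,
    11, 6, 61, 13, 9, 16,
    69, 79, 13, 14, 16, 17), nrow = 4L, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), NULL)),
  minus10 = matrix(c(
    8, 76, 15, 61, 56, 6,
    8, 8, 13, 13, 14, 6,
    7, 8, 12, 14, 13, 6,
    77, 8, 60, 12, 17, 82), nrow = 4L, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), NULL)))

## score penalty per bp of spacer deviation from the optimal 17 bp
.SPACER_PENALTY <- 0.35

#' The packaged sigma-70 promoter weight table
#'
#' Positional base frequencies (percent) of the -35 and -10 hexamers used
#' by [predictPromoters()], with consensus `TTGACA` / `TATAAT`.
#'
#' @return list with matrices `minus35` and `minus10` (4 bases x 6
#'   positions) and the `spacerPenalty` per bp of deviation from 17.
#' @export
sigma70WeightTable <- function() {
  c(.SIGMA70_FREQ, list(spacerPenalty = .SPACER_PENALTY))
}

.hexamerScore <- function(hex, mat) {
  ri <- match(strsplit(hex, "", fixed = TRUE)[[1L]], rownames(mat))
  if (anyNA(ri)) return(NA_real_)
  sum(log(mat[cbind(ri, 1:6)] / 25))
}

#' Predict sigma-70 promoters by hexamer homology scoring
#'
#' Scores every pairing of a -35 hexamer and a -10 hexamer separated by a
#' 15-21 bp spacer.  The score is the percent of the consensus score:
#' positional log-odds `ln(f/25)` summed over the 12 hexamer bases, minus
#' a spacer-length penalty (`0.35` per bp of deviation from 17), linearly
#' rescaled so the consensus `TTGACA - 17 bp - TATAAT` arrangement scores
#' 100 and the worst possible arrangement 0.  Forward strand only; scan
#' the reverse complement for the other strand.
#'
#' @param seq DNA sequence (at least 27 bp: 6 + 15 + 6).
#' @param minScore report only calls scoring at least this (default 60).
#' @param seqId label recorded in the output.
#' @return data.frame sorted by decreasing score: `seq_id`,
#'   `minus35_start`, `minus35_seq`, `minus10_start`, `minus10_seq`,
#'   `spacer_len` (always within 15-21), `score`.  Hexamers containing N
#'   are skipped.
#' @export
predictPromoters <- function(seq, minScore = 60, seqId = "seq") {
  s <- asSeqChar(seq)
  L <- nchar(s)
  empty <- data.frame(seq_id = character(), minus35_start = integer(),
                      minus35_seq = character(), minus10_start = integer(),
                      minus10_seq = character(), spacer_len = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (L < 27L) return(empty)
  ## precompute hexamer scores at every position
  n <- L - 5L
  hex <- substring(s, seq_len(n), seq_len(n) + 5L)
  s35 <- vapply(hex, .hexamerScore, numeric(1L),
                mat = .SIGMA70_FREQ$minus35, USE.NAMES = FALSE)
  s10 <- vapply(hex, .hexamerScore, numeric(1L),
                mat = .SIGMA70_FREQ$minus10, USE.NAMES = FALSE)
  smax <- .hexamerScore("TTGACA", .SIGMA70_FREQ$minus35) +
    .hexamerScore("TATAAT", .SIGMA70_FREQ$minus10)
  smin <- sum(log(apply(.SIGMA70_FREQ$minus35, 2L, min) / 25)) +
    sum(log(apply(.SIGMA70_FREQ$minus10, 2L, min) / 25)) -
    .SPACER_PENALTY * 4
  out <- list()
  for (spacer in 15:21) {
    i35 <- seq_len(max(0L, n - spacer - 6L))
    if (!length(i35)) next
    i10 <- i35 + 6L + spacer
    raw <- s35[i35] + s10[i10] - .SPACER_PENALTY * abs(spacer - 17L)
    score <- 100 * (raw - smin) / (smax - smin)
    keep <- which(!is.na(score) & score >= minScore)
    if (length(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seqId, minus35_start = i35[keep], minus35_seq = hex[i35[keep]],
        minus10_start = i10[keep], minus10_seq = hex[i10[keep]],
        spacer_len = spacer, score = score[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$score, res$minus35_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pair binding sites with their nearest downstream promoter
#'
#' LysR-type activation sites sit at the immediate upstream edge of the
#' -35 box they regulate.  Each site is paired with the nearest promoter
#' whose -35 box starts downstream of the site end, and flagged
#' `immediately_upstream` when the gap between the site end and the -35
#' start is at most `maxGap` bases.
#'
#' @param sites data.frame of motif or half-site hits; the site end is
#'   taken from an `end` column if present, else from
#'   `pmax(t_pos, a_pos) + arm_len - 1` for TN11A hits.
#' @param promoters data.frame from [predictPromoters()].
#' @param maxGap threshold for the immediately-upstream flag (default 5).
#' @return `sites` with added columns `promoter_minus35_start`, `gap`,
#'   `immediately_upstream` (NA where no downstream promoter exists).
#' @export
sitePromoterArchitecture <- function(sites, promoters, maxGap = 5) {
  if (!nrow(sites)) return(sites)
  siteEnd <- as.integer(if ("end" %in% names(sites)) sites$end
                        else pmax(sites$t_pos, sites$a_pos) + sites$arm_len - 1L)
  p35 <- as.integer(sort(promoters$minus35_start))
  near <- vapply(siteEnd, function(e) {
    d <- p35[p35 > e]
    if (!length(d)) NA_integer_ else d[1L]
  }, integer(1L))
  sites$promoter_minus35_start <- near
  sites$gap <- near - siteEnd - 1L
  sites$immediately_upstream <- !is.na(sites$gap) & sites$gap <= maxGap
  sites
}
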