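#' @include AllClasses.R GenomeRecord.R
NULL

#' Build an exact-match k-mer index of a genome
#'
#' Enumerates every k-mer of the forward strand and stores its 1-based
#' start positions in a hash.  Reverse-strand hits are recovered at query
#' time by looking up the reverse complement of the query, so both strands
#' are queryable while positions stay in forward coordinates.  K-mers
#' containing N are never stored.
#'
#' @param genome a [GenomeRecord] or a character/DNAString sequence.
#' @param k seed length (default 21).
#' @return a [KmerIndex-class] object.
#' @examples
#' idx <- buildKmerIndex(strrep("ACGT", 10), k = 21)
#' queryKmer(idx, substr(strrep("ACGT", 10), 1, 21))
#' @export
buildKmerIndex <- function(genome, k = 21) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  id <- if (is(genome, "GenomeRecord")) recordId(genome) else "genome"
  s <- if (is(genome, "GenomeRecord")) asSeqChar(recordSeq(genome)) else asSeqChar(genome)
  L <- nchar(s)
  if (L < k) stop("genome (", L, " bp) is shorter than k = ", k)
  n <- L - k + 1L
  kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  lookup <- list2env(split(seq_len(n)[ok], kmers[ok]), hash = TRUE,
                     size = max(16L, sum(ok)))
  new("KmerIndex", k = k, genomeId = id, genomeLength = L, lookup = lookup)
}

#' Query a k-mer against an index
#'
#' @param index a [KmerIndex].
#' @param kmer character seed of length `k`.  Queries containing N return
#'   no hits.
#' @return data.frame with columns `pos` (1-based forward-strand start of
#'   the k-long match) and `strand` (`+` if the seed itself matches the
#'   forward strand, `-` if its reverse complement does).
#' @export
queryKmer <- function(index, kmer) {
  stopifnot(is(index, "KmerIndex"))
  kmer <- asSeqChar(kmer)
  if (nchar(kmer) != index@k)
    stop("query length ", nchar(kmer), " != k = ", index@k)
  if (grepl("N", kmer, fixed = TRUE))
    return(data.frame(pos = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  fwd <- index@lookup[[kmer]]
  rc <- revComp(kmer)
  rev <- if (identical(rc, kmer)) integer() else index@lookup[[rc]]
  data.frame(pos = c(fwd, rev),
             strand = c(rep("+", length(fwd)), rep("-", length(rev))),
             stringsAsFactors = FALSE)
}

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex over '", object@genomeId, "' (", object@genomeLength,
      " bp): k = ", object@k, ", ",
      length(ls(object@lookup)), " distinct k-mers\n", sep = "")
})
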