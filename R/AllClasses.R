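#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' GenomeRecord: a named DNA sequence with strand-aware interval features
#'
#' Central container of the package: one DNA sequence (a chromosome, an
#' excised circle, or a regulatory region) together with 1-based inclusive
#' interval features.  Feature kinds follow the biology of integrative and
#' conjugative elements: `gene`, `attL`, `attR`, `attP`, `attB`, `motif`,
#' `primer`, `REPT` and `oriT_core`.
#'
#' When both an `attL` and an `attR` feature are present they must have
#' identical sequence content -- they are the two copies of the direct
#' repeat flanking the integrated element.
#'
#' @slot id single character label.
#' @slot seq a [Biostrings::DNAString] over A/C/G/T/N.
#' @slot features a [GenomicRanges::GRanges] with metadata columns
#'   `name` and `kind`.
#' @slot circular logical flag; `TRUE` for excised (attP-bearing) circles,
#'   which are stored linearly with the junction repeat at position 1.
#'
#' @seealso [GenomeRecord()] for the user-facing constructor,
#'   [recordSeq()], [featureTable()].
#' @exportClass GenomeRecord
setClass("GenomeRecord",
         slots = c(id = "character",
                   seq = "DNAString",
                   features = "GRanges",
                   circular = "logical"))

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  L <- length(object@seq)
  fr <- object@features
  if (length(fr)) {
    if (is.null(fr$name) || is.null(fr$kind))
      msg <- c(msg, "features must carry 'name' and 'kind' metadata columns")
    s <- BiocGenerics::start(fr); e <- BiocGenerics::end(fr)
    if (any(s < 1L) || any(e > L) || any(s > e))
      msg <- c(msg, "feature coordinates must satisfy 1 <= start <= end <= length(seq)")
    ## the two copies of the boundary direct repeat must be identical
    if (!is.null(fr$kind) && all(c("attL", "attR") %in% fr$kind) &&
        all(s >= 1L) && all(e <= L)) {
      aL <- fr[fr$kind == "attL"][1L]
      aR <- fr[fr$kind == "attR"][1L]
      sL <- as.character(Biostrings::subseq(object@seq,
                                            BiocGenerics::start(aL),
                                            BiocGenerics::end(aL)))
      sR <- as.character(Biostrings::subseq(object@seq,
                                            BiocGenerics::start(aR),
                                            BiocGenerics::end(aR)))
      if (!identical(sL, sR))
        msg <- c(msg, "attL and attR features must have identical sequence content")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic-data generator
#'
#' Holds every tunable of the simulator in one validated object.  The
#' defaults describe the study system: a host chromosome carrying an
#' integrated element flanked by the 9-bp direct repeat `GATTTTAAG`, a
#' baseline excised fraction of 1e-5 (about one excised copy per 1e5
#' chromosomes), and a short-read paired library with a 300 +/- 50 bp
#' fragment-length distribution.
#'
#' @slot hostLength host chromosome length (bp).
#' @slot iceLength element payload length (bp), excluding the two repeat
#'   copies added at its boundaries.
#' @slot attRepeat the boundary direct repeat (DNA string).
#' @slot excisionFraction fraction of chromosomes in the excised state,
#'   in \[0, 1\].
#' @slot expressionWeights named non-negative numeric: per-feature
#'   sampling weights for read simulation.  Empty means uniform coverage.
#' @slot readLength read length (nt); must be >= 21 for the seed mapper.
#' @slot insertMean,insertSd fragment (end-to-end) length distribution (bp).
#' @slot nPairs number of read pairs to simulate.
#' @slot seed integer root seed; all child generators derive from it in a
#'   documented order, so identical configs give byte-identical output.
#' @slot errorRate per-base substitution error rate (default 0: the mapper
#'   demands 100% seed identity, so errors are off unless you are probing
#'   mapper loss).
#'
#' @exportClass SimConfig
setClass("SimConfig",
         slots = c(hostLength = "integer",
                   iceLength = "integer",
                   attRepeat = "character",
                   excisionFraction = "numeric",
                   expressionWeights = "numeric",
                   readLength = "integer",
                   insertMean = "numeric",
                   insertSd = "numeric",
                   nPairs = "integer",
                   seed = "integer",
                   errorRate = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@excisionFraction < 0 || object@excisionFraction > 1)
    msg <- c(msg, "excisionFraction must lie in [0, 1]")
  if (object@insertMean < 20)
    msg <- c(msg, "insertMean must be >= 20 bp (the minimum mappable end-to-end distance)")
  if (object@insertSd < 0) msg <- c(msg, "insertSd must be non-negative")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
  if (object@nPairs < 0L) msg <- c(msg, "nPairs must be non-negative")
  if (!grepl("^[ACGT]+$", object@attRepeat))
    msg <- c(msg, "attRepeat must be a non-empty string over A/C/G/T")
  if (length(object@expressionWeights) && any(object@expressionWeights < 0))
    msg <- c(msg, "expressionWeights must be non-negative")
  if (object@errorRate < 0 || object@errorRate > 1)
    msg <- c(msg, "errorRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' KmerIndex: exact-match k-mer lookup over one genome
#'
#' Hash from every k-mer of the forward strand to its 1-based start
#' positions.  Reverse-strand queries are answered by looking up the
#' reverse complement of the query, so positions are always reported in
#' forward-strand coordinates.  K-mers containing N are never stored, and
#' queries containing N never hit.
#'
#' @slot k seed length (default 21 throughout the package).
#' @slot genomeId label of the indexed sequence.
#' @slot genomeLength length of the indexed sequence (bp).
#' @slot lookup environment mapping k-mer strings to integer position
#'   vectors.
#'
#' @seealso [buildKmerIndex()], [queryKmer()], [mapPair()]
#' @exportClass KmerIndex
setClass("KmerIndex",
         slots = c(k = "integer",
                   genomeId = "character",
                   genomeLength = "integer",
                   lookup = "environment"))

#' SimulatedReads: paired reads plus the truth bookkeeping
#'
#' Output of [simulateReadPairs()]: the two mates of every simulated pair
#' and a truth table recording, for each pair, the template it was drawn
#' from and the 1-based fragment interval.  With the default error rate of
#' zero, re-extracting the truth interval reproduces the read bases
#' exactly.  Truth intervals on circular templates are stored modulo the
#' circle length (`end < start` marks a fragment spanning the junction).
#'
#' @slot reads1,reads2 [Biostrings::DNAStringSet]; mate 1 is the forward
#'   strand of the fragment start, mate 2 the reverse complement of the
#'   fragment end.
#' @slot truth data.frame with columns `pair_id`, `template`, `start`,
#'   `end`, `frag_len`.
#' @slot rejections number of fragment draws discarded because they could
#'   not fit their template.
#'
#' @exportClass SimulatedReads
setClass("SimulatedReads",
         slots = c(reads1 = "DNAStringSet",
                   reads2 = "DNAStringSet",
                   truth = "data.frame",
                   rejections = "integer"))

#' ExcisionProducts: the two molecules generated by att-site recombination
#'
#' Excision of an integrated element by recombination between its attL and
#' attR direct repeats yields a circular molecule carrying attP and a
#' shortened chromosome carrying attB; each product retains exactly one
#' copy of the boundary repeat, and their lengths sum to the length of the
#' integrated chromosome.
#'
#' @slot circle attP-bearing [GenomeRecord] with its circular flag set;
#'   stored with the junction repeat at position 1.
#' @slot chromosome attB-bearing [GenomeRecord].
#' @slot repeatSeq the boundary direct repeat (DNA string).
#'
#' @seealso [excise()], [integrateICE()]
#' @exportClass ExcisionProducts
setClass("ExcisionProducts",
         slots = c(circle = "GenomeRecord",
                   chromosome = "GenomeRecord",
                   repeatSeq = "character"))

setValidity("ExcisionProducts", function(object) {
  msg <- character()
  if (!grepl("^[ACGT]+$", object@repeatSeq))
    msg <- c(msg, "repeatSeq must be a non-empty DNA string")
  if (!object@circle@circular)
    msg <- c(msg, "the attP product must be flagged circular")
  if (length(msg)) msg else TRUE
})
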