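#' @include AllClasses.R
NULL

#' Accessors for GenomeRecord and friends
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x a [GenomeRecord], [SimulatedReads] or [ExcisionProducts] object.
#' @return `recordId` the label; `recordSeq` a [Biostrings::DNAString];
#'   `recordLength` the sequence length in bp; `featureRanges` the feature
#'   [GenomicRanges::GRanges]; `featureTable` the features as a 1-based
#'   data.frame (name, start, end, strand, kind); `isCircularRecord` the
#'   circular flag.
#' @name record-accessors
#' @aliases recordId recordSeq recordLength featureRanges featureTable
#'   isCircularRecord
NULL

#' @rdname record-accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname record-accessors
#' @export
setGeneric("recordSeq", function(x) standardGeneric("recordSeq"))

#' @rdname record-accessors
#' @export
setGeneric("recordLength", function(x) standardGeneric("recordLength"))

#' @rdname record-accessors
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))

#' @rdname record-accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname record-accessors
#' @export
setGeneric("isCircularRecord", function(x) standardGeneric("isCircularRecord"))

#' Truth table of a simulated read set
#'
#' @param x a [SimulatedReads] object.
#' @return data.frame with columns `pair_id`, `template`, `start`, `end`,
#'   `frag_len`.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' Products of an excision reaction
#'
#' @param x an [ExcisionProducts] object.
#' @return `attPCircle` / `attBChromosome` the two product
#'   [GenomeRecord]s; `boundaryRepeat` the repeat string.
#' @name excision-accessors
#' @aliases attPCircle attBChromosome boundaryRepeat
NULL

#' @rdname excision-accessors
#' @export
setGeneric("attPCircle", function(x) standardGeneric("attPCircle"))

#' @rdname excision-accessors
#' @export
setGeneric("attBChromosome", function(x) standardGeneric("attBChromosome"))

#' @rdname excision-accessors
#' @export
setGeneric("boundaryRepeat", function(x) standardGeneric("boundaryRepeat"))
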