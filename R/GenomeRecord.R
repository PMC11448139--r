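#' @include AllGenerics.R
NULL

#' Construct a GenomeRecord
#'
#' @param id single character label.
#' @param seq DNA sequence: a character string or [Biostrings::DNAString].
#' @param features either a [GenomicRanges::GRanges] with metadata columns
#'   `name` and `kind`, or a data.frame with columns `name`, `start`,
#'   `end`, and optionally `strand` (default `+`) and `kind`
#'   (default `gene`).  Coordinates are 1-based inclusive.
#' @param circular logical; mark the record as a circular molecule (stored
#'   linearly, junction at position 1).
#' @return a validated [GenomeRecord-class] object.
#' @examples
#' g <- GenomeRecord("toy", "ACGTACGTACGT",
#'                   data.frame(name = "geneA", start = 2, end = 9))
#' recordLength(g)
#' featureTable(g)
#' @export
GenomeRecord <- function(id, seq, features = NULL, circular = FALSE) {
  seq <- Biostrings::DNAString(asSeqChar(seq))
  if (is.null(features)) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$name <- character()
    mcols(gr)$kind <- character()
  } else if (is.data.frame(features)) {
    gr <- featuresFromDataFrame(features)
  } else {
    gr <- features
    if (is.null(mcols(gr)$name)) mcols(gr)$name <- paste0("feat", seq_along(gr))
    if (is.null(mcols(gr)$kind)) mcols(gr)$kind <- rep("gene", length(gr))
  }
  new("GenomeRecord", id = as.character(id)[1L], seq = seq,
      features = gr, circular = isTRUE(circular))
}

featuresFromDataFrame <- function(df) {
  stopifnot(all(c("name", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) as.character(df$strand) else rep("+", nrow(df))
  kind <- if ("kind" %in% names(df)) as.character(df$kind) else rep("gene", nrow(df))
  gr <- GenomicRanges::GRanges(
    seqnames = rep("seq", nrow(df)),
    ranges = IRanges::IRanges(start = as.integer(df$start), end = as.integer(df$end)),
    strand = strand)
  mcols(gr)$name <- as.character(df$name)
  mcols(gr)$kind <- kind
  gr
}

#' @rdname record-accessors
setMethod("recordId", "GenomeRecord", function(x) x@id)

#' @rdname record-accessors
setMethod("recordSeq", "GenomeRecord", function(x) x@seq)

#' @rdname record-accessors
setMethod("recordLength", "GenomeRecord", function(x) length(x@seq))

#' @rdname record-accessors
setMethod("featureRanges", "GenomeRecord", function(x) x@features)

#' @rdname record-accessors
setMethod("featureTable", "GenomeRecord", function(x) {
  fr <- x@features
  data.frame(name = as.character(mcols(fr)$name),
             start = BiocGenerics::start(fr),
             end = BiocGenerics::end(fr),
             strand = as.character(BiocGenerics::strand(fr)),
             kind = as.character(mcols(fr)$kind),
             stringsAsFactors = FALSE)
})

#' @rdname record-accessors
setMethod("isCircularRecord", "GenomeRecord", function(x) x@circular)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord '", object@id, "': ",
      length(object@seq), " bp",
      if (object@circular) " (circular)" else "",
      ", ", length(object@features), " feature(s)\n", sep = "")
  ft <- featureTable(object)
  if (nrow(ft)) {
    n <- min(nrow(ft), 8L)
    print(ft[seq_len(n), ], row.names = FALSE)
    if (nrow(ft) > n) cat("  ... and", nrow(ft) - n, "more\n")
  }
})

#' Look up one feature of a record
#'
#' @param record a [GenomeRecord].
#' @param name feature name (matched against the `name` metadata column),
#'   or `NULL` to select by `kind` alone.
#' @param kind optional feature kind filter.
#' @return `getFeature` a one-row data.frame (error if absent or
#'   ambiguous); `featureSeq` the feature sequence as a character string,
#'   reverse-complemented for `-` strand features.
#' @export
getFeature <- function(record, name = NULL, kind = NULL) {
  ft <- featureTable(record)
  if (!is.null(name)) ft <- ft[ft$name == name, , drop = FALSE]
  if (!is.null(kind)) ft <- ft[ft$kind == kind, , drop = FALSE]
  if (nrow(ft) == 0L)
    stop("record '", recordId(record), "' has no feature ",
         if (!is.null(name)) paste0("named '", name, "'") else paste0("of kind '", kind, "'"))
  ft[1L, , drop = FALSE]
}

#' @rdname getFeature
#' @export
featureSeq <- function(record, name = NULL, kind = NULL) {
  f <- getFeature(record, name = name, kind = kind)
  s <- as.character(Biostrings::subseq(recordSeq(record), f$start, f$end))
  if (identical(f$strand, "-")) s <- revComp(s)
  s
}

#' Read/write feature tables and FASTA/FASTQ
#'
#' Plain-text interchange used throughout: features travel as 1-based
#' inclusive TSV (`name`, `start`, `end`, `strand`, `kind`); genomes as
#' 60-column wrapped FASTA; read pairs as a pair of `_R1`/`_R2` FASTQ
#' files with constant Phred33 quality `I`.
#'
#' @param record a [GenomeRecord] (or for `writeReadPairsFastq` a
#'   [SimulatedReads]).
#' @param path,prefix output path; `writeReadPairsFastq` writes
#'   `<prefix>_R1.fastq` and `<prefix>_R2.fastq`.
#' @param df,record feature data.frame / record to write.
#' @return file paths, invisibly; `readFeatureTable` returns a data.frame,
#'   `readGenomeFasta` a [GenomeRecord].
#' @name icemob-io
NULL

#' @rdname icemob-io
#' @export
writeGenomeFasta <- function(record, path) {
  x <- Biostrings::DNAStringSet(as.character(recordSeq(record)))
  names(x) <- recordId(record)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' @rdname icemob-io
#' @export
readGenomeFasta <- function(path, features = NULL, circular = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  GenomeRecord(id = names(x)[1L], seq = as.character(x[[1L]]),
               features = features, circular = circular)
}

#' @rdname icemob-io
#' @export
writeFeatureTable <- function(record, path) {
  utils::write.table(featureTable(record), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname icemob-io
#' @export
readFeatureTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
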