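#' @include GenomeRecord.R
NULL

#' Structural measurements on an annotated genome
#'
#' Coordinate arithmetic used to verify an annotated (real or synthetic)
#' host chromosome: `elementSpan` is the attL-to-attR span of the
#' integrated element (first attL base through last attR base,
#' inclusive); `intergenicLength` is the gap between two adjacent genes
#' (bases strictly between them).  Applied to the real host genome
#' record, these reproduce the element length and the relaxase-upstream
#' (traF-traI) intergenic length; the real accession is not bundled with
#' the package, so such runs require a locally downloaded FASTA plus
#' feature table via [loadAnnotatedGenome()].
#'
#' @param record an annotated [GenomeRecord].
#' @param left,right gene names bounding the intergenic region.
#' @return length in bp.
#' @export
elementSpan <- function(record) {
  aL <- getFeature(record, kind = "attL")
  aR <- getFeature(record, kind = "attR")
  aR$end - aL$start + 1L
}

#' @rdname elementSpan
#' @export
intergenicLength <- function(record, left, right) {
  fL <- getFeature(record, name = left)
  fR <- getFeature(record, name = right)
  if (fL$start > fR$start) { tmp <- fL; fL <- fR; fR <- tmp }
  gap <- fR$start - fL$end - 1L
  if (gap < 0L) stop("features '", left, "' and '", right, "' overlap")
  gap
}

#' @rdname elementSpan
#' @param fasta,features paths to a genome FASTA and a 1-based feature
#'   TSV (`name`, `start`, `end`, `strand`, `kind`).
#' @export
loadAnnotatedGenome <- function(fasta, features) {
  if (!file.exists(fasta))
    stop("genome FASTA not found: '", fasta, "'. The host genome accession ",
         "is not bundled; download it and supply the local path.")
  if (!file.exists(features))
    stop("feature table not found: '", features, "'")
  readGenomeFasta(fasta, features = readFeatureTable(features))
}
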