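#' @include GenomeRecord.R SimConfig.R
NULL

#' Build a host chromosome with an integrated element
#'
#' Assembles `upstream host -- repeat -- element payload -- repeat --
#' downstream host`: the integrated state of an element flanked by two
#' identical copies of the boundary direct repeat (attL and attR).  Gene
#' features are placed both inside the element (`xis`, `int`, `traI`,
#' `traG`, `traR`) and outside it (`rrn` on the host), so expression
#' weights and reference-gene normalization can be exercised downstream.
#'
#' The random host and payload are regenerated until three structural
#' guarantees hold: the repeat occurs exactly twice in the whole genome
#' (only at attL/attR), the repeat pair cannot be extended by one base on
#' either side, and no competing direct-repeat pair of at least the
#' repeat length exists within the boundary windows that
#' [detectBoundaryRepeat()] searches when given the element interval as a
#' hint.  Boundary detection with `elementHint` on these fixtures is
#' therefore guaranteed to recover exactly the planted repeat.  (A
#' genome-wide guarantee is not attempted: on a multi-kilobase random
#' sequence, chance repeat pairs of 9+ bp are expected and carry no
#' biological meaning.)
#'
#' @param cfg a [SimConfig]; uses `hostLength`, `iceLength`, `attRepeat`
#'   and `seed`.
#' @param maxTries regeneration attempts before giving up (default 200).
#' @return a [GenomeRecord] of length
#'   `hostLength + iceLength + 2 * nchar(attRepeat)` with attL/attR and
#'   gene features.
#' @examples
#' g <- makeIntegratedGenome(SimConfig(hostLength = 300, iceLength = 1000,
#'                                     seed = 1))
#' recordLength(g)  # 300 + 1000 + 2*9
#' @export
makeIntegratedGenome <- function(cfg, maxTries = 200L) {
  stopifnot(is(cfg, "SimConfig"))
  rep_ <- cfg@attRepeat
  r <- nchar(rep_)
  if (cfg@iceLength <= 2L * r)
    stop("iceLength must exceed twice the repeat length")
  if (cfg@hostLength < 100L)
    stop("hostLength must be at least 100 bp")
  set.seed(childSeed(cfg@seed, 0L))
  insertAt <- cfg@hostLength %/% 2L
  for (try in seq_len(maxTries)) {
    host <- randomDNA(cfg@hostLength)
    payload <- randomDNA(cfg@iceLength)
    genome <- paste0(substr(host, 1L, insertAt), rep_, payload, rep_,
                     substr(host, insertAt + 1L, cfg@hostLength))
    lS <- insertAt + 1L                      # attL start
    rS <- insertAt + r + cfg@iceLength + 1L  # attR start
    if (.repeatIsCleanlyUnique(genome, rep_, lS, rS)) {
      return(.annotateIntegrated(genome, cfg, insertAt, r))
    }
  }
  stop("could not build a genome with a unique, non-extendable boundary repeat in ",
       maxTries, " attempts; try a longer repeat or different seed")
}

## TRUE iff `rep_` occurs exactly at lS and rS, the pair is maximal
## (one-base extension breaks identity), and hinted boundary detection
## recovers exactly this pair (no competing repeat in the windows).
.repeatIsCleanlyUnique <- function(genome, rep_, lS, rS) {
  r <- nchar(rep_)
  L <- nchar(genome)
  occ <- allStarts(rep_, genome)
  if (!identical(occ, c(lS, rS))) return(FALSE)
  ## non-extendable either direction
  if (lS > 1L && rS > 1L &&
      substr(genome, lS - 1L, lS - 1L) == substr(genome, rS - 1L, rS - 1L))
    return(FALSE)
  if (rS + r <= L &&
      substr(genome, lS + r, lS + r) == substr(genome, rS + r, rS + r))
    return(FALSE)
  det <- tryCatch(
    detectBoundaryRepeat(genome, elementHint = c(lS, rS + r - 1L),
                         minLen = min(6L, r)),
    error = function(e) NULL)
  !is.null(det) && det$length == r &&
    identical(det$attL, c(lS, lS + r - 1L)) &&
    identical(det$attR, c(rS, rS + r - 1L))
}

.annotateIntegrated <- function(genome, cfg, insertAt, r) {
  lS <- insertAt + 1L
  pS <- lS + r                       # payload start
  pE <- pS + cfg@iceLength - 1L      # payload end
  rS <- pE + 1L                      # attR start
  feats <- data.frame(name = c("attL", "attR"),
                      start = c(lS, rS), end = c(lS + r - 1L, rS + r - 1L),
                      strand = "+", kind = c("attL", "attR"),
                      stringsAsFactors = FALSE)
  ## genes inside the element: five evenly spaced blocks of the payload
  iceGenes <- c("xis", "int", "traI", "traG", "traR")
  block <- cfg@iceLength %/% length(iceGenes)
  if (block >= 60L) {
    glen <- min(300L, block - 20L)
    gs <- pS + (seq_along(iceGenes) - 1L) * block + 10L
    feats <- rbind(feats, data.frame(name = iceGenes, start = gs,
                                     end = gs + glen - 1L, strand = "+",
                                     kind = "gene", stringsAsFactors = FALSE))
  }
  ## a host gene outside the element (reference gene for normalization)
  if (insertAt >= 140L) {
    feats <- rbind(feats, data.frame(name = "rrn", start = 20L,
                                     end = min(120L, insertAt - 10L),
                                     strand = "+", kind = "gene",
                                     stringsAsFactors = FALSE))
  }
  GenomeRecord(id = "integrated_host", seq = genome, features = feats)
}

#' Plant a sequence into a record and register it as a feature
#'
#' Overwrites `nchar(seq)` bases starting at `at` and appends a feature so
#' the planted site is recoverable by the scanners at its recorded
#' coordinate.
#'
#' @param record a [GenomeRecord].
#' @param seq DNA string to plant (plus-strand orientation).
#' @param at 1-based start position.
#' @param name,kind feature annotation (defaults `kind = "motif"`).
#' @return the modified [GenomeRecord].
#' @export
plantFeature <- function(record, seq, at, name, kind = "motif") {
  seq <- asSeqChar(seq)
  L <- recordLength(record)
  end <- at + nchar(seq) - 1L
  if (at < 1L || end > L) stop("planted interval [", at, ",", end,
                               "] exceeds the sequence bounds")
  s <- asSeqChar(recordSeq(record))
  substr(s, at, end) <- seq
  ft <- featureTable(record)
  ft <- rbind(ft, data.frame(name = name, start = at, end = end,
                             strand = "+", kind = kind,
                             stringsAsFactors = FALSE))
  GenomeRecord(recordId(record), s, ft, circular = isCircularRecord(record))
}

#' Template mixture of integrated and excised states
#'
#' Runs the excision reaction on an integrated chromosome and returns the
#' three DNA templates present in a partially excised population: the
#' intact integrated chromosome (weight `1 - fraction`), the attB-bearing
#' chromosome and the attP-bearing circle (weight `fraction` each).
#'
#' @param integrated a [GenomeRecord] carrying `attL` and `attR` features.
#' @param fraction excised fraction in \[0, 1\].
#' @return list of `list(record = <GenomeRecord>, weight = <numeric>)`, in
#'   the order integrated, attB chromosome, attP circle.
#' @seealso [excise()], [simulateReadPairs()], [simulateQpcrPanel()]
#' @export
makeExcisionMixture <- function(integrated, fraction) {
  stopifnot(is(integrated, "GenomeRecord"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  ft <- featureTable(integrated)
  for (k in c("attL", "attR")) {
    if (!k %in% ft$kind)
      stop("integrated record lacks the required '", k, "' feature")
  }
  prod <- excise(integrated)
  list(list(record = integrated, weight = 1 - fraction),
       list(record = attBChromosome(prod), weight = fraction),
       list(record = attPCircle(prod), weight = fraction))
}

#' Simulate paired reads from a weighted template mixture
#'
#' Draws fragments from templates with probability proportional to
#' `template weight x expression weight` of the feature the fragment is
#' anchored on, then emits the two mates: mate 1 is the forward strand of
#' the fragment start, mate 2 the reverse complement of the fragment end.
#' Fragment lengths follow Normal(`insertMean`, `insertSd`), rounded and
#' truncated by rejection to `[readLength, template length]` (rejections
#' are counted).  On circular templates fragments may span the junction
#' (sequence rotation); their truth intervals are stored modulo the circle
#' length.
#'
#' If `expressionWeights` is empty, each template contributes one
#' whole-length pseudo-feature, i.e. uniform coverage.  Otherwise only
#' features whose `name` appears in the weight map are sampled; a
#' positive-weight template with no matching feature contributes nothing
#' (with a warning).
#'
#' No sequencing error is introduced unless `errorRate > 0`, so the truth
#' interval re-extracts the read bases exactly.
#'
#' @param mix a [GenomeRecord], or a list of
#'   `list(record = , weight = )` as returned by [makeExcisionMixture()].
#' @param cfg a [SimConfig]; uses `readLength`, `insertMean`, `insertSd`,
#'   `nPairs`, `seed` (child stream 1) and `errorRate`.
#' @return a [SimulatedReads] object.
#' @export
simulateReadPairs <- function(mix, cfg) {
  stopifnot(is(cfg, "SimConfig"))
  if (is(mix, "GenomeRecord")) mix <- list(list(record = mix, weight = 1))
  w <- vapply(mix, function(m) as.numeric(m$weight), numeric(1L))
  if (any(w < 0)) stop("template weights must be non-negative")
  if (!any(w > 0)) stop("at least one template weight must be positive")
  if (cfg@readLength < 21L)
    stop("readLength must be >= 21 (seed length of the mapper)")
  set.seed(childSeed(cfg@seed, 1L))

  frame <- .samplingFrame(mix, w, cfg@expressionWeights)
  n <- cfg@nPairs
  if (n == 0L) {
    return(new("SimulatedReads",
               reads1 = Biostrings::DNAStringSet(), reads2 = Biostrings::DNAStringSet(),
               truth = data.frame(pair_id = character(), template = character(),
                                  start = integer(), end = integer(),
                                  frag_len = integer(), stringsAsFactors = FALSE),
               rejections = 0L))
  }
  lower <- max(cfg@readLength, 20L)
  if (any(frame$tlen[frame$prob > 0] < lower))
    stop("a positive-weight template is shorter than the minimum fragment length")

  rows <- sample.int(nrow(frame), n, replace = TRUE, prob = frame$prob)
  tlen <- frame$tlen[rows]
  ## truncated-normal fragment lengths by rejection
  flen <- as.integer(round(stats::rnorm(n, cfg@insertMean, cfg@insertSd)))
  rejections <- 0L
  for (iter in seq_len(1000L)) {
    bad <- which(flen < lower | flen > tlen)
    if (!length(bad)) break
    rejections <- rejections + length(bad)
    flen[bad] <- as.integer(round(stats::rnorm(length(bad), cfg@insertMean, cfg@insertSd)))
  }
  if (length(which(flen < lower | flen > tlen)))
    stop("could not draw in-range fragment lengths; check insertMean/insertSd")

  ## fragment start uniform over positions overlapping the anchor feature
  fs <- frame$fstart[rows]; fe <- frame$fend[rows]
  circ <- frame$circular[rows]
  lo <- fs - flen + 1L
  hi <- fe
  lin <- !circ
  lo[lin] <- pmax(lo[lin], 1L)
  hi[lin] <- pmin(hi[lin], tlen[lin] - flen[lin] + 1L)
  start <- as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))
  start[circ] <- ((start[circ] - 1L) %% tlen[circ]) + 1L

  seqs <- frame$tseq[rows]
  seqs[circ] <- frame$tseq2[rows][circ]   # doubled sequence for junction-spanning
  frag <- substring(seqs, start, start + flen - 1L)
  reads1 <- substr(frag, 1L, cfg@readLength)
  reads2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(frag, flen - cfg@readLength + 1L, flen))))
  if (cfg@errorRate > 0) {
    reads1 <- .addErrors(reads1, cfg@errorRate)
    reads2 <- .addErrors(reads2, cfg@errorRate)
  }
  ids <- sprintf("pair%06d", seq_len(n))
  end <- start + flen - 1L
  end[circ] <- ((end[circ] - 1L) %% tlen[circ]) + 1L
  truth <- data.frame(pair_id = ids, template = frame$tid[rows],
                      start = start, end = end, frag_len = flen,
                      stringsAsFactors = FALSE)
  r1 <- Biostrings::DNAStringSet(reads1); names(r1) <- ids
  r2 <- Biostrings::DNAStringSet(reads2); names(r2) <- ids
  new("SimulatedReads", reads1 = r1, reads2 = r2, truth = truth,
      rejections = rejections)
}

.samplingFrame <- function(mix, w, weights) {
  out <- list()
  for (i in seq_along(mix)) {
    rec <- mix[[i]]$record
    if (w[i] <= 0) next
    s <- asSeqChar(recordSeq(rec))
    L <- nchar(s)
    circ <- isCircularRecord(rec)
    base <- data.frame(tid = recordId(rec), tseq = s,
                       tseq2 = if (circ) paste0(s, s) else s,
                       tlen = L, circular = circ, stringsAsFactors = FALSE)
    if (!length(weights)) {
      row <- base; row$fstart <- 1L; row$fend <- L; row$prob <- w[i]
      out[[length(out) + 1L]] <- row
    } else {
      ft <- featureTable(rec)
      ft <- ft[ft$name %in% names(weights), , drop = FALSE]
      ew <- weights[ft$name]
      keep <- which(ew > 0)
      if (!length(keep)) {
        warning("template '", recordId(rec),
                "' has positive weight but no feature matching expressionWeights")
        next
      }
      for (j in keep) {
        row <- base
        row$fstart <- as.integer(ft$start[j]); row$fend <- as.integer(ft$end[j])
        row$prob <- w[i] * unname(ew[j])
        out[[length(out) + 1L]] <- row
      }
    }
  }
  frame <- do.call(rbind, out)
  if (is.null(frame) || !nrow(frame) || sum(frame$prob) <= 0)
    stop("no sampleable (template, feature) combination with positive probability")
  frame
}

.addErrors <- function(reads, rate) {
  vapply(reads, function(rd) {
    ch <- strsplit(rd, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' @rdname truthTable
setMethod("truthTable", "SimulatedReads", function(x) x@truth)

#' Mate sequences of a simulated read set
#'
#' @param x a [SimulatedReads].
#' @param mate 1 or 2.
#' @return a named [Biostrings::DNAStringSet].
#' @export
mateReads <- function(x, mate = 1) {
  stopifnot(is(x, "SimulatedReads"))
  if (mate == 1) x@reads1 else x@reads2
}

setMethod("show", "SimulatedReads", function(object) {
  cat("SimulatedReads:", length(object@reads1), "pairs,",
      object@rejections, "fragment rejection(s)\n")
  if (nrow(object@truth)) {
    cat("  templates:",
        paste(unique(object@truth$template), collapse = ", "), "\n")
  }
})

#' @rdname icemob-io
#' @param x a [SimulatedReads] object.
#' @export
writeReadPairsFastq <- function(x, prefix) {
  stopifnot(is(x, "SimulatedReads"))
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (i in 1:2) {
    reads <- mateReads(x, i)
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    names(quals) <- names(reads)
    Biostrings::writeXStringSet(reads, filepath = paths[i], format = "fastq",
                                qualities = quals)
  }
  invisible(paths)
}

#' @rdname icemob-io
#' @export
writeTruthTable <- function(x, path) {
  utils::write.table(truthTable(x), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic origin-of-transfer region
#'
#' Builds a 463-bp stand-in for the intergenic region between the relaxase
#' gene (`traI`) and its upstream neighbour (`traF`), with the features the
#' real region carries planted at fixed coordinates: two LysR-motif sites
#' (TN11A in an interrupted inverted repeat) in the dispensable left part,
#' a conserved 20-bp core containing the `CAAAAGG` half-site, and three
#' inverted-repeat elements REPT1/REPT2/REPT3.  The true sequence of the
#' region is not bundled (it is only available from the host genome
#' accession); coordinates of the planted features are consistent with the
#' published deletion-series phenotypes bundled in
#' `inst/extdata/orit_constructs.tsv`.
#'
#' @param seed integer seed for the random background (default 1).
#' @return a [GenomeRecord] of length 463 with labelled features.
#' @export
makeOriTRegion <- function(seed = 1) {
  set.seed(childSeed(seed, 0L))
  rec <- GenomeRecord("oriT_region_synthetic", randomDNA(463L))
  sites <- traRBindingSites()
  conserved20 <- "ACCGTGCTACAAAAGGTGAT"      # carries the CAAAAGG half-site
  rept1 <- paste0("GCTAGGCA", "TT", revComp("GCTAGGCA"))              # 8+2+8
  rept2 <- paste0("ATCGGACTGTAC", "AAATTTC", revComp("ATCGGACTGTAC")) # 12+7+12
  rept3 <- paste0("GGATCCTGAACTG", "CGCAT", revComp("GGATCCTGAACTG")) # 13+5+13
  rec <- plantFeature(rec, sites[["BSxis"]], 120L, "LysR_motif_1", "motif")
  rec <- plantFeature(rec, sites[["BS15836"]], 200L, "LysR_motif_2", "motif")
  rec <- plantFeature(rec, conserved20, 281L, "conserved20", "oriT_core")
  rec <- plantFeature(rec, rept1, 301L, "REPT1", "REPT")
  rec <- plantFeature(rec, rept2, 350L, "REPT2", "REPT")
  rec <- plantFeature(rec, rept3, 400L, "REPT3", "REPT")
  rec
}

#' Diverged homologs of a reference region
#'
#' Emulates the cross-element comparison that reveals a conserved core:
#' every position outside the protected window is substituted with
#' probability `divergence`, while the protected window is copied intact
#' (optionally with a fixed number of mismatches).
#'
#' @param region a [GenomeRecord] or character reference sequence.
#' @param n number of homologs (default 3).
#' @param divergence per-base substitution probability outside the
#'   protected window (default 0.3).
#' @param protect integer c(start, end) window to keep conserved; default
#'   is the `conserved20` feature of `region` if present, else no window.
#' @param seed integer seed.
#' @return character vector of homolog sequences.
#' @export
makeOriTHomologs <- function(region, n = 3, divergence = 0.3,
                             protect = NULL, seed = 1) {
  s <- if (is(region, "GenomeRecord")) asSeqChar(recordSeq(region)) else asSeqChar(region)
  if (is.null(protect) && is(region, "GenomeRecord")) {
    ft <- featureTable(region)
    hit <- ft[ft$name == "conserved20", , drop = FALSE]
    if (nrow(hit)) protect <- c(hit$start[1L], hit$end[1L])
  }
  set.seed(childSeed(seed, 3L))
  ch0 <- strsplit(s, "", fixed = TRUE)[[1L]]
  keep <- rep(FALSE, length(ch0))
  if (!is.null(protect)) keep[protect[1L]:protect[2L]] <- TRUE
  vapply(seq_len(n), function(i) {
    ch <- ch0
    hit <- which(!keep & stats::runif(length(ch)) < divergence)
    for (j in hit) ch[j] <- sample(setdiff(.BASES, ch[j]), 1L)
    paste(ch, collapse = "")
  }, character(1L))
}
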