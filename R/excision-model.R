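#' @include GenomeRecord.R
NULL

#' @rdname excision-accessors
setMethod("attPCircle", "ExcisionProducts", function(x) x@circle)

#' @rdname excision-accessors
setMethod("attBChromosome", "ExcisionProducts", function(x) x@chromosome)

#' @rdname excision-accessors
setMethod("boundaryRepeat", "ExcisionProducts", function(x) x@repeatSeq)

setMethod("show", "ExcisionProducts", function(object) {
  cat("ExcisionProducts: boundary repeat", object@repeatSeq,
      "(", nchar(object@repeatSeq), "bp )\n")
  cat("  attP circle    :", recordLength(object@circle), "bp\n")
  cat("  attB chromosome:", recordLength(object@chromosome), "bp\n")
})

#' Detect the direct repeat flanking an integrated element
#'
#' Finds the longest pair of identical same-strand substrings such that
#' extending either copy by one base in either direction breaks identity
#' (a maximal direct-repeat pair).  With no hint the whole genome is
#' scanned by seeding on `minLen`-mers and extending; with an
#' `elementHint` interval only windows around the two hint boundaries are
#' searched, which is both faster and robust to chance repeats elsewhere
#' on a large chromosome.
#'
#' @param genome a [GenomeRecord] or character sequence.
#' @param elementHint optional integer `c(start, end)` of the integrated
#'   element (attL start to attR end).
#' @param minLen minimum repeat length considered (default 6: below
#'   that, chance matches dominate at chromosome scale).
#' @param window half-width of the boundary windows searched when a hint
#'   is given (default 60).
#' @return list: `repeat_seq`, `length`, `attL = c(start, end)`,
#'   `attR = c(start, end)`.  Error if no repeat pair of at least
#'   `minLen` bp exists.
#' @export
detectBoundaryRepeat <- function(genome, elementHint = NULL, minLen = 6,
                                 window = 60) {
  s <- if (is(genome, "GenomeRecord")) asSeqChar(recordSeq(genome)) else asSeqChar(genome)
  minLen <- as.integer(minLen)
  L <- nchar(s)
  if (is.null(elementHint)) {
    pairs <- .maximalRepeatPairs(s, minLen)
  } else {
    h1 <- max(1L, elementHint[1L] - window)
    h2 <- min(L, elementHint[1L] + window)
    h3 <- max(1L, elementHint[2L] - window)
    h4 <- min(L, elementHint[2L] + window)
    pairs <- .maximalRepeatPairs(s, minLen,
                                 region1 = c(h1, h2), region2 = c(h3, h4))
  }
  if (is.null(pairs) || !nrow(pairs))
    stop("no direct repeat pair of length >= ", minLen, " bp found")
  best <- pairs[order(-pairs$len, pairs$p1), ][1L, ]
  list(repeat_seq = substr(s, best$p1, best$p1 + best$len - 1L),
       length = best$len,
       attL = c(best$p1, best$p1 + best$len - 1L),
       attR = c(best$p2, best$p2 + best$len - 1L))
}

## all maximal non-overlapping direct-repeat pairs of length >= minLen;
## optional regions restrict the left and right copy starts
.maximalRepeatPairs <- function(s, minLen, region1 = NULL, region2 = NULL) {
  L <- nchar(s)
  n <- L - minLen + 1L
  if (n < 2L) return(NULL)
  pos <- seq_len(n)
  kmers <- substring(s, pos, pos + minLen - 1L)
  grp <- split(pos, kmers)
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp)) return(NULL)
  out <- list()
  for (g in grp) {
    for (a in seq_len(length(g) - 1L)) {
      for (b in (a + 1L):length(g)) {
        p1 <- g[a]; p2 <- g[b]
        if (!is.null(region1) &&
            !(p1 >= region1[1L] - minLen && p1 <= region1[2L])) next
        if (!is.null(region2) &&
            !(p2 >= region2[1L] - minLen && p2 <= region2[2L])) next
        ## extend left
        while (p1 > 1L && p2 > 1L &&
               substr(s, p1 - 1L, p1 - 1L) == substr(s, p2 - 1L, p2 - 1L) &&
               p1 + minLen - 1L < p2 - 1L + 1L) {
          p1 <- p1 - 1L; p2 <- p2 - 1L
        }
        len <- minLen
        ## extend right, keeping the copies non-overlapping
        while (p2 + len <= L && p1 + len < p2 &&
               substr(s, p1 + len, p1 + len) == substr(s, p2 + len, p2 + len)) {
          len <- len + 1L
        }
        if (p1 + len - 1L >= p2) next      # overlapping copies: not a pair
        out[[length(out) + 1L]] <- c(p1, p2, len)
      }
    }
  }
  if (!length(out)) return(NULL)
  m <- unique(do.call(rbind, out))
  data.frame(p1 = m[, 1L], p2 = m[, 2L], len = m[, 3L])
}

#' Excise an element by att-site recombination
#'
#' Site-specific recombination between the identical attL and attR direct
#' repeats releases the element as a circle carrying one repeat copy
#' (attP) and leaves the chromosome with the other copy (attB).  The
#' crossover is placed at the repeat's left edge, so the circle keeps the
#' attL copy; because the two copies are identical, any consistent
#' crossover convention yields the same molecules.  The circle is
#' returned linearized with the attP junction repeat at position 1.
#'
#' Features entirely inside the excised interval are remapped onto the
#' circle; features entirely outside onto the shortened chromosome;
#' features straddling a junction are dropped with a warning.  Length is
#' conserved: `length(circle) + length(chromosome) = length(input)`.
#'
#' @param genome integrated [GenomeRecord].
#' @param attL,attR integer `c(start, end)` of the two repeat copies;
#'   default taken from the record's `attL`/`attR` features.
#' @return an [ExcisionProducts-class] object.
#' @examples
#' g <- makeIntegratedGenome(SimConfig(hostLength = 300, iceLength = 1000,
#'                                     seed = 1))
#' p <- excise(g)
#' recordLength(attPCircle(p)) + recordLength(attBChromosome(p)) ==
#'   recordLength(g)
#' @export
excise <- function(genome, attL = NULL, attR = NULL) {
  stopifnot(is(genome, "GenomeRecord"))
  if (is.null(attL)) {
    f <- getFeature(genome, kind = "attL"); attL <- c(f$start, f$end)
  }
  if (is.null(attR)) {
    f <- getFeature(genome, kind = "attR"); attR <- c(f$start, f$end)
  }
  s <- asSeqChar(recordSeq(genome))
  L <- nchar(s)
  lS <- attL[1L]; lE <- attL[2L]; rS <- attR[1L]; rE <- attR[2L]
  r <- lE - lS + 1L
  if (rE - rS + 1L != r) stop("attL and attR have different lengths")
  if (lE >= rS) stop("attL must lie entirely left of attR")
  repSeq <- substr(s, lS, lE)
  if (repSeq != substr(s, rS, rE))
    stop("attL and attR sequences differ: not a valid recombination substrate")

  circleSeq <- substr(s, lS, rS - 1L)              # attL copy + payload
  chromSeq <- paste0(substr(s, 1L, lS - 1L), substr(s, rS, L))
  circleLen <- nchar(circleSeq)

  ft <- featureTable(genome)
  ft <- ft[!ft$kind %in% c("attL", "attR"), , drop = FALSE]
  inside <- ft$start >= lS & ft$end <= rS - 1L
  outside <- ft$end <= lS - 1L | ft$start >= rS
  straddle <- !(inside | outside)
  if (any(straddle))
    warning("dropping ", sum(straddle),
            " feature(s) straddling an excision junction: ",
            paste(ft$name[straddle], collapse = ", "))
  cFt <- ft[inside, , drop = FALSE]
  cFt$start <- cFt$start - lS + 1L
  cFt$end <- cFt$end - lS + 1L
  cFt <- rbind(data.frame(name = "attP", start = 1L, end = r, strand = "+",
                          kind = "attP", stringsAsFactors = FALSE), cFt)
  hFt <- ft[outside, , drop = FALSE]
  shift <- ifelse(hFt$start >= rS, circleLen, 0L)
  hFt$start <- hFt$start - shift
  hFt$end <- hFt$end - shift
  hFt <- rbind(data.frame(name = "attB", start = lS, end = lS + r - 1L,
                          strand = "+", kind = "attB", stringsAsFactors = FALSE),
               hFt)
  circle <- GenomeRecord(paste0(recordId(genome), "_attP_circle"), circleSeq,
                         cFt, circular = TRUE)
  chrom <- GenomeRecord(paste0(recordId(genome), "_attB_chromosome"), chromSeq,
                        hFt, circular = FALSE)
  new("ExcisionProducts", circle = circle, chromosome = chrom,
      repeatSeq = repSeq)
}

#' Integrate a circle into an attB-bearing chromosome
#'
#' Inverse of [excise()]: recombination between the circle's attP repeat
#' and the chromosome's attB repeat inserts the circle immediately before
#' the attB copy, regenerating the integrated state with attL and attR
#' flanking the element.  `integrateICE(attPCircle(p), attBChromosome(p))`
#' reproduces the pre-excision chromosome byte for byte.
#'
#' @param circle attP-bearing [GenomeRecord] (junction repeat at
#'   position 1).
#' @param chromosome attB-bearing [GenomeRecord].
#' @param attB integer `c(start, end)` of the attB repeat; default taken
#'   from the chromosome's `attB` feature.
#' @return integrated [GenomeRecord].
#' @export
integrateICE <- function(circle, chromosome, attB = NULL) {
  stopifnot(is(circle, "GenomeRecord"), is(chromosome, "GenomeRecord"))
  if (is.null(attB)) {
    f <- getFeature(chromosome, kind = "attB"); attB <- c(f$start, f$end)
  }
  cs <- asSeqChar(recordSeq(circle))
  hs <- asSeqChar(recordSeq(chromosome))
  b1 <- attB[1L]; b2 <- attB[2L]
  r <- b2 - b1 + 1L
  repB <- substr(hs, b1, b2)
  if (substr(cs, 1L, r) != repB)
    stop("circle attP repeat and chromosome attB repeat differ: ",
         "not a valid recombination substrate")
  out <- paste0(substr(hs, 1L, b1 - 1L), cs, substr(hs, b1, nchar(hs)))
  circleLen <- nchar(cs)

  cFt <- featureTable(circle)
  cFt <- cFt[cFt$kind != "attP", , drop = FALSE]
  cFt$start <- cFt$start + b1 - 1L
  cFt$end <- cFt$end + b1 - 1L
  hFt <- featureTable(chromosome)
  hFt <- hFt[hFt$kind != "attB", , drop = FALSE]
  shift <- ifelse(hFt$start >= b1, circleLen, 0L)
  hFt$start <- hFt$start + shift
  hFt$end <- hFt$end + shift
  att <- data.frame(name = c("attL", "attR"),
                    start = c(b1, b1 + circleLen),
                    end = c(b1 + r - 1L, b1 + circleLen + r - 1L),
                    strand = "+", kind = c("attL", "attR"),
                    stringsAsFactors = FALSE)
  GenomeRecord(sub("_attB_chromosome$", "", recordId(chromosome)), out,
               rbind(att, cFt, hFt), circular = FALSE)
}

#' Predict PCR products of primer pairs on a set of templates
#'
#' Exact primer matching on both strands; a product runs from the forward
#' primer's 5' end through the reverse primer's 5' end and must not
#' exceed `max_product`.  Circular templates are searched across the
#' junction by scanning `seq + seq[1..max_product]`.  A primer pair with
#' more than one product on one template is flagged nonspecific.
#'
#' @param templates list of [GenomeRecord]s (or a [makeExcisionMixture()]
#'   result, whose records are extracted).
#' @param primers data.frame: `name`, `fwd`, `rev`, `max_product`
#'   (primers at least 15 nt).
#' @return data.frame: `template`, `primer_set`, `product_length` (NA if
#'   no product), `n_products`, `nonspecific`.
#' @export
predictAmplicons <- function(templates, primers) {
  if (is(templates, "GenomeRecord")) templates <- list(templates)
  templates <- lapply(templates, function(t)
    if (is(t, "GenomeRecord")) t else t$record)
  if (any(nchar(primers$fwd) < 15L) || any(nchar(primers$rev) < 15L))
    stop("primers must be at least 15 nt")
  out <- list()
  for (tm in templates) {
    L <- recordLength(tm)
    s <- asSeqChar(recordSeq(tm))
    for (i in seq_len(nrow(primers))) {
      maxp <- as.integer(primers$max_product[i])
      subj <- if (isCircularRecord(tm)) paste0(s, substr(s, 1L, min(maxp, L)))
      else s
      lens <- .ampliconLengths(subj, L, isCircularRecord(tm),
                               asSeqChar(primers$fwd[i]),
                               asSeqChar(primers$rev[i]), maxp)
      out[[length(out) + 1L]] <- data.frame(
        template = recordId(tm), primer_set = primers$name[i],
        product_length = if (length(lens)) min(lens) else NA_integer_,
        n_products = length(lens), nonspecific = length(lens) > 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## product lengths for one primer pair on one (possibly doubled) subject
.ampliconLengths <- function(subj, L, circular, fwd, rev, maxp) {
  lens <- integer()
  for (orient in 1:2) {
    a <- if (orient == 1L) fwd else rev       # primer annealing on +
    b <- if (orient == 1L) rev else fwd       # primer annealing on -
    fpos <- allStarts(a, subj)                # 5' ends of the + primer
    rpos <- allStarts(revComp(b), subj)       # sites whose 5' end is at +lenB-1
    if (circular) fpos <- fpos[fpos <= L]     # avoid double counting
    if (!length(fpos) || !length(rpos)) next
    r5 <- rpos + nchar(b) - 1L
    for (f in fpos) {
      pl <- r5 - f + 1L
      pl <- pl[pl >= nchar(a) + nchar(b) & pl <= maxp]
      lens <- c(lens, pl)
    }
  }
  lens
}

#' Design the three diagnostic primer sets for excision qPCR
#'
#' Derives, from an integrated genome with annotated att sites, synthetic
#' primer pairs reproducing the standard excision-assay design: set `a`
#' spans the attP junction and amplifies only the excised circle; set `b`
#' spans the attB junction and amplifies only the post-excision
#' chromosome (on the integrated form its product would span the whole
#' element and exceeds `maxProduct`); set `c` sits inside the element and
#' amplifies both the integrated form and the circle, serving as the
#' internal standard for total element copies.
#'
#' @param integrated [GenomeRecord] with `attL`/`attR` features and at
#'   least 80 bp of host on both sides of the element.
#' @param primerLen primer length (default 20).
#' @param maxProduct maximum product size (default 400).
#' @return primer data.frame accepted by [predictAmplicons()] and
#'   [simulateQpcrPanel()], sets named `set_a`, `set_b`, `set_c`.
#' @export
designDiagnosticPrimers <- function(integrated, primerLen = 20, maxProduct = 400) {
  s <- asSeqChar(recordSeq(integrated))
  fL <- getFeature(integrated, kind = "attL")
  fR <- getFeature(integrated, kind = "attR")
  lS <- fL$start; rS <- fR$start; rE <- fR$end
  pS <- fL$end + 1L                 # payload start
  pE <- rS - 1L                     # payload end
  pl <- as.integer(primerLen)
  if (pS + 120L + pl > pE) stop("element payload too short for primer design")
  if (lS - 61L < 1L || rE + 60L + pl > nchar(s))
    stop("need at least ~80 bp of host flank on both sides of the element")
  sub <- function(a, b) substr(s, a, b)
  primers <- data.frame(
    name = c("set_a", "set_b", "set_c"),
    fwd = c(sub(pE - 60L - pl + 1L, pE - 60L),          # payload right end ->
            sub(lS - 60L - pl + 1L, lS - 60L),          # host left of attL ->
            sub(pS + 40L, pS + 40L + pl - 1L)),         # inside payload ->
    rev = c(revComp(sub(pS + 40L, pS + 40L + pl - 1L)), # <- payload left start
            revComp(sub(rE + 41L, rE + 40L + pl)),      # <- host right of attR
            revComp(sub(pS + 120L, pS + 120L + pl - 1L))),
    max_product = as.integer(maxProduct),
    stringsAsFactors = FALSE)
  primers
}
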