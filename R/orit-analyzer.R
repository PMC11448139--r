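#' @include utils.R
NULL

#' Find inverted repeats with a mismatch budget
#'
#' Enumerates every anchor `(i, j)` — left arm innermost base `i`, right
#' arm innermost base `j`, loop `j - i - 1` between 0 and `maxLoop` — and
#' extends the arms outward greedily while at most `maxMismatch` arm
#' positions fail to be complementary; terminal mismatched pairs are
#' trimmed so arms always end in a complementary pair.  Hits shorter than
#' `minArm` are discarded, and a hit whose arms are contained in a longer
#' hit with no more mismatches is suppressed as redundant.
#'
#' @param seq DNA sequence.
#' @param minArm minimum arm length (>= 3; default 6).
#' @param maxLoop maximum loop length between the arms (default 12).
#' @param maxMismatch maximum non-complementary arm positions (default 1).
#' @param seqId label recorded in the output.
#' @return data.frame: `seq_id`, `left_start`, `left_end`, `right_start`,
#'   `right_end`, `arm_len`, `loop_len`, `mismatches`.
#' @export
findInvertedRepeats <- function(seq, minArm = 6, maxLoop = 12,
                                maxMismatch = 1, seqId = "seq") {
  minArm <- as.integer(minArm)
  if (minArm < 3L) stop("minArm must be >= 3")
  maxLoop <- as.integer(maxLoop); maxMismatch <- as.integer(maxMismatch)
  ch <- seqChars(seq)
  L <- length(ch)
  comp <- unname(.COMP[ch])       # complement of each base (NA-safe via .COMP)
  hits <- list()
  for (i in seq_len(L - 1L)) {
    jmax <- min(L, i + 1L + maxLoop)
    for (j in (i + 1L):jmax) {
      ## extend: compare ch[i - t] against complement of ch[j + t]
      t <- 0L; mm <- 0L
      mmAt <- integer()
      while (i - t >= 1L && j + t <= L) {
        match <- !is.na(comp[j + t]) && ch[i - t] == comp[j + t] &&
          ch[i - t] %in% .BASES
        if (!match) {
          if (mm + 1L > maxMismatch) break
          mm <- mm + 1L
          mmAt <- c(mmAt, t)
        }
        t <- t + 1L
      }
      ## trim terminal (outermost) mismatches
      arm <- t
      while (arm > 0L && (arm - 1L) %in% mmAt) {
        arm <- arm - 1L
        mm <- mm - 1L
        mmAt <- mmAt[mmAt != arm]
      }
      if (arm >= minArm) {
        hits[[length(hits) + 1L]] <- c(i - arm + 1L, i, j, j + arm - 1L,
                                       arm, j - i - 1L, mm)
      }
    }
  }
  empty <- data.frame(seq_id = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), arm_len = integer(),
                      loop_len = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  m <- do.call(rbind, hits)
  df <- data.frame(seq_id = seqId, left_start = m[, 1L], left_end = m[, 2L],
                   right_start = m[, 3L], right_end = m[, 4L],
                   arm_len = m[, 5L], loop_len = m[, 6L],
                   mismatches = m[, 7L], stringsAsFactors = FALSE)
  df <- unique(df)
  .suppressContainedIRs(df)
}

## drop hits whose both arms are contained in another hit's arms with
## no fewer mismatches allowed (<= same mismatches in the container)
.suppressContainedIRs <- function(df) {
  n <- nrow(df)
  if (n <= 1L) return(df)
  keep <- rep(TRUE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b || !keep[a]) next
      contained <- df$left_start[a] >= df$left_start[b] &&
        df$left_end[a] <= df$left_end[b] &&
        df$right_start[a] >= df$right_start[b] &&
        df$right_end[a] <= df$right_end[b] &&
        df$arm_len[a] < df$arm_len[b]
      if (contained && df$mismatches[b] <= df$mismatches[a]) keep[a] <- FALSE
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find the most conserved fixed-length window across homologs
#'
#' For every `window`-length subsequence of the reference, computes the
#' best Hamming identity of that window against all offsets of each
#' homolog (both strands, substitutions only), and returns the window
#' maximizing the mean identity over homologs; ties go to the leftmost
#' window.  This is the alignment-free analogue of spotting a conserved
#' core in a cross-element comparison of intergenic regions.
#'
#' @param reference reference sequence (character, DNAString or
#'   [GenomeRecord]).
#' @param homologs character vector (or list) of homolog sequences; each
#'   must be at least `window` long (shorter homologs are an error, not a
#'   partial overlap).
#' @param window window length (default 20).
#' @return list: `start`, `end`, `window`, `mean_identity`,
#'   `per_homolog` (named numeric of best identities for the returned
#'   window).
#' @export
findConservedWindow <- function(reference, homologs, window = 20) {
  window <- as.integer(window)
  ref <- if (is(reference, "GenomeRecord")) asSeqChar(recordSeq(reference))
  else asSeqChar(reference)
  homologs <- vapply(as.list(homologs), asSeqChar, character(1L))
  if (!length(homologs)) stop("at least one homolog is required")
  if (window > nchar(ref)) stop("window exceeds the reference length")
  short <- which(nchar(homologs) < window)
  if (length(short))
    stop("homolog(s) ", paste(short, collapse = ", "),
         " are shorter than the window (", window, " bp)")
  refInt <- utf8ToInt(ref)
  nw <- nchar(ref) - window + 1L
  refWin <- .windowMatrix(refInt, window)          # window x nw
  best <- matrix(0, nrow = nw, ncol = length(homologs))
  for (h in seq_along(homologs)) {
    for (s in c(homologs[h], revComp(homologs[h]))) {
      hw <- .windowMatrix(utf8ToInt(s), window)    # window x nh
      for (i in seq_len(nw)) {
        ident <- colSums(hw == refWin[, i]) / window
        best[i, h] <- max(best[i, h], max(ident))
      }
    }
  }
  meanId <- rowMeans(best)
  i <- which.max(meanId)                           # leftmost on ties
  per <- best[i, ]
  names(per) <- if (!is.null(names(homologs)) && any(nzchar(names(homologs))))
    names(homologs) else paste0("homolog", seq_along(homologs))
  list(start = as.integer(i), end = as.integer(i + window - 1L),
       window = window, mean_identity = meanId[i], per_homolog = per)
}

.windowMatrix <- function(intseq, w) {
  n <- length(intseq) - w + 1L
  m <- embed(intseq, w)[, w:1, drop = FALSE]       # n x w, rows = windows
  t(m)
}

#' Classify deletion constructs by the features they retain
#'
#' A construct retains a feature iff the feature interval is entirely
#' inside the union of the construct's retained intervals.  The
#' functional rule distilled from the deletion series: transfer requires
#' the conserved 20-bp core (`conserved20`) and the innermost inverted
#' repeat (`REPT1`); constructs keeping both but lacking `REPT2` are
#' `attenuated` (transfer drops about two orders of magnitude but stays
#' detectable); everything else is `nonfunctional`.
#'
#' @param constructs data.frame with columns `name`, `start`, `end`
#'   (multiple rows with the same name form a multi-interval construct).
#' @param features data.frame with columns `label` (or `name`), `start`,
#'   `end`; must include `conserved20` and `REPT1` (and `REPT2` for the
#'   attenuation call).
#' @return data.frame: `name`, one logical `retains_<label>` column per
#'   feature, `predicted_class` in functional/attenuated/nonfunctional,
#'   `transfers` (TRUE for functional and attenuated).
#' @export
classifyConstructs <- function(constructs, features) {
  if (!"label" %in% names(features)) {
    if ("name" %in% names(features)) features$label <- features$name
    else stop("features need a 'label' (or 'name') column")
  }
  required <- c("conserved20", "REPT1", "REPT2")
  missing <- setdiff(required, features$label)
  if (length(missing))
    stop("classification rule needs feature label(s): ",
         paste(missing, collapse = ", "))
  featIR <- IRanges::IRanges(start = features$start, end = features$end)
  names(featIR) <- features$label
  out <- lapply(unique(constructs$name), function(nm) {
    rows <- constructs[constructs$name == nm, , drop = FALSE]
    kept <- IRanges::reduce(IRanges::IRanges(start = rows$start, end = rows$end))
    retains <- vapply(seq_along(featIR), function(i) {
      gap <- BiocGenerics::setdiff(featIR[i], kept)
      length(gap) == 0L
    }, logical(1L))
    names(retains) <- names(featIR)
    core <- retains[["conserved20"]] && retains[["REPT1"]]
    cls <- if (!core) "nonfunctional"
    else if (retains[["REPT2"]]) "functional" else "attenuated"
    df <- data.frame(name = nm, stringsAsFactors = FALSE)
    for (lab in names(retains)) df[[paste0("retains_", lab)]] <- retains[[lab]]
    df$predicted_class <- cls
    df$transfers <- cls %in% c("functional", "attenuated")
    df
  })
  do.call(rbind, out)
}

#' Minimal essential region from a deletion series
#'
#' Intersects the retained intervals of all transfer-competent constructs;
#' the result is the interval whose retention is (within the series)
#' necessary and sufficient for function.  Errors if the intersection is
#' empty or non-contiguous, and warns if a nonfunctional construct fully
#' contains the result (which would contradict the rule).
#'
#' @param functional list (or single data.frame) of retained-interval
#'   data.frames (`start`, `end`; multiple rows form a union) of the
#'   functional constructs; order is irrelevant.
#' @param nonfunctional optional list of the same shape for the
#'   nonfunctional constructs, used only for the consistency warning.
#' @return list `start`, `end`, `length` (`end - start + 1`).
#' @export
essentialRegion <- function(functional, nonfunctional = list()) {
  asIR <- function(df) IRanges::reduce(IRanges::IRanges(start = df$start,
                                                        end = df$end))
  if (is.data.frame(functional)) functional <- list(functional)
  if (is.data.frame(nonfunctional)) nonfunctional <- list(nonfunctional)
  if (!length(functional)) stop("at least one functional construct is required")
  acc <- asIR(functional[[1L]])
  for (df in functional[-1L]) {
    acc <- BiocGenerics::intersect(acc, asIR(df))
    if (!length(acc)) stop("functional constructs have an empty intersection")
  }
  if (length(acc) > 1L)
    stop("functional constructs intersect in a non-contiguous region")
  res <- list(start = BiocGenerics::start(acc), end = BiocGenerics::end(acc),
              length = BiocGenerics::width(acc))
  for (df in nonfunctional) {
    gap <- BiocGenerics::setdiff(acc, asIR(df))
    if (length(gap) == 0L)
      warning("a nonfunctional construct fully contains the essential region; ",
              "the deletion series is internally inconsistent")
  }
  res
}

#' Re-evaluate an inverted repeat after point mutations
#'
#' Applies substitutions to the sequence and recounts the arm mismatches
#' of the given inverted repeat.  Mutations applied symmetrically (both
#' arms, preserving complementarity) leave the mismatch count unchanged;
#' a single-arm substitution adds one mismatch.  `still_ir` is TRUE while
#' the recount stays within `tolerance` — the published observation being
#' that the repeat's presence, not its exact sequence, is what matters.
#'
#' @param seq DNA sequence the repeat lives on.
#' @param ir one row of [findInvertedRepeats()] output (data.frame or
#'   list with `left_start`, `left_end`, `right_start`, `right_end`).
#' @param mutations data.frame with columns `pos`, `base` (or a list of
#'   `c(pos, base)` pairs); empty for no mutations.
#' @param tolerance maximum arm mismatches still accepted as an inverted
#'   repeat (default 1).
#' @return list `still_ir` (logical), `arm_mismatches` (integer).
#' @export
irIntegrity <- function(seq, ir, mutations = NULL, tolerance = 1) {
  ch <- seqChars(seq)
  if (!is.null(mutations) && length(mutations)) {
    if (!is.data.frame(mutations))
      mutations <- do.call(rbind, lapply(mutations, function(m)
        data.frame(pos = as.integer(m[[1L]]), base = toupper(as.character(m[[2L]])),
                   stringsAsFactors = FALSE)))
    if (any(mutations$pos < 1L | mutations$pos > length(ch)))
      stop("mutation position outside the sequence")
    ch[mutations$pos] <- toupper(mutations$base)
  }
  left <- ch[ir$left_start:ir$left_end]
  right <- ch[ir$right_start:ir$right_end]
  rcRight <- rev(unname(.COMP[right]))
  mm <- sum(left != rcRight | is.na(rcRight))
  list(still_ir = mm <= tolerance, arm_mismatches = as.integer(mm))
}

#' Bundled deletion-series fixtures
#'
#' Loads the packaged deletion-construct boundaries (printed endpoints of
#' the oriT deletion series, with the published transfer phenotype) and
#' the stand-in feature coordinates consistent with them.
#'
#' @return list with data.frames `constructs` (name, start, end,
#'   transfers) and `features` (label, start, end).
#' @export
oritDeletionFixture <- function() {
  cpath <- system.file("extdata", "orit_constructs.tsv", package = "icemob",
                       mustWork = TRUE)
  fpath <- system.file("extdata", "orit_features_synthetic.tsv",
                       package = "icemob", mustWork = TRUE)
  list(constructs = utils::read.delim(cpath, stringsAsFactors = FALSE),
       features = utils::read.delim(fpath, stringsAsFactors = FALSE))
}
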