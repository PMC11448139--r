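#' @include excision-model.R
NULL

#' Relative quantification of excision from a raw qPCR panel
#'
#' Implements the internal-standard design of the excision assay: at each
#' timepoint the measured copies of every target are divided by the
#' copies of the normalizer (the primer set detecting both the integrated
#' and the excised element, i.e. total element copies), which cancels
#' differences in template DNA input; fold changes are then expressed
#' relative to the first timepoint, which is set to 1.
#'
#' The panel is scale-invariant: multiplying all raw values of one
#' timepoint by a constant changes nothing downstream.
#'
#' @param panel data.frame with columns `target`, `timepoint`, `value`
#'   (raw measured copies; all positive).
#' @param normalizer target name used as internal standard
#'   (default `set_c`).
#' @return the panel with added columns `normalized`
#'   (`value / normalizer value at the same timepoint`) and `fold_change`
#'   (`normalized / normalized at the first timepoint`), ordered by
#'   target then timepoint.
#' @export
quantifyExcision <- function(panel, normalizer = "set_c") {
  need <- c("target", "timepoint", "value")
  if (!all(need %in% names(panel)))
    stop("panel needs columns: ", paste(need, collapse = ", "))
  if (!normalizer %in% panel$target)
    stop("normalizer target '", normalizer, "' absent from the panel")
  if (any(!is.finite(panel$value) | panel$value <= 0))
    stop("all raw panel values must be positive")
  tps <- sort(unique(panel$timepoint))
  t0 <- tps[1L]
  normRow <- panel[panel$target == normalizer, , drop = FALSE]
  if (!all(tps %in% normRow$timepoint))
    stop("normalizer '", normalizer, "' must be measured at every timepoint")
  normAt <- stats::setNames(normRow$value, as.character(normRow$timepoint))
  panel$normalized <- panel$value / normAt[as.character(panel$timepoint)]
  base <- panel[panel$timepoint == t0, , drop = FALSE]
  if (!all(unique(panel$target) %in% base$target))
    stop("every target needs a measurement at the first timepoint (fold undefined otherwise)")
  baseAt <- stats::setNames(base$normalized, base$target)
  panel$fold_change <- panel$normalized / baseAt[panel$target]
  panel <- panel[order(panel$target, panel$timepoint), , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Simulate a qPCR excision panel from a template mixture sweep
#'
#' Generates raw qPCR measurements for a time course in which the
#' excised fraction changes: at each timepoint the integrated/attB/attP
#' template mixture is built at the given fraction, each primer set's
#' expected copies are the summed weights of the templates it amplifies
#' (from [predictAmplicons()]), scaled by a per-timepoint DNA input and
#' multiplicative log-normal noise with coefficient of variation
#' `noiseCV`.
#'
#' @param integrated [GenomeRecord] with att features.
#' @param fractions numeric vector of excised fractions, one per
#'   timepoint (timepoints are numbered `0, 1, ...`).
#' @param primers primer data.frame; default
#'   [designDiagnosticPrimers()] on `integrated`.
#' @param depth expected copies at input scale (default 1e6).
#' @param noiseCV multiplicative noise coefficient of variation
#'   (default 0.2, typical qPCR technical variability).
#' @param seed integer seed (child stream 2).
#' @return raw panel data.frame (`target`, `timepoint`, `value`) for
#'   [quantifyExcision()].
#' @export
simulateQpcrPanel <- function(integrated, fractions, primers = NULL,
                              depth = 1e6, noiseCV = 0.2, seed = 1) {
  if (is.null(primers)) primers <- designDiagnosticPrimers(integrated)
  set.seed(childSeed(seed, 2L))
  sdlog <- sqrt(log(1 + noiseCV^2))
  out <- list()
  for (t in seq_along(fractions)) {
    mix <- makeExcisionMixture(integrated, fractions[t])
    amp <- predictAmplicons(mix, primers)
    w <- stats::setNames(vapply(mix, `[[`, numeric(1L), "weight"),
                         vapply(mix, function(m) recordId(m$record), character(1L)))
    input <- depth * stats::rlnorm(1L, 0, sdlog)     # per-timepoint DNA amount
    for (p in unique(amp$primer_set)) {
      hit <- amp[amp$primer_set == p & !is.na(amp$product_length), , drop = FALSE]
      copies <- sum(w[hit$template])
      out[[length(out) + 1L]] <- data.frame(
        target = p, timepoint = t - 1L,
        value = copies * input * stats::rlnorm(1L, 0, sdlog),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Convert quantification-cycle values to relative copies
#'
#' Optional adapter for instruments reporting Cq: assuming amplification
#' efficiency 2 (perfect doubling per cycle), relative copies are
#' `2^(-Cq)` up to a common scale, which [quantifyExcision()] cancels.
#'
#' @param cq numeric Cq values.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return relative copy numbers.
#' @export
cqToCopies <- function(cq, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must exceed 1")
  efficiency^(-cq)
}
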