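#' @include AllClasses.R
NULL

#' Construct a simulation configuration
#'
#' @param hostLength host chromosome length in bp (default 3000).
#' @param iceLength element payload length in bp, excluding the two
#'   boundary repeat copies (default 8000).
#' @param attRepeat boundary direct repeat; the element studied here is
#'   flanked by the 9-bp repeat `GATTTTAAG` (default).
#' @param excisionFraction fraction of chromosomes in the excised state
#'   (default 1e-5, the baseline excision level of the uninduced element).
#' @param expressionWeights named non-negative numeric vector of
#'   per-feature sampling weights for read simulation; empty (default)
#'   means fragments are drawn uniformly from the whole template.
#' @param readLength read length in nt (default 75; must be >= 21 for the
#'   seed mapper downstream).
#' @param insertMean,insertSd mean and sd of the fragment end-to-end
#'   length in bp (defaults 300 and 50).
#' @param nPairs number of read pairs to simulate (default 1000).
#' @param seed integer root seed (default 1).
#' @param errorRate per-base substitution error rate (default 0).
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(hostLength = 300, iceLength = 1000, seed = 7)
#' cfg
#' @export
SimConfig <- function(hostLength = 3000,
                      iceLength = 8000,
                      attRepeat = "GATTTTAAG",
                      excisionFraction = 1e-5,
                      expressionWeights = numeric(),
                      readLength = 75,
                      insertMean = 300,
                      insertSd = 50,
                      nPairs = 1000,
                      seed = 1,
                      errorRate = 0) {
  new("SimConfig",
      hostLength = as.integer(hostLength),
      iceLength = as.integer(iceLength),
      attRepeat = toupper(as.character(attRepeat)),
      excisionFraction = as.numeric(excisionFraction),
      expressionWeights = expressionWeights,
      readLength = as.integer(readLength),
      insertMean = as.numeric(insertMean),
      insertSd = as.numeric(insertSd),
      nPairs = as.integer(nPairs),
      seed = as.integer(seed),
      errorRate = as.numeric(errorRate))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: host", object@hostLength, "bp + element", object@iceLength,
      "bp (repeat", object@attRepeat, ")\n")
  cat("  excised fraction", object@excisionFraction,
      "| reads", object@nPairs, "x", object@readLength, "nt, insert",
      object@insertMean, "+/-", object@insertSd,
      "| seed", object@seed, "\n")
  if (length(object@expressionWeights)) {
    cat("  expression weights:",
        paste(names(object@expressionWeights), object@expressionWeights,
              sep = "=", collapse = ", "), "\n")
  }
})
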