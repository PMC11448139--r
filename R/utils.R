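## Internal low-level helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## random DNA as a plain character string (uses the current RNG stream)
randomDNA <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

## coerce DNAString / character to an upper-case character scalar
asSeqChar <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  toupper(as.character(x)[1L])
}

## reverse complement of a character string, N-safe
revComp <- function(x) {
  vapply(as.character(x), function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

## split into a character vector of single bases
seqChars <- function(x) strsplit(asSeqChar(x), "", fixed = TRUE)[[1L]]

## Hamming distance between two equal-length strings
hamming <- function(a, b) {
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  stopifnot(length(ai) == length(bi))
  sum(ai != bi)
}

## Child seeds: one root seed, children derived per operation in a fixed,
## documented order (offset 0 = genome assembly, 1 = read simulation,
## 2 = qPCR noise, 3 = homolog generation).  Kept below 2^31.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset * 7919) %% 2147483629)
}

## all start positions of `pattern` in `subject` (exact, overlapping);
## plain-string fallback used where Biostrings objects are not in play
allStarts <- function(pattern, subject) {
  lp <- nchar(pattern)
  if (lp == 0L || lp > nchar(subject)) return(integer())
  hits <- integer()
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (i == -1L) break
    hits <- c(hits, from + as.integer(i) - 1L)
    from <- from + as.integer(i)
    if (from > nchar(subject) - lp + 1L) break
  }
  hits
}
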