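test_that("the planted 9-bp boundary repeat is recovered exactly", {
  cfg <- SimConfig(hostLength = 300, iceLength = 1000, seed = 1)
  g <- makeIntegratedGenome(cfg)
  ft <- featureTable(g)
  hint <- c(ft$start[ft$kind == "attL"], ft$end[ft$kind == "attR"])
  br <- detectBoundaryRepeat(g, elementHint = hint)
  expect_identical(br$repeat_seq, "GATTTTAAG")
  expect_identical(br$length, 9L)
  expect_identical(br$attL, c(ft$start[ft$kind == "attL"],
                              ft$end[ft$kind == "attL"]))
  ## a hint-free genome-wide scan returns the longest maximal pair, which
  ## on a random host background may be a chance repeat at least as long
  br2 <- detectBoundaryRepeat(g)
  expect_gte(br2$length, 9L)
  expect_identical(substr(as.character(recordSeq(g)), br2$attL[1], br2$attL[2]),
                   br2$repeat_seq)
  expect_identical(substr(as.character(recordSeq(g)), br2$attR[1], br2$attR[2]),
                   br2$repeat_seq)
})

test_that("repeat detection is maximal and fails cleanly without repeats", {
  ## a 12-bp flanking repeat must come back whole, not as a 9-mer
  cfg <- SimConfig(hostLength = 300, iceLength = 800,
                   attRepeat = "GATTTTAAGCCT", seed = 2)
  g <- makeIntegratedGenome(cfg)
  ft <- featureTable(g)
  br <- detectBoundaryRepeat(g, elementHint = c(ft$start[ft$kind == "attL"],
                                                ft$end[ft$kind == "attR"]))
  expect_identical(br$repeat_seq, "GATTTTAAGCCT")
  expect_identical(br$length, 12L)
  ## a sequence verified to share no 6-mer twice gives an error
  set.seed(80)
  repeat {
    s <- randomDNAStr(70)
    kmers <- substring(s, 1:65, 6:70)
    if (!anyDuplicated(kmers)) break
  }
  expect_error(detectBoundaryRepeat(s), "no direct repeat")
})

test_that("excision conserves length and reconstitutes on integration", {
  cfg <- SimConfig(hostLength = 300, iceLength = 1000, seed = 1)
  g <- makeIntegratedGenome(cfg)
  p <- excise(g)
  circle <- attPCircle(p); chrom <- attBChromosome(p)
  expect_identical(recordLength(circle), 1009L)   # repeat + payload
  expect_identical(recordLength(chrom), 309L)     # host + one repeat copy
  expect_identical(recordLength(circle) + recordLength(chrom),
                   recordLength(g))
  expect_true(isCircularRecord(circle))
  expect_identical(boundaryRepeat(p), "GATTTTAAG")
  ## attB junction is host-left + repeat + host-right
  s <- as.character(recordSeq(g))
  expect_identical(as.character(recordSeq(chrom)),
                   paste0(substr(s, 1, 150), "GATTTTAAG",
                          substr(s, 1169, 1318)))
  ## each product carries exactly one copy of the repeat
  expect_identical(length(gregexpr("GATTTTAAG",
                                   as.character(recordSeq(circle)),
                                   fixed = TRUE)[[1]]), 1L)
  expect_identical(length(gregexpr("GATTTTAAG",
                                   as.character(recordSeq(chrom)),
                                   fixed = TRUE)[[1]]), 1L)
  ## round trip is byte-identical, features included
  g2 <- integrateICE(circle, chrom)
  expect_identical(as.character(recordSeq(g2)), s)
  f1 <- featureTable(g); f2 <- featureTable(g2)
  expect_identical(f1[order(f1$name), ], f2[order(f2$name), ],
                   ignore_attr = TRUE)
  ## mismatched att sequences are not a recombination substrate
  expect_error(excise(g, attL = c(151, 159), attR = c(200, 208)),
               "differ")
})

test_that("length conservation holds across random fixtures", {
  for (seed in 1:5) {
    cfg <- SimConfig(hostLength = 200 + 37 * seed, iceLength = 500 + 91 * seed,
                     seed = seed)
    g <- makeIntegratedGenome(cfg)
    p <- excise(g)
    expect_identical(recordLength(attPCircle(p)) +
                       recordLength(attBChromosome(p)), recordLength(g))
    g2 <- integrateICE(attPCircle(p), attBChromosome(p))
    expect_identical(as.character(recordSeq(g2)), as.character(recordSeq(g)))
  }
})

test_that("integration into a different host shifts features predictably", {
  cfg <- SimConfig(hostLength = 400, iceLength = 1200, seed = 3)
  g <- makeIntegratedGenome(cfg)
  p <- excise(g)
  circle <- attPCircle(p)
  ## a fresh host with one attB copy planted at position 101
  set.seed(81)
  host <- GenomeRecord("host2", randomDNAStr(700))
  host <- plantFeature(host, boundaryRepeat(p), 101, "attB", kind = "attB")
  res <- integrateICE(circle, host)
  expect_identical(recordLength(res), 700L + recordLength(circle))
  ## element features land at attB_start - 1 + circle coordinate
  cft <- featureTable(circle)
  rft <- featureTable(res)
  xisC <- cft[cft$name == "xis", ]
  xisR <- rft[rft$name == "xis", ]
  expect_identical(xisR$start, 101L - 1L + xisC$start)
  expect_identical(xisR$end, 101L - 1L + xisC$end)
  ## attL/attR recreated around the element
  expect_identical(rft$start[rft$kind == "attL"], 101L)
  expect_identical(rft$start[rft$kind == "attR"],
                   101L + recordLength(circle))
  ## repeat mismatch is an error
  bad <- plantFeature(GenomeRecord("bad", randomDNAStr(300)),
                      "TTTTTTTTT", 50, "attB", kind = "attB")
  expect_error(integrateICE(circle, bad), "differ")
})

test_that("diagnostic primer sets reproduce the excision-assay logic", {
  cfg <- SimConfig(hostLength = 2000, iceLength = 8000, seed = 5)
  g <- makeIntegratedGenome(cfg)
  primers <- designDiagnosticPrimers(g)
  mix <- makeExcisionMixture(g, 0.5)
  amp <- predictAmplicons(mix, primers)
  hit <- function(tmpl, set) {
    row <- amp[grepl(tmpl, amp$template) & amp$primer_set == set, ]
    !is.na(row$product_length)
  }
  ## set a: circle only; set b: attB chromosome only; set c: integrated + circle
  expect_false(hit("integrated_host$", "set_a"))
  expect_false(hit("attB", "set_a"))
  expect_true(hit("attP", "set_a"))
  expect_false(hit("integrated_host$", "set_b"))
  expect_true(hit("attB", "set_b"))
  expect_false(hit("attP", "set_b"))
  expect_true(hit("integrated_host$", "set_c"))
  expect_false(hit("attB", "set_c"))
  expect_true(hit("attP", "set_c"))
  ## the attP product spans the circle junction: longer than the distance
  ## of the primer sites to the junction on either side alone
  aRow <- amp[grepl("attP", amp$template) & amp$primer_set == "set_a", ]
  expect_false(aRow$nonspecific)
  expect_lte(aRow$product_length, primers$max_product[1])
  ## primers below 15 nt are refused
  short <- primers; short$fwd[1] <- "ACGTACGTAC"
  expect_error(predictAmplicons(mix, short), "15 nt")
})

test_that("multiple products on one template are flagged nonspecific", {
  set.seed(82)
  core <- randomDNAStr(500)
  fwd <- substr(core, 51, 70)
  rev <- revCompStr(substr(core, 181, 200))
  dup <- paste0(core, substr(core, 41, 220))   # duplicated amplicon region
  t1 <- GenomeRecord("t1", dup)
  amp <- predictAmplicons(list(t1), data.frame(name = "p", fwd = fwd,
                                               rev = rev, max_product = 400))
  expect_identical(amp$n_products, 2L)
  expect_true(amp$nonspecific)
})
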