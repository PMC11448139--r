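test_that("a constructed palindrome is found and poly-A is empty", {
  ir <- findInvertedRepeats("GGGGCCAATTNNNNAATTGGCCCC", minArm = 8,
                            maxLoop = 10, maxMismatch = 0)
  expect_identical(nrow(ir), 1L)
  expect_gte(ir$arm_len, 8L)
  expect_identical(ir$mismatches, 0L)
  expect_identical(revCompStr(substr("GGGGCCAATTNNNNAATTGGCCCC",
                                     ir$right_start, ir$right_end)),
                   substr("GGGGCCAATTNNNNAATTGGCCCC",
                          ir$left_start, ir$left_end))
  expect_identical(nrow(findInvertedRepeats(strrep("A", 100), minArm = 4,
                                            maxLoop = 8, maxMismatch = 0)), 0L)
  expect_error(findInvertedRepeats("ACGT", minArm = 2), "minArm")
})

test_that("inverted-repeat scan equals the exhaustive oracle", {
  set.seed(71)
  for (rep in 1:3) {
    s <- randomDNAStr(300)
    for (mm in 0:1) {
      got <- findInvertedRepeats(s, minArm = 5, maxLoop = 6, maxMismatch = mm)
      want <- naiveIRScan(s, minArm = 5, maxLoop = 6, maxMm = mm)
      cols <- c("left_start", "left_end", "right_start", "right_end",
                "arm_len", "loop_len", "mismatches")
      key <- function(d) if (is.null(d) || !nrow(d)) character() else
        sort(do.call(paste, d[cols]))
      expect_identical(key(got), key(want))
    }
  }
})

test_that("inverted-repeat results mirror under reverse complement", {
  set.seed(72)
  s <- randomDNAStr(250)
  L <- nchar(s)
  fwd <- findInvertedRepeats(s, minArm = 4, maxLoop = 8, maxMismatch = 0)
  rev <- findInvertedRepeats(revCompStr(s), minArm = 4, maxLoop = 8,
                             maxMismatch = 0)
  mirror <- data.frame(left_start = L - rev$right_end + 1L,
                       left_end = L - rev$right_start + 1L,
                       right_start = L - rev$left_end + 1L,
                       right_end = L - rev$left_start + 1L)
  key <- function(d) sort(paste(d$left_start, d$left_end,
                                d$right_start, d$right_end))
  expect_identical(key(fwd), key(mirror))
})

test_that("conserved-window search maximizes mean best-offset identity", {
  set.seed(73)
  ref <- randomDNAStr(120)
  ## identical homologs: perfect identity, leftmost window wins the tie
  cw <- findConservedWindow(ref, c(ref, ref), window = 20)
  expect_identical(cw$start, 1L)
  expect_equal(cw$mean_identity, 1)
  ## corrupt the left half of one homolog: the window moves right
  hom <- paste0(randomDNAStr(60), substr(ref, 61, 120))
  cw2 <- findConservedWindow(ref, hom, window = 20)
  expect_gte(cw2$start, 61L)
  expect_equal(cw2$mean_identity, 1)
  ## identity values equal a brute-force all-offsets maximum
  hom2 <- makeOriTHomologs(ref, n = 1, divergence = 0.4,
                           protect = c(41, 60), seed = 5)
  cw3 <- findConservedWindow(ref, hom2, window = 12)
  brute <- 0
  for (s in c(hom2, revCompStr(hom2))) {
    for (j in seq_len(nchar(s) - 11)) {
      w1 <- strsplit(substr(ref, cw3$start, cw3$start + 11), "")[[1]]
      w2 <- strsplit(substr(s, j, j + 11), "")[[1]]
      brute <- max(brute, mean(w1 == w2))
    }
  }
  expect_equal(unname(cw3$per_homolog[1]), brute)
  ## homologs shorter than the window are an error, not a partial match
  expect_error(findConservedWindow(ref, "ACGTACGT", window = 20), "shorter")
})

test_that("deletion constructs are classified by retained features", {
  fx <- oritDeletionFixture()
  cls <- classifyConstructs(fx$constructs, fx$features)
  ## the printed series: transfer iff conserved core + innermost repeat kept
  lab <- setNames(cls$transfers, cls$name)
  want <- setNames(fx$constructs$transfers == "yes", fx$constructs$name)
  expect_identical(lab[names(want)], want)
  ## the three-way classes behind the binary labels
  expect_identical(cls$predicted_class[cls$name == "del4"], "functional")
  expect_identical(cls$predicted_class[cls$name == "del8"], "nonfunctional")
  expect_identical(cls$predicted_class[cls$name == "del7"], "attenuated")
  expect_identical(cls$predicted_class[cls$name == "del17"], "nonfunctional")
  expect_identical(cls$predicted_class[cls$name == "del25"], "attenuated")
  expect_error(classifyConstructs(fx$constructs,
                                  data.frame(label = "x", start = 1, end = 2)),
               "conserved20")
})

test_that("classification is monotone in the retained interval", {
  fx <- oritDeletionFixture()
  rank <- c(nonfunctional = 0, attenuated = 1, functional = 2)
  set.seed(74)
  for (i in 1:20) {
    s <- sample(1:400, 1); e <- s + sample(20:60, 1)
    small <- data.frame(name = "c", start = s, end = e)
    big <- data.frame(name = "c", start = max(1, s - 40), end = e + 60)
    cs <- classifyConstructs(small, fx$features)$predicted_class
    cb <- classifyConstructs(big, fx$features)$predicted_class
    expect_gte(rank[[cb]], rank[[cs]])
  }
})

test_that("essential region is the order-invariant intersection", {
  a <- data.frame(start = 261, end = 393)
  b <- data.frame(start = 1, end = 318)
  er <- essentialRegion(list(a, b))
  expect_identical(er$start, 261L)
  expect_identical(er$end, 318L)
  expect_identical(er$length, 58L)
  expect_identical(essentialRegion(list(b, a)), er)
  expect_identical(essentialRegion(list(a)),
                   list(start = 261L, end = 393L, length = 133L))
  expect_error(essentialRegion(list(data.frame(start = 1, end = 50),
                                    data.frame(start = 100, end = 150))),
               "empty intersection")
  expect_warning(essentialRegion(list(a, b),
                                 nonfunctional = list(data.frame(start = 200,
                                                                 end = 400))),
                 "inconsistent")
})

test_that("repeat integrity survives complement-preserving mutations", {
  ## perfect 8-bp-arm inverted repeat with a 2-bp loop
  arm <- "GCTAGGCA"
  s <- paste0("AAAA", arm, "TT", revCompStr(arm), "AAAA")
  ir <- findInvertedRepeats(s, minArm = 8, maxLoop = 4, maxMismatch = 0)[1, ]
  expect_identical(irIntegrity(s, ir)$arm_mismatches, 0L)
  ## symmetric substitution keeps complementarity: position 5 (left arm G)
  ## and its partner both flipped
  lpos <- ir$left_start; rpos <- ir$right_end
  sym <- data.frame(pos = c(lpos, rpos), base = c("T", "A"))
  r1 <- irIntegrity(s, ir, sym)
  expect_identical(r1$arm_mismatches, 0L)
  expect_true(r1$still_ir)
  ## one single-arm substitution: one mismatch in the eight, still an IR
  mut <- data.frame(pos = lpos + 2, base = setdiff(c("A", "C", "G", "T"),
                                                   substr(s, lpos + 2,
                                                          lpos + 2))[1])
  r2 <- irIntegrity(s, ir, mut, tolerance = 1)
  expect_identical(r2$arm_mismatches, 1L)
  expect_true(r2$still_ir)
  expect_false(irIntegrity(s, ir, mut, tolerance = 0)$still_ir)
  expect_error(irIntegrity(s, ir, data.frame(pos = 999, base = "A")),
               "outside")
})
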