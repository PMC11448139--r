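test_that("a unique placement gives the exact span and distance", {
  set.seed(41)
  g <- randomDNAStr(3000)
  idx <- buildKmerIndex(g)
  r1 <- substr(g, 1001, 1075)
  r2 <- revCompStr(substr(g, 1426, 1500))
  res <- mapPair(idx, r1, r2)
  expect_identical(res$status, "mapped")
  expect_identical(res$span_start, 1001L)
  expect_identical(res$span_end, 1500L)
  expect_identical(res$distance, 500L)
  ## swapping the mates (read1 on the minus strand) maps identically
  res2 <- mapPair(idx, r2, r1)
  expect_identical(res2[, c("status", "span_start", "span_end", "distance")],
                   res[, c("status", "span_start", "span_end", "distance")])
})

test_that("the shortest of several distance-valid placements is selected", {
  set.seed(43)
  g <- randomDNAStr(2000)
  site <- substr(g, 201, 250)
  substr(g, 951, 1000) <- site          # second copy of the mate-2 site
  idx <- buildKmerIndex(g)
  r1 <- substr(g, 101, 150)
  r2 <- revCompStr(site)
  res <- mapPair(idx, r1, r2)
  expect_identical(res$status, "mapped")
  expect_identical(res$n_candidates, 2L)
  expect_identical(res$distance, 150L)  # 900 bp placement rejected as longer
  expect_identical(res$span_start, 101L)
  expect_identical(res$span_end, 250L)
  want <- oracleMapPair(g, r1, r2)
  expect_identical(res$status, want$status)
  expect_identical(res$distance, want$distance)
})

test_that("distance bounds and identity rule produce the right statuses", {
  set.seed(44)
  g <- randomDNAStr(3000)
  idx <- buildKmerIndex(g)
  ## only placement is 2550 bp end to end
  res <- mapPair(idx, substr(g, 101, 150), revCompStr(substr(g, 2601, 2650)))
  expect_identical(res$status, "distance_violation")
  expect_identical(res$n_candidates, 0L)
  ## a single seed mismatch defeats the 100%-identity rule
  r1 <- substr(g, 101, 150)
  ch <- substr(r1, 5, 5)
  substr(r1, 5, 5) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  res2 <- mapPair(idx, r1, revCompStr(substr(g, 301, 350)))
  expect_identical(res2$status, "unmapped")
  ## reads shorter than the seed are rejected by name
  expect_error(mapPair(idx, substr(g, 1, 10), substr(g, 101, 150)), "read 1")
})

test_that("identical-copy placements tie and come back ambiguous", {
  set.seed(45)
  core <- randomDNAStr(1200)
  g <- paste0(core, substr(core, 101, 700))   # duplicated 600 bp block
  idx <- buildKmerIndex(g)
  r1 <- substr(core, 201, 250)
  r2 <- revCompStr(substr(core, 451, 500))    # fragment inside the dup block
  res <- mapPair(idx, r1, r2)
  expect_identical(res$status, "ambiguous")
  expect_gte(res$n_candidates, 2L)
  expect_identical(oracleMapPair(g, r1, r2)$status, "ambiguous")
})

test_that("mapper equals the brute-force oracle on mixed read sets", {
  set.seed(47)
  for (rep in 1:5) {
    core <- randomDNAStr(1500 + rep * 100)
    g <- if (rep %% 2 == 0) paste0(core, substr(core, 201, 800)) else core
    rec <- GenomeRecord(paste0("g", rep), g)
    idx <- buildKmerIndex(rec)
    cfg <- SimConfig(nPairs = 40, readLength = 40, insertMean = 180,
                     insertSd = 60, seed = 100 + rep)
    sr <- simulateReadPairs(rec, cfg)
    s1 <- as.character(mateReads(sr, 1)); s2 <- as.character(mateReads(sr, 2))
    ## plus reads that are not from the genome at all
    s1 <- c(s1, replicate(10, randomDNAStr(40)))
    s2 <- c(s2, replicate(10, randomDNAStr(40)))
    got <- mapPairs(idx, s1, s2)
    for (i in seq_along(s1)) {
      want <- oracleMapPair(g, s1[i], s2[i])
      expect_identical(got$status[i], want$status)
      expect_identical(got$span_start[i], want$span_start)
      expect_identical(got$span_end[i], want$span_end)
      expect_identical(got$distance[i], want$distance)
      expect_identical(got$n_candidates[i], want$n_candidates)
    }
  }
})

test_that("error-free in-range fragments always map back to their truth", {
  cfg <- SimConfig(hostLength = 2000, iceLength = 6000, seed = 13,
                   nPairs = 300, readLength = 40, insertMean = 150,
                   insertSd = 40)
  g <- makeIntegratedGenome(cfg)
  sr <- simulateReadPairs(g, cfg)
  res <- mapPairs(buildKmerIndex(g), sr)
  tt <- truthTable(sr)
  ok <- res$status == "mapped"
  expect_gt(mean(ok), 0.99)
  expect_identical(res$span_start[ok], tt$start[ok])
  expect_identical(res$span_end[ok], tt$end[ok])
  ## widening the distance window never loses mapped pairs
  narrow <- mapPairs(buildKmerIndex(g), sr, minDist = 100, maxDist = 300)
  expect_lte(sum(narrow$status == "mapped"), sum(res$status == "mapped"))
})

test_that("span counting follows the >=1 bp overlap rule", {
  feats <- data.frame(name = c("left", "right", "far", "rrn"),
                      start = c(900, 1200, 5000, 7000),
                      end = c(1100, 1600, 5500, 7500),
                      kind = "gene")
  res <- data.frame(pair_id = c("p1", "p2", "p3"),
                    status = c("mapped", "mapped", "ambiguous"),
                    span_start = c(1001, 7001, 5000),
                    span_end = c(1500, 7400, 5400),
                    distance = c(500, 400, 401), n_candidates = c(1, 1, 2))
  ct <- countSpans(res, feats, reference = "rrn")
  expect_identical(ct$count[ct$feature == "left"], 1L)   # 1001-1100 overlap
  expect_identical(ct$count[ct$feature == "right"], 1L)  # 1200-1500 overlap
  expect_identical(ct$count[ct$feature == "far"], 0L)    # ambiguous ignored
  expect_identical(ct$normalized[ct$feature == "rrn"], 1)
  ## empty input gives an all-zero table
  ct0 <- countSpans(res[0, ], feats)
  expect_true(all(ct0$count == 0L))
})

test_that("fold change is reference-normalized with infinities flagged", {
  a <- data.frame(feature = c("g", "rrn"), count = c(2L, 2L))
  b <- data.frame(feature = c("g", "rrn"), count = c(26L, 2L))
  expect_identical(foldChange(a, a, "rrn")$fold, c(1, 1))
  fc <- foldChange(a, b, "rrn")
  expect_identical(fc$fold[fc$feature == "g"], 13)
  z <- data.frame(feature = c("g", "rrn"), count = c(0L, 2L))
  fz <- foldChange(z, b, "rrn")
  expect_true(is.infinite(fz$fold[fz$feature == "g"]))
  expect_true(fz$infinite[fz$feature == "g"])
  bad <- data.frame(feature = c("g", "rrn"), count = c(5L, 0L))
  expect_error(foldChange(bad, b, "rrn"), "zero count")
})
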