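test_that("rank-sum exact enumeration matches hand example and wilcox.test", {
  rs <- rankSumTest(c(10, 12, 14), c(1, 2, 3))
  expect_equal(rs$rank_sum, 15)  # ranks 4,5,6
  expect_equal(rs$p, 0.1)        # 2/20 assignments as extreme
  expect_equal(rs$method, "exact")
  # tie-free random small cases against the independent implementation
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m)
    expect_equal(rankSumTest(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("rank-sum normal approximation matches wilcox.test with ties", {
  set.seed(12)
  for (i in 1:10) {
    x <- sample(1:6, 30, replace = TRUE)  # heavy ties
    y <- sample(2:7, 25, replace = TRUE)
    ours <- rankSumTest(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$method, "normal")
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact rank-sum handles ties via midrank enumeration", {
  # Monte-Carlo permutation oracle under ties
  set.seed(13)
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  rs <- rankSumTest(x, y)
  pool <- c(x, y)
  obs <- sum(rank(pool)[1:4])
  perm <- replicate(40000, {
    idx <- sample(8, 4)
    sum(rank(pool)[idx])
  })
  pLo <- mean(perm <= obs); pHi <- mean(perm >= obs)
  expect_equal(rs$p, min(1, 2 * min(pLo, pHi)), tolerance = 0.02)
})

test_that("rank-sum p is well-calibrated under the null", {
  set.seed(14)
  ps <- replicate(200, rankSumTest(rnorm(30), rnorm(30))$p)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("featureEnrichment compares classes against intergenic windows", {
  # 20 windows: gene body in windows 3..8 with high counts
  counts <- matrix(5L, nrow = 20, ncol = 2)
  counts[3:8, ] <- 50L
  hx <- make_hx(counts, c(chr1 = 3000), groups = c("CON", "HFD"))
  g <- GRanges("chr1", IRanges(301, 1200), strand = "+")
  mcols(g)$gene_id <- "G1"
  fs <- deriveFeatures(g, GRanges(), c(chr1 = 3000))
  ann <- annotateWindows(rowRanges(hx), fs)
  enr <- featureEnrichment(hx, ann, by = "group")
  gb <- enr[enr$class == "gene_body", ]
  expect_true(all(gb$mean_rpm > gb$intergenic_mean_rpm))
  expect_true(all(gb$p < 0.01))
  inter <- enr[enr$class == "intergenic", ]
  expect_true(all(is.na(inter$p)))  # no self-comparison
  expect_equal(sort(unique(enr$unit)), c("CON", "HFD"))
})

test_that("region-level enrichment averages windows within each region", {
  counts <- matrix(5L, nrow = 30, ncol = 2)
  counts[3:8, ] <- 50L   # G1 body; G2 body stays at background
  hx <- make_hx(counts, c(chr1 = 4500), groups = c("CON", "HFD"))
  g <- GRanges("chr1", IRanges(c(301, 2701), c(1200, 3300)),
               strand = c("+", "+"))
  mcols(g)$gene_id <- c("G1", "G2")
  fs <- deriveFeatures(g, GRanges(), c(chr1 = 4500))
  # two intergenic gaps: [1200,1700) and [3300,4500)
  expect_equal(length(featureRegions(fs, "intergenic")), 2L)
  enr <- suppressWarnings(
    featureEnrichment(hx, NULL, by = "group", level = "region",
                      features = fs))
  gb <- enr[enr$class == "gene_body" & enr$unit == "CON", ]
  expect_equal(gb$n_windows, 2L)  # two regions, not windows
  # G1 covers windows 3-8 exactly, so its region mean is their mean rpm
  expect_equal(mean(region_means <- c(mean(rpm(hx)[3:8, "s1"]),
                                      mean(rpm(hx)[19:22, "s1"]))),
               gb$mean_rpm, tolerance = 1e-9)
  expect_true(gb$mean_rpm > gb$intergenic_mean_rpm)
})

test_that("any-overlap counting mode multi-counts straddling fragments", {
  g <- buildWindowGrid(c(chr1 = 600), width = 150)
  r <- GRanges("chr1", IRanges(101, 250))  # BED [100,250): windows 1 and 2
  ov <- countReads(g, r, assign = "overlap")
  expect_equal(ov$counts, c(1L, 1L, 0L, 0L))
  expect_equal(countReads(g, r)$counts, c(0L, 1L, 0L, 0L))  # midpoint: one
})

test_that("input subtraction clamps at zero and preserves shape", {
  ip <- make_hx(matrix(c(10L, 40L, 10L, 20L, 80L, 20L), ncol = 2),
                c(chr1 = 450), groups = c("CON", "HFD"))
  input <- make_hx(matrix(c(20L, 20L, 20L), ncol = 1), c(chr1 = 450))
  corrected <- rpmMinusInput(ip, input)
  expect_equal(dim(corrected), dim(rpm(ip)))
  expect_true(all(corrected >= 0))
  # uniform input: the enriched middle window survives, the rest zero out
  expect_gt(corrected[2, 1], 0)
  expect_equal(unname(corrected[1, 1]), 0)
  expect_error(rpmMinusInput(ip, make_hx(matrix(1:4, ncol = 1),
                                         c(chr1 = 600))),
               "window grid")
})

test_that("metagene of a constant track is flat and equal to the value", {
  counts <- matrix(10L, nrow = 40, ncol = 1)  # one 6 kb chromosome
  hx <- make_hx(counts, c(chr1 = 6000))
  g <- GRanges("chr1", IRanges(start = 1801, end = 4200), strand = "+")
  mcols(g)$gene_id <- "G1"
  prof <- metageneProfile(hx, g, flankBp = 1500, bodyBins = 10)
  v <- 1e6 / 40
  expect_equal(prof$CON, rep(v, nrow(prof)), tolerance = 1e-9)
  expect_equal(nrow(prof), 10 + 2 * 10)
  expect_equal(unique(prof$bin_class[1:10]), "upstream")
})

test_that("metagene reverses minus-strand genes (strand symmetry)", {
  counts <- matrix(c(rep(2L, 12), rep(40L, 14), rep(2L, 14)), ncol = 1)
  hx <- make_hx(counts, c(chr1 = 6000))
  gPlus <- GRanges("chr1", IRanges(1801, 4200), strand = "+")
  mcols(gPlus)$gene_id <- "G1"
  gMinus <- gPlus; strand(gMinus) <- "-"
  pP <- metageneProfile(hx, gPlus, flankBp = 1500, bodyBins = 8)
  pM <- metageneProfile(hx, gMinus, flankBp = 1500, bodyBins = 8)
  expect_equal(pM$CON, rev(pP$CON), tolerance = 1e-9)
})

test_that("gene-body enrichment shows up as body > flank in the metagene", {
  cfg <- tiny_config(seed = 5, readsPerSample = 50000L)
  st <- simulateStudy(cfg)
  hx <- countWindows(buildWindowGrid(st$chromSizes), st$reads, st$samples)
  prof <- metageneProfile(hx, st$genes, by = "group")
  body <- prof$bin_class == "body"
  for (u in c("CON", "HFD")) {
    expect_gt(mean(prof[[u]][body]), mean(prof[[u]][!body]))
  }
  # genes shorter than bodyBins bp are excluded with a message
  shortG <- c(st$genes, GRanges("chr1", IRanges(1, 20), strand = "+",
                                gene_id = "tiny"))
  expect_message(metageneProfile(hx, shortG, bodyBins = 40L),
                 "1 gene\\(s\\) shorter")
})
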