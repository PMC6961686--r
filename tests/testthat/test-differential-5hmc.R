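test_that("gene-body score is the mean rpm over windows with midpoint inside", {
  counts <- matrix(0L, nrow = 10, ncol = 1)
  counts[3, ] <- 1L; counts[4, ] <- 3L  # rpm 250000 and 750000
  counts[1, ] <- 0L
  hx <- make_hx(counts, c(chr1 = 1500))
  g <- GRanges("chr1", IRanges(301, 600), strand = "+")  # windows 3 and 4
  mcols(g)$gene_id <- "G1"
  sc <- geneBodyScores(hx, g)
  expect_equal(unname(sc["G1", 1]), (250000 + 750000) / 2)
  # a sub-window gene not containing any window midpoint is excluded
  g2 <- c(g, GRanges("chr1", IRanges(1401, 1421), strand = "+",
                     gene_id = "short"))
  expect_message(sc2 <- geneBodyScores(hx, g2), "excluded")
  expect_equal(rownames(sc2), "G1")
})

test_that("scores match brute-force recomputation through count->rpm->mean", {
  cfg <- tiny_config(seed = 4, readsPerSample = 5000L)
  st <- simulateStudy(cfg)
  grid <- buildWindowGrid(st$chromSizes)
  hx <- countWindows(grid, st$reads, st$samples)
  sc <- geneBodyScores(hx, st$genes)
  s <- "HFD_2"
  raw <- bf_count(grid, st$reads[[s]])
  nr <- raw$counts / sum(raw$counts) * 1e6
  mid <- floor((start(grid) - 1 + end(grid)) / 2)
  for (gid in sample(rownames(sc), 5)) {
    gene <- st$genes[gid]
    inBody <- as.character(seqnames(grid)) == as.character(seqnames(gene)) &
      mid >= start(gene) - 1 & mid < end(gene)
    expect_equal(unname(sc[gid, s]), mean(nr[inBody]), tolerance = 1e-9)
  }
})

test_that("delta-5hmc is the group-mean difference and antisymmetric", {
  sc <- matrix(c(5, 3, 5, 1, 3, 2, 3, 4), nrow = 2,
               dimnames = list(c("g1", "g2"), c("a", "b", "c", "d")))
  samples <- data.frame(sample_id = c("a", "b", "c", "d"),
                        group = c("HFD", "HFD", "CON", "CON"))
  d <- delta5hmc(sc, samples, "HFD", "CON")
  expect_equal(d$delta_5hmc, c(mean(c(5, 5)) - mean(c(3, 3)),
                               mean(c(3, 1)) - mean(c(2, 4))))
  dSwap <- delta5hmc(sc, samples, "CON", "HFD")
  expect_equal(dSwap$delta_5hmc, -d$delta_5hmc)
  expect_error(delta5hmc(sc, samples, "HFD", "KETO"), "unknown group")
})

test_that("regression recovers an exact line and rejects degenerate x", {
  df <- data.frame(expr_log2fc = c(0, 1, 2), delta_5hmc = c(0, 1, 2))
  fit <- regressDeltaExpression(df)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 3L)
  expect_error(regressDeltaExpression(
    data.frame(expr_log2fc = c(1, 1, 1), delta_5hmc = 1:3)), "zero variance")
  expect_error(regressDeltaExpression(
    data.frame(expr_log2fc = 1:2, delta_5hmc = 1:2)), ">= 3")
})

test_that("shuffled x gives a uniform-ish regression p (permutation null)", {
  set.seed(21)
  x <- rnorm(100); y <- 2 * x + rnorm(100)
  ps <- replicate(100, {
    regressDeltaExpression(data.frame(expr_log2fc = sample(x),
                                      delta_5hmc = y))$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("z-scores standardise rows; identical samples merge at height 0", {
  sc <- matrix(c(1, 2, 3,
                 4, 6, 8), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        group = c("CON", "CON", "HFD"))
  cl <- zscoreCluster(sc, samples, k = 2)
  z <- zscoreMatrix(cl)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  # duplicate sample columns merge first at distance 0
  sc2 <- cbind(sc, a2 = sc[, "a"])
  samples2 <- rbind(samples, data.frame(sample_id = "a2", group = "CON"))
  cl2 <- zscoreCluster(sc2, samples2, k = 2)
  hc <- cl2@dendrogram
  expect_equal(hc$height[1], 0)
  first <- sort(colnames(zscoreMatrix(cl2))[-hc$merge[1, ]])
  expect_equal(first, c("a", "a2"))
  # zero-variance rows dropped; all-zero-variance is an error
  sc3 <- rbind(sc, g3 = c(7, 7, 7))
  cl3 <- zscoreCluster(sc3, samples)
  expect_equal(cl3@droppedGenes, "g3")
  expect_error(zscoreCluster(matrix(1, 2, 3,
                                    dimnames = list(c("x", "y"), samples$sample_id)),
                             samples), "zero variance")
})

test_that("adjustedRandIndex matches the independent igraph implementation", {
  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:4, 20, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b),
                 igraph::compare(a, b, method = "adjusted.rand"),
                 tolerance = 1e-12)
  }
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
})

test_that("topGenes ranks by |log2FC|, breaks ties by adj p then id", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                   log2fc = c(2, -3, 2, 1.5, 0.4),
                   adj_p = c(0.01, 0.001, 0.002, 0.2, 0.01))
  top <- topGenes(de, "induced", n = 2)
  expect_equal(top, c("g3", "g1"))  # tie on |fc|=2 -> lower adj p first
  expect_warning(topAll <- topGenes(de, "induced", n = 10),
                 "only 3 significant")
  expect_equal(topAll, c("g3", "g1", "g5"))  # g4 fails alpha
  expect_equal(topGenes(de, "suppressed", n = 1), "g2")
  # invariant to input row order
  set.seed(5)
  expect_equal(topGenes(de[sample(5), ], "induced", n = 2), top)
})

test_that("percent input follows the input-fraction-adjusted Ct formula", {
  expect_equal(percentInput(25, 25, 0.10), 10)   # equal Ct -> exactly 10%
  expect_equal(percentInput(20, 23, 0.10), 80)   # 2^3 / 10 * 100
  expect_equal(percentInput(25, 25, 0.05), 5)
  expect_error(percentInput(25, 25, 0), "inputFraction")
})

test_that("hMeDIP-qPCR analysis: fold change vs CON, ANOVA and Tukey", {
  set.seed(41)
  groups <- rep(c("CON", "HFD", "HFD-reversal"), each = 4)
  animals <- paste0("m", seq_along(groups))
  shift <- c(CON = 0, HFD = -1.5, `HFD-reversal` = -0.2)  # lower IP Ct = more
  ct <- data.frame(animal_id = animals, group = groups, locus = "Scd1_body",
                   ct_ip = 24 + shift[groups] + rnorm(12, 0, 0.15),
                   ct_input = 25 + rnorm(12, 0, 0.1))
  res <- hmedipQpcr(ct)
  conFold <- res$table$fold_vs_con[res$table$group == "CON"]
  expect_equal(mean(conFold), 1, tolerance = 1e-12)
  expect_gt(mean(res$table$fold_vs_con[res$table$group == "HFD"]), 2)
  # independent ANOVA oracle on the same numbers
  ref <- oneway.test(fold_vs_con ~ group, data = res$table,
                     var.equal = TRUE)
  expect_equal(res$tests$anova$p[1], ref$p.value, tolerance = 1e-10)
  expect_equal(res$tests$anova$F[1], unname(ref$statistic), tolerance = 1e-10)
  # independent Tukey oracle: studentized range by hand
  x <- res$table$fold_vs_con; g <- factor(res$table$group)
  mse <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / (12 - 3)
  means <- tapply(x, g, mean)
  q <- abs(means["HFD"] - means["CON"]) / sqrt(mse / 4)
  pHand <- 1 - ptukey(q, nmeans = 3, df = 9)
  tk <- res$tests$tukey
  expect_equal(tk$p_adj[tk$comparison == "HFD-CON"], unname(pHand),
               tolerance = 1e-10)
  # all-identical animals: fold changes 1, no real F statistic
  ct0 <- ct; ct0$ct_ip <- 24; ct0$ct_input <- 25
  res0 <- suppressWarnings(hmedipQpcr(ct0))
  expect_true(all(res0$table$fold_vs_con == 1))
  expect_equal(res0$tests$anova$F[1], 0)
  expect_true(all(res0$tests$tukey$p_adj == 1))
  # missing input Ct drops the row
  ctNA <- ct; ctNA$ct_input[1] <- NA
  expect_message(resNA <- hmedipQpcr(ctNA), "dropped")
  expect_equal(nrow(resNA$table), 11)
})

test_that("intergenic controls are size-matched and avoid features", {
  cfg <- tiny_config(seed = 6)
  gen <- simulateGenome(cfg)
  fs <- deriveFeatures(gen$genes, gen$enhancers, gen$chromSizes)
  ctrl <- intergenicControlRegions(fs, gen$genes, seed = 2)
  expect_equal(length(ctrl), length(gen$genes))
  ov <- countOverlaps(ctrl, featureRegions(fs, "gene_body"),
                      ignore.strand = TRUE) +
    countOverlaps(ctrl, featureRegions(fs, "enhancer"), ignore.strand = TRUE)
  expect_true(all(ov == 0))
})

test_that("dendrograms serialise to parseable Newick", {
  sc <- matrix(rnorm(40), nrow = 10,
               dimnames = list(paste0("g", 1:10), c("a", "b", "c", "d")))
  samples <- data.frame(sample_id = c("a", "b", "c", "d"),
                        group = c("CON", "CON", "HFD", "HFD"))
  cl <- zscoreCluster(sc, samples)
  f <- tempfile(fileext = ".nwk")
  writeNewick(cl, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("a", "b", "c", "d"))
})
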