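suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## small, fast simulation config for unit tests
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, nChroms = 1L, chromLength = 5e5, nGenes = 40L,
               readsPerSample = 20000L, nInduced = 6L, nSuppressed = 6L)
  args <- utils::modifyList(args, list(...))
  do.call(simConfig, args)
}

## build an HmcExperiment directly from a raw count matrix (for tests that
## need exact window values rather than sampled reads)
make_hx <- function(counts, chromSizes, groups = NULL, width = 150L) {
  grid <- buildWindowGrid(chromSizes, width = width)
  stopifnot(nrow(counts) == length(grid))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(groups)) groups <- rep("CON", ncol(counts))
  se <- SummarizedExperiment(
    assays = list(counts = counts, rpm = rpmNormalize(counts)),
    rowRanges = grid,
    colData = S4Vectors::DataFrame(group = groups,
                                   total_reads = as.integer(colSums(counts)),
                                   dropped_reads = 0L,
                                   row.names = colnames(counts)))
  as(se, "HmcExperiment")
}

## brute-force oracle: assign every read to every window by midpoint scan
bf_count <- function(grid, reads) {
  counts <- integer(length(grid))
  gchr <- as.character(seqnames(grid))
  gs0 <- start(grid) - 1L
  ge0 <- end(grid)
  rchr <- as.character(seqnames(reads))
  mid0 <- floor((start(reads) - 1 + end(reads)) / 2)
  dropped <- 0L
  for (i in seq_along(reads)) {
    hit <- which(gchr == rchr[i] & gs0 <= mid0[i] & mid0[i] < ge0)
    if (length(hit) == 1) counts[hit] <- counts[hit] + 1L
    else dropped <- dropped + 1L
  }
  list(counts = counts, dropped = dropped)
}

## brute-force Benjamini-Hochberg step-up: adj_i = min_{j >= i} m * p_(j) / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  adj
}

## random reads on a toy genome
random_reads <- function(n, chromSizes, seed) {
  set.seed(seed)
  chrom <- sample(names(chromSizes), n, replace = TRUE)
  mid <- floor(runif(n) * (chromSizes[chrom] - 400)) + 200
  len <- sample(100:400, n, replace = TRUE)
  s0 <- pmax(0, mid - len %/% 2)
  GRanges(chrom, IRanges(start = s0 + 1, width = len))
}
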