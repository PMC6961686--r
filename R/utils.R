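## Shared statistical primitives: Wilcoxon rank-sum with exact enumeration at
## small n, adjusted Rand index, one-way ANOVA + Tukey HSD wrapper, truncated
## normal sampling.

#' Wilcoxon rank-sum test of two samples
#'
#' Two-sided test of the rank-sum of `x` against `y`. For small groups (both
#' sizes <= `exactMax`) the null is enumerated exactly over all
#' choose(n+m, n) rank assignments, which remains valid under ties
#' (midranks). Larger groups use the normal approximation with the usual tie
#' correction and a 0.5 continuity correction.
#'
#' @param x,y numeric vectors.
#' @param exactMax enumerate exactly when both group sizes are <= this
#'   (default 8).
#' @return list with `rank_sum` (sum of midranks of `x`), `W` (Mann-Whitney
#'   statistic), `p` (two-sided), and `method` ("exact" or "normal").
#' @examples
#' rankSumTest(c(10, 12, 14), c(1, 2, 3))$p  # 0.1, exact
#' @export
rankSumTest <- function(x, y, exactMax = 8L) {
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  rs <- sum(r[seq_len(n)])
  W <- rs - n * (n + 1) / 2
  if (n <= exactMax && m <= exactMax) {
    sums <- combn(r, n, sum)
    pLo <- mean(sums <= rs + 1e-9)
    pHi <- mean(sums >= rs - 1e-9)
    p <- min(1, 2 * min(pLo, pHi))
    return(list(rank_sum = rs, W = W, p = p, method = "exact"))
  }
  N <- n + m
  mu <- n * (N + 1) / 2
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tieAdj)
  if (sigma2 <= 0) return(list(rank_sum = rs, W = W, p = 1, method = "normal"))
  z <- (rs - mu - sign(rs - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(rank_sum = rs, W = W, p = p, method = "normal")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and reference labels;
#' 1 means identical partitions, 0 is the chance expectation.
#'
#' @param a,b equal-length label vectors (any atomic type).
#' @return numeric scalar.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  nPairs <- comb2(length(a))
  expected <- sumI * sumJ / nPairs
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)  # both partitions trivial
  (sumIJ - expected) / (maxIdx - expected)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Standard construction: pooled within-group variance, studentized-range
#' distribution for the pairwise honest significant differences.
#'
#' @param value numeric response.
#' @param group factor or character group labels (>= 2 levels).
#' @return list with `anova` (data.frame: F, df1, df2, p) and `tukey`
#'   (data.frame: comparison, diff, lwr, upr, p_adj).
#' @export
groupAnovaTukey <- function(value, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  keep <- is.finite(value) & !is.na(group)
  if (var(value[keep]) == 0) {
    ## degenerate null: no variation at all -> F = 0, nothing to compare
    lv <- levels(droplevels(group[keep]))
    cmb <- combn(rev(lv), 2)
    return(list(
      anova = data.frame(F = 0, df1 = length(lv) - 1,
                         df2 = sum(keep) - length(lv), p = 1),
      tukey = data.frame(comparison = paste(cmb[1, ], cmb[2, ], sep = "-"),
                         diff = 0, lwr = 0, upr = 0, p_adj = 1)))
  }
  fit <- aov(value[keep] ~ group[keep])
  at <- anova(fit)
  av <- data.frame(F = at[1, "F value"], df1 = at[1, "Df"],
                   df2 = at[2, "Df"], p = at[1, "Pr(>F)"])
  tk <- TukeyHSD(fit)[[1]]
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova = av, tukey = tukey)
}

## Truncated-normal draws by inverse-CDF (no rejection, exact truncation).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

## Ordinary least squares of y on x with slope t-test; returned fields match
## the regression summary used for the delta-5hmC vs expression fit.
ols_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete observations")
  if (var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       slope_se = sm$coefficients[2, 2], n = n)
}
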