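#' Dunn's post-hoc test for all pairs of groups
#'
#' Rank-sum multiple-comparison z tests following a Kruskal-Wallis omnibus
#' test. All observations are ranked jointly (average ranks for ties); for
#' each pair of groups the statistic is the difference of mean ranks over
#' its standard error with the usual tie correction,
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with \eqn{T = \sum (t^3 - t) / (12 (N - 1))} over tie groups. Two-sided
#' p-values are adjusted over the comparison family (Bonferroni by
#' default).
#'
#' @param values numeric vector of observations
#' @param groups group labels, same length
#' @param pAdjust adjustment method passed to \code{\link[stats]{p.adjust}}
#' @return data.frame with one row per pair: group1, group2, z, p_value,
#'   p_adjusted.
#' @export
#' @examples
#' dunnTest(c(rnorm(10), rnorm(10, 3)), rep(c("a", "b"), each = 10))
dunnTest <- function(values, groups, pAdjust = "bonferroni") {
  groups <- factor(groups)
  stopIfNot(length(values) == length(groups),
            "values and groups must have equal length")
  n <- table(groups)
  stopIfNot(all(n >= 1L), "every group needs at least one observation")
  N <- length(values)
  r <- rank(values)
  meanRank <- tapply(r, groups, mean)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) *
                 (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    (meanRank[[p[1]]] - meanRank[[p[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_value = p, p_adjusted = stats::p.adjust(p, pAdjust),
             stringsAsFactors = FALSE)
}

#' Nonparametric comparison of measurement groups
#'
#' Kruskal-Wallis omnibus test across two or more groups (e.g. normalized
#' stained areas of tumor vs peritumoral vs control tissue), followed by
#' Dunn's post-hoc z tests on every pair with multiplicity adjustment. A
#' Shapiro-Wilk normality check per group is reported alongside but does
#' not gate the nonparametric analysis.
#'
#' @param values numeric vector of observations
#' @param groups group labels, same length as values
#' @param posthoc run Dunn's pairwise tests (default TRUE when > 2 groups
#'   are present; always computed unless FALSE)
#' @param pAdjust multiplicity adjustment for the pairwise family
#' @return A \linkS4class{ComparisonResult}; the normality check is
#'   attached as attribute "shapiro" of the pairwise table.
#' @export
#' @examples
#' compareGroups(c(rnorm(15), rnorm(15, 2)), rep(c("t", "c"), each = 15))
compareGroups <- function(values, groups, posthoc = TRUE,
                          pAdjust = "bonferroni") {
  groups <- factor(groups)
  stopIfNot(nlevels(groups) >= 2L, "at least two groups are required")
  stopIfNot(all(table(groups) >= 1L),
            "every group needs at least one observation")
  kw <- stats::kruskal.test(values, groups)
  pw <- if (isTRUE(posthoc)) dunnTest(values, groups, pAdjust) else
    data.frame()
  shapiro <- lapply(split(values, groups), function(v) {
    if (length(unique(v)) >= 3L && length(v) >= 3L && length(v) <= 5000L)
      stats::shapiro.test(v)$p.value else NA_real_
  })
  attr(pw, "shapiro") <- unlist(shapiro)
  new("ComparisonResult", test = "Kruskal-Wallis + Dunn",
      statistic = unname(kw$statistic), pValue = kw$p.value,
      pairwise = pw, groups = levels(groups))
}

#' Spearman rank correlation
#'
#' Correlation between paired measurements (e.g. stained area vs the final
#' grade of positivity) using average ranks for ties; the p-value uses the
#' large-sample approximation so tied data do not warn.
#'
#' @param x,y equal-length paired numeric vectors, n >= 3
#' @return list with rho and p_value.
#' @export
#' @examples
#' correlate(1:10, (1:10)^3)  # rho = 1
correlate <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 3L, "at least three pairs are required")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Pearson chi-squared test on a contingency table
#'
#' Categorical comparison (e.g. final grade of positivity across species)
#' without continuity correction.
#'
#' @param tab 2D matrix or table of non-negative counts
#' @return A \linkS4class{ComparisonResult}.
#' @export
#' @examples
#' categoricalTest(matrix(c(20, 0, 0, 20), 2))  # statistic 40
categoricalTest <- function(tab) {
  tab <- as.matrix(tab)
  stopIfNot(all(tab >= 0), "counts must be non-negative")
  stopIfNot(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
            "every row and column must have a positive margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new("ComparisonResult", test = "Pearson chi-squared",
      statistic = unname(ct$statistic), pValue = ct$p.value,
      pairwise = data.frame(),
      groups = as.character(c(rownames(tab), colnames(tab))))
}
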