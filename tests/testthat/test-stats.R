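test_that("identical groups give a null Kruskal-Wallis result", {
  res <- compareGroups(rep(c(1, 2, 3, 4, 5), 2),
                       rep(c("a", "b"), each = 5))
  expect_lt(res@statistic, 1e-8)
  expect_gt(res@pValue, 0.99)
})

test_that("a large true difference is detected reliably", {
  set.seed(101)
  hits <- 0L
  for (i in 1:40) {
    x <- c(rlnorm(50, log(2e5), 0.5), rlnorm(50, log(2e4), 0.5))
    g <- rep(c("tumor", "control"), each = 50)
    if (compareGroups(x, g)@pValue < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Dunn pairwise adjustment never shrinks p-values and matches KW for 2 groups", {
  set.seed(7)
  x <- c(rnorm(12), rnorm(12, 1), rnorm(12, 2))
  g <- rep(letters[1:3], each = 12)
  pw <- dunnTest(x, g)
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-12))
  # two-group identity: KW chi-square equals the squared Dunn z
  # (independent check through stats::kruskal.test's tie correction)
  y <- c(rpois(15, 4), rpois(15, 6))   # ties present
  h <- rep(c("a", "b"), each = 15)
  kw <- kruskal.test(y, factor(h))$statistic
  z <- dunnTest(y, h)$z
  expect_equal(unname(kw), z^2, tolerance = 1e-10)
})

test_that("Spearman correlation handles monotone transforms and signs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(correlate(x, x)$rho, 1)
  expect_equal(correlate(x, -x)$rho, -1)
  y <- runif(20)
  expect_equal(correlate(y, exp(5 * y))$rho, 1)
  expect_equal(correlate(x, exp(x))$rho, correlate(x, x)$rho)
  expect_warning(res <- correlate(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})

test_that("chi-squared follows the closed form without continuity correction", {
  res <- categoricalTest(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res@statistic, 0)
  expect_equal(res@pValue, 1)
  res <- categoricalTest(matrix(c(20, 0, 0, 20), 2))
  expect_equal(res@statistic, 40)
  expect_error(categoricalTest(matrix(c(5, 5, 0, 0), 2)), "margin")
})

test_that("null calibration: type-I error near nominal for both tests", {
  set.seed(202)
  nrep <- 400
  kwRej <- 0L; chiRej <- 0L
  for (i in seq_len(nrep)) {
    x <- rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    if (kruskal.test(x, factor(g))$p.value < 0.05) kwRej <- kwRej + 1L
    tab <- table(sample(c("u", "v"), 40, TRUE), sample(c("p", "q"), 40, TRUE))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) &&
        categoricalTest(tab)@pValue < 0.05) chiRej <- chiRej + 1L
  }
  expect_lt(abs(kwRej / nrep - 0.05), 0.03)
  expect_lt(abs(chiRej / nrep - 0.05), 0.03)
})
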