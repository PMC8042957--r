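test_that("Pearson coefficient matches the direct covariance formula and cor.test", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  r <- pearsonFromPairs(x, y)$r
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, rOracle, tolerance = 1e-12)

  set.seed(8)
  a <- rnorm(12); b <- 0.6 * a + rnorm(12)
  mine <- pearsonFromPairs(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  x6 <- c(3, 1, 4, 1, 5, 9)
  expect_equal(suppressWarnings(pearsonFromPairs(x6, x6)$r), 1)
  expect_equal(suppressWarnings(pearsonFromPairs(x6, -x6)$r), -1)
  expect_error(pearsonFromPairs(1:5, rep(2, 5)), "zero variance")
  expect_error(pearsonFromPairs(1:5, 1:4), "equal length")
})

test_that("correlation p-values behave lawfully in |r| and n", {
  # strictly decreasing in |r| at fixed n, invariant to sign
  ps <- vapply(seq(0.05, 0.95, by = 0.1),
               function(r) pearsonPFromR(r, 8)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_equal(pearsonPFromR(-0.6, 8)$p_value, pearsonPFromR(0.6, 8)$p_value)
  expect_equal(pearsonPFromR(0, 10)$p_value, 1)
  expect_warning(p1 <- pearsonPFromR(1, 6), "limiting")
  expect_equal(p1$p_value, 0)
  expect_error(pearsonPFromR(0.5, 2), ">= 3")
})

test_that("t-tail probabilities agree with numerical integration of the density", {
  tDens <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  for (case in list(c(r = 0.74, n = 6), c(r = 0.41, n = 6),
                    c(r = 0.3, n = 9))) {
    pr <- pearsonPFromR(case[["r"]], case[["n"]])
    num <- 2 * stats::integrate(tDens, abs(pr$t_stat), Inf,
                                df = pr$df, rel.tol = 1e-10)$value
    expect_equal(pr$p_value, num, tolerance = 1e-6)
  }
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10)
  r0 <- pearsonFromPairs(x, y)$r
  expect_equal(pearsonFromPairs(2.5 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearsonFromPairs(x, 0.3 * y - 11)$r, r0, tolerance = 1e-12)
})

test_that("paired t from summaries and from pairs are definitionally consistent", {
  x <- c(1, 2, 3); y <- c(0, 0, 0)
  pp <- pairedTFromPairs(x, y)
  expect_equal(pp$t_stat, 2 * sqrt(3), tolerance = 1e-12)  # mean 2, sd 1, n 3
  ps <- pairedTFromSummary(mean(x - y), sd(x - y), 3)
  expect_equal(pp$p_value, ps$p_value)
  expect_equal(pp$mean_diff, pp$mean_a - pp$mean_b)

  # identical pairs: no differences at all, p = 1 by convention
  ident <- pairedTFromPairs(x, x)
  expect_equal(ident$p_value, 1)
  expect_equal(ident$mean_diff, 0)
  # but a systematic shift with zero variance is degenerate
  expect_error(pairedTFromSummary(2, 0, 5), "sd_diff")
  expect_equal(pairedTFromSummary(0.0001, 5, 6)$p_value, 1, tolerance = 1e-3)

  set.seed(5)
  a <- rnorm(9, 50, 10); b <- rnorm(9, 48, 10)
  ref <- stats::t.test(a, b, paired = TRUE)
  mine <- pairedTFromPairs(a, b)
  expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # sign symmetry
  expect_equal(pairedTFromSummary(-3.2, 4, 7)$p_value,
               pairedTFromSummary(3.2, 4, 7)$p_value)
})

test_that("correlation strength labels follow the 0.40 / 0.70 cut-offs", {
  expect_equal(classifyStrength(0.74), "strong")
  expect_equal(classifyStrength(0.46), "moderate")
  expect_equal(classifyStrength(0.41), "moderate")
  expect_equal(classifyStrength(0.30), "weak")
  expect_equal(classifyStrength(-0.75), "strong")
  expect_equal(classifyStrength(0.40), "moderate")
  expect_equal(classifyStrength(0.70), "strong")
  expect_error(classifyStrength(1.2), "<= 1")
})

test_that("the agreement table composes the underlying tests per group", {
  hist1 <- c(60, 65, 70, 62, 68, 64)
  uct1 <- hist1                       # perfect agreement
  set.seed(2)
  hist2 <- rnorm(6, 50, 10); uct2 <- hist2 + rnorm(6, 2, 5)
  tab <- suppressWarnings(
    buildAgreementTable(list(ideal = list(a = hist1, b = uct1),
                             noisy = list(a = hist2, b = uct2))))
  expect_equal(nrow(tab), 2)
  i <- tab[tab$group == "ideal", ]
  expect_equal(i$mean_diff, 0)
  expect_equal(i$r, 1)
  expect_equal(i$t_p, 1)
  expect_error(buildAgreementTable(list(bad = list(a = 1, b = 1))), "n >= 2")
  expect_error(buildAgreementTable(list(x = list(a = 1:3, b = 1:2))),
               "differ in length")

  n <- tab[tab$group == "noisy", ]
  expect_equal(n$r, pearsonFromPairs(hist2, uct2)$r)
  expect_equal(n$t_p, pairedTFromPairs(hist2, uct2)$p_value)
  expect_equal(n$mean_diff, mean(hist2 - uct2))
})
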