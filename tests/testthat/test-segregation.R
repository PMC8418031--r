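# Polysomic gamete model, expected ratios, chi-square tests, tabulation.

test_that("gamete distributions match hand enumeration for small cases", {
  g <- gamete_frequencies("Aaaa", 2)
  expect_equal(setNames(g$probability, g$k), c(`0` = 0.5, `1` = 0.5))
  g <- gamete_frequencies("AAaa", 2)
  expect_equal(setNames(g$probability, g$k),
               c(`0` = 1 / 6, `1` = 4 / 6, `2` = 1 / 6))
  g <- gamete_frequencies("aa", 1)
  expect_equal(setNames(g$probability, g$k), c(`0` = 1))
  expect_error(gamete_frequencies("Aaaa", 5), "1..4")
})

test_that("gamete masses agree with exhaustive subset enumeration (ploidy <= 8)", {
  for (m in 1:8) {
    for (nA in 0:m) {
      alleles <- c(rep(1L, nA), rep(0L, m - nA))
      for (g in 1:m) {
        dist <- gamete_frequencies(allelic_configuration(m, nA), g)
        # enumeration oracle: every C(m, g) subset of allele copies
        subsets <- combn(m, g)
        counts <- table(factor(colSums(matrix(alleles[subsets], nrow = g)),
                               levels = dist$k))
        expect_equal(dist$probability, as.vector(counts / ncol(subsets)),
                     tolerance = 1e-12)
        # exact rational normalization: numerators sum to the denominator
        expect_identical(sum(dist$numerator), dist$denominator[1L])
        # dhyper cross-check (independent library implementation)
        expect_equal(dist$probability, dhyper(dist$k, nA, m - nA, g),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("swapping A and a mirrors the gamete distribution", {
  for (m in 2:8) {
    for (nA in 0:m) {
      for (g in 1:m) {
        d1 <- gamete_frequencies(allelic_configuration(m, nA), g)
        d2 <- gamete_frequencies(allelic_configuration(m, m - nA), g)
        expect_equal(setNames(d1$probability, d1$k),
                     rev(setNames(d2$probability, g - d2$k)))
      }
    }
  }
})

test_that("sampling gametes matches the exact masses", {
  set.seed(2024)
  n <- 1e5
  parent <- c(1L, 1L, 0L, 0L)  # AAaa
  draws <- replicate(n, sum(sample(parent, 2L)))
  dist <- gamete_frequencies("AAaa", 2)
  for (i in seq_len(nrow(dist))) {
    p <- dist$probability[i]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws == dist$k[i]) - p), 3 * se)
  }
})

test_that("default gamete allocation reproduces the printed cross ratios", {
  # diploid parent contributes g = 1; polyploid parent the remainder
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("aa", "Aaaa", 2))),
               c(red = 1, white = 3), ignore_attr = TRUE)
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("aa", "Aaaa", 3))),
               c(red = 1, white = 1), ignore_attr = TRUE)
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("aa", "Aaaa", 4))),
               c(red = 3, white = 1), ignore_attr = TRUE)
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("aa", "AAaa", 2))),
               c(red = 1, white = 1), ignore_attr = TRUE)
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("aa", "AAaa", 3))),
               c(red = 5, white = 1), ignore_attr = TRUE)
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("aa", "AAAA", 3))),
               c(red = 1, white = 0), ignore_attr = TRUE)
  # unreduced 4n gamete route: pentaploids from AAaa x aa are all red
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("AAaa", "aa", 5))),
               c(red = 1, white = 0), ignore_attr = TRUE)
})

test_that("offspring distributions are exact convolutions", {
  d <- offspring_distribution(cross_spec("aa", "Aaaa", 3))
  expect_equal(setNames(d$probability, d$k), c(`0` = 0.5, `1` = 0.5))
  d <- offspring_distribution(cross_spec("aa", "AAAA", 3))
  expect_equal(setNames(d$probability, d$k), c(`2` = 1))  # all AAa
  # masses always sum to one exactly in integer arithmetic
  for (cs in list(cross_spec("aa", "AAaa", 3), cross_spec("Aaaa", "aa", 4),
                  cross_spec("AAaa", "aa", 5))) {
    d <- offspring_distribution(cs)
    expect_identical(sum(d$numerator), d$denominator[1L])
  }
})

test_that("classical diploid crosses recover Mendelian ratios", {
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("Aa", "Aa", 2))),
               c(red = 3, white = 1), ignore_attr = TRUE)
  expect_equal(unclass(expected_phenotype_ratio(cross_spec("Aa", "aa", 2))),
               c(red = 1, white = 1), ignore_attr = TRUE)
})

test_that("zygote doubling models the even-ploidy off-type route", {
  # n + n zygote doubled to 4x: Aa:aa 1:1 becomes AAaa:aaaa 1:1
  cs <- cross_spec("aa", "AAaa", 4, female_gametes = 1L, male_gametes = 1L,
                   doubled = TRUE)
  expect_equal(unclass(expected_phenotype_ratio(cs)),
               c(red = 1, white = 1), ignore_attr = TRUE)
  d <- offspring_distribution(cs)
  expect_identical(d$k, c(0L, 2L))  # doubled allele counts only
})

test_that("chi-square matches the published two-class tests", {
  t1 <- chi_square_gof(4, 5, c(1, 3))
  expect_equal(round(t1$chi2, 2), 1.81)
  expect_equal(t1$df, 1L)
  t2 <- chi_square_gof(10, 0, c(5, 1))
  expect_equal(round(t2$chi2, 2), 2.00)
  t3 <- chi_square_gof(5, 5, c(1, 1))
  expect_equal(t3$chi2, 0)
  expect_equal(t3$p, 1)
  # independent oracle: stats::chisq.test without continuity correction
  ct <- suppressWarnings(chisq.test(c(4, 5), p = c(1, 4) / 5))
  expect_equal(chi_square_gof(4, 5, c(1, 4))$chi2, unname(ct$statistic))
  expect_equal(chi_square_gof(4, 5, c(1, 4))$p, ct$p.value)
})

test_that("degenerate expected classes are flagged, not divided by", {
  ok <- chi_square_gof(7, 0, c(1, 0))
  expect_equal(ok$chi2, 0)
  expect_false(ok$degenerate)
  bad <- chi_square_gof(7, 2, c(1, 0))
  expect_true(bad$degenerate)
  expect_identical(bad$chi2, Inf)
  expect_error(chi_square_gof(1, 1, c(0, 0)), "not both zero")
})

test_that("the segregation table reproduces published rows and placeholders", {
  report <- segregation_table(published_crosses())
  cell <- function(cross, class) report[report$cross == cross &
                                          report$class == class, ]
  expect_identical(cell("GFxB431", "2x")$chi2, "1.81")
  expect_identical(cell("GFxB431", "2x")$expected_ratio, "1:3")
  expect_identical(cell("B431xGF", "3x")$chi2, "2.00")
  expect_identical(cell("B456xHB1", "3x")$observed_ratio, "4.71:1")
  expect_identical(cell("B456xHB1", "3x")$chi2, "0.04")
  # empty class rows carry placeholders
  expect_identical(cell("B431xGF", "4x")$chi2, "/")
  expect_identical(cell("B431xGF", "4x")$observed_ratio, "/")
  # pooled Total rows are emitted per cross
  expect_identical(nrow(cell("GFxB431", "Total")), 1L)
  expect_equal(cell("GFxB431", "Total")$red, 11)
  expect_equal(cell("GFxB431", "Total")$white, 10)
})

test_that("ploidy tabulation reproduces the published percentages", {
  tab <- ploidy_tabulation(data.frame(
    cross = c("B431xGF", "B431xGF", "H424xHB1", "half", "half"),
    ploidy = c(2, 3, 3, 2, 3),
    count = c(1, 50, 5, 1, 1)))
  expect_equal(tab$percent, c(1.96, 98.04, 100.00, 50.00, 50.00))
  expect_error(ploidy_tabulation(data.frame(cross = "x", ploidy = 3,
                                            count = 0)), "zero progeny")
})
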