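# independent oracle: two-sided Fisher p by brute-force enumeration of the
# hypergeometric support using factorial identities (no dhyper)
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- r1 + r2
  ks <- max(0, c1 - r2):min(c1, r1)
  pr <- exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1))
  p_obs <- pr[ks == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

test_that("Pearson chi-square reproduces the published allelic statistics", {
  expect_equal(pearson_chi2(matrix(c(74, 57, 74, 103), 2))$chi2, 6.499,
               tolerance = 0.001 / 6.499)
  expect_equal(pearson_chi2(matrix(c(56, 97, 56, 59), 2))$chi2, 3.947,
               tolerance = 0.001 / 3.947)
  ident <- pearson_chi2(matrix(c(10, 10, 20, 20), 2))
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p_value, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("Pearson chi-square matches the 2x2 closed form and stats::chisq.test", {
  set.seed(101)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    n <- sum(tab)
    closed <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      prod(rowSums(tab), colSums(tab))
    got <- pearson_chi2(tab)
    expect_equal(got$chi2, closed, tolerance = 1e-9)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("Fisher exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252)
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(1:6, 2)), "2x2")
  set.seed(7)
  for (i in 1:100) {
    tab <- matrix(rbinom(4, 10, 0.5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)$p_value
    expect_equal(p, fisher_enum(tab), tolerance = 1e-12)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-6)
  }
})

test_that("odds ratio and Woolf interval reproduce published rows", {
  # fetal rs1063320 allelic
  o <- odds_ratio(matrix(c(74, 57, 74, 103), 2))
  expect_equal(o$or, 1.807, tolerance = 0.001 / 1.807)
  expect_equal(o$ci_low, 1.144, tolerance = 0.001)
  expect_equal(o$ci_high, 2.852, tolerance = 0.001)
  # maternal rs649216 allelic
  expect_equal(odds_ratio(matrix(c(23, 31, 125, 129), 2))$or, 0.765,
               tolerance = 0.001)
  # paternal rs1630185: published value is the major-allele orientation
  expect_equal(odds_ratio(matrix(c(56, 97, 56, 59), 2), invert = TRUE)$or,
               1.644, tolerance = 0.001)
})

test_that("odds ratio orientation algebra behaves as expected", {
  tab <- matrix(c(12, 7, 30, 41), 2)
  o <- odds_ratio(tab)
  # swapping both rows and columns leaves the OR unchanged
  expect_equal(odds_ratio(tab[2:1, 2:1])$or, o$or)
  # a single swap inverts it, as does invert = TRUE
  expect_equal(odds_ratio(tab[, 2:1])$or, 1 / o$or)
  inv <- odds_ratio(tab, invert = TRUE)
  expect_equal(inv$or, 1 / o$or)
  expect_equal(inv$ci_low, 1 / o$ci_high)
  # symmetric table: OR 1, interval symmetric on the log scale
  s <- odds_ratio(matrix(c(50, 50, 50, 50), 2))
  expect_equal(s$or, 1)
  expect_equal(log(s$ci_high), -log(s$ci_low))
})

test_that("zero cells get the Haldane-Anscombe correction and a flag", {
  o <- odds_ratio(matrix(c(5, 0, 3, 8), 2))
  expect_true(o$corrected)
  expect_equal(o$or, (5.5 * 8.5) / (3.5 * 0.5))
  expect_false(odds_ratio(matrix(c(5, 1, 3, 8), 2))$corrected)
})

test_that("logistic fit on a saturated 2x2 equals the crude odds ratio", {
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 25) + 1, 2)
    expect_equal(or_logistic(tab)$or, odds_ratio(tab)$or, tolerance = 1e-6)
  }
})

test_that("genotype collapsing reproduces published model ORs and keeps totals", {
  # fetal rs1063320 dominant: case 19/36/19, control 37/29/14
  g <- matrix(c(19, 37, 36, 29, 19, 14), 2,
              dimnames = list(c("case", "control"), c("CC", "CG", "GG")))
  dom <- collapse_genotypes(g, "dominant")
  expect_equal(odds_ratio(dom)$or, 2.491, tolerance = 0.001)
  expect_equal(rowSums(dom), rowSums(g))
  expect_equal(colnames(dom), c("CG/GG", "CC"))
  # paternal rs1630185 recessive: case 18/20/18, control 28/41/9
  g2 <- matrix(c(18, 28, 20, 41, 18, 9), 2)
  rec <- collapse_genotypes(g2, "recessive")
  expect_equal(odds_ratio(rec)$or, 3.632, tolerance = 0.001)
  expect_equal(rowSums(rec), rowSums(g2))
  # degenerate collapse is flagged
  expect_true(isTRUE(attr(collapse_genotypes(matrix(c(5, 6, 0, 0, 0, 0), 2),
                                             "dominant"), "degenerate")))
})

test_that("Hardy-Weinberg test behaves across exact, off and degenerate input", {
  expect_equal(hwe_test(c(25, 50, 25))$chi2, 0)
  h <- hwe_test(c(30, 40, 30))
  expect_equal(h$chi2, 4)
  expect_equal(h$p_value, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(sum(h$expected), 100)
  mono <- hwe_test(c(0, 0, 50))
  expect_true(mono$monomorphic)
  expect_equal(mono$chi2, 0)
  expect_equal(mono$maf, 1)
  expect_error(hwe_test(c(0, 0, 0)), "empty")
  # chi2 = 0 whenever AB^2 = 4 AA BB
  set.seed(9)
  for (i in 1:25) {
    aa <- sample(1:50, 1); bb <- sample(1:50, 1)
    expect_equal(hwe_test(c(aa, 2 * sqrt(aa * bb), bb))$chi2, 0,
                 tolerance = 1e-12)
  }
})

test_that("allele and genotype count tables tabulate by status with per-locus exclusion", {
  coh <- make_cohort(list(
    list(m = "GA", c = "AA", status = "case"),
    list(m = "GG", c = "GA", status = "case"),
    list(m = "GA", c = NA,   status = "case"),     # excluded from offspring
    list(m = "GG", c = "GG", status = "control"),
    list(m = "GA", c = "GA", status = "control")))
  g <- genotype_count_table(coh, "rs1", "offspring")
  expect_equal(unname(g["case", ]), c(0, 1, 1))
  expect_equal(unname(g["control", ]), c(1, 1, 0))
  expect_equal(colnames(g), c("GG", "GA", "AA"))
  a <- allele_count_table(coh, "rs1", "offspring")
  expect_equal(unname(a["case", ]), c(3, 1))    # minor A then major G
  expect_equal(unname(a["control", ]), c(1, 3))
  m <- allele_count_table(coh, "rs1", "mother")
  expect_equal(sum(m["case", ]), 6)             # missing child doesn't drop mother
  expect_error(allele_count_table(coh, "rs1", "father"), "no genotyped")
})
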