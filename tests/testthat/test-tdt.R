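# brute-force recount oracle: enumerate parental allele assignments from the
# raw allele strings of each family, then count minor-allele transmissions
tdt_recount <- function(cohort, rsid, status) {
  loc <- cohort$loci[cohort$loci$rsid == rsid, ]
  g <- cohort$genotypes[cohort$genotypes$rsid == rsid, ]
  fam <- cohort$families[cohort$families$status == status &
                           cohort$families$father_present, ]
  a <- b <- 0
  for (id in fam$family_id) {
    geno <- function(role) {
      r <- g[g$family_id == id & g$role == role, ]
      if (nrow(r) != 1 || is.na(r$a1)) NULL else c(r$a1, r$a2)
    }
    m <- geno("mother"); f <- geno("father"); c <- geno("offspring")
    if (is.null(m) || is.null(f) || is.null(c)) next
    pairs <- list()
    for (i in 1:2) for (j in 1:2)
      if (identical(sort(c(m[i], f[j])), sort(c)))
        pairs[[length(pairs) + 1]] <- c(mo = m[i], fa = f[j])
    if (!length(pairs)) next  # Mendelian violation
    mo_tr <- unique(vapply(pairs, `[[`, "", "mo"))
    fa_tr <- unique(vapply(pairs, `[[`, "", "fa"))
    if (m[1] != m[2] && f[1] != f[2] &&
        length(mo_tr) > 1) {  # doubly het, het child: one minor + one major
      a <- a + 1; b <- b + 1
    } else {
      if (m[1] != m[2]) {
        if (mo_tr == loc$minor) a <- a + 1 else b <- b + 1
      }
      if (f[1] != f[2]) {
        if (fa_tr == loc$minor) a <- a + 1 else b <- b + 1
      }
    }
  }
  c(a = a, b = b)
}

test_that("transmissions are inferred correctly from trio genotypes", {
  coh <- make_cohort(list(
    list(m = "GA", f = "GG", c = "GG"),   # mother gave G, father uninformative
    list(m = "GA", f = "GA", c = "AA"),   # both gave A
    list(m = "GA", f = "GA", c = "GA"),   # ambiguous parent-of-origin
    list(m = "GA", c = "AA"),             # dyad: no records
    list(m = "GG", f = "AA", c = "GG")))  # violation: no records
  r <- infer_transmissions(coh, "rs1")
  r1 <- r[r$family_id == "F1", ]
  expect_equal(r1$transmitted[r1$parent == "mother"], "G")
  expect_equal(r1$untransmitted[r1$parent == "mother"], "A")
  expect_true(r1$informative[r1$parent == "mother"])
  expect_false(r1$informative[r1$parent == "father"])
  r2 <- r[r$family_id == "F2", ]
  expect_equal(r2$transmitted, c("A", "A"))
  expect_true(all(r2$informative))
  r3 <- r[r$family_id == "F3", ]
  expect_true(all(r3$ambiguous))
  expect_true(all(is.na(r3$transmitted)))
  expect_false(any(r$family_id %in% c("F4", "F5")))
})

test_that("the TDT statistic reproduces the published triad analyses", {
  t <- tdt_statistic(28, 8)
  expect_equal(t$chi2, 11.111, tolerance = 0.0001)
  expect_equal(t$chi2, 400 / 36)
  expect_equal(tdt_statistic(14, 4)$chi2, 100 / 18)   # 5.556
  t3 <- tdt_statistic(19, 10)
  expect_equal(t3$chi2, 81 / 29)                      # 2.793
  expect_close(t3$p_value, 0.095, 0.001)
  eq <- tdt_statistic(6, 6)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p_value, 1)
  expect_error(tdt_statistic(0, 0), "undefined")
})

test_that("parent strata and the ambiguity policy reconcile with the overall count", {
  p <- sim_params(n_case = 60, n_control = 60, dyad_fraction_case = 0.2,
                  dyad_fraction_control = 0.2)
  for (seed in 1:5) {
    coh <- simulate_cohort(p, seed = seed)
    for (rs in c("rs9380142", "rs649216")) {
      res <- tdt(coh, rs, status = "control")
      all_ab <- res$a[1] + res$b[1]
      mo_ab <- res$a[2] + res$b[2]
      fa_ab <- res$a[3] + res$b[3]
      expect_equal(mo_ab + fa_ab + res$n_ambiguous[1], all_ab)
      sp <- tdt(coh, rs, status = "control", ambiguity = "split")
      expect_equal(sp$a[2] + sp$b[2] + sp$a[3] + sp$b[3], all_ab)
      expect_equal(sp$a[1], res$a[1])  # overall stratum unaffected by policy
    }
  }
})

test_that("tdt agrees with a brute-force recount on small cohorts", {
  p <- sim_params(n_case = 15, n_control = 15,
                  loci = locus_table("rsX", "G1", "G", "A"), maf = 0.4)
  for (seed in 1:8) {
    coh <- simulate_cohort(p, seed = 100 + seed)
    for (st in c("case", "control")) {
      res <- tdt(coh, "rsX", status = st)
      oracle <- tdt_recount(coh, "rsX", st)
      expect_equal(res$a[1], unname(oracle["a"]))
      expect_equal(res$b[1], unname(oracle["b"]))
      if (res$a[1] + res$b[1] > 0)
        expect_equal(res$chi2[1],
                     tdt_statistic(unname(oracle["a"]),
                                   unname(oracle["b"]))$chi2)
    }
  }
})

test_that("minor-allele transmission is symmetric under the null and skewed under distortion", {
  one_locus <- locus_table("rsX", "G1", "G", "A")
  null <- simulate_cohort(sim_params(n_case = 0, n_control = 2000,
                                     dyad_fraction_control = 0,
                                     loci = one_locus, maf = 0.4),
                          seed = 21)
  res <- tdt(null, "rsX", status = "control")
  n <- res$a[1] + res$b[1]
  expect_gt(n, 1000)
  expect_lt(abs(res$a[1] / n - 0.5), 3 * sqrt(0.25 / n))
  skew <- simulate_cohort(sim_params(n_case = 0, n_control = 2000,
                                     dyad_fraction_control = 0,
                                     loci = one_locus, maf = 0.4, tau = 0.8),
                          seed = 22)
  rs <- tdt(skew, "rsX", status = "control")
  expect_gt(rs$a[1] / (rs$a[1] + rs$b[1]), 0.7)
})

test_that("Mendelian-violating families are excluded from transmission counting", {
  coh <- make_cohort(list(
    list(m = "GA", f = "GG", c = "GG", status = "case"),
    list(m = "GG", f = "AA", c = "GG", status = "case")))  # violation
  expect_equal(nrow(check_mendelian(coh)), 1L)
  res <- tdt(coh, "rs1", status = "case")
  expect_equal(res$a[1] + res$b[1], 1)  # only the consistent triad counts
})
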