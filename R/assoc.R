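#' Case-control association scan across the loci of a cohort
#'
#' Runs the allelic or genotypic case-control analysis at every locus for
#' one family role and returns a tidy table: counts, crude odds ratio with
#' Woolf 95\% confidence interval, test statistic and p-value.
#'
#' With `level = "genotype"` and `model = "none"` the test is the global
#' 2x3 heterogeneity test and no odds ratio is reported; with a dominant or
#' recessive `model` the genotype table is collapsed to 2x2 first. The
#' `test` argument selects Pearson's chi-square, Fisher's exact test, or an
#' automatic rule (Fisher whenever an expected cell is below 5). Odds
#' ratios are oriented on the minor allele (or collapsed carrier class) in
#' cases versus controls; `orient = "invert"` reports the reciprocal.
#'
#' @param cohort a `triad_cohort`.
#' @param role `"mother"`, `"father"` or `"offspring"`.
#' @param level `"allele"` or `"genotype"`.
#' @param model `"none"`, `"dominant"` or `"recessive"` (genotype level
#'   only).
#' @param test `"auto"`, `"pearson"` or `"fisher"`.
#' @param orient `"minor"` (default) or `"invert"`.
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()] (`"none"`, `"bonferroni"`, `"BH"`, ...); off by
#'   default.
#' @return `data.frame`, one row per locus.
#' @examples
#' coh <- simulate_cohort(sim_params(n_case = 40, n_control = 40), seed = 7)
#' cohort_assoc(coh, role = "offspring", level = "allele", test = "pearson")
#' @export
cohort_assoc <- function(cohort, role = "offspring",
                         level = c("allele", "genotype"),
                         model = c("none", "dominant", "recessive"),
                         test = c("auto", "pearson", "fisher"),
                         orient = c("minor", "invert"),
                         p_adjust = "none") {
  level <- match.arg(level)
  model <- match.arg(model)
  test <- match.arg(test)
  orient <- match.arg(orient)
  rows <- lapply(cohort$loci$rsid, function(rs) {
    tab <- if (level == "allele") allele_count_table(cohort, rs, role)
           else genotype_count_table(cohort, rs, role)
    if (level == "genotype" && model != "none")
      tab <- collapse_genotypes(tab, model)
    use <- select_test(tab, test)
    tst <- if (use == "pearson") pearson_chi2(tab) else {
      if (ncol(tab) == 2L) fisher_exact(tab)
      else structure(list(chi2 = NA_real_, df = NA_integer_,
                          p_value = stats::fisher.test(tab)$p.value,
                          test = "fisher"), class = "assoc_test")
    }
    base <- data.frame(rsid = rs,
                       gene = cohort$loci$gene[cohort$loci$rsid == rs],
                       role = role, level = level, model = model,
                       n_case = sum(tab[1L, ]), n_control = sum(tab[2L, ]),
                       test = tst$test, chi2 = tst$chi2, df = tst$df,
                       p_value = tst$p_value, stringsAsFactors = FALSE)
    if (ncol(tab) == 2L) {
      o <- odds_ratio(tab, invert = orient == "invert")
      base$or <- o$or; base$ci_low <- o$ci_low; base$ci_high <- o$ci_high
      base$orientation <- o$orientation
    } else {
      base$or <- NA_real_; base$ci_low <- NA_real_; base$ci_high <- NA_real_
      base$orientation <- NA_character_
    }
    base
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Hardy-Weinberg screen of a cohort
#'
#' Applies [hwe_test()] at every locus to one role and status group
#' (conventionally control mothers/fathers, the group in which equilibrium
#' is expected under random mating).
#'
#' @param cohort a `triad_cohort`.
#' @param role family member.
#' @param status group tested (default `"control"`).
#' @return `data.frame` with `rsid`, `n`, `maf`, `chi2`, `p_value`,
#'   `monomorphic`.
#' @export
cohort_hwe <- function(cohort, role = "mother", status = "control") {
  d <- dosage_matrix(cohort, role)
  d <- d[cohort$families$status == status, , drop = FALSE]
  rows <- lapply(colnames(d), function(rs) {
    x <- d[, rs]; x <- x[!is.na(x)]
    counts <- tabulate(x + 1L, nbins = 3L)
    h <- hwe_test(counts)
    data.frame(rsid = rs, n = length(x), maf = h$maf, chi2 = h$chi2,
               p_value = h$p_value, monomorphic = h$monomorphic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
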