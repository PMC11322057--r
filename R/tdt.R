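#' Infer transmitted and untransmitted alleles in triads
#'
#' For every complete, Mendelian-consistent triad at a locus, works out
#' which allele each parent transmitted to the offspring by subtracting the
#' other parent's forced contribution from the offspring genotype. A parent
#' is *informative* only when heterozygous. When both parents and the
#' offspring are heterozygous the pair of transmissions is one major plus
#' one minor allele, but which parent gave which cannot be resolved: both
#' records are flagged `ambiguous` and their `transmitted`/`untransmitted`
#' fields are `NA`.
#'
#' Dyads (missing father) and families with a missing or Mendelian-
#' inconsistent genotype at the locus yield no records.
#'
#' @param cohort a `triad_cohort`.
#' @param rsid locus identifier.
#' @param status optional `"case"`/`"control"` filter on families.
#' @return `data.frame` with columns `family_id`, `rsid`, `parent`,
#'   `transmitted`, `untransmitted`, `informative`, `ambiguous`.
#' @export
infer_transmissions <- function(cohort, rsid, status = NULL) {
  if (!rsid %in% cohort$loci$rsid) stop("unknown locus: ", rsid)
  loc <- cohort$loci[cohort$loci$rsid == rsid, ]
  fam <- cohort$families
  keep <- if (is.null(status)) rep(TRUE, nrow(fam)) else fam$status == status
  ok <- mendel_ok_matrix(cohort)[, rsid] & keep
  m <- dosage_matrix(cohort, "mother")[, rsid]
  f <- dosage_matrix(cohort, "father")[, rsid]
  c <- dosage_matrix(cohort, "offspring")[, rsid]
  idx <- which(ok)
  if (!length(idx))
    return(data.frame(family_id = character(0), rsid = character(0),
                      parent = character(0), transmitted = character(0),
                      untransmitted = character(0), informative = logical(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  sym <- function(d) ifelse(is.na(d), NA_character_,
                            ifelse(d == 1L, loc$minor, loc$major))
  rec <- function(i, parent, g_par, g_other) {
    ambiguous <- g_par == 1L & g_other == 1L & c[i] == 1L
    # transmitted minor-dosage for this parent when resolvable
    t_dose <- rep(NA_integer_, length(i))
    hom <- g_par != 1L
    t_dose[hom] <- g_par[hom] %/% 2L
    het_res <- g_par == 1L & !ambiguous
    # other parent heterozygous and child homozygous: both gave c/2;
    # other parent homozygous: this parent gave c - other/2
    oth_het <- g_other == 1L
    t_dose[het_res & oth_het] <- c[i][het_res & oth_het] %/% 2L
    t_dose[het_res & !oth_het] <-
      c[i][het_res & !oth_het] - g_other[het_res & !oth_het] %/% 2L
    u_dose <- ifelse(g_par == 1L, 1L - t_dose, t_dose)
    data.frame(family_id = fam$family_id[i], rsid = rsid, parent = parent,
               transmitted = ifelse(ambiguous, NA_character_, sym(t_dose)),
               untransmitted = ifelse(ambiguous, NA_character_, sym(u_dose)),
               informative = g_par == 1L, ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  }
  out <- rbind(rec(idx, "mother", m[idx], f[idx]),
               rec(idx, "father", f[idx], m[idx]))
  out[order(match(out$family_id, fam$family_id)), , drop = FALSE]
}

#' Transmission disequilibrium test statistic
#'
#' Given `a` transmissions and `b` non-transmissions of the allele of
#' interest from heterozygous parents, computes the McNemar-type statistic
#' chi2 = (a - b)^2 / (a + b), referred to the chi-square distribution with
#' one degree of freedom.
#'
#' @param a number of transmissions of the allele of interest.
#' @param b number of non-transmissions.
#' @return list of class `tdt_result` with `a`, `b`, `chi2`, `df`,
#'   `p_value`.
#' @examples
#' tdt_statistic(28, 8)  # chi2 = 11.111, p = 0.00086
#' @export
tdt_statistic <- function(a, b) {
  stopifnot(a >= 0, b >= 0)
  if (a + b == 0) stop("undefined TDT statistic: no informative transmissions")
  chi2 <- (a - b)^2 / (a + b)
  structure(list(a = a, b = b, chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, 1L, lower.tail = FALSE)),
            class = "tdt_result")
}

#' @export
print.tdt_result <- function(x, ...) {
  cat(sprintf("TDT: transmitted %s vs %s, chi2 = %.3f (df 1), p = %.3g\n",
              format(x$a), format(x$b), x$chi2, x$p_value))
  invisible(x)
}

#' Transmission disequilibrium test, overall and by parent of origin
#'
#' Counts transmissions of the allele of interest from heterozygous parents
#' in complete triads of the given status and applies [tdt_statistic()]
#' overall and separately for maternal and paternal transmissions.
#'
#' In the overall stratum a doubly-heterozygous triad with a heterozygous
#' offspring contributes one transmission of each allele (the pair is known
#' even though the parent of origin is not). In the parent strata such
#' ambiguous records are handled by `ambiguity`: `"exclude"` drops them
#' (default; their count is reported so the discrepancy with the overall
#' stratum is visible), `"split"` adds half a transmission of each allele to
#' each parent.
#'
#' @param cohort a `triad_cohort`.
#' @param rsid locus identifier.
#' @param status `"case"` or `"control"`; strata are never pooled across
#'   status.
#' @param allele allele of interest: `"minor"` (default), `"major"`, or an
#'   explicit allele symbol of the locus.
#' @param ambiguity `"exclude"` or `"split"` (parent strata only).
#' @return `data.frame` with one row per stratum (`all`, `mother`,
#'   `father`): counts `a` (transmitted) and `b` (untransmitted), `chi2`,
#'   `df`, `p_value`, `n_informative`, `n_ambiguous`. Strata with no
#'   informative transmissions get `NA` statistics.
#' @examples
#' coh <- simulate_cohort(sim_params(n_case = 50, n_control = 50), seed = 1)
#' tdt(coh, coh$loci$rsid[1], status = "control")
#' @export
tdt <- function(cohort, rsid, status, allele = "minor",
                ambiguity = c("exclude", "split")) {
  ambiguity <- match.arg(ambiguity)
  status <- match.arg(status, c("case", "control"))
  loc <- cohort$loci[cohort$loci$rsid == rsid, ]
  if (!nrow(loc)) stop("unknown locus: ", rsid)
  interest <- switch(allele, minor = loc$minor, major = loc$major, allele)
  if (!interest %in% c(loc$major, loc$minor))
    stop("allele '", allele, "' is not an allele of ", rsid)
  rec <- infer_transmissions(cohort, rsid, status = status)
  inf <- rec[rec$informative, , drop = FALSE]
  n_amb_rec <- sum(inf$ambiguous)            # ambiguous parent records
  n_amb_fam <- n_amb_rec / 2                 # ambiguous triads
  count <- function(r, amb_each) {
    a <- sum(r$transmitted == interest, na.rm = TRUE) + amb_each
    b <- sum(r$untransmitted == interest, na.rm = TRUE) + amb_each
    c(a = a, b = b)
  }
  strata <- list(
    all = count(inf, amb_each = n_amb_fam),
    mother = count(inf[inf$parent == "mother", , drop = FALSE],
                   amb_each = if (ambiguity == "split") n_amb_fam / 2 else 0),
    father = count(inf[inf$parent == "father", , drop = FALSE],
                   amb_each = if (ambiguity == "split") n_amb_fam / 2 else 0))
  n_inf <- c(all = nrow(inf), mother = sum(inf$parent == "mother"),
             father = sum(inf$parent == "father"))
  n_amb <- c(all = n_amb_rec, mother = n_amb_fam, father = n_amb_fam)
  rows <- lapply(names(strata), function(s) {
    ab <- strata[[s]]
    if (sum(ab) > 0) {
      t <- tdt_statistic(ab[["a"]], ab[["b"]])
      data.frame(rsid = rsid, status = status, stratum = s,
                 allele = interest, a = t$a, b = t$b, chi2 = t$chi2,
                 df = 1L, p_value = t$p_value, n_informative = n_inf[[s]],
                 n_ambiguous = n_amb[[s]], stringsAsFactors = FALSE)
    } else {
      data.frame(rsid = rsid, status = status, stratum = s,
                 allele = interest, a = 0, b = 0, chi2 = NA_real_,
                 df = 1L, p_value = NA_real_, n_informative = n_inf[[s]],
                 n_ambiguous = n_amb[[s]], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
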