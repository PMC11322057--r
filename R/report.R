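#' Packaged count tables from the motivating study
#'
#' Returns the integer count tables transcribed from the published tables of
#' the motivating preeclampsia study: `"allele"` (case/control minor-allele
#' counts per role and locus), `"genotype"` (AA/AB/BB counts), `"tdt"`
#' (transmitted/untransmitted counts per stratum), `"combo"`
#' (maternal-by-fetal combination counts) and `"printed"` (the published OR,
#' chi-square and p statistics, kept separately so that every statistic in
#' the reproduction report is recomputed from counts, never echoed).
#'
#' @param table one of `"allele"`, `"genotype"`, `"tdt"`, `"combo"`,
#'   `"printed"`.
#' @return `data.frame`.
#' @export
paper_counts <- function(table = c("allele", "genotype", "tdt", "combo",
                                   "printed")) {
  table <- match.arg(table)
  fname <- c(allele = "allele_counts.tsv", genotype = "genotype_counts.tsv",
             tdt = "tdt_counts.tsv", combo = "combo_counts.tsv",
             printed = "printed_stats.tsv")[[table]]
  path <- system.file("extdata", "paper_tables", fname, package = "triadtest")
  if (path == "") stop("packaged fixture not found: ", fname)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = if (table == "printed")
                      c(printed = "character") else NA)
}

# decimals printed in a number string
printed_dp <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}

# classify agreement of a printed value with candidate recomputations;
# the reported recomputation is the closest candidate
audit_value <- function(printed_str, candidates, note = "") {
  printed <- as.numeric(printed_str)
  d <- abs(candidates - printed)
  j <- which.min(d)
  band_round <- 0.5 * 10^(-printed_dp(printed_str)) + 0.002
  severity <- if (d[j] <= 0.002) "match"
    else if (d[j] <= band_round) "rounding"
    else "inconsistent"
  list(recomputed = candidates[j], severity = severity,
       note = if (length(candidates) > 1 && severity != "inconsistent")
         names(candidates)[j] %||% note else note)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recompute the motivating study's statistics from its count tables
#'
#' Recomputes every auditable statistic of the published allele, genotype,
#' TDT and combined-genotype tables from their integer counts and compares
#' it with the printed value. Audited statistics are odds ratios and
#' chi-square values plus the global genotype-test p-values; published
#' confidence-interval bounds and per-collapse p-values are not audited
#' (they carry no information beyond the OR and its standard error at the
#' printed precision).
#'
#' Because the published tables orient some odds ratios on the major allele
#' and, at one locus with a control-group allele-frequency tie, swap the
#' collapsed classes, each printed OR is compared against the recomputed
#' value under every orientation (value, inverse, and for collapsed
#' genotypes the dominant/recessive pair and their inverses); the closest
#' candidate is reported. Global genotype p-values are compared against both
#' the Pearson and the exact (Fisher) test, as the source switches between
#' them without a stated rule.
#'
#' @return list of class `paper_reproduction` with a `findings` data frame
#'   (`table`, `row_id`, `statistic`, `printed`, `recomputed`, `severity`
#'   one of match/rounding/inconsistent, `note`) and the recomputed
#'   per-table reports.
#' @examples
#' rep <- reproduce_paper()
#' subset(rep$findings, severity == "inconsistent")
#' @export
reproduce_paper <- function() {
  printed <- paper_counts("printed")
  findings <- list()
  add <- function(table, row_id, statistic, audit) {
    p <- printed[printed$table == table & printed$row_id == row_id &
                   printed$statistic == statistic, "printed"]
    if (length(p) != 1L) stop("missing printed value for ", row_id, " ", statistic)
    findings[[length(findings) + 1L]] <<- data.frame(
      table = table, row_id = row_id, statistic = statistic,
      printed = as.numeric(p), recomputed = audit(p)$recomputed,
      severity = audit(p)$severity, note = audit(p)$note,
      stringsAsFactors = FALSE)
  }

  ## allele table: 2x2 minor/major by case/control
  al <- paper_counts("allele")
  allele_report <- do.call(rbind, lapply(seq_len(nrow(al)), function(i) {
    r <- al[i, ]
    tab <- matrix(c(r$case_minor, r$control_minor,
                    r$case_total - r$case_minor,
                    r$control_total - r$control_minor), 2L,
                  dimnames = list(c("case", "control"), c(r$minor, r$major)))
    o <- odds_ratio(tab)
    x <- pearson_chi2(tab)
    row_id <- paste(r$role, r$rsid)
    add("allele", row_id, "or", function(p)
      audit_value(p, c(minor = o$or, major = 1 / o$or)))
    add("allele", row_id, "chi2", function(p) audit_value(p, x$chi2))
    data.frame(role = r$role, rsid = r$rsid, or_minor = o$or,
               ci_low = o$ci_low, ci_high = o$ci_high, chi2 = x$chi2,
               p_value = x$p_value, stringsAsFactors = FALSE)
  }))

  ## genotype table: global test + collapsed ORs
  ge <- paper_counts("genotype")
  genotype_report <- do.call(rbind, lapply(seq_len(nrow(ge)), function(i) {
    r <- ge[i, ]
    tab <- matrix(c(r$case_AA, r$control_AA, r$case_AB, r$control_AB,
                    r$case_BB, r$control_BB), 2L,
                  dimnames = list(c("case", "control"), c("AA", "AB", "BB")))
    p_pearson <- pearson_chi2(tab)$p_value
    p_fisher <- stats::fisher.test(tab)$p.value
    or_dom <- odds_ratio(collapse_genotypes(tab, "dominant"))$or
    or_rec <- odds_ratio(collapse_genotypes(tab, "recessive"))$or
    cand <- c(dominant = or_dom, recessive = or_rec,
              `inverse dominant` = 1 / or_dom,
              `inverse recessive` = 1 / or_rec)
    row_id <- paste(r$role, r$rsid)
    add("genotype", row_id, "p_global", function(p)
      audit_value(p, c(pearson = p_pearson, fisher = p_fisher)))
    add("genotype", row_id, "or_dom", function(p) audit_value(p, cand))
    add("genotype", row_id, "or_rec", function(p) audit_value(p, cand))
    data.frame(role = r$role, rsid = r$rsid, p_pearson = p_pearson,
               p_fisher = p_fisher, or_dominant = or_dom,
               or_recessive = or_rec, stringsAsFactors = FALSE)
  }))

  ## TDT table
  td <- paper_counts("tdt")
  tdt_report <- do.call(rbind, lapply(seq_len(nrow(td)), function(i) {
    r <- td[i, ]
    t <- tdt_statistic(r$a, r$b)
    add("tdt", paste(r$rsid, r$status, r$stratum), "chi2",
        function(p) audit_value(p, t$chi2))
    data.frame(rsid = r$rsid, status = r$status, stratum = r$stratum,
               a = r$a, b = r$b, chi2 = t$chi2, p_value = t$p_value,
               stringsAsFactors = FALSE)
  }))

  ## combined-genotype tables
  co <- paper_counts("combo")
  combo_report <- do.call(rbind, lapply(split(co, co$maternal_rsid), function(d) {
    d <- d[order(match(d$maternal_class, unique(d$maternal_class))), ]
    tab <- rbind(case = d$case, control = d$control)
    colnames(tab) <- paste(d$maternal_class, d$fetal_class, sep = ":")
    g <- combo_global_test(tab)
    ors <- combo_reference_ors(tab, reference = "auto")
    mrs <- d$maternal_rsid[1L]
    add("combo", paste(mrs, "x", d$fetal_rsid[1L]), "chi2_global",
        function(p) audit_value(p, g$chi2))
    for (k in which(!ors$reference)) {
      local({kk <- k
        add("combo", paste(mrs, ors$category[kk]), "or",
            function(p) audit_value(p, ors$or[kk]))})
    }
    data.frame(maternal_rsid = mrs, fetal_rsid = d$fetal_rsid[1L],
               category = ors$category, case = ors$case,
               control = ors$control, or = ors$or, ci_low = ors$ci_low,
               ci_high = ors$ci_high, p_value = ors$p_value,
               reference = ors$reference, chi2_global = g$chi2,
               p_global = g$p_value, stringsAsFactors = FALSE)
  }))
  rownames(combo_report) <- NULL

  findings <- do.call(rbind, findings)
  structure(list(findings = findings, allele = allele_report,
                 genotype = genotype_report, tdt = tdt_report,
                 combo = combo_report),
            class = "paper_reproduction")
}

#' @export
print.paper_reproduction <- function(x, ...) {
  tab <- table(factor(x$findings$severity,
                      levels = c("match", "rounding", "inconsistent")))
  cat(sprintf("reproduction audit: %d statistics recomputed from counts\n",
              nrow(x$findings)))
  cat(sprintf("  match: %d   rounding: %d   inconsistent: %d\n",
              tab[["match"]], tab[["rounding"]], tab[["inconsistent"]]))
  bad <- x$findings[x$findings$severity == "inconsistent", , drop = FALSE]
  if (nrow(bad)) {
    cat("printed values inconsistent with their own counts:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  %-8s %-28s %-10s printed %-8.3f recomputed %.3f\n",
                  bad$table[i], bad$row_id[i], bad$statistic[i],
                  bad$printed[i], bad$recomputed[i]))
  }
  invisible(x)
}
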