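#' Maternal-by-fetal combined-genotype count table
#'
#' Cross-classifies complete mother-offspring pairs by a collapsed maternal
#' genotype class at one locus and a collapsed fetal genotype class at
#' another, and counts cases and controls in each of the K = 2 x 2
#' combination categories. Collapsing is carrier-based: `"dominant"` splits
#' carriers of the minor allele (AB+BB) from non-carriers (AA);
#' `"recessive"` splits minor homozygotes (BB) from the rest. Empty
#' categories are retained with zero counts.
#'
#' @param cohort a `triad_cohort`.
#' @param maternal_rsid,fetal_rsid loci for the mother and the offspring.
#' @param maternal_model,fetal_model `"dominant"` or `"recessive"` collapsing
#'   of the respective genotype.
#' @return 2xK count matrix, rows `case`/`control`; columns are labelled
#'   `<maternal class>:<fetal class>` (e.g. `"CC:AA/GA"`).
#' @export
combo_table <- function(cohort, maternal_rsid, fetal_rsid,
                        maternal_model = c("dominant", "recessive"),
                        fetal_model = c("dominant", "recessive")) {
  maternal_model <- match.arg(maternal_model)
  fetal_model <- match.arg(fetal_model)
  classes <- function(rsid, model, d) {
    loc <- cohort$loci[cohort$loci$rsid == rsid, ]
    if (!nrow(loc)) stop("unknown locus: ", rsid)
    hom_maj <- paste0(loc$major, loc$major)
    het <- paste0(loc$major, loc$minor)
    hom_min <- paste0(loc$minor, loc$minor)
    if (model == "dominant") {
      lab <- c(hom_maj, paste(het, hom_min, sep = "/"))
      cls <- ifelse(d >= 1L, lab[2L], lab[1L])
    } else {
      lab <- c(paste(hom_maj, het, sep = "/"), hom_min)
      cls <- ifelse(d == 2L, lab[2L], lab[1L])
    }
    list(cls = cls, levels = lab)
  }
  dm <- dosage_matrix(cohort, "mother")[, maternal_rsid]
  df <- dosage_matrix(cohort, "offspring")[, fetal_rsid]
  keep <- !is.na(dm) & !is.na(df)
  mo <- classes(maternal_rsid, maternal_model, dm[keep])
  fe <- classes(fetal_rsid, fetal_model, df[keep])
  st <- factor(cohort$families$status[keep], levels = c("case", "control"))
  cat_lab <- as.vector(t(outer(mo$levels, fe$levels, paste, sep = ":")))
  cls <- factor(paste(mo$cls, fe$cls, sep = ":"), levels = cat_lab)
  out <- as.matrix(table(st, cls))
  names(dimnames(out)) <- NULL
  if (any(colSums(out) == 0L)) attr(out, "degenerate") <- TRUE
  out
}

#' Global heterogeneity test for a combined-genotype table
#'
#' Pearson chi-square on the 2xK case-control combination table,
#' df = K - 1: do the combined maternal-fetal genotype categories differ in
#' distribution between cases and controls?
#'
#' @param table 2xK count matrix as from [combo_table()].
#' @return an `assoc_test` (see [pearson_chi2()]).
#' @export
combo_global_test <- function(table) {
  stopifnot(is.matrix(table), nrow(table) == 2L, ncol(table) >= 2L)
  pearson_chi2(table)
}

#' Per-category odds ratios against a reference combination
#'
#' For each non-reference category of a 2xK combined-genotype table,
#' computes the crude case-control odds ratio versus the reference category
#' (2x2 sub-table) with Woolf confidence interval and Wald p-value. The
#' default reference is the category with the largest combined case+control
#' count ("highest incidence"); zero cells trigger the Haldane-Anscombe
#' correction and a flag.
#'
#' @param table 2xK count matrix, rows `case`/`control`.
#' @param reference `"auto"` (largest total) or a column label.
#' @return `data.frame` with one row per category: counts, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `reference` (logical), `corrected` (logical).
#'   The reference row has OR 1 and `NA` interval.
#' @examples
#' tab <- matrix(c(43, 27, 10, 26, 15, 19, 6, 8), nrow = 2,
#'               dimnames = list(c("case", "control"),
#'                               c("CC:AA/GA", "CC:GG", "CT/TT:AA/GA", "CT/TT:GG")))
#' combo_reference_ors(tab)  # CC:GG vs reference: OR 0.242
#' @export
combo_reference_ors <- function(table, reference = "auto") {
  stopifnot(is.matrix(table), nrow(table) == 2L)
  labs <- colnames(table)
  if (is.null(labs)) labs <- paste0("cat", seq_len(ncol(table)))
  ref <- if (identical(reference, "auto")) {
    labs[which.max(colSums(table))]
  } else {
    if (!reference %in% labs) stop("reference '", reference, "' not a category")
    reference
  }
  ri <- match(ref, labs)
  rows <- lapply(seq_along(labs), function(j) {
    if (j == ri)
      return(data.frame(category = labs[j], case = table[1L, j],
                        control = table[2L, j], or = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        reference = TRUE, corrected = FALSE,
                        stringsAsFactors = FALSE))
    sub <- cbind(table[, j], table[, ri])
    o <- odds_ratio(sub)
    data.frame(category = labs[j], case = table[1L, j], control = table[2L, j],
               or = o$or, ci_low = o$ci_low, ci_high = o$ci_high,
               p_value = o$p_value, reference = FALSE, corrected = o$corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- ref
  out
}
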