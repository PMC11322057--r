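#' Check Mendelian consistency of a cohort
#'
#' For each family and locus with complete genotypes, verifies that the
#' offspring genotype can be produced by one allele from the mother and (for
#' triads) one from the father. For dyads the offspring must share at least
#' one allele with the mother. Violations make transmission counting
#' meaningless at that locus, so [tdt()] excludes the affected family there;
#' case-control allele/genotype counting is unaffected.
#'
#' @param cohort a `triad_cohort`.
#' @return `data.frame` with columns `family_id`, `rsid`, `description`
#'   (zero rows when the cohort is consistent).
#' @examples
#' # mother GG x father AA cannot produce a GG child
#' loci <- locus_table("rs1", "GENE", "G", "A")
#' coh <- triad_cohort(loci,
#'   data.frame(family_id = "F1", status = "case", father_present = TRUE),
#'   data.frame(family_id = "F1", role = c("mother", "father", "offspring"),
#'              rsid = "rs1", a1 = c("G", "A", "G"), a2 = c("G", "A", "G")))
#' check_mendelian(coh)
#' @export
check_mendelian <- function(cohort) {
  mo <- dosage_matrix(cohort, "mother")
  fa <- dosage_matrix(cohort, "father")
  off <- dosage_matrix(cohort, "offspring")
  fam <- cohort$families
  out <- data.frame(family_id = character(0), rsid = character(0),
                    description = character(0), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(off))) {
    rs <- colnames(off)[j]
    m <- mo[, j]; f <- fa[, j]; c <- off[, j]
    triad <- fam$father_present & !is.na(m) & !is.na(f) & !is.na(c)
    dyad <- !is.na(m) & is.na(f) & !is.na(c)
    # possible transmitted minor-allele counts per genotype dosage:
    # 0 -> {0}, 1 -> {0,1}, 2 -> {1}
    lo <- function(g) ifelse(g == 2, 1L, 0L)
    hi <- function(g) ifelse(g == 0, 0L, 1L)
    bad_triad <- triad & (c < lo(m) + lo(f) | c > hi(m) + hi(f))
    bad_dyad <- dyad & (c - hi(m) > 1L | c - lo(m) < 0L)
    for (i in which(bad_triad))
      out <- rbind(out, data.frame(
        family_id = fam$family_id[i], rsid = rs,
        description = sprintf("offspring dosage %d incompatible with mother %d / father %d",
                              c[i], m[i], f[i]), stringsAsFactors = FALSE))
    for (i in which(bad_dyad))
      out <- rbind(out, data.frame(
        family_id = fam$family_id[i], rsid = rs,
        description = sprintf("offspring dosage %d shares no allele with mother %d (dyad)",
                              c[i], m[i]), stringsAsFactors = FALSE))
  }
  out
}

# fast logical matrix of Mendelian-consistent (complete) triads, families x loci
mendel_ok_matrix <- function(cohort) {
  mo <- dosage_matrix(cohort, "mother")
  fa <- dosage_matrix(cohort, "father")
  off <- dosage_matrix(cohort, "offspring")
  lo <- function(g) ifelse(g == 2, 1L, 0L)
  hi <- function(g) ifelse(g == 0, 0L, 1L)
  complete <- !is.na(mo) & !is.na(fa) & !is.na(off)
  complete & off >= lo(mo) + lo(fa) & off <= hi(mo) + hi(fa)
}
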