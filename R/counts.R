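#' Case-control allele count table
#'
#' Tabulates allele counts (two per genotyped individual) by case/control
#' status for one locus and one family role. Individuals with a missing call
#' at the locus are excluded from that locus only (per-locus complete case),
#' so different loci and roles may have different Ns.
#'
#' @param cohort a `triad_cohort`.
#' @param rsid locus identifier.
#' @param role `"mother"`, `"father"` or `"offspring"`.
#' @return 2x2 integer matrix, rows `case`/`control`, columns minor then
#'   major allele symbol.
#' @examples
#' coh <- simulate_cohort(sim_params(n_case = 30, n_control = 30), seed = 1)
#' allele_count_table(coh, coh$loci$rsid[1], "offspring")
#' @export
allele_count_table <- function(cohort, rsid, role = "offspring") {
  g <- genotype_count_table(cohort, rsid, role)
  loc <- cohort$loci[cohort$loci$rsid == rsid, ]
  out <- cbind(minor = 2L * g[, 3L] + g[, 2L],
               major = 2L * g[, 1L] + g[, 2L])
  colnames(out) <- c(loc$minor, loc$major)
  out
}

#' Case-control genotype count table
#'
#' Tabulates AA/AB/BB genotype counts (A = major, B = minor allele) by
#' case/control status for one locus and one family role.
#'
#' @inheritParams allele_count_table
#' @return 2x3 integer matrix, rows `case`/`control`, columns the three
#'   genotype labels (e.g. `"CC"`, `"CG"`, `"GG"`).
#' @export
genotype_count_table <- function(cohort, rsid, role = "offspring") {
  role <- match.arg(role, c("mother", "father", "offspring"))
  if (!rsid %in% cohort$loci$rsid) stop("unknown locus: ", rsid)
  d <- dosage_matrix(cohort, role)[, rsid]
  st <- cohort$families$status
  if (all(is.na(d))) stop("no genotyped ", role, " at ", rsid)
  loc <- cohort$loci[cohort$loci$rsid == rsid, ]
  lab <- c(paste0(loc$major, loc$major), paste0(loc$major, loc$minor),
           paste0(loc$minor, loc$minor))
  out <- matrix(0L, 2L, 3L, dimnames = list(c("case", "control"), lab))
  for (s in c("case", "control")) {
    tab <- tabulate(d[st == s & !is.na(d)] + 1L, nbins = 3L)
    out[s, ] <- tab
  }
  out
}

#' Collapse a genotype table under a genetic model
#'
#' Reduces a 2x3 AA/AB/BB case-control genotype table to 2x2 with respect to
#' the minor allele B: `"dominant"` compares carriers (AB+BB) with AA,
#' `"recessive"` compares BB homozygotes with AA+AB. Group totals are
#' preserved.
#'
#' @param table_2x3 2x3 count matrix as from [genotype_count_table()] (column
#'   order AA, AB, BB).
#' @param model `"dominant"` or `"recessive"` (with respect to the minor
#'   allele).
#' @return 2x2 count matrix; the first column is the collapsed "exposed"
#'   class.
#' @export
collapse_genotypes <- function(table_2x3, model = c("dominant", "recessive")) {
  model <- match.arg(model)
  stopifnot(is.matrix(table_2x3), ncol(table_2x3) == 3L)
  cn <- colnames(table_2x3)
  if (is.null(cn)) cn <- c("AA", "AB", "BB")
  out <- if (model == "dominant")
    cbind(table_2x3[, 2L] + table_2x3[, 3L], table_2x3[, 1L])
  else
    cbind(table_2x3[, 3L], table_2x3[, 1L] + table_2x3[, 2L])
  colnames(out) <- if (model == "dominant")
    c(paste(cn[2L], cn[3L], sep = "/"), cn[1L])
  else
    c(cn[3L], paste(cn[1L], cn[2L], sep = "/"))
  rownames(out) <- rownames(table_2x3)
  if (any(colSums(out) == 0L))
    attr(out, "degenerate") <- TRUE
  out
}
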