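#' Define the loci of a study
#'
#' A locus table describes the biallelic SNPs genotyped in a cohort: the rsID,
#' a gene label, and the major and minor allele symbols. The minor allele is
#' the allele whose population frequency is (nominally) below one half; all
#' odds ratios, genotype collapsing and TDT counting in this package are
#' oriented on the minor allele unless stated otherwise.
#'
#' @param rsid character vector of SNP identifiers, unique.
#' @param gene character vector of gene labels (recycled if length 1).
#' @param major,minor single-character allele symbols per locus.
#' @return A `data.frame` of class `locus_table` with columns
#'   `rsid`, `gene`, `major`, `minor`.
#' @examples
#' locus_table("rs1063320", "HLA-G", major = "C", minor = "G")
#' @export
locus_table <- function(rsid, gene, major, minor) {
  rsid <- as.character(rsid)
  n <- length(rsid)
  gene <- rep_len(as.character(gene), n)
  major <- rep_len(as.character(major), n)
  minor <- rep_len(as.character(minor), n)
  if (anyDuplicated(rsid))
    stop("duplicate rsid in locus table: ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  if (any(nchar(major) != 1L) || any(nchar(minor) != 1L))
    stop("allele symbols must be single characters")
  if (any(major == minor))
    stop("major and minor allele must differ at every locus")
  out <- data.frame(rsid = rsid, gene = gene, major = major, minor = minor,
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Read a locus-definition table
#'
#' Reads a tab-separated file with header columns `rsid`, `gene`, `major`,
#' `minor` (one row per SNP).
#'
#' @param path path to a TSV file.
#' @return A `locus_table`.
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop("locus file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "gene", "major", "minor")
  if (!all(need %in% names(df)))
    stop("locus file must have columns: ", paste(need, collapse = ", "))
  locus_table(df$rsid, df$gene, df$major, df$minor)
}

#' Construct a triad cohort
#'
#' A cohort bundles a locus table, a family table and a long genotype table.
#' Families are mother-offspring pairs with an optional father (a *triad* when
#' the father is present, a *dyad* when absent) and a binary case/control
#' status taken from the pregnancy, not the offspring.
#'
#' @param loci a [locus_table()].
#' @param families `data.frame` with columns `family_id`, `status`
#'   (`"case"`/`"control"`), `father_present` (logical), and optionally
#'   `mother_id`, `father_id`, `child_id` (invented from `family_id` if
#'   absent).
#' @param genotypes long `data.frame` with columns `family_id`, `role`
#'   (`"mother"`, `"father"`, `"offspring"`), `rsid`, `a1`, `a2` (allele
#'   symbols, `NA` for a missing call).
#' @return An object of class `triad_cohort`.
#' @seealso [read_ped()], [simulate_cohort()]
#' @export
triad_cohort <- function(loci, families, genotypes) {
  stopifnot(inherits(loci, "locus_table"))
  families <- as.data.frame(families, stringsAsFactors = FALSE)
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  if (!all(c("family_id", "status", "father_present") %in% names(families)))
    stop("families needs columns family_id, status, father_present")
  if (!all(c("family_id", "role", "rsid", "a1", "a2") %in% names(genotypes)))
    stop("genotypes needs columns family_id, role, rsid, a1, a2")
  families$family_id <- as.character(families$family_id)
  if (anyDuplicated(families$family_id))
    stop("duplicate family_id")
  if (!all(families$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  for (idcol in c("mother_id", "father_id", "child_id"))
    if (is.null(families[[idcol]]))
      families[[idcol]] <- paste0(families$family_id, "_",
                                  switch(idcol, mother_id = "M",
                                         father_id = "F", child_id = "C"))
  genotypes$family_id <- as.character(genotypes$family_id)
  if (!all(genotypes$role %in% c("mother", "father", "offspring")))
    stop("role must be mother, father or offspring")
  if (!all(genotypes$rsid %in% loci$rsid))
    stop("genotype at undeclared locus: ",
         paste(unique(setdiff(genotypes$rsid, loci$rsid)), collapse = ", "))
  if (!all(genotypes$family_id %in% families$family_id))
    stop("genotype for unknown family")
  # allele symbols must belong to their locus
  i <- match(genotypes$rsid, loci$rsid)
  ok <- function(a) is.na(a) | a == loci$major[i] | a == loci$minor[i]
  bad <- !(ok(genotypes$a1) & ok(genotypes$a2)) |
    (is.na(genotypes$a1) != is.na(genotypes$a2))
  if (any(bad)) {
    b <- genotypes[which(bad)[1L], ]
    stop(sprintf("invalid genotype %s/%s at %s (family %s): alleles must both be in {%s,%s} or both missing",
                 b$a1, b$a2, b$rsid, b$family_id,
                 loci$major[match(b$rsid, loci$rsid)],
                 loci$minor[match(b$rsid, loci$rsid)]))
  }
  structure(list(loci = loci, families = families, genotypes = genotypes),
            class = "triad_cohort")
}

#' @export
print.triad_cohort <- function(x, ...) {
  n_case <- sum(x$families$status == "case")
  n_ctrl <- sum(x$families$status == "control")
  n_dyad <- sum(!x$families$father_present)
  cat(sprintf("triad cohort: %d loci; %d families (%d case, %d control; %d dyads)\n",
              nrow(x$loci), nrow(x$families), n_case, n_ctrl, n_dyad))
  invisible(x)
}

# Minor-allele dosage matrix (families x loci) for one role; NA = missing call
# or, for fathers, an absent parent.
dosage_matrix <- function(cohort, role) {
  fam <- cohort$families$family_id
  rs <- cohort$loci$rsid
  g <- cohort$genotypes[cohort$genotypes$role == role, , drop = FALSE]
  m <- matrix(NA_integer_, nrow = length(fam), ncol = length(rs),
              dimnames = list(fam, rs))
  if (nrow(g)) {
    minor <- cohort$loci$minor[match(g$rsid, rs)]
    d <- (g$a1 == minor) + (g$a2 == minor)
    m[cbind(match(g$family_id, fam), match(g$rsid, rs))] <- as.integer(d)
  }
  m
}

#' Cohort summary of minor-allele frequencies
#'
#' @param cohort a `triad_cohort`.
#' @param role which family member to summarise.
#' @return `data.frame` with per-locus genotyped N and minor-allele frequency
#'   by case/control status.
#' @export
maf_summary <- function(cohort, role = "offspring") {
  d <- dosage_matrix(cohort, role)
  st <- cohort$families$status
  out <- lapply(c("case", "control"), function(s) {
    ds <- d[st == s, , drop = FALSE]
    data.frame(rsid = colnames(d), status = s,
               n = colSums(!is.na(ds)),
               maf = colSums(ds, na.rm = TRUE) / (2 * colSums(!is.na(ds))),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
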