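#' Read a linkage/PED pedigree-genotype file
#'
#' Parses the classic linkage ("PED") dialect: one whitespace-separated row
#' per individual with six leading columns (family ID, individual ID, father
#' ID, mother ID, sex, phenotype) followed by two allele columns per locus,
#' in the order of `loci`. A `"0"` allele denotes a missing call; `"0"` in
#' the parent-ID columns denotes an unknown parent. Both letter alleles
#' (A/C/G/T) and numeric 1/2 coding are accepted; `1` maps to the major and
#' `2` to the minor allele of the locus.
#'
#' Families are assembled around offspring rows (rows whose parent IDs link
#' to other individuals in the same family). The case/control status of the
#' family is read from the *offspring* row's phenotype: `1` = control, `2` =
#' case; `0` or `-9` = missing, in which case the family is dropped with a
#' warning. Individuals that are neither an offspring nor a linked parent
#' are ignored with a warning.
#'
#' @param path path to the PED file.
#' @param loci a [locus_table()] describing the SNP columns, in file order.
#' @return A [triad_cohort()].
#' @examples
#' loci <- locus_table("rs1", "GENE", major = "G", minor = "A")
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("F1 M 0 0 2 1 G A",
#'              "F1 F 0 0 1 1 G G",
#'              "F1 C F M 2 2 G G"), ped)
#' read_ped(ped, loci)
#' @export
read_ped <- function(path, loci) {
  stopifnot(inherits(loci, "locus_table"))
  if (!file.exists(path)) stop("PED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  nfield <- 6L + 2L * nrow(loci)
  rows <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(rows)
  if (any(len != nfield))
    stop(sprintf("malformed PED row at line %d: expected %d fields, found %d",
                 which(len != nfield)[1L], nfield, len[which(len != nfield)[1L]]))
  m <- do.call(rbind, rows)
  fid <- m[, 1L]; iid <- m[, 2L]; pat <- m[, 3L]; mat <- m[, 4L]
  pheno <- m[, 6L]
  key <- paste(fid, iid)
  if (anyDuplicated(key))
    stop("duplicate individual ID within family: ", key[duplicated(key)][1L])

  # decode allele columns; "0" -> NA, 1/2 -> major/minor
  decode <- function(a, locus_i) {
    a[a == "0"] <- NA
    a[a == "1"] <- loci$major[locus_i]
    a[a == "2"] <- loci$minor[locus_i]
    bad <- !is.na(a) & a != loci$major[locus_i] & a != loci$minor[locus_i]
    if (any(bad))
      stop(sprintf("allele '%s' not valid for %s (expected %s or %s)",
                   a[bad][1L], loci$rsid[locus_i],
                   loci$major[locus_i], loci$minor[locus_i]))
    a
  }
  a1 <- a2 <- matrix(NA_character_, nrow = nrow(m), ncol = nrow(loci))
  for (j in seq_len(nrow(loci))) {
    a1[, j] <- decode(m[, 6L + 2L * j - 1L], j)
    a2[, j] <- decode(m[, 6L + 2L * j], j)
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing genotype (one allele '0') at line ", which(half)[1L])

  is_child <- (pat != "0" & paste(fid, pat) %in% key) |
              (mat != "0" & paste(fid, mat) %in% key)
  if (!any(is_child)) stop("no offspring rows (parent links) found in ", path)

  fam_list <- list(); geno_list <- list(); used <- rep(FALSE, nrow(m))
  for (i in which(is_child)) {
    mi <- match(paste(fid[i], mat[i]), key)
    fi <- match(paste(fid[i], pat[i]), key)
    if (is.na(mi))
      stop("offspring ", iid[i], " in family ", fid[i],
           " has no genotyped mother row; mother is required")
    status <- switch(pheno[i], "1" = "control", "2" = "case", NA_character_)
    if (is.na(status)) {
      warning("family ", fid[i], " dropped: offspring phenotype '",
              pheno[i], "' is missing/unknown", call. = FALSE)
      used[c(i, mi, fi)] <- TRUE
      next
    }
    used[c(i, mi, fi)] <- TRUE
    fam_list[[length(fam_list) + 1L]] <- data.frame(
      family_id = fid[i], status = status, father_present = !is.na(fi),
      mother_id = iid[mi], father_id = if (is.na(fi)) NA_character_ else iid[fi],
      child_id = iid[i], stringsAsFactors = FALSE)
    idx <- c(offspring = i, mother = mi, father = fi)
    idx <- idx[!is.na(idx)]
    geno_list[[length(geno_list) + 1L]] <- data.frame(
      family_id = fid[i],
      role = rep(names(idx), each = nrow(loci)),
      rsid = rep(loci$rsid, times = length(idx)),
      a1 = as.vector(t(a1[idx, , drop = FALSE])),
      a2 = as.vector(t(a2[idx, , drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  if (any(!used))
    warning(sum(!used), " individual(s) not linked to any offspring were ignored",
            call. = FALSE)
  families <- do.call(rbind, fam_list)
  if (is.null(families)) stop("no usable families in ", path)
  if (anyDuplicated(families$family_id))
    stop("multiple offspring per family are not supported (family ",
         families$family_id[duplicated(families$family_id)][1L], ")")
  genotypes <- do.call(rbind, geno_list)
  genotypes <- genotypes[!is.na(genotypes$a1), , drop = FALSE]
  triad_cohort(loci, families, genotypes)
}

#' Write a cohort in linkage/PED format
#'
#' Inverse of [read_ped()]: one row per individual (mother, father when
#' present, offspring), letter alleles, missing calls coded `0 0`, offspring
#' phenotype 1 = control / 2 = case, parental phenotype 0.
#'
#' @param cohort a `triad_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(cohort, path) {
  fam <- cohort$families
  loci <- cohort$loci
  g <- cohort$genotypes
  gkey <- paste(g$family_id, g$role, g$rsid)
  row_for <- function(fid, iid, patid, matid, sex, pheno, role) {
    al <- character(2L * nrow(loci))
    i <- match(paste(fid, role, loci$rsid), gkey)
    al[seq(1L, by = 2L, length.out = nrow(loci))] <- ifelse(is.na(i), "0", g$a1[i])
    al[seq(2L, by = 2L, length.out = nrow(loci))] <- ifelse(is.na(i), "0", g$a2[i])
    al[is.na(al)] <- "0"
    paste(c(fid, iid, patid, matid, sex, pheno, al), collapse = "\t")
  }
  out <- character(0)
  for (k in seq_len(nrow(fam))) {
    f <- fam[k, ]
    out <- c(out,
             row_for(f$family_id, f$mother_id, "0", "0", "2", "0", "mother"),
             if (f$father_present)
               row_for(f$family_id, f$father_id, "0", "0", "1", "0", "father"),
             row_for(f$family_id, f$child_id,
                     if (f$father_present) f$father_id else "0",
                     f$mother_id, "0",
                     if (f$status == "case") "2" else "1", "offspring"))
  }
  writeLines(out, path)
  invisible(path)
}
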