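# Build a single-locus cohort from compact genotype strings.
# families: list of lists with elements m, f (NULL = dyad), c (two-character
# genotype strings, NA = missing call) and status.
make_cohort <- function(families, loci = locus_table("rs1", "GENE", "G", "A")) {
  fam <- do.call(rbind, lapply(seq_along(families), function(i) {
    x <- families[[i]]
    data.frame(family_id = paste0("F", i),
               status = if (is.null(x$status)) "case" else x$status,
               father_present = !is.null(x$f), stringsAsFactors = FALSE)
  }))
  geno <- do.call(rbind, lapply(seq_along(families), function(i) {
    x <- families[[i]]
    rows <- list()
    push <- function(role, g) {
      if (is.null(g)) return()
      a <- if (is.na(g)) c(NA_character_, NA_character_)
           else strsplit(g, "")[[1]]
      rows[[length(rows) + 1]] <<- data.frame(
        family_id = paste0("F", i), role = role, rsid = loci$rsid[1],
        a1 = a[1], a2 = a[2], stringsAsFactors = FALSE)
    }
    push("mother", x$m); push("father", x$f); push("offspring", x$c)
    do.call(rbind, rows)
  }))
  triad_cohort(loci, fam, geno)
}

# absolute-tolerance comparison (published values are printed to a fixed
# number of decimals, so the natural tolerance is absolute, not relative)
expect_close <- function(actual, expected, tol = 0.001) {
  expect_lt(abs(unname(actual) - expected), tol + 1e-12)
}

# write a PED file from a character vector of rows, returning its path
write_ped_lines <- function(lines) {
  path <- tempfile(fileext = ".ped")
  writeLines(lines, path)
  path
}
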