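#' Default study loci for simulation
#'
#' The seven SNPs of the motivating maternal KIR2DL4 / fetal HLA-G study,
#' with control-group minor-allele frequencies.
#'
#' @return list with a `locus_table` (`loci`) and a named numeric vector of
#'   minor-allele frequencies (`maf`).
#' @export
study_loci <- function() {
  loci <- locus_table(
    rsid = c("rs649216", "rs1051456", "rs34785252",
             "rs9380142", "rs1063320", "rs1630185", "rs1130363"),
    gene = c("KIR2DL4", "KIR2DL4", "KIR2DL4",
             "HLA-G", "HLA-G", "HLA-G", "HLA-G"),
    major = c("C", "C", "C", "G", "C", "A", "G"),
    minor = c("T", "G", "A", "A", "G", "G", "A"))
  maf <- c(rs649216 = 0.193, rs1051456 = 0.500, rs34785252 = 0.468,
           rs9380142 = 0.500, rs1063320 = 0.375, rs1630185 = 0.412,
           rs1130363 = 0.412)
  list(loci = loci, maf = maf)
}

#' Simulation parameters for a triad cohort
#'
#' Defaults reproduce the design of the motivating study: 74 preeclampsia
#' and 80 control mother-offspring pairs, of which 56/74 and 78/80 are full
#' triads (the remainder are dyads with a missing father), the seven study
#' SNPs at their control-group minor-allele frequencies, a baseline disease
#' prevalence of 5%, Mendelian transmission (tau = 0.5) and no genetic
#' effects.
#'
#' Disease risk follows a logistic model on the family:
#' `logit P(case) = qlogis(prevalence) + log(maternal_or[l]) * maternal
#' risk-class indicator + log(fetal_or[l]) * fetal carrier indicator +
#' log(combo$or) * combined-category indicator`, summed over loci. Families
#' are then accepted by status until both arms are filled (case-control
#' ascertainment by rejection).
#'
#' @param n_case,n_control families per arm.
#' @param dyad_fraction_case,dyad_fraction_control fraction of families
#'   whose father is removed after simulation; the realised dyad count is
#'   `round(fraction * n)`, exactly.
#' @param loci a `locus_table` (default: the seven study SNPs).
#' @param maf named vector of minor-allele frequencies in (0,1), one per
#'   locus.
#' @param maternal_or,fetal_or named per-locus genotype relative odds for
#'   the mother's / offspring's collapsed risk class (default 1 = null;
#'   unnamed scalars recycle across loci).
#' @param maternal_model,fetal_model collapsing model defining the risk
#'   class (`"dominant"` = minor-allele carrier, `"recessive"` = minor
#'   homozygote).
#' @param combo optional list `list(maternal_rsid=, fetal_rsid=, or=)`
#'   multiplying the odds when both the mother and the offspring are in
#'   their risk classes at the named loci.
#' @param tau probability that a heterozygous parent transmits the minor
#'   allele (0.5 = Mendelian null); scalar or named per-locus.
#' @param prevalence baseline disease probability for a family with no risk
#'   genotypes.
#' @param draw_cap maximum families drawn per requested family before the
#'   acceptance loop aborts.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_case = 74, n_control = 80,
                       dyad_fraction_case = 18 / 74,
                       dyad_fraction_control = 2 / 80,
                       loci = NULL, maf = NULL,
                       maternal_or = 1, fetal_or = 1,
                       maternal_model = c("dominant", "recessive"),
                       fetal_model = c("dominant", "recessive"),
                       combo = NULL, tau = 0.5, prevalence = 0.05,
                       draw_cap = 1000) {
  if (is.null(loci) && is.null(maf)) {
    s <- study_loci(); loci <- s$loci; maf <- s$maf
  }
  stopifnot(inherits(loci, "locus_table"))
  maf <- rep_len(maf, nrow(loci))
  if (!is.null(names(maf)) && all(loci$rsid %in% names(maf)))
    maf <- maf[loci$rsid]
  names(maf) <- loci$rsid
  stopifnot(all(maf > 0 & maf < 1))
  expand <- function(x) {
    out <- rep_len(1, nrow(loci)); names(out) <- loci$rsid
    if (is.null(names(x))) out[] <- rep_len(x, nrow(loci))
    else out[names(x)] <- x
    stopifnot(all(out > 0))
    out
  }
  tau <- expand(tau)
  stopifnot(all(tau > 0 & tau < 1), prevalence > 0 && prevalence < 1,
            dyad_fraction_case >= 0, dyad_fraction_case <= 1,
            dyad_fraction_control >= 0, dyad_fraction_control <= 1)
  structure(list(n_case = n_case, n_control = n_control,
                 dyad_fraction_case = dyad_fraction_case,
                 dyad_fraction_control = dyad_fraction_control,
                 loci = loci, maf = maf,
                 maternal_or = expand(maternal_or),
                 fetal_or = expand(fetal_or),
                 maternal_model = match.arg(maternal_model),
                 fetal_model = match.arg(fetal_model),
                 combo = combo, tau = tau, prevalence = prevalence,
                 draw_cap = draw_cap),
            class = "sim_params")
}

risk_class <- function(dosage, model) {
  if (model == "dominant") dosage >= 1L else dosage == 2L
}

#' Simulate a triad/dyad cohort
#'
#' Parents are drawn genotype-wise from Hardy-Weinberg proportions at the
#' locus minor-allele frequency; each parent transmits one allele to the
#' offspring, a heterozygous parent transmitting the minor allele with
#' probability `tau`. Family case/control status is drawn from the logistic
#' disease model of [sim_params()] and families are accepted by status until
#' both arms are filled; fathers are then deleted at the configured dyad
#' fractions. The same `seed` reproduces the same cohort exactly.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed for the cohort's pseudo-random stream.
#' @return A [triad_cohort()]; the seed is stored in `attr(, "seed")`.
#' @export
simulate_cohort <- function(params, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  L <- nrow(params$loci)
  need <- c(case = params$n_case, control = params$n_control)
  got <- list(case = list(), control = list())
  n_got <- c(case = 0L, control = 0L)
  drawn <- 0L
  cap <- params$draw_cap * max(1L, sum(need))
  batch <- max(256L, 4L * sum(need))
  while (any(n_got < need)) {
    if (drawn >= cap)
      stop("simulation error: acceptance loop exceeded draw cap (",
           cap, " families); is the requested prevalence reachable?")
    B <- min(batch, cap - drawn)
    drawn <- drawn + B
    mo <- matrix(stats::rbinom(B * L, 2L, rep(params$maf, each = B)), B, L)
    fa <- matrix(stats::rbinom(B * L, 2L, rep(params$maf, each = B)), B, L)
    transmit <- function(g) {
      t <- matrix(0L, B, L)
      t[g == 2L] <- 1L
      het <- g == 1L
      t[het] <- stats::rbinom(sum(het), 1L,
                              rep(params$tau, each = B)[het])
      t
    }
    off <- transmit(mo) + transmit(fa)
    eta <- stats::qlogis(params$prevalence) +
      risk_class(mo, params$maternal_model) %*% log(params$maternal_or) +
      risk_class(off, params$fetal_model) %*% log(params$fetal_or)
    if (!is.null(params$combo)) {
      mi <- match(params$combo$maternal_rsid, params$loci$rsid)
      fi <- match(params$combo$fetal_rsid, params$loci$rsid)
      both <- risk_class(mo[, mi], params$maternal_model) &
        risk_class(off[, fi], params$fetal_model)
      eta <- eta + both * log(params$combo$or)
    }
    case <- stats::rbinom(B, 1L, stats::plogis(as.vector(eta))) == 1L
    for (s in c("case", "control")) {
      want <- need[[s]] - n_got[[s]]
      if (want <= 0L) next
      idx <- which(if (s == "case") case else !case)
      idx <- idx[seq_len(min(want, length(idx)))]
      if (length(idx)) {
        got[[s]][[length(got[[s]]) + 1L]] <-
          list(mo = mo[idx, , drop = FALSE], fa = fa[idx, , drop = FALSE],
               off = off[idx, , drop = FALSE])
        n_got[[s]] <- n_got[[s]] + length(idx)
      }
    }
  }
  bindrole <- function(s, r) do.call(rbind, lapply(got[[s]], `[[`, r))
  mo <- rbind(bindrole("case", "mo"), bindrole("control", "mo"))
  fa <- rbind(bindrole("case", "fa"), bindrole("control", "fa"))
  off <- rbind(bindrole("case", "off"), bindrole("control", "off"))
  n <- sum(need)
  status <- rep(c("case", "control"), times = need)
  fid <- sprintf("%s%04d", ifelse(status == "case", "PE", "CT"), seq_len(n))
  # exact dyad split per arm
  father_present <- rep(TRUE, n)
  for (s in c("case", "control")) {
    frac <- if (s == "case") params$dyad_fraction_case
            else params$dyad_fraction_control
    arm <- which(status == s)
    k <- round(frac * length(arm))
    if (k > 0L) father_present[sample(arm, k)] <- FALSE
  }
  # long genotype table from dosage matrices
  a_of <- function(d, which_a) {
    # which_a = 1 -> first allele (major unless hom-minor), 2 -> second
    m <- rep(params$loci$major, each = n)
    mi <- rep(params$loci$minor, each = n)
    d <- as.vector(d)
    if (which_a == 1L) ifelse(d == 2L, mi, m) else ifelse(d >= 1L, mi, m)
  }
  roles <- list(mother = mo, father = fa, offspring = off)
  geno <- do.call(rbind, lapply(names(roles), function(r) {
    data.frame(family_id = rep(fid, times = nrow(params$loci)),
               role = r,
               rsid = rep(params$loci$rsid, each = n),
               a1 = a_of(roles[[r]], 1L), a2 = a_of(roles[[r]], 2L),
               stringsAsFactors = FALSE)
  }))
  geno <- geno[!(geno$role == "father" &
                   !father_present[match(geno$family_id, fid)]), ]
  families <- data.frame(family_id = fid, status = status,
                         father_present = father_present,
                         stringsAsFactors = FALSE)
  out <- triad_cohort(params$loci, families, geno)
  attr(out, "seed") <- seed
  out
}

#' Monte-Carlo power (or size) of a pipeline test
#'
#' Simulates `n_reps` cohorts from `params` and reports the fraction of
#' replicates in which the chosen test rejects at level `alpha`, with a
#' binomial standard error and normal-approximation confidence interval.
#' With null parameters the estimate is the empirical type-I error and
#' should sit near `alpha`.
#'
#' @param params a [sim_params()] object.
#' @param test `"allelic"` (offspring case-control Pearson test), `"tdt"`
#'   (overall-stratum TDT), or `"combo"` (global combined-genotype test).
#' @param rsid locus tested (default: first locus; for `"combo"`, a length-2
#'   vector maternal/fetal, defaulting to the loci of `params$combo` or the
#'   first two loci).
#' @param status families used for the TDT stratum (default `"control"`).
#' @param n_reps number of simulated cohorts; below 100 the estimate is
#'   flagged as unstable.
#' @param alpha nominal test level.
#' @param seed seed for the replicate stream; replicate r uses `seed + r`.
#' @return list with `power`, `se`, `ci_low`, `ci_high`, `n_reps`, `alpha`,
#'   `unstable`.
#' @export
estimate_power <- function(params, test = c("allelic", "tdt", "combo"),
                           rsid = NULL, status = "control",
                           n_reps = 1000, alpha = 0.05, seed = 1) {
  test <- match.arg(test)
  if (is.null(rsid))
    rsid <- switch(test,
                   combo = if (!is.null(params$combo))
                     c(params$combo$maternal_rsid, params$combo$fetal_rsid)
                   else params$loci$rsid[1:2],
                   params$loci$rsid[1L])
  pvals <- vapply(seq_len(n_reps), function(r) {
    coh <- simulate_cohort(params, seed = seed + r)
    switch(test,
           allelic = pearson_chi2(
             allele_count_table(coh, rsid, "offspring"))$p_value,
           tdt = tdt(coh, rsid, status = status)$p_value[1L],
           combo = combo_global_test(
             combo_table(coh, rsid[1L], rsid[2L],
                         params$maternal_model, params$fetal_model))$p_value)
  }, numeric(1))
  rej <- mean(pvals < alpha, na.rm = TRUE)
  se <- sqrt(rej * (1 - rej) / n_reps)
  list(power = rej, se = se,
       ci_low = max(0, rej - 1.96 * se), ci_high = min(1, rej + 1.96 * se),
       n_reps = n_reps, alpha = alpha, unstable = n_reps < 100)
}
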