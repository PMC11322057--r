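#' Pearson chi-square test on a contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson goodness-of-fit
#' statistic for an r x c case-control count table, with
#' df = (r-1)(c-1) and the p-value from the upper chi-square tail.
#'
#' @param table count matrix with non-negative entries and no zero margin.
#' @return list of class `assoc_test` with `chi2`, `df`, `p_value`,
#'   `expected`, `test = "pearson"`.
#' @examples
#' pearson_chi2(matrix(c(74, 57, 74, 103), 2))  # chi2 = 6.499
#' @export
pearson_chi2 <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0))
  r <- rowSums(table); c <- colSums(table); n <- sum(table)
  if (any(r == 0) || any(c == 0))
    stop("degenerate table: zero row or column margin")
  e <- outer(r, c) / n
  chi2 <- sum((table - e)^2 / e)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 expected = e, test = "pearson"),
            class = "assoc_test")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by the point-probability rule: conditioning on the
#' margins, the p-value is the sum of hypergeometric probabilities of all
#' tables no more probable than the observed one (a relative tolerance of
#' 1e-7 absorbs floating-point ties).
#'
#' @param table 2x2 count matrix.
#' @return list of class `assoc_test` with `p_value`, `test = "fisher"`.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))  # p = 34/70
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L))
    stop("fisher_exact requires a 2x2 table")
  m <- sum(table[1L, ]); n <- sum(table[2L, ]); k <- sum(table[, 1L])
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(table[1L, 1L], m, n, k)
  p <- min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
  structure(list(chi2 = NA_real_, df = NA_integer_, p_value = p,
                 test = "fisher"), class = "assoc_test")
}

#' Crude odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with rows (case, control) and columns (exposed, baseline),
#' computes OR = (n11 n22)/(n12 n21), the Woolf/Wald 95\% interval
#' exp(log OR +/- z sqrt(sum 1/n_ij)), and the Wald p-value. If any cell is
#' zero, the Haldane-Anscombe correction (+0.5 to every cell) is applied and
#' the result is flagged via `corrected = TRUE`.
#'
#' @param table 2x2 count matrix; `odds_ratio(table, invert = TRUE)` reports
#'   the reciprocal orientation (baseline category in cases vs controls), as
#'   some published tables do.
#' @param conf_level confidence level (default 0.95).
#' @param invert report 1/OR with the interval flipped accordingly.
#' @return list of class `odds_ratio` with `or`, `ci_low`, `ci_high`,
#'   `p_value`, `log_se`, `corrected`, `orientation`.
#' @examples
#' odds_ratio(matrix(c(74, 57, 74, 103), 2))  # OR 1.807 (1.144-2.852)
#' @export
odds_ratio <- function(table, conf_level = 0.95, invert = FALSE) {
  if (!is.matrix(table) || any(dim(table) != 2L))
    stop("odds_ratio requires a 2x2 table")
  corrected <- any(table == 0)
  t <- unname(table + if (corrected) 0.5 else 0)
  or <- (t[1L, 1L] * t[2L, 2L]) / (t[1L, 2L] * t[2L, 1L])
  se <- sqrt(sum(1 / t))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- exp(log(or) - z * se); hi <- exp(log(or) + z * se)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  if (invert) {
    tmp <- lo; lo <- 1 / hi; hi <- 1 / tmp; or <- 1 / or
  }
  cn <- colnames(table); rn <- rownames(table)
  orientation <- sprintf("%s in %s vs %s",
                         if (is.null(cn)) "col1" else cn[1L + invert],
                         if (is.null(rn)) "row1" else rn[1L],
                         if (is.null(rn)) "row2" else rn[2L])
  structure(list(or = or, ci_low = lo, ci_high = hi, p_value = p,
                 log_se = se, corrected = corrected,
                 conf_level = conf_level, orientation = orientation),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("OR = %.3f (%d%% CI %.3f-%.3f), p = %.3g [%s]%s\n",
              x$or, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$p_value, x$orientation,
              if (x$corrected) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' @export
print.assoc_test <- function(x, ...) {
  if (x$test == "pearson")
    cat(sprintf("Pearson chi2 = %.3f, df = %d, p = %.3g\n",
                x$chi2, x$df, x$p_value))
  else
    cat(sprintf("Fisher exact p = %.3g\n", x$p_value))
  invisible(x)
}

#' Single-predictor logistic odds ratio (cross-check)
#'
#' Fits case/control status on a binary exposure by maximum-likelihood
#' logistic regression (via [stats::glm()]). On a saturated 2x2 table the
#' fitted odds ratio equals the crude odds ratio; this is exposed as a
#' cross-check, not as a separate result.
#'
#' @param table 2x2 count matrix, rows (case, control), columns (exposed,
#'   baseline).
#' @return list with `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
or_logistic <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  d <- data.frame(case = c(1, 1, 0, 0), exposed = c(1, 0, 1, 0),
                  w = as.vector(t(table)))
  fit <- stats::glm(case ~ exposed, family = stats::binomial(),
                    data = d, weights = d$w)
  b <- stats::coef(fit)[["exposed"]]
  se <- sqrt(stats::vcov(fit)["exposed", "exposed"])
  list(or = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
       p_value = 2 * stats::pnorm(-abs(b) / se))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Pearson goodness-of-fit chi-square (df = 1) comparing observed AA/AB/BB
#' counts in one group (conventionally the controls) with the counts
#' expected under Hardy-Weinberg proportions at the allele frequency
#' estimated from the same counts. A monomorphic sample is flagged and
#' returns chi2 = 0.
#'
#' @param counts numeric vector of three genotype counts, ordered
#'   major-homozygote, heterozygote, minor-homozygote.
#' @return list of class `hwe_test` with `chi2`, `df`, `p_value`,
#'   `observed`, `expected`, `maf`, `monomorphic`.
#' @examples
#' hwe_test(c(30, 40, 30))  # chi2 = 4, p = 0.0455
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype counts")
  q <- (2 * counts[3L] + counts[2L]) / (2 * n)  # minor-allele frequency
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  monomorphic <- q == 0 || q == 1
  chi2 <- if (monomorphic) 0 else sum((counts - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, 1L, lower.tail = FALSE),
                 observed = counts, expected = expected, maf = q,
                 monomorphic = monomorphic),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE chi2 = %.3f (df 1), p = %.3g, MAF = %.3f%s\n",
              x$chi2, x$p_value, x$maf,
              if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

# "auto" rule: Fisher when any expected count < 5, else Pearson
select_test <- function(table, test = c("auto", "pearson", "fisher")) {
  test <- match.arg(test)
  if (test == "auto") {
    e <- outer(rowSums(table), colSums(table)) / sum(table)
    test <- if (any(e < 5)) "fisher" else "pearson"
  }
  test
}
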