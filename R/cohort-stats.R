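#' Agreement counts between two binary risk classifiers
#'
#' Cell counts of the paired high/low classifications of a reference tool
#' (e.g. FRAX-HFP) and a comparator (e.g. P_Fx): `both_high`, `both_low`,
#' `down` (reference high, comparator low) and `up` (reference low, comparator
#' high).
#'
#' @param both_high,both_low,down,up Non-negative integer counts.
#' @return Object of class `agreement_counts`.
#' @export
#' @examples
#' agreement_counts(227, 284, 162, 27)
agreement_counts <- function(both_high, both_low, down, up) {
  counts <- c(both_high = both_high, both_low = both_low, down = down, up = up)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("agreement counts must be non-negative integers")
  }
  structure(as.list(counts), total = sum(counts), class = "agreement_counts")
}

#' @export
print.agreement_counts <- function(x, ...) {
  cat("Paired risk-classification counts (N =", attr(x, "total"), ")\n")
  cat(sprintf("  both high %d | both low %d | down-classified %d | up-classified %d\n",
              x$both_high, x$both_low, x$down, x$up))
  invisible(x)
}

#' Classify subjects by FRAX hip-fracture probability
#'
#' High risk iff FRAX-HFP is strictly greater than the threshold (2% by
#' default).
#'
#' @param frax_hfp Percent values >= 0 (vectorised).
#' @param threshold Percent.
#' @return Character vector `"high"`/`"low"`.
#' @export
classify_frax <- function(frax_hfp, threshold = 2) {
  if (any(frax_hfp < 0)) stop("FRAX-HFP must be >= 0")
  ifelse(frax_hfp > threshold, "high", "low")
}

#' Classify subjects by the top tertile of P_Fx
#'
#' High risk iff P_Fx is strictly greater than the cohort's 66.67th percentile
#' (linear-interpolation quantile); ties at the threshold are low risk. The
#' tertile rule is used because no established P_Fx threshold exists and it is
#' insensitive to outliers.
#'
#' @param pfx_values Percent values (>= 3 of them).
#' @return List with `class` (character vector `"high"`/`"low"`) and
#'   `threshold` (the tertile cut in percent).
#' @export
#' @examples
#' classify_pfx_tertile(1:9)
classify_pfx_tertile <- function(pfx_values) {
  if (length(pfx_values) < 3) stop("need at least 3 P_Fx values for a tertile split")
  thr <- unname(stats::quantile(pfx_values, 2 / 3, type = 7))
  list(class = ifelse(pfx_values > thr, "high", "low"), threshold = thr)
}

#' Cohen's kappa for paired binary classifications
#'
#' Chance-corrected agreement `kappa = (Po - Pe) / (1 - Pe)`, with observed
#' agreement `Po = (both_high + both_low)/N` and expected agreement `Pe` from
#' the product of the marginal classification rates. Returns `NA` when the
#' marginals are degenerate (`Pe = 1`).
#'
#' @param counts An [agreement_counts()].
#' @return Kappa in [-1, 1], or `NA`.
#' @export
#' @examples
#' cohens_kappa(agreement_counts(227, 284, 162, 27))   # ~0.48
cohens_kappa <- function(counts) {
  stopifnot(inherits(counts, "agreement_counts"))
  n <- attr(counts, "total")
  if (n == 0) stop("empty table")
  po <- (counts$both_high + counts$both_low) / n
  ref_high <- (counts$both_high + counts$down) / n
  cmp_high <- (counts$both_high + counts$up) / n
  pe <- ref_high * cmp_high + (1 - ref_high) * (1 - cmp_high)
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' McNemar's test on paired binary classifications
#'
#' Tests whether the two classifiers disagree symmetrically, using only the
#' discordant cells. With fewer than 25 discordant subjects an exact two-sided
#' binomial test is used; otherwise the continuity-corrected chi-square
#' statistic `(|down - up| - 1)^2 / (down + up)` on 1 df. With no discordant
#' pairs the p-value is 1 by convention (flagged via the `method` element).
#'
#' @param counts An [agreement_counts()].
#' @return List with `p_value`, `method` and the discordant counts.
#' @export
mcnemar_test <- function(counts) {
  stopifnot(inherits(counts, "agreement_counts"))
  d <- counts$down; u <- counts$up
  if (d + u == 0) {
    return(list(p_value = 1, method = "degenerate (no discordant pairs)",
                down = d, up = u))
  }
  if (d + u < 25) {
    p <- stats::binom.test(d, d + u, p = 0.5)$p.value
    method <- "exact binomial"
  } else {
    tab <- matrix(c(counts$both_high, u, d, counts$both_low), 2, 2)
    p <- stats::mcnemar.test(tab, correct = TRUE)$p.value
    method <- "chi-square with continuity correction"
  }
  list(p_value = p, method = method, down = d, up = u)
}

#' Reclassification metrics of the comparator against the reference
#'
#' `down_pct` is the percentage of reference-high subjects reclassified low by
#' the comparator, `100 * down / (both_high + down)`; `net_down_pct` is the
#' down-classifications minus up-classifications normalised by the cohort
#' size, `100 * (down - up) / N`.
#'
#' @param counts An [agreement_counts()].
#' @return List with `down_pct` (`NA` when the reference-high margin is empty)
#'   and `net_down_pct`.
#' @export
#' @examples
#' reclassification(agreement_counts(227, 284, 162, 27))
reclassification <- function(counts) {
  stopifnot(inherits(counts, "agreement_counts"))
  n <- attr(counts, "total")
  ref_high <- counts$both_high + counts$down
  list(
    down_pct = if (ref_high > 0) 100 * counts$down / ref_high else NA_real_,
    net_down_pct = 100 * (counts$down - counts$up) / n
  )
}

#' Odds ratio, Wald confidence interval and Fisher exact p for a 2x2 table
#'
#' `OR = a*d / (b*c)` on the table `rbind(c(a, b), c(c, d))` (rows = groups,
#' columns = high/low risk). If any cell is zero the Haldane-Anscombe
#' correction (+0.5 to every cell) is applied before the OR and its CI are
#' computed. The 95% CI is `exp(log OR +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`
#' on the (possibly corrected) cells. The two-sided p-value is Fisher's exact
#' test on the uncorrected table. Empty margins give `NA` OR.
#'
#' @param a,b,c,d Non-negative counts.
#' @param conf_level Confidence level of the Wald interval.
#' @return List with `or`, `ci` (length 2), `p_value`, `corrected` (logical).
#' @export
#' @examples
#' odds_ratio(91, 49, 17, 52)   # OR = 91*52 / (49*17)
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be >= 0")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_), p_value = NA_real_,
                corrected = FALSE))
  }
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
  list(or = or, ci = ci, p_value = p, corrected = corrected)
}

#' Compliance-adjusted relative risk
#'
#' Mixture of protected and unprotected risk under partial compliance:
#' `RR_adj = compliance * rr + (1 - compliance)`. At 50% compliance an RR of
#' 0.38 becomes 0.69 and an RR of 0.43 becomes 0.715 (printed as 0.72).
#'
#' @param rr Relative risk under full compliance (>= 0, vectorised).
#' @param compliance Fraction in [0, 1].
#' @return Adjusted RR.
#' @seealso [format_rr()] for the half-away-from-zero 2-decimal formatting.
#' @export
compliance_adjust <- function(rr, compliance) {
  if (any(rr < 0, na.rm = TRUE)) stop("rr must be >= 0")
  if (compliance < 0 || compliance > 1) stop("compliance must lie in [0, 1]")
  compliance * rr + (1 - compliance)
}

#' Format a relative risk to 2 decimals, rounding half away from zero
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric rounded half away from zero.
#' @export
#' @examples
#' format_rr(0.715)   # 0.72
format_rr <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Two-sample sample size from Cohen's d (normal approximation)
#'
#' `n = 2 * (z_{1-alpha/2} + z_{power})^2 / d^2` subjects per group, rounded
#' to the nearest integer with a floor of 2 per group. With d = 0.81,
#' alpha = 0.05 and power 0.90 this gives 32 per group.
#'
#' @param effect_size_d Cohen's d (> 0).
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @return Integer subjects per group.
#' @export
#' @examples
#' sample_size(0.81, 0.05, 0.90)   # 32
sample_size <- function(effect_size_d, alpha = 0.05, power = 0.90) {
  if (effect_size_d <= 0) stop("effect size must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  raw <- 2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / effect_size_d^2
  max(2L, as.integer(round(raw)))
}

#' Classify relative risk against the trial-derived 0.4 threshold
#'
#' High RR (limited protector benefit) iff RR strictly exceeds 0.4, the mean
#' relative risk reported by a systematic review of hip-protector randomised
#' trials. Undefined RRs (`NA`) stay `NA` and are excluded from counts.
#'
#' @param rr Relative risk (vectorised; `NA` allowed).
#' @param threshold Cut-off.
#' @return Character vector `"high"`/`"low"` with `NA` preserved.
#' @export
classify_rr <- function(rr, threshold = 0.4) {
  ifelse(is.na(rr), NA_character_, ifelse(rr > threshold, "high", "low"))
}
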