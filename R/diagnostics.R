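# Heterogeneity, pleiotropy, sensitivity and multiplicity diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j * (ratio_j - beta_fe)^2)` about the fixed-effect IVW centre,
#' referred to a chi-square with `J - 1` degrees of freedom (upper tail).
#' This is exactly the Q used to inflate the multiplicative-random-effects
#' IVW standard error.
#'
#' @param w a `wald_ratios` object (or a `harmonized_set`).
#' @return list with elements `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(w) {
  if (inherits(w, "harmonized_set")) w <- wald_ratios(w)
  J <- nrow(w)
  if (J < 2L) stop("Cochran's Q requires at least 2 SNPs", call. = FALSE)
  beta_fe <- sum(w$weight * w$ratio) / sum(w$weight)
  Q <- sum(w$weight * (w$ratio - beta_fe)^2)
  list(Q = Q, df = J - 1L,
       pvalue = stats::pchisq(Q, df = J - 1L, lower.tail = FALSE))
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the multiplicative-random-effects IVW estimate excluding each
#' SNP in turn, in input order.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @param ci_level confidence level.
#' @return data.frame with one row per excluded SNP: `snp_id`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pvalue`, `n_snp`.
#' @export
leave_one_out <- function(h, ci_level = 0.95) {
  J <- nrow(h)
  if (J < 2L) stop("leave-one-out requires at least 2 SNPs", call. = FALSE)
  rows <- lapply(seq_len(J), function(j) {
    est <- mr_ivw(hset_rows(h, -j), "mre", ci_level)
    data.frame(snp_id = h$snp_id[j], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, n_snp = est$n_snp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`adjusted = min(1, p * m)`, per-test threshold `alpha / m`)
#' or Benjamini-Hochberg step-up FDR control. Flags mark tests with
#' `adjusted < alpha` (strict). Adjustment delegates to [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha significance level (default 0.05).
#' @return list with `adjusted` (numeric vector), `significant` (logical
#'   vector), `threshold` (Bonferroni: the per-test threshold `alpha / m`;
#'   BH: the data-dependent step-up cutoff, 0 when nothing is flagged) and
#'   `method`.
#' @export
adjust_pvalues <- function(pvalues, method = c("bonferroni", "bh"),
                           alpha = 0.05) {
  method <- match.arg(method)
  bad <- which(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)
  if (length(bad))
    stop("p-value outside [0, 1] at index ", bad[1], call. = FALSE)
  m <- length(pvalues)
  adjusted <- stats::p.adjust(pvalues,
                              method = if (method == "bh") "BH"
                                       else "bonferroni")
  significant <- adjusted < alpha
  threshold <- if (method == "bonferroni") {
    alpha / m
  } else if (any(significant)) {
    max(pvalues[significant])
  } else 0
  list(adjusted = adjusted, significant = significant,
       threshold = threshold, method = method)
}

#' Funnel-plot data
#'
#' One row per SNP with the Wald ratio and its precision (`1 / se`);
#' asymmetry around the IVW centre line suggests directional pleiotropy.
#'
#' @param w a `wald_ratios` object (or a `harmonized_set`).
#' @return data.frame with columns `snp_id`, `ratio`, `precision` and a
#'   constant `center` column holding the IVW estimate (the funnel centre
#'   line).
#' @export
funnel_data <- function(w) {
  if (inherits(w, "harmonized_set")) w <- wald_ratios(w)
  center <- sum(w$weight * w$ratio) / sum(w$weight)
  data.frame(snp_id = w$snp_id, ratio = w$ratio, precision = 1 / w$se,
             center = center, stringsAsFactors = FALSE)
}

#' Full diagnostics report
#'
#' Cochran's Q with its I-squared companion, the MR-Egger intercept triple,
#' the leave-one-out table and the funnel table for one harmonized
#' instrument set.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @param ci_level confidence level for the leave-one-out estimates.
#' @return list of class `mr_diagnostics`: `Q`, `Q_df`, `Q_pvalue`, `I2`
#'   (`max(0, (Q - df) / Q)`), `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p` (NA with fewer than 3 SNPs), `leave_one_out`,
#'   `funnel`.
#' @export
mr_diagnostics <- function(h, ci_level = 0.95) {
  w <- wald_ratios(h)
  q <- cochran_q(w)
  i2 <- if (q$Q > 0) max(0, (q$Q - q$df) / q$Q) else 0
  eg <- if (nrow(h) >= 3L) {
    tryCatch(mr_egger(h, ci_level)$extras,
             error = function(e) list(intercept = NA_real_,
                                      intercept_se = NA_real_,
                                      intercept_p = NA_real_))
  } else {
    list(intercept = NA_real_, intercept_se = NA_real_,
         intercept_p = NA_real_)
  }
  structure(list(
    Q = q$Q, Q_df = q$df, Q_pvalue = q$pvalue, I2 = i2,
    egger_intercept = eg$intercept,
    egger_intercept_se = eg$intercept_se,
    egger_intercept_p = eg$intercept_p,
    leave_one_out = leave_one_out(h, ci_level),
    funnel = funnel_data(w)), class = "mr_diagnostics")
}

#' @export
print.mr_diagnostics <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g (I2 = %.1f%%)\n",
              x$Q, x$Q_df, x$Q_pvalue, 100 * x$I2))
  if (is.finite(x$egger_intercept))
    cat(sprintf("Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_p))
  cat(sprintf("leave-one-out: %d estimates; funnel: %d points\n",
              nrow(x$leave_one_out), nrow(x$funnel)))
  invisible(x)
}
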