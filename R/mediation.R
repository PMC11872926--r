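# Stepwise mediation decomposition.
#
# The causal chain exposure -> mediator -> outcome is decomposed into
#   beta_all  : total exposure -> outcome effect,
#   beta1     : exposure -> mediator effect,
#   beta2     : mediator -> outcome effect,
#   beta_med  = beta1 * beta2            (indirect, product of coefficients),
#   beta_dir  = beta_all - beta_med      (direct),
# with the indirect-effect SE by the first-order delta method
#   se_med = sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
# (no cross term). All effects live on the log / log-OR scale; odds-ratio
# views are exp() of the betas.

#' Product-of-coefficients mediation decomposition
#'
#' @param beta_all,se_all total exposure -> outcome effect and SE (log-OR).
#' @param beta1,se1 exposure -> mediator effect and SE.
#' @param beta2,se2 mediator -> outcome effect and SE (log-OR).
#' @param ci_level confidence level for the indirect-effect CI.
#' @return A list of class `mediation_result` with fields `beta_all`,
#'   `se_all`, `beta1`, `se1`, `beta2`, `se2`, `beta_med`, `se_med`,
#'   `med_ci_low`, `med_ci_high`, `med_pvalue`, `beta_dir`,
#'   `prop_mediated` (`beta_med / beta_all`; `NA` with a
#'   `prop_undefined = TRUE` flag when `|beta_all| < 1e-12`),
#'   `sign_discordant` (`TRUE` when the indirect effect opposes the total
#'   effect) and odds-ratio views `or_all`, `or_med`, `or_dir`. The
#'   identities `beta_dir + beta_med == beta_all` and
#'   `beta_med == beta1 * beta2` hold exactly.
#' @export
mediate_decompose <- function(beta_all, se_all, beta1, se1, beta2, se2,
                              ci_level = 0.95) {
  for (s in c(se_all = se_all, se1 = se1, se2 = se2))
    if (!is.finite(s) || s <= 0)
      stop("standard errors must be positive", call. = FALSE)
  z <- z_crit(ci_level)
  beta_med <- beta1 * beta2
  se_med <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  beta_dir <- beta_all - beta_med
  prop_undefined <- abs(beta_all) < 1e-12
  prop <- if (prop_undefined) NA_real_ else beta_med / beta_all
  med_p <- if (se_med > 0) two_sided_p(beta_med / se_med) else 1
  structure(list(
    beta_all = beta_all, se_all = se_all,
    beta1 = beta1, se1 = se1,
    beta2 = beta2, se2 = se2,
    beta_med = beta_med, se_med = se_med,
    med_ci_low = beta_med - z * se_med,
    med_ci_high = beta_med + z * se_med,
    med_pvalue = med_p,
    beta_dir = beta_dir,
    prop_mediated = prop, prop_undefined = prop_undefined,
    sign_discordant = !prop_undefined && !is.na(prop) && prop < 0,
    or_all = exp(beta_all), or_med = exp(beta_med), or_dir = exp(beta_dir),
    ci_level = ci_level, reverse_estimate = NULL),
    class = "mediation_result")
}

#' Reverse-direction MR
#'
#' Probes reverse causation by swapping the roles: instruments are selected
#' from the outcome GWAS and the causal effect of the outcome on the
#' exposure is estimated.
#'
#' @param outcome,exposure summary-statistics data.frames; instruments come
#'   from `outcome`.
#' @param ld r-squared matrix covering the outcome SNPs.
#' @param sel a [selection_config()].
#' @param method estimator name (see [mr_estimate()]).
#' @param seed RNG seed for bootstrap-based estimators.
#' @param ci_level confidence level.
#' @return An `mr_estimate` for the outcome -> exposure effect, with the
#'   harmonized set in `attr(, "harmonized")`.
#' @export
reverse_mr <- function(outcome, exposure, ld, sel = selection_config(),
                       method = "ivw_mre", seed = NULL, ci_level = 0.95) {
  h <- select_instruments(outcome, exposure, ld, sel)
  if (nrow(h) == 0L)
    stop("reverse MR: no instruments for the outcome trait", call. = FALSE)
  est <- mr_estimate(h, method, ci_level = ci_level, seed = seed)
  attr(est, "harmonized") <- h
  est
}

#' Stepwise two-sample MR mediation analysis
#'
#' Runs the three univariable MR fits of the stepwise design — each with
#' its own instrument selection from its own exposure-role table — and the
#' product-of-coefficients decomposition:
#' (a) exposure -> outcome gives `beta_all`;
#' (b) exposure -> mediator gives `beta1`;
#' (c) mediator -> outcome gives `beta2` (instruments selected from the
#' mediator GWAS). Optionally a reverse MR (outcome -> exposure) is
#' attached. A run manifest records thresholds, seed and per-step SNP
#' accounting.
#'
#' @param exposure,mediator,outcome summary-statistics data.frames over a
#'   shared SNP-identifier space.
#' @param ld r-squared matrix covering the SNPs reaching the clumping stage.
#' @param sel a [selection_config()], shared by all steps.
#' @param method estimator name used for every step (default `"ivw_mre"`,
#'   the primary method).
#' @param seed RNG seed; step-specific seeds are derived from it, and the
#'   whole result is deterministic given it.
#' @param ci_level confidence level.
#' @param include_reverse attach the reverse-MR estimate (default `TRUE`).
#' @return A `mediation_result` whose `estimates` field holds the three
#'   step `mr_estimate`s (`all`, `step1`, `step2`), `harmonized` the three
#'   instrument sets, `reverse_estimate` the reverse MR (or `NULL`), and
#'   `manifest` the run manifest.
#' @export
run_two_step <- function(exposure, mediator, outcome, ld,
                         sel = selection_config(), method = "ivw_mre",
                         seed = NULL, ci_level = 0.95,
                         include_reverse = TRUE) {
  step_seed <- function(k) if (is.null(seed)) NULL else seed + k
  fit_step <- function(exp_tbl, out_tbl, label, k) {
    h <- select_instruments(exp_tbl, out_tbl, ld, sel)
    if (nrow(h) == 0L)
      stop("no instruments for step ", label, call. = FALSE)
    list(est = mr_estimate(h, method, ci_level = ci_level,
                           seed = step_seed(k)),
         h = h)
  }
  s_all <- fit_step(exposure, outcome, "total effect (exposure -> outcome)", 1L)
  s_b1 <- fit_step(exposure, mediator, "beta1 (exposure -> mediator)", 2L)
  s_b2 <- fit_step(mediator, outcome, "beta2 (mediator -> outcome)", 3L)

  res <- mediate_decompose(
    s_all$est$beta, s_all$est$se,
    s_b1$est$beta, s_b1$est$se,
    s_b2$est$beta, s_b2$est$se, ci_level)

  res$estimates <- list(all = s_all$est, step1 = s_b1$est, step2 = s_b2$est)
  res$harmonized <- list(all = s_all$h, step1 = s_b1$h, step2 = s_b2$h)
  if (include_reverse)
    res$reverse_estimate <- reverse_mr(outcome, exposure, ld, sel, method,
                                       step_seed(4L), ci_level)
  counts <- function(h) {
    ex <- exclusion_log(h)
    c(retained = nrow(h), excluded = nrow(ex))
  }
  res$manifest <- list(
    method = method, seed = seed, ci_level = ci_level,
    selection = unclass(sel),
    include_reverse = include_reverse,
    snp_counts = list(all = counts(s_all$h), step1 = counts(s_b1$h),
                      step2 = counts(s_b2$h)))
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Stepwise MR mediation decomposition (log-OR scale)\n")
  cat(sprintf("  beta_all = %8.4f (SE %.4f)   total effect\n",
              x$beta_all, x$se_all))
  cat(sprintf("  beta1    = %8.4f (SE %.4f)   exposure -> mediator\n",
              x$beta1, x$se1))
  cat(sprintf("  beta2    = %8.4f (SE %.4f)   mediator -> outcome\n",
              x$beta2, x$se2))
  cat(sprintf("  beta_med = %8.4f (SE %.4f)   %d%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta_med, x$se_med, round(100 * x$ci_level),
              x$med_ci_low, x$med_ci_high, x$med_pvalue))
  cat(sprintf("  beta_dir = %8.4f              direct effect\n", x$beta_dir))
  if (x$prop_undefined) {
    cat("  proportion mediated undefined (total effect ~ 0)\n")
  } else {
    cat(sprintf("  proportion mediated = %.3f%s\n", x$prop_mediated,
                if (x$sign_discordant) " (sign-discordant with total effect)"
                else ""))
  }
  if (!is.null(x$reverse_estimate))
    cat(sprintf("  reverse MR: beta = %.4g (SE %.4g), p = %.3g\n",
                x$reverse_estimate$beta, x$reverse_estimate$se,
                x$reverse_estimate$pvalue))
  invisible(x)
}

#' Serialize a mediation result to structured JSON text
#'
#' @param x a `mediation_result`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
mediation_report_json <- function(x, path = NULL) {
  flat_est <- function(e) if (is.null(e)) NULL else {
    e$extras$weights <- NULL
    unclass(e)
  }
  payload <- list(
    decomposition = x[c("beta_all", "se_all", "beta1", "se1", "beta2",
                        "se2", "beta_med", "se_med", "med_ci_low",
                        "med_ci_high", "med_pvalue", "beta_dir",
                        "prop_mediated", "prop_undefined",
                        "sign_discordant", "or_all", "or_med", "or_dir")],
    estimates = lapply(x$estimates, flat_est),
    reverse_estimate = flat_est(x$reverse_estimate),
    manifest = x$manifest)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
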