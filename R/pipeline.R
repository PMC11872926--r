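# Multi-exposure screening orchestration: many exposures against one
# outcome, with multiplicity correction over the primary (IVW-MRE)
# p-values and forest-ready table export.

#' Screen many exposures against one outcome
#'
#' For each exposure table: select and harmonize instruments, run the
#' requested estimators and diagnostics, then adjust the primary
#' (multiplicative-random-effects IVW) p-values across exposures by both
#' Bonferroni and Benjamini-Hochberg at `alpha`. Exposures that yield no
#' instruments are recorded as skipped, not fatal errors; ordering follows
#' the input order.
#'
#' @param exposures named list of summary-statistics data.frames (unnamed
#'   lists get `exposure_1`, `exposure_2`, ... labels).
#' @param outcome summary-statistics data.frame.
#' @param ld r-squared matrix covering the exposure SNPs.
#' @param sel a [selection_config()] shared by all exposures.
#' @param methods estimator names to run for each exposure; `"ivw_mre"` is
#'   always run (it is the screening method).
#' @param alpha significance level for both corrections (default 0.05).
#' @param ci_level confidence level.
#' @param seed RNG seed; per-exposure seeds are derived from it.
#' @param diagnostics also compute [mr_diagnostics()] per exposure
#'   (default `TRUE`; requires at least 2 instruments, otherwise `NULL`).
#' @param quiet suppress per-exposure progress messages (default `TRUE`).
#' @return A list of class `mr_screen` with elements `table` (one row per
#'   analyzed exposure: `exposure`, `n_snp`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `p_bonferroni`, `p_bh`, `sig_bonferroni`,
#'   `sig_bh`), `results` (per-exposure estimates/diagnostics/harmonized
#'   set), `skipped` (exposure label + reason), `bonferroni_threshold`,
#'   `alpha`, `methods`.
#' @export
mr_screen <- function(exposures, outcome, ld, sel = selection_config(),
                      methods = "ivw_mre", alpha = 0.05, ci_level = 0.95,
                      seed = NULL, diagnostics = TRUE, quiet = TRUE) {
  if (!is.list(exposures) || length(exposures) == 0L)
    stop("at least one exposure table is required", call. = FALSE)
  labels <- names(exposures)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- sprintf("exposure_%d", seq_along(exposures))
  methods <- union(methods, "ivw_mre")

  results <- list()
  skipped <- empty_skip <- data.frame(exposure = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)
  for (i in seq_along(exposures)) {
    lab <- labels[i]
    h <- select_instruments(exposures[[i]], outcome, ld, sel)
    if (nrow(h) == 0L) {
      skipped <- rbind(skipped, data.frame(exposure = lab,
                                           reason = "no instruments",
                                           stringsAsFactors = FALSE))
      if (!quiet) message(lab, ": skipped (no instruments)")
      next
    }
    ests <- lapply(methods, function(mth) {
      tryCatch(mr_estimate(h, mth, ci_level = ci_level,
                           seed = if (is.null(seed)) NULL else seed + i),
               error = function(e) NULL)
    })
    names(ests) <- methods
    diag <- if (diagnostics && nrow(h) >= 2L)
      mr_diagnostics(h, ci_level) else NULL
    if (!quiet)
      message(sprintf("%s: %d instrument(s), IVW-MRE p = %.3g", lab,
                      nrow(h), ests$ivw_mre$pvalue))
    results[[lab]] <- list(exposure = lab, estimates = ests,
                           diagnostics = diag, harmonized = h)
  }
  if (length(results) == 0L)
    return(structure(list(table = NULL, results = results,
                          skipped = skipped, alpha = alpha,
                          methods = methods,
                          bonferroni_threshold = NA_real_),
                     class = "mr_screen"))

  primary <- lapply(results, function(r) r$estimates$ivw_mre)
  p_raw <- vapply(primary, function(e) e$pvalue, numeric(1))
  bonf <- adjust_pvalues(p_raw, "bonferroni", alpha)
  bh <- adjust_pvalues(p_raw, "bh", alpha)
  tab <- data.frame(
    exposure = names(results),
    n_snp = vapply(primary, function(e) e$n_snp, integer(1)),
    beta = vapply(primary, function(e) e$beta, numeric(1)),
    se = vapply(primary, function(e) e$se, numeric(1)),
    ci_low = vapply(primary, function(e) e$ci_low, numeric(1)),
    ci_high = vapply(primary, function(e) e$ci_high, numeric(1)),
    pvalue = p_raw,
    p_bonferroni = bonf$adjusted,
    p_bh = bh$adjusted,
    sig_bonferroni = bonf$significant,
    sig_bh = bh$significant,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, results = results, skipped = skipped,
                 alpha = alpha, methods = methods,
                 bonferroni_threshold = bonf$threshold),
            class = "mr_screen")
}

#' Forest-ready long-format table
#'
#' One row per (exposure, method) pair with odds ratios and CI bounds,
#' suitable for external forest-plot rendering.
#'
#' @param result an `mr_screen` result.
#' @return data.frame with columns `exposure`, `method`, `n_snp`, `or`,
#'   `or_ci_low`, `or_ci_high`, `pvalue`.
#' @export
forest_table <- function(result) {
  stopifnot(inherits(result, "mr_screen"))
  if (length(result$results) == 0L)
    stop("empty screen result", call. = FALSE)
  rows <- list()
  for (r in result$results) {
    for (mth in names(r$estimates)) {
      e <- r$estimates[[mth]]
      if (is.null(e)) next
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = r$exposure, method = e$method, n_snp = e$n_snp,
        or = e$odds_ratio, or_ci_low = e$or_ci_low,
        or_ci_high = e$or_ci_high, pvalue = e$pvalue,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.mr_screen <- function(x, ...) {
  n_done <- length(x$results)
  cat(sprintf("MR screen: %d exposure(s) analyzed, %d skipped, alpha = %g\n",
              n_done, nrow(x$skipped), x$alpha))
  if (!is.null(x$table)) {
    cat(sprintf("  Bonferroni per-test threshold: %.3g\n",
                x$bonferroni_threshold))
    cat(sprintf("  significant: %d (Bonferroni), %d (BH)\n",
                sum(x$table$sig_bonferroni), sum(x$table$sig_bh)))
  }
  invisible(x)
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML mapping mirrors [selection_config()] plus optional `methods`,
#' `alpha`, `ci_level` and `seed` entries; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return list with elements `sel` (a `selection_config`), `methods`,
#'   `alpha`, `ci_level`, `seed`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  sel_keys <- c("p_threshold", "clump_r2", "clump_window_kb", "f_min",
                "palindrome_policy", "ambiguity_window")
  other_keys <- c("methods", "alpha", "ci_level", "seed")
  unknown <- setdiff(names(cfg), c(sel_keys, other_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sel <- do.call(selection_config, cfg[intersect(names(cfg), sel_keys)])
  list(sel = sel,
       methods = cfg$methods %||% "ivw_mre",
       alpha = cfg$alpha %||% 0.05,
       ci_level = cfg$ci_level %||% 0.95,
       seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
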