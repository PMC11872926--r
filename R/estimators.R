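# Causal-effect estimators for two-sample MR.
#
# All estimators consume a harmonized_set (aligned per-SNP exposure and
# outcome associations) and return an `mr_estimate`. Effects are computed
# and stored on the log-OR scale; odds ratios are derived views (exp).
# Wald tests use the normal reference distribution throughout, with CI
# multiplier qnorm(0.975) = 1.959963985 at the default 95% level.

#' Per-SNP Wald ratios
#'
#' The per-instrument causal-effect estimate `ratio_j = beta_outcome_j /
#' beta_exposure_j` with first-order SE `se_outcome_j / |beta_exposure_j|`
#' or second-order SE
#' `sqrt(se_out^2 / bx^2 + by^2 * se_exp^2 / bx^4)`.
#'
#' @param h a `harmonized_set`.
#' @param order `"first"` (default) or `"second"` order SEs.
#' @return A data.frame of class `wald_ratios` with columns `snp_id`,
#'   `ratio`, `se`, `weight` (`se^-2`); the source set is kept in
#'   `attr(, "harmonized")`.
#' @export
wald_ratios <- function(h, order = c("first", "second")) {
  order <- match.arg(order)
  bx <- h$beta_exposure
  zero <- h$snp_id[bx == 0]
  if (length(zero))
    stop("zero exposure effect for SNP(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  ratio <- h$beta_outcome / bx
  se <- if (order == "first") {
    h$se_outcome / abs(bx)
  } else {
    sqrt(h$se_outcome^2 / bx^2 + h$beta_outcome^2 * h$se_exposure^2 / bx^4)
  }
  structure(data.frame(snp_id = h$snp_id, ratio = ratio, se = se,
                       weight = se^-2, stringsAsFactors = FALSE),
            class = c("wald_ratios", "data.frame"),
            harmonized = h, order = order)
}

# assemble an mr_estimate from a point estimate and normal-theory SE
make_estimate <- function(method, beta, se, n_snp, ci_level = 0.95,
                          extras = list()) {
  z <- z_crit(ci_level)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    pvalue = two_sided_p(beta / se),
    odds_ratio = exp(beta), or_ci_low = exp(ci_low),
    or_ci_high = exp(ci_high),
    n_snp = as.integer(n_snp), ci_level = ci_level, extras = extras),
    class = "mr_estimate")
}

#' Inverse-variance weighted estimator
#'
#' Precision-weighted average of the per-SNP Wald ratios,
#' `beta = sum(w_j * ratio_j) / sum(w_j)` with `w_j = se_j^-2`. Under the
#' fixed-effect model `SE = (sum w_j)^-1/2`; under multiplicative random
#' effects (`"mre"`, the default) the SE is inflated by
#' `sqrt(max(1, Q / (J - 1)))` where `Q` is Cochran's heterogeneity
#' statistic — the SE never deflates, and with a single SNP MRE equals
#' fixed. P-values are two-sided normal.
#'
#' @param h a `harmonized_set` (or `wald_ratios`).
#' @param model `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @param ci_level confidence level (default 0.95).
#' @param order Wald-ratio SE order, see [wald_ratios()].
#' @return An `mr_estimate` (method `ivw_mre` or `ivw_fe`); `extras`
#'   carries `Q`, `Q_df` and the applied `inflation`.
#' @export
mr_ivw <- function(h, model = c("mre", "fixed"), ci_level = 0.95,
                   order = "first") {
  model <- match.arg(model)
  w <- if (inherits(h, "wald_ratios")) h else wald_ratios(h, order)
  J <- nrow(w)
  if (J < 1L) stop("no instruments", call. = FALSE)
  sw <- sum(w$weight)
  beta <- sum(w$weight * w$ratio) / sw
  se_fixed <- sw^-0.5
  Q <- sum(w$weight * (w$ratio - beta)^2)
  inflation <- if (model == "mre" && J > 1L) sqrt(max(1, Q / (J - 1))) else 1
  make_estimate(if (model == "mre") "ivw_mre" else "ivw_fe",
                beta, se_fixed * inflation, J, ci_level,
                extras = list(Q = Q, Q_df = J - 1L, inflation = inflation))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations with a free intercept, after orienting every pair so the
#' exposure association is non-negative; weights are `se_outcome^-2`. The
#' slope is the causal estimate; a non-zero intercept indicates directional
#' horizontal pleiotropy. Standard errors use multiplicative overdispersion
#' floored at 1. Requires at least 3 SNPs.
#'
#' @param h a `harmonized_set`.
#' @param ci_level confidence level.
#' @param constrain_intercept internal: force the intercept to 0 (the
#'   estimator then reproduces the fixed-effect IVW solution; no
#'   overdispersion scaling is applied in that mode).
#' @return An `mr_estimate` (method `egger`); `extras` carries `intercept`,
#'   `intercept_se`, `intercept_p` and the overdispersion `phi`.
#' @export
mr_egger <- function(h, ci_level = 0.95, constrain_intercept = FALSE) {
  J <- nrow(h)
  if (!constrain_intercept && J < 3L)
    stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  s <- ifelse(h$beta_exposure < 0, -1, 1)
  bx <- s * h$beta_exposure
  by <- s * h$beta_outcome
  w <- h$se_outcome^-2
  X <- if (constrain_intercept) cbind(slope = bx)
       else cbind(intercept = 1, slope = bx)
  if (!constrain_intercept && stats::var(bx) == 0)
    stop("no spread in instrument strength", call. = FALSE)
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * by)))
  resid <- by - drop(X %*% coefs)
  df <- J - ncol(X)
  cov0 <- solve(xtwx)
  if (constrain_intercept) {
    phi <- 1
  } else {
    phi <- max(1, sum(w * resid^2) / df)
  }
  ses <- sqrt(diag(cov0) * phi)
  slope <- coefs[["slope"]]
  slope_se <- ses[[if (constrain_intercept) 1L else 2L]]
  extras <- list(phi = phi)
  if (!constrain_intercept) {
    extras$intercept <- coefs[["intercept"]]
    extras$intercept_se <- ses[[1L]]
    extras$intercept_p <- two_sided_p(coefs[["intercept"]] / ses[[1L]])
  }
  make_estimate("egger", slope, slope_se, J, ci_level, extras = extras)
}

# interpolated weighted median of `ratio` with weights `weight`
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# parametric bootstrap SE shared by the median and mode estimators:
# redraw both association vectors from normals centred at the observed
# values with the observed SEs, recompute ratios and first-order weights,
# re-estimate
bootstrap_se <- function(h, point_fun, n_boot, seed) {
  with_seed(seed, {
    J <- nrow(h)
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, h$beta_exposure, h$se_exposure)
      by <- stats::rnorm(J, h$beta_outcome, h$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      point_fun(by / bx, bx^2 / h$se_outcome^2)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted median estimator
#'
#' Linear interpolation of the ordered Wald ratios at cumulative normalized
#' weight 0.5; consistent when at least half the weight comes from valid
#' instruments. The SE is estimated by parametric bootstrap (each replicate
#' redraws both association vectors from normals centred at the observed
#' values with the observed SEs). Deterministic given `seed`.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @param n_boot bootstrap replicates (default 1000, minimum 100).
#' @param seed RNG seed for the bootstrap.
#' @param ci_level confidence level.
#' @return An `mr_estimate` (method `weighted_median`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = NULL,
                               ci_level = 0.95) {
  J <- nrow(h)
  if (J < 2L) stop("weighted median requires at least 2 SNPs", call. = FALSE)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  w <- wald_ratios(h)
  beta <- weighted_median_point(w$ratio, w$weight)
  se <- bootstrap_se(h, weighted_median_point, n_boot, seed)
  make_estimate("weighted_median", beta, se, J, ci_level,
                extras = list(n_boot = n_boot))
}

# kernel-density mode of the ratios; returns estimate and bandwidth
mode_point <- function(ratio, weight, phi) {
  J <- length(ratio)
  spread <- min(stats::sd(ratio), stats::IQR(ratio) / 1.34)
  bw <- phi * 0.9 * spread * J^(-1 / 5)
  if (!is.finite(bw) || bw <= 0)
    return(list(estimate = ratio[1], bandwidth = 0))
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512L)
  dens <- colSums(weight * stats::dnorm(outer(ratio, grid, "-"), sd = bw))
  list(estimate = grid[which.max(dens)], bandwidth = bw)
}

#' Mode-based estimators (simple and weighted mode)
#'
#' The estimate is the argmax of a normal-kernel density of the Wald ratios
#' over a 512-point grid spanning the ratios plus/minus three bandwidths,
#' with bandwidth `phi * 0.9 * min(SD, IQR/1.34) * J^(-1/5)`. The simple
#' mode gives every kernel equal weight; the weighted mode weights kernels
#' by the inverse-variance weights. SE by the same parametric bootstrap as
#' the weighted median. If all ratios coincide (zero bandwidth) the common
#' ratio is returned.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param weighted `FALSE` for the simple mode (default), `TRUE` for the
#'   weighted mode.
#' @param phi bandwidth multiplier (default 1); the bandwidth is linear in
#'   it and is reported in `extras$bandwidth`.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param ci_level confidence level.
#' @return An `mr_estimate` (method `simple_mode` or `weighted_mode`).
#' @export
mr_mode <- function(h, weighted = FALSE, phi = 1, n_boot = 1000L,
                    seed = NULL, ci_level = 0.95) {
  J <- nrow(h)
  if (J < 3L) stop("mode estimators require at least 3 SNPs", call. = FALSE)
  check_scalar(phi, "phi", lo = 0, strict_lo = TRUE)
  w <- wald_ratios(h)
  kernel_w <- if (weighted) w$weight else rep(1, J)
  pt <- mode_point(w$ratio, kernel_w, phi)
  point_fun <- if (weighted) {
    function(r, wt) mode_point(r, wt, phi)$estimate
  } else {
    function(r, wt) mode_point(r, rep(1, length(r)), phi)$estimate
  }
  se <- bootstrap_se(h, point_fun, n_boot, seed)
  make_estimate(if (weighted) "weighted_mode" else "simple_mode",
                pt$estimate, se, J, ci_level,
                extras = list(bandwidth = pt$bandwidth, phi = phi,
                              n_boot = n_boot))
}

#' Run one estimator by name
#'
#' Dispatch helper used by the pipeline: maps a method label to the
#' corresponding estimator.
#'
#' @param h a `harmonized_set`.
#' @param method one of `"ivw_fe"`, `"ivw_mre"`, `"egger"`,
#'   `"weighted_median"`, `"simple_mode"`, `"weighted_mode"`, `"bwmr"`.
#' @param ci_level confidence level.
#' @param seed RNG seed (used by the bootstrap-based methods).
#' @param n_boot bootstrap replicates for the median/mode methods.
#' @param phi bandwidth multiplier for the mode methods.
#' @return An `mr_estimate`.
#' @export
mr_estimate <- function(h, method = "ivw_mre", ci_level = 0.95, seed = NULL,
                        n_boot = 1000L, phi = 1) {
  switch(method,
    ivw_fe = mr_ivw(h, "fixed", ci_level),
    ivw_mre = mr_ivw(h, "mre", ci_level),
    egger = mr_egger(h, ci_level),
    weighted_median = mr_weighted_median(h, n_boot = n_boot, seed = seed,
                                         ci_level = ci_level),
    simple_mode = mr_mode(h, weighted = FALSE, phi = phi, n_boot = n_boot,
                          seed = seed, ci_level = ci_level),
    weighted_mode = mr_mode(h, weighted = TRUE, phi = phi, n_boot = n_boot,
                            seed = seed, ci_level = ci_level),
    bwmr = mr_bwmr(h, seed = seed, ci_level = ci_level),
    stop("unknown method: ", method, call. = FALSE))
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4g (SE %.4g), %d%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$pvalue))
  cat(sprintf("  OR = %.4g [%.4g, %.4g]\n", x$odds_ratio, x$or_ci_low,
              x$or_ci_high))
  if (!is.null(x$extras$intercept))
    cat(sprintf("  Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                x$extras$intercept, x$extras$intercept_se,
                x$extras$intercept_p))
  if (!is.null(x$extras$converged))
    cat(sprintf("  converged: %s (tau = %.4g)\n", x$extras$converged,
                x$extras$tau))
  invisible(x)
}
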