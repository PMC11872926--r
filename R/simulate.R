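# Synthetic GWAS summary-statistics generator.
#
# Emulates the statistical structure of a three-trait summary-statistics
# study: an exposure GWAS (continuous lipid-like trait), a mediator GWAS
# (circulating protein level) and a binary-outcome GWAS on the log-OR scale,
# linked by the causal chain exposure -> mediator -> outcome with an
# additional direct exposure -> outcome path.
#
# Per SNP j with effect-allele frequency f_j and GWAS sample size n, the
# sampling SE of a per-allele effect is approximated by the standardized
# working model s = 1 / sqrt(2 * n * f_j * (1 - f_j)); observed betas are
# true means plus Gaussian noise of that SD. Binary-outcome effects are
# simulated directly on the log-OR scale (no individual-level logistic
# model): two-sample MR consumes only summary statistics, and the Gaussian
# working model keeps every sampling oracle closed-form.

#' Configuration for a synthetic three-trait GWAS study
#'
#' Defaults mirror the scale of the motivating application (an exposure GWAS
#' of ~7,000 participants, a protein GWAS of ~15,000, a disease GWAS of
#' ~400,000); tests typically scale `n_snps` and sample sizes down.
#'
#' @param n_snps number of candidate instrument SNPs.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 2).
#' @param maf_range length-2 range of effect-allele frequencies in (0, 0.5].
#' @param gamma_sd SD of true per-SNP effects on the exposure (> 0).
#' @param beta1 exposure -> mediator causal effect (log scale).
#' @param beta2 mediator -> outcome causal effect (log-OR scale).
#' @param beta_dir direct exposure -> outcome effect (log-OR scale); the
#'   total effect is `beta_all = beta_dir + beta1 * beta2`.
#' @param pleiotropy_sd SD of per-SNP direct-on-outcome (pleiotropic)
#'   effects (>= 0); `0` disables random pleiotropy.
#' @param pleiotropy_mean mean of the pleiotropic effects (a nonzero value
#'   induces directional pleiotropy, visible to the Egger intercept).
#' @param weak_fraction proportion of exposure-instrument SNPs drawn with
#'   near-zero true effect (SD `gamma_sd / 10`).
#' @param palindromic_fraction proportion of SNPs given A/T or C/G pairs.
#' @param flip_fraction proportion of outcome rows emitted on the opposite
#'   allele orientation (alleles swapped, beta negated, eaf complemented) —
#'   a pure change of representation that harmonization must undo.
#' @param delta_sd SD of mediator-specific per-SNP effects (>= 0). Together
#'   with `mediator_snp_fraction` this gives the mediator GWAS instruments
#'   of its own, without which the mediator -> outcome step has no valid
#'   instruments whenever `beta1 = 0`.
#' @param mediator_snp_fraction proportion of SNPs whose true effect acts
#'   directly on the mediator (effect `delta_j ~ N(0, delta_sd^2)`, zero
#'   effect on the exposure); the outcome inherits `beta2 * delta_j`.
#' @param ld_block_size SNPs per LD block (1 = all SNPs independent).
#' @param ld_block_r2 pairwise r-squared within an LD block, in \[0, 1).
#' @param seed integer RNG seed; the whole study is deterministic given it.
#' @return A validated `sim_config` object (a named list).
#' @export
simulation_config <- function(n_snps = 150L,
                              n_exposure = 7174L,
                              n_mediator = 14824L,
                              n_outcome = 411317L,
                              maf_range = c(0.05, 0.5),
                              gamma_sd = 0.15,
                              beta1 = 0,
                              beta2 = 0,
                              beta_dir = 0,
                              pleiotropy_sd = 0,
                              pleiotropy_mean = 0,
                              weak_fraction = 0,
                              palindromic_fraction = 0,
                              flip_fraction = 0,
                              delta_sd = 0,
                              mediator_snp_fraction = 0,
                              ld_block_size = 1L,
                              ld_block_r2 = 0,
                              seed = 1L) {
  check_scalar(n_snps, "n_snps", lo = 1, integer = TRUE)
  check_scalar(n_exposure, "n_exposure", lo = 2, integer = TRUE)
  check_scalar(n_mediator, "n_mediator", lo = 2, integer = TRUE)
  check_scalar(n_outcome, "n_outcome", lo = 2, integer = TRUE)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("invalid configuration: `maf_range` must be an increasing pair in (0, 0.5]",
         call. = FALSE)
  check_scalar(gamma_sd, "gamma_sd", lo = 0, strict_lo = TRUE)
  check_scalar(beta1, "beta1")
  check_scalar(beta2, "beta2")
  check_scalar(beta_dir, "beta_dir")
  check_scalar(pleiotropy_sd, "pleiotropy_sd", lo = 0)
  check_scalar(pleiotropy_mean, "pleiotropy_mean")
  check_scalar(weak_fraction, "weak_fraction", lo = 0, hi = 1)
  check_scalar(palindromic_fraction, "palindromic_fraction", lo = 0, hi = 1)
  check_scalar(flip_fraction, "flip_fraction", lo = 0, hi = 1)
  check_scalar(delta_sd, "delta_sd", lo = 0)
  check_scalar(mediator_snp_fraction, "mediator_snp_fraction", lo = 0, hi = 1)
  check_scalar(ld_block_size, "ld_block_size", lo = 1, integer = TRUE)
  check_scalar(ld_block_r2, "ld_block_r2", lo = 0, hi = 1, strict_hi = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(
    n_snps = as.integer(n_snps), n_exposure = as.integer(n_exposure),
    n_mediator = as.integer(n_mediator), n_outcome = as.integer(n_outcome),
    maf_range = as.numeric(maf_range), gamma_sd = gamma_sd,
    beta1 = beta1, beta2 = beta2, beta_dir = beta_dir,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
    weak_fraction = weak_fraction,
    palindromic_fraction = palindromic_fraction,
    flip_fraction = flip_fraction,
    delta_sd = delta_sd, mediator_snp_fraction = mediator_snp_fraction,
    ld_block_size = as.integer(ld_block_size), ld_block_r2 = ld_block_r2,
    seed = as.integer(seed)), class = "sim_config")
}

# sampling SE of a per-allele effect under the standardized working model
sampling_se <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

.non_palindromic_pairs <- rbind(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
.palindromic_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a linked three-trait GWAS summary-statistics study
#'
#' Generates exposure, mediator and outcome summary-statistics tables over a
#' shared SNP panel with a known causal chain, the generating truth, and a
#' block-diagonal LD matrix. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()] object.
#' @return A list of class `mr_sim_study` with elements `exposure`,
#'   `mediator`, `outcome` (summary-statistics data.frames), `truth`
#'   (class `simulation_truth`: per-SNP effects `gamma`, `delta`, `alpha`
#'   and the configured/derived path coefficients, with
#'   `beta_all = beta_dir + beta1 * beta2` exactly) and `ld` (r-squared
#'   matrix with SNP dimnames).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(simulation_config, as.list(config))
  with_seed(config$seed, {
    n <- config$n_snps
    snp_id <- sprintf("rs%06d", seq_len(n))

    # block-diagonal LD layout: blocks of consecutive SNPs, 10 kb spacing
    # within a block, blocks 20,000 kb apart (beyond the default clumping
    # window) and cycled over chromosomes 1..22
    block <- (seq_len(n) - 1L) %/% config$ld_block_size
    within <- (seq_len(n) - 1L) %% config$ld_block_size
    chrom <- as.character((block %% 22L) + 1L)
    chrom_block_idx <- stats::ave(block, chrom, FUN = function(b)
      match(b, unique(b)) - 1L)
    pos <- chrom_block_idx * 2e7 + within * 1e4 + 1

    eaf <- stats::runif(n, config$maf_range[1], config$maf_range[2])

    n_pal <- round(config$palindromic_fraction * n)
    pal <- rep(FALSE, n)
    if (n_pal > 0) pal[sample.int(n, n_pal)] <- TRUE
    alleles <- matrix("", n, 2)
    if (any(!pal))
      alleles[!pal, ] <- .non_palindromic_pairs[
        sample.int(nrow(.non_palindromic_pairs), sum(!pal), replace = TRUE), ,
        drop = FALSE]
    if (any(pal))
      alleles[pal, ] <- .palindromic_pairs[
        sample.int(nrow(.palindromic_pairs), sum(pal), replace = TRUE), ,
        drop = FALSE]

    # SNP roles: exposure instruments carry gamma, mediator-specific SNPs
    # carry delta (and gamma = 0)
    n_med_snp <- round(config$mediator_snp_fraction * n)
    med_role <- rep(FALSE, n)
    if (n_med_snp > 0) med_role[sample.int(n, n_med_snp)] <- TRUE

    gamma <- numeric(n)
    exp_role <- which(!med_role)
    if (length(exp_role)) {
      sd_j <- rep(config$gamma_sd, length(exp_role))
      n_weak <- round(config$weak_fraction * length(exp_role))
      if (n_weak > 0)
        sd_j[sample.int(length(exp_role), n_weak)] <- config$gamma_sd / 10
      gamma[exp_role] <- stats::rnorm(length(exp_role), 0, sd_j)
    }
    delta <- numeric(n)
    if (any(med_role))
      delta[med_role] <- stats::rnorm(sum(med_role), 0, config$delta_sd)
    # directional pleiotropy is defined on the exposure-increasing allele
    # orientation (the orientation Egger regression uses); otherwise the
    # arbitrary choice of effect allele would scramble the shift's sign
    # and no mean pleiotropy could ever be expressed
    sgn <- ifelse(gamma < 0, -1, 1)
    alpha <- sgn * stats::rnorm(n, config$pleiotropy_mean,
                                config$pleiotropy_sd)

    beta_all <- config$beta_dir + config$beta1 * config$beta2
    s_x <- sampling_se(config$n_exposure, eaf)
    s_m <- sampling_se(config$n_mediator, eaf)
    s_y <- sampling_se(config$n_outcome, eaf)
    beta_x <- stats::rnorm(n, gamma, s_x)
    beta_m <- stats::rnorm(n, config$beta1 * gamma + delta, s_m)
    beta_y <- stats::rnorm(n, beta_all * gamma + config$beta2 * delta + alpha,
                           s_y)

    mk_table <- function(beta, se, nn) data.frame(
      snp_id = snp_id, chrom = chrom, pos = as.numeric(pos),
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta, se = se, pvalue = two_sided_p(beta / se),
      n = as.integer(nn), stringsAsFactors = FALSE)

    exposure <- mk_table(beta_x, s_x, config$n_exposure)
    mediator <- mk_table(beta_m, s_m, config$n_mediator)
    outcome <- mk_table(beta_y, s_y, config$n_outcome)

    # orientation flips on the outcome table: representation change only
    n_flip <- round(config$flip_fraction * n)
    if (n_flip > 0) {
      fl <- sample.int(n, n_flip)
      ea <- outcome$effect_allele[fl]
      outcome$effect_allele[fl] <- outcome$other_allele[fl]
      outcome$other_allele[fl] <- ea
      outcome$beta[fl] <- -outcome$beta[fl]
      outcome$eaf[fl] <- 1 - outcome$eaf[fl]
    }

    ld <- diag(1, n)
    if (config$ld_block_size > 1L && config$ld_block_r2 > 0) {
      same_block <- outer(block, block, "==")
      ld[same_block] <- config$ld_block_r2
      diag(ld) <- 1
    }
    dimnames(ld) <- list(snp_id, snp_id)

    truth <- structure(list(
      snp_id = snp_id, gamma = gamma, delta = delta, alpha = alpha,
      mediator_snp = med_role,
      beta1 = config$beta1, beta2 = config$beta2,
      beta_dir = config$beta_dir,
      beta_all = beta_all, beta_med = config$beta1 * config$beta2,
      config = config), class = "simulation_truth")

    structure(list(exposure = exposure, mediator = mediator,
                   outcome = outcome, truth = truth, ld = ld),
              class = "mr_sim_study")
  })
}

#' @export
print.mr_sim_study <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic three-trait GWAS study\n")
  cat(sprintf("  SNPs: %d  (palindromic %.0f%%, mediator-specific %.0f%%)\n",
              cfg$n_snps, 100 * cfg$palindromic_fraction,
              100 * cfg$mediator_snp_fraction))
  cat(sprintf("  n: exposure %d, mediator %d, outcome %d\n",
              cfg$n_exposure, cfg$n_mediator, cfg$n_outcome))
  cat(sprintf("  truth: beta1 = %.4g, beta2 = %.4g, beta_dir = %.4g, beta_all = %.4g\n",
              x$truth$beta1, x$truth$beta2, x$truth$beta_dir, x$truth$beta_all))
  invisible(x)
}
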