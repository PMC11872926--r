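# Shared fixtures: build harmonized instrument sets and small
# summary-statistics tables directly, without running the full pipeline.

make_hset <- function(bx, bxse, by, byse,
                      snp_id = sprintf("rs%06d", seq_along(bx))) {
  mrmediate:::harmonized_set(snp_id, bx, bxse, by, byse)
}

# minimal valid summary-statistics table
make_sumstats <- function(beta, se,
                          snp_id = sprintf("rs%06d", seq_along(beta)),
                          chrom = "1", pos = seq_along(beta),
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, n = 10000L) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se,
             pvalue = pmax(2 * pnorm(-abs(beta / se)),
                           .Machine$double.xmin),
             n = as.integer(n), stringsAsFactors = FALSE)
}

# identity LD matrix over a set of SNP ids
identity_ld <- function(snp_id) {
  ld <- diag(1, length(snp_id))
  dimnames(ld) <- list(snp_id, snp_id)
  ld
}

# study conditions used by calibration-style tests: strong, clean
# instruments on a modest panel (sizes discussed in the methods vignette)
null_study_config <- function(seed, n_snps = 50L) {
  simulation_config(n_snps = n_snps, n_exposure = 5e4, n_mediator = 5e4,
                    n_outcome = 5e4, gamma_sd = 0.3, seed = seed)
}

# study conditions for mediation-recovery tests: half the panel acts
# directly on the mediator so every step has its own instruments.
# Common variants and very strong instruments (per-SNP F in the
# thousands) keep ratio-estimator dilution and winner's curse an order
# of magnitude below the Monte-Carlo resolution of the recovery checks,
# while |beta1| * gamma_sd stays far below the mediator significance
# threshold so exposure-driven SNPs do not contaminate the
# mediator-instrument set (see the methods vignette).
mediation_study_config <- function(seed, beta1, beta2, beta_dir,
                                   n_snps = 120L) {
  simulation_config(n_snps = n_snps, n_exposure = 5e6, n_mediator = 1e5,
                    n_outcome = 1e5, maf_range = c(0.2, 0.5),
                    gamma_sd = 0.05, delta_sd = 0.3,
                    mediator_snp_fraction = 0.5,
                    beta1 = beta1, beta2 = beta2, beta_dir = beta_dir,
                    seed = seed)
}
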