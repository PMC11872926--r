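# Instrument selection: significance and strength filters, greedy LD
# clumping, and allele harmonization.

test_that("significance filter uses a strict inequality and keeps order", {
  tbl <- make_sumstats(beta = c(0.3, 0.2, 0.25), se = 0.03)
  tbl$pvalue <- c(1e-9, 5e-8, 4e-8)
  kept <- select_significant(tbl, 5e-8)
  expect_identical(kept$pvalue, c(1e-9, 4e-8))
  expect_identical(kept$snp_id, tbl$snp_id[c(1, 3)])
  tbl$pvalue <- rep(0.5, 3)
  expect_identical(nrow(select_significant(tbl, 5e-8)), 0L)
})

test_that("significance filter matches a brute-force recount on simulated data", {
  st <- simulate_study(simulation_config(
    n_snps = 300, n_exposure = 7174, gamma_sd = 0.2, seed = 17))
  kept <- select_significant(st$exposure, 5e-8)
  expect_identical(kept$snp_id,
                   st$exposure$snp_id[st$exposure$pvalue < 5e-8])
  expect_gt(nrow(kept), 0)
})

test_that("F-statistic arithmetic and strict threshold", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  # F = 9.9999999... sits below 10 and is excluded under the strict rule
  tbl <- make_sumstats(beta = c(0.1, 0.0316227766), se = c(0.02, 0.01))
  expect_lt(f_statistic(0.0316227766, 0.01), 10)
  expect_identical(filter_strong(tbl, 10)$snp_id, tbl$snp_id[1])
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("strength filter matches a brute-force recount", {
  set.seed(5)
  tbl <- make_sumstats(beta = rnorm(50, 0, 0.1), se = runif(50, 0.01, 0.05))
  expect_identical(filter_strong(tbl, 10)$snp_id,
                   tbl$snp_id[(tbl$beta / tbl$se)^2 > 10])
})

test_that("LD clumping keeps the most significant SNP of a correlated pair", {
  tbl <- make_sumstats(beta = c(0.3, 0.28), se = 0.03,
                       pos = c(1000, 2000))       # 1 kb apart
  tbl$pvalue <- c(1e-10, 1e-9)
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(tbl$snp_id, tbl$snp_id))
  expect_identical(ld_clump(tbl, ld, 0.001, 10000)$snp_id, tbl$snp_id[1])
  # same r2 but 20,000 kb apart: outside the window, both kept
  tbl$pos <- c(1L, 2e7L)
  expect_identical(nrow(ld_clump(tbl, ld, 0.001, 10000)), 2L)
})

test_that("greedy clumping equals a step-by-step independent oracle", {
  # 8-SNP toy panel with two LD blocks on one chromosome
  set.seed(31)
  tbl <- make_sumstats(beta = rnorm(8, 0.3, 0.05), se = 0.03,
                       pos = c(1e3, 5e3, 9e3, 2e4, 5e6, 5.01e6, 5.02e6, 3e7))
  r2 <- diag(1, 8)
  blocks <- list(1:4, 5:7)
  for (b in blocks) r2[b, b] <- 0.5
  diag(r2) <- 1
  dimnames(r2) <- list(tbl$snp_id, tbl$snp_id)

  # independent re-implementation of the greedy definition
  oracle <- function(tbl, r2, thr, win_kb) {
    left <- tbl
    kept <- character()
    while (nrow(left) > 0) {
      ord <- order(left$pvalue, left$snp_id)
      top <- left[ord[1], ]
      kept <- c(kept, top$snp_id)
      keep_row <- logical(nrow(left))
      for (k in seq_len(nrow(left))) {
        same <- left$chrom[k] == top$chrom &&
          abs(left$pos[k] - top$pos) <= win_kb * 1000 &&
          r2[top$snp_id, left$snp_id[k]] > thr
        keep_row[k] <- !(same || left$snp_id[k] == top$snp_id)
      }
      left <- left[keep_row, , drop = FALSE]
    }
    kept
  }
  expect_identical(ld_clump(tbl, r2, 0.001, 10000)$snp_id,
                   oracle(tbl, r2, 0.001, 10000))
  expect_identical(ld_clump(tbl, r2, 0.6, 10000)$snp_id,
                   oracle(tbl, r2, 0.6, 10000))
})

test_that("clumping a SNP absent from the LD matrix names it", {
  tbl <- make_sumstats(beta = c(0.3, 0.2), se = 0.03)
  ld <- identity_ld(tbl$snp_id[1])
  expect_error(ld_clump(tbl, ld), tbl$snp_id[2])
})

test_that("harmonization flips swapped outcome alleles", {
  ex <- make_sumstats(beta = 0.10, se = 0.02,
                      effect_allele = "A", other_allele = "G")
  ou <- make_sumstats(beta = -0.05, se = 0.02,
                      effect_allele = "G", other_allele = "A", eaf = 0.7)
  h <- harmonize(ex, ou)
  expect_identical(nrow(h), 1L)
  expect_identical(h$effect_allele, "A")
  expect_identical(h$beta_outcome, 0.05)
  expect_equal(h$eaf_outcome, 0.3)
})

test_that("palindromic SNPs are excluded under the default policy", {
  ex <- make_sumstats(beta = 0.1, se = 0.02,
                      effect_allele = "A", other_allele = "T", eaf = 0.2)
  ou <- make_sumstats(beta = 0.05, se = 0.02,
                      effect_allele = "A", other_allele = "T", eaf = 0.2)
  h <- harmonize(ex, ou, "drop_all_palindromic")
  expect_identical(nrow(h), 0L)
  log <- exclusion_log(h)
  expect_identical(log$reason, "palindromic")
})

test_that("frequency rescue of palindromic SNPs under drop_ambiguous_only", {
  ex <- make_sumstats(beta = c(0.1, 0.1), se = 0.02,
                      effect_allele = "A", other_allele = "T",
                      eaf = c(0.2, 0.5))
  ou <- make_sumstats(beta = c(0.05, 0.05), se = 0.02,
                      effect_allele = "A", other_allele = "T",
                      eaf = c(0.8, 0.5))
  h <- harmonize(ex, ou, "drop_ambiguous_only")
  # SNP 1: informative frequencies on opposite sides of 0.5 -> flipped
  expect_identical(h$snp_id, ex$snp_id[1])
  expect_identical(h$beta_outcome, -0.05)
  expect_equal(h$eaf_outcome, 0.2)
  # SNP 2: ambiguous frequency -> excluded
  expect_identical(exclusion_log(h)$snp_id, ex$snp_id[2])
  expect_identical(exclusion_log(h)$reason, "palindromic")
})

test_that("mismatched allele sets and missing SNPs are logged", {
  ex <- make_sumstats(beta = c(0.1, 0.1, 0.1), se = 0.02,
                      effect_allele = c("A", "A", "A"),
                      other_allele = c("G", "G", "G"))
  ou <- make_sumstats(beta = c(0.05, 0.05), se = 0.02,
                      snp_id = ex$snp_id[1:2],
                      effect_allele = c("A", "T"),
                      other_allele = c("G", "C"))
  h <- harmonize(ex, ou)
  expect_identical(h$snp_id, ex$snp_id[1])
  log <- exclusion_log(h)
  expect_setequal(log$reason, c("allele_mismatch", "missing_in_outcome"))
  # partition: every exposure SNP accounted for exactly once
  expect_identical(nrow(h) + nrow(log), nrow(ex))
  expect_identical(sort(c(h$snp_id, log$snp_id)), sort(ex$snp_id))
})

test_that("duplicate SNP identifiers are an error naming the id", {
  ex <- make_sumstats(beta = c(0.1, 0.1), se = 0.02,
                      snp_id = c("rs1", "rs1"))
  ou <- make_sumstats(beta = 0.05, se = 0.02, snp_id = "rs1")
  expect_error(harmonize(ex, ou), "rs1")
})

test_that("harmonization is idempotent", {
  st <- simulate_study(simulation_config(
    n_snps = 80, palindromic_fraction = 0.2, flip_fraction = 0.4, seed = 13))
  h1 <- harmonize(st$exposure, st$outcome)
  # re-feed the harmonized pairs as exposure/outcome tables
  as_tbl <- function(h, side) make_sumstats(
    beta = h[[paste0("beta_", side)]], se = h[[paste0("se_", side)]],
    snp_id = h$snp_id, chrom = h$chrom, pos = h$pos,
    effect_allele = h$effect_allele, other_allele = h$other_allele,
    eaf = h[[paste0("eaf_", side)]])
  h2 <- harmonize(as_tbl(h1, "exposure"), as_tbl(h1, "outcome"),
                  "drop_ambiguous_only")
  expect_identical(h2$snp_id, h1$snp_id)
  expect_identical(h2$beta_outcome, h1$beta_outcome)
  expect_identical(h2$beta_exposure, h1$beta_exposure)
})

test_that("full selection pipeline partitions the exposure panel", {
  st <- simulate_study(simulation_config(
    n_snps = 150, n_exposure = 7174, n_outcome = 5e4, gamma_sd = 0.2,
    palindromic_fraction = 0.15, ld_block_size = 5, ld_block_r2 = 0.5,
    weak_fraction = 0.3, seed = 23))
  h <- select_instruments(st$exposure, st$outcome, st$ld)
  log <- exclusion_log(h)
  expect_identical(nrow(h) + nrow(log), nrow(st$exposure))
  expect_true(all(log$reason %in% c("not_significant", "clumped",
                                    "weak_instrument", "palindromic",
                                    "allele_mismatch", "missing_in_outcome")))
  expect_gt(nrow(h), 0)
  # stages are consistent with reasons
  expect_true(all(log$stage[log$reason == "clumped"] == "clump"))
})
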