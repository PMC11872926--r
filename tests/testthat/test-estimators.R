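# Causal-effect estimators: arithmetic identities, independent oracles,
# and robustness constructions.

test_that("Wald ratio arithmetic, first and second order", {
  h <- make_hset(bx = 0.1, bxse = 0.02, by = 0.2, byse = 0.05)
  w1 <- wald_ratios(h, "first")
  expect_equal(w1$ratio, 2)
  expect_equal(w1$se, 0.5)
  # with zero exposure-side SE the second order collapses to the first
  h0 <- make_hset(bx = c(0.1, -0.2), bxse = 1e-300, by = c(0.2, 0.1),
                  byse = 0.05)
  expect_equal(wald_ratios(h0, "second")$se, wald_ratios(h0, "first")$se,
               tolerance = 1e-12)
  expect_error(wald_ratios(make_hset(0, 0.01, 0.1, 0.01)), "rs000001")
})

test_that("second-order Wald SE matches a Monte-Carlo oracle", {
  bx <- 0.2; bxse <- 0.02; by <- 0.1; byse <- 0.03
  h <- make_hset(bx, bxse, by, byse)
  se2 <- wald_ratios(h, "second")$se
  set.seed(42)
  draws <- rnorm(1e6, by, byse) / rnorm(1e6, bx, bxse)
  expect_lt(abs(sd(draws) - se2) / se2, 0.05)
})

test_that("IVW reduces to the mean under equal weights and to the Wald ratio at J = 1", {
  h <- make_hset(bx = rep(1, 3), bxse = 1e-12, by = c(0.1, 0.2, 0.3),
                 byse = 0.1)
  est <- mr_ivw(h, "fixed")
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1 / sqrt(3))
  # identical ratios: Q = 0, MRE equals fixed
  h2 <- make_hset(bx = rep(1, 3), bxse = 1e-12, by = rep(0.15, 3),
                  byse = 0.1)
  expect_equal(mr_ivw(h2, "mre")$extras$Q, 0)
  expect_identical(mr_ivw(h2, "mre")$se, mr_ivw(h2, "fixed")$se)
  # single instrument
  h1 <- make_hset(bx = 0.1, bxse = 0.02, by = 0.2, byse = 0.05)
  est1 <- mr_ivw(h1, "mre")
  expect_equal(est1$beta, 2)
  expect_equal(est1$se, 0.5)
  expect_error(mr_ivw(make_hset(numeric(0), numeric(0), numeric(0),
                                numeric(0))), "no instruments")
})

test_that("IVW equals a weighted-least-squares-through-origin oracle to 10 digits", {
  set.seed(8)
  h <- make_hset(bx = rnorm(20, 0.2, 0.05), bxse = 0.01,
                 by = rnorm(20, 0.05, 0.03), byse = runif(20, 0.01, 0.05))
  est <- mr_ivw(h, "fixed")
  # independent normal-equations oracle: ratios regressed through the
  # origin on 1 with weights se^-2 == lm fit of by on bx through origin
  # weighted by se_outcome^-2
  fit <- lm(by ~ bx - 1, data = list(by = h$beta_outcome,
                                     bx = h$beta_exposure),
            weights = h$se_outcome^-2)
  expect_equal(est$beta, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(est$se,
               sqrt(1 / sum(h$beta_exposure^2 / h$se_outcome^2)),
               tolerance = 1e-10)
})

test_that("odds-ratio views are exp of the beta fields and CIs bracket the estimate", {
  set.seed(9)
  h <- make_hset(bx = rnorm(10, 0.3, 0.05), bxse = 0.02,
                 by = rnorm(10, 0.06, 0.02), byse = 0.02)
  for (est in list(mr_ivw(h), mr_egger(h),
                   mr_weighted_median(h, n_boot = 100, seed = 1))) {
    expect_equal(est$odds_ratio, exp(est$beta), tolerance = 1e-12)
    expect_equal(est$or_ci_low, exp(est$ci_low), tolerance = 1e-12)
    expect_lte(est$ci_low, est$beta)
    expect_gte(est$ci_high, est$beta)
  }
})

test_that("Egger recovers exact linear data to 10 digits", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.55)
  a <- 0.013; b <- -0.21
  h <- make_hset(bx = bx, bxse = 0.01, by = a + b * bx, byse = 0.02)
  est <- mr_egger(h)
  expect_equal(est$beta, b, tolerance = 1e-10)
  expect_equal(est$extras$intercept, a, tolerance = 1e-10)
  expect_error(mr_egger(make_hset(1:2 / 10, 0.01, 1:2 / 20, 0.01)),
               "at least 3")
  expect_error(mr_egger(make_hset(rep(0.2, 4), 0.01,
                                  c(0.1, 0.12, 0.09, 0.11), 0.02)),
               "no spread")
})

test_that("intercept-constrained Egger reproduces fixed-effect IVW", {
  set.seed(10)
  h <- make_hset(bx = rnorm(15, 0.25, 0.08), bxse = 0.02,
                 by = rnorm(15, 0.05, 0.03), byse = runif(15, 0.01, 0.04))
  cons <- mr_egger(h, constrain_intercept = TRUE)
  ivw <- mr_ivw(h, "fixed")
  expect_equal(cons$beta, ivw$beta, tolerance = 1e-12)
  expect_equal(cons$se, ivw$se, tolerance = 1e-12)
})

test_that("Egger intercept is calibrated under balanced and directional pleiotropy", {
  run_reps <- function(pmean, reps) {
    vapply(seq_len(reps), function(i) {
      st <- simulate_study(simulation_config(
        n_snps = 40, n_exposure = 5e4, n_outcome = 5e4, gamma_sd = 0.3,
        beta_dir = 0.1, pleiotropy_sd = 0.01, pleiotropy_mean = pmean,
        seed = 4000 + i))
      h <- select_instruments(st$exposure, st$outcome, st$ld)
      mr_egger(h)$extras$intercept
    }, numeric(1))
  }
  bal <- run_reps(0, 500)
  expect_lt(abs(mean(bal)), 3 * sd(bal) / sqrt(length(bal)))
  dir <- run_reps(0.02, 500)
  expect_lt(abs(mean(dir) - 0.02), 3 * sd(dir) / sqrt(length(dir)))
})

test_that("weighted median interpolates the ordered ratios", {
  h <- make_hset(bx = rep(1, 3), bxse = 1e-12, by = c(1, 2, 3), byse = 1)
  est <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(est$beta, 2)
  # driving one weight to zero leaves the weighted median of the rest
  h2 <- make_hset(bx = c(1, 1, 1, 1), bxse = 1e-12,
                  by = c(1, 2, 3, 50), byse = c(1, 1, 1, 1e6))
  est2 <- mr_weighted_median(h2, n_boot = 100, seed = 1)
  expect_lt(abs(est2$beta - 2), 0.01)
  expect_error(mr_weighted_median(make_hset(1, 0.1, 1, 0.1)), "at least 2")
  expect_error(mr_weighted_median(h, n_boot = 10), "at least 100")
})

test_that("bootstrap SEs are seed-deterministic and stable across seeds", {
  set.seed(12)
  h <- make_hset(bx = rnorm(10, 0.3, 0.05), bxse = 0.02,
                 by = rnorm(10, 0.06, 0.02), byse = 0.02)
  a <- mr_weighted_median(h, n_boot = 2000, seed = 5)
  b <- mr_weighted_median(h, n_boot = 2000, seed = 5)
  expect_identical(a$se, b$se)
  c2 <- mr_weighted_median(h, n_boot = 2000, seed = 6)
  expect_identical(a$beta, c2$beta)          # point estimate has no RNG
  expect_lt(abs(a$se - c2$se) / a$se, 0.10)
})

test_that("mode estimators find the dominant cluster", {
  h <- make_hset(bx = rep(1, 4), bxse = 1e-12, by = c(1, 1, 1, 5),
                 byse = 0.5)
  est <- mr_mode(h, n_boot = 100, seed = 1)
  expect_lt(abs(est$beta - 1), 2 * est$extras$bandwidth)
  # bandwidth is linear in phi
  est2 <- mr_mode(h, phi = 2, n_boot = 100, seed = 1)
  expect_equal(est2$extras$bandwidth, 2 * est$extras$bandwidth,
               tolerance = 1e-12)
  expect_error(mr_mode(make_hset(1:2 / 10, 0.01, 1:2 / 10, 0.01)),
               "at least 3")
})

test_that("simple mode resists a pleiotropic minority", {
  beta_true <- 0.2
  set.seed(14)
  bx <- runif(10, 0.2, 0.4)
  by <- bx * beta_true
  by[8:10] <- bx[8:10] * (beta_true + 0.5)   # 3 of 10 pleiotropic
  h <- make_hset(bx, 0.01, by + rnorm(10, 0, 0.002), 0.02)
  est <- mr_mode(h, n_boot = 100, seed = 2)
  expect_lt(abs(est$beta - beta_true), est$extras$bandwidth)
})

test_that("identical ratios give the common ratio with zero bandwidth", {
  h <- make_hset(bx = c(1, 2, 4), bxse = 1e-12, by = c(0.3, 0.6, 1.2),
                 byse = 0.01)
  est <- mr_mode(h, n_boot = 100, seed = 3)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_identical(est$extras$bandwidth, 0)
})

test_that("all estimators are invariant to simultaneous sign flips", {
  set.seed(15)
  J <- 12
  h <- make_hset(bx = rnorm(J, 0.3, 0.08), bxse = 0.02,
                 by = rnorm(J, 0.06, 0.03), byse = 0.02)
  flip <- c(2, 5, 7, 11)
  hf <- make_hset(bx = replace(h$beta_exposure, flip,
                               -h$beta_exposure[flip]),
                  bxse = h$se_exposure,
                  by = replace(h$beta_outcome, flip,
                               -h$beta_outcome[flip]),
                  byse = h$se_outcome)
  for (m in c("ivw_fe", "ivw_mre", "egger", "weighted_median",
              "simple_mode", "weighted_mode", "bwmr")) {
    e0 <- mr_estimate(h, m, seed = 9, n_boot = 100)
    e1 <- mr_estimate(hf, m, seed = 9, n_boot = 100)
    expect_equal(e1$beta, e0$beta, tolerance = 1e-10,
                 label = paste("beta under sign flip,", m))
  }
})

test_that("BWMR downweights a single gross outlier", {
  set.seed(16)
  bx <- runif(20, 0.2, 0.4)
  by <- 0.1 * bx + rnorm(20, 0, 0.002)
  by[20] <- 2.0 * bx[20]
  h <- make_hset(bx, 0.01, by, 0.02)
  bw <- mr_bwmr(h)
  fe <- mr_ivw(h, "fixed")
  expect_lt(abs(bw$beta - 0.1), abs(fe$beta - 0.1))
  expect_lt(min(bw$extras$weights), 0.01)   # the outlier is downweighted
  expect_true(bw$extras$converged)
})

test_that("BWMR agrees with IVW in the absence of pleiotropy", {
  reps <- 120
  d <- t(vapply(seq_len(reps), function(i) {
    st <- simulate_study(simulation_config(
      n_snps = 40, n_exposure = 5e4, n_outcome = 5e4, gamma_sd = 0.3,
      beta_dir = 0.1, seed = 6000 + i))
    h <- select_instruments(st$exposure, st$outcome, st$ld)
    c(mr_bwmr(h)$beta, mr_ivw(h, "fixed")$beta)
  }, numeric(2)))
  diff <- d[, 1] - d[, 2]
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(reps))
})

test_that("every estimator recovers the true effect on clean strong-instrument data", {
  beta_true <- 0.15
  reps <- 300
  methods <- c("ivw_mre", "egger", "weighted_median", "simple_mode",
               "weighted_mode", "bwmr")
  est <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  for (i in seq_len(reps)) {
    st <- simulate_study(simulation_config(
      n_snps = 50, n_exposure = 5e4, n_outcome = 5e4, gamma_sd = 0.3,
      beta_dir = beta_true, seed = 7000 + i))
    h <- select_instruments(st$exposure, st$outcome, st$ld)
    for (m in methods)
      est[i, m] <- mr_estimate(h, m, seed = i, n_boot = 100)$beta
  }
  for (m in methods) {
    mc_se <- sd(est[, m]) / sqrt(reps)
    expect_lt(abs(mean(est[, m]) - beta_true), 3 * mc_se,
              label = paste("mean recovery,", m))
  }
})
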