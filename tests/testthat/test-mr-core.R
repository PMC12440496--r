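test_that("Wald ratios are element-wise division with the delta SE", {
  h <- mrmediation:::harmonized_set("v1", beta_exp = 0.1, se_exp = 0.01,
                                    beta_out = 0.05, se_out = 0.01)
  wr <- mr_wald_ratios(h)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se_ratio, 0.1)

  h <- mrmediation:::harmonized_set("v1", beta_exp = -0.1, se_exp = 0.01,
                                    beta_out = 0.05, se_out = 0.01)
  wr <- mr_wald_ratios(h)
  expect_equal(wr$ratio, -0.5)
  expect_equal(wr$se_ratio, 0.1)

  h <- random_harmonized(30, seed = 101)
  wr <- mr_wald_ratios(h)
  expect_equal(wr$ratio, h$beta_out / h$beta_exp)
  expect_equal(wr$se_ratio, h$se_out / abs(h$beta_exp))

  h$beta_exp[4] <- 0
  expect_error(mr_wald_ratios(h), "rs4", class = "mrmediation_domain_error")
})

test_that("IVW reproduces the weighted-mean closed form and Q arithmetic", {
  # two ratios 0.1 and 0.3, each with se 0.1: beta 0.2, Q = 2, I2 = 50%
  h <- mrmediation:::harmonized_set(
    c("a", "b"), beta_exp = c(1, 1), se_exp = c(0.01, 0.01),
    beta_out = c(0.1, 0.3), se_out = c(0.1, 0.1)
  )
  fit <- mr_ivw(h, model = "fixed")
  expect_equal(fit$beta, 0.2)
  expect_equal(fit$se, sqrt(1 / 200))
  expect_equal(fit$q, 2.0)
  expect_equal(fit$q_df, 1L)
  expect_equal(fit$i2, 50)

  # single ratio degenerates to the Wald fit
  fit1 <- mr_ivw(mrmediation:::harmonized_set("a", 0.1, 0.01, 0.05, 0.01))
  expect_equal(fit1$method, "wald_single")
  expect_equal(fit1$beta, 0.5)
  expect_equal(fit1$se, 0.1)

  # homogeneous ratios give Q = 0 and the fixed model under auto
  h0 <- mrmediation:::harmonized_set(
    paste0("v", 1:5), beta_exp = rep(0.1, 5), se_exp = 0.01,
    beta_out = rep(0.05, 5), se_out = seq(0.01, 0.03, length.out = 5)
  )
  fit0 <- mr_ivw(h0, model = "auto")
  expect_equal(fit0$method, "ivw_fixed")
  expect_equal(fit0$beta, 0.5)
  expect_equal(fit0$q, 0)
  expect_equal(fit0$i2, 0)

  # oracle equivalence on random instances
  for (seed in 1:50) {
    h <- random_harmonized(sample(3:20, 1), seed = seed)
    orc <- oracle_ivw_fixed(h$beta_exp, h$beta_out, h$se_out)
    fit <- mr_ivw(h, model = "fixed")
    expect_equal(fit$beta, orc$beta, tolerance = 1e-12)
    expect_equal(fit$se, orc$se, tolerance = 1e-12)
  }
})

test_that("IVW is invariant to joint sign flips and random-effects SE dominates", {
  h <- random_harmonized(15, seed = 7)
  flipped <- h
  flipped$beta_exp[3] <- -flipped$beta_exp[3]
  flipped$beta_out[3] <- -flipped$beta_out[3]
  expect_equal(mr_ivw(flipped, "fixed")$beta, mr_ivw(h, "fixed")$beta,
               tolerance = 1e-12)

  for (seed in 1:20) {
    h <- random_harmonized(10, seed = seed + 400)
    expect_gte(mr_ivw(h, "random")$se, mr_ivw(h, "fixed")$se - 1e-14)
  }
})

test_that("REML tau2 agrees with metafor's REML on the ratio scale", {
  skip_if_not_installed("metafor")
  for (seed in c(3, 17, 99)) {
    withr::with_seed(seed, {
      k <- 12
      yi <- rnorm(k, 0.2, 0.15)
      sei <- runif(k, 0.05, 0.2)
    })
    tau2 <- mrmediation:::tau2_reml(yi, sei)
    ref <- metafor::rma(yi = yi, sei = sei, method = "REML",
                        control = list(threshold = 1e-10))
    expect_equal(tau2, ref$tau2, tolerance = 1e-7)
    h <- mrmediation:::harmonized_set(paste0("v", 1:k), beta_exp = 1,
                                      se_exp = 1e-6, beta_out = yi, se_out = sei)
    fit <- mr_ivw(h, model = "random")
    expect_equal(fit$beta, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(fit$se, ref$se, tolerance = 1e-8)
  }
})

test_that("Egger recovers exact lines and matches a WLS oracle", {
  # exact pleiotropic line beta_out = 0.05 + 0.5 beta_exp
  h <- mrmediation:::harmonized_set(
    c("a", "b", "c"), beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
    beta_out = 0.05 + 0.5 * c(0.1, 0.2, 0.3), se_out = 0.01
  )
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.05, tolerance = 1e-10)

  # no pleiotropy: intercept 0
  h0 <- mrmediation:::harmonized_set(
    c("a", "b", "c"), beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
    beta_out = 0.5 * c(0.1, 0.2, 0.3), se_out = 0.01
  )
  fit0 <- mr_egger(h0)
  expect_equal(fit0$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(fit0$beta, 0.5, tolerance = 1e-10)

  # oracle equivalence incl. standard errors on random instances
  for (seed in 1:50) {
    h <- random_harmonized(20, seed = seed + 1000)
    orc <- oracle_wls_egger(h$beta_exp, h$beta_out, h$se_out)
    fit <- mr_egger(h)
    expect_equal(fit$beta, orc$slope, tolerance = 1e-10)
    expect_equal(fit$egger_intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$se, orc$se_slope, tolerance = 1e-10)
    expect_equal(fit$egger_intercept_se, orc$se_intercept, tolerance = 1e-10)
  }

  expect_error(mr_egger(random_harmonized(2, 1)),
               class = "mrmediation_insufficient_instruments_error")
})

test_that("weighted median interpolates cumulative weights correctly", {
  mk <- function(ratios, se_out = rep(0.01, length(ratios))) {
    mrmediation:::harmonized_set(
      paste0("v", seq_along(ratios)), beta_exp = 1, se_exp = 1e-6,
      beta_out = ratios, se_out = se_out
    )
  }
  fit <- mr_weighted_median(mk(c(0.1, 0.2, 0.3)), n_boot = 200)
  expect_equal(fit$beta, 0.2, tolerance = 1e-12)

  fit_c <- mr_weighted_median(mk(rep(0.25, 5)), n_boot = 200)
  expect_equal(fit_c$beta, 0.25, tolerance = 1e-12)
  expect_lt(fit_c$se, 0.02)

  # majority cluster wins when outliers carry < 50% of weight
  h <- mk(c(0.2, 0.21, 0.19, 0.2, 1.5, 1.6, 1.7),
          se_out = c(rep(0.01, 4), rep(0.05, 3)))
  fit_m <- mr_weighted_median(h, n_boot = 200)
  expect_lt(abs(fit_m$beta - 0.2), 0.05)

  # a dominant instrument flanked by balanced weight returns its ratio
  h_d <- mk(c(0.1, 0.4, 0.9), se_out = c(0.1, 0.01 / sqrt(98), 0.1))
  fit_d <- mr_weighted_median(h_d, n_boot = 200)
  expect_equal(fit_d$beta, 0.4, tolerance = 1e-12)

  # brute-force oracle equivalence on random instances
  for (seed in 1:50) {
    h <- random_harmonized(sample(3:25, 1), seed = seed + 2000)
    wr <- mr_wald_ratios(h)
    expect_equal(mr_weighted_median(h, n_boot = 100)$beta,
                 oracle_weighted_median(wr$ratio, wr$weight),
                 tolerance = 1e-12)
  }

  # deterministic given the seed
  f1 <- mr_weighted_median(random_harmonized(8, 5), n_boot = 300, seed = 99)
  f2 <- mr_weighted_median(random_harmonized(8, 5), n_boot = 300, seed = 99)
  expect_identical(f1$se, f2$se)
})

test_that("leave-one-out equals k independent IVW recomputations", {
  h <- random_harmonized(8, seed = 31)
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 8)
  for (j in 1:8) {
    ref <- mr_ivw(mrmediation:::subset_harmonized(h, -j), model = "auto")
    expect_equal(loo$beta[j], ref$beta, tolerance = 1e-12)
    expect_equal(loo$se[j], ref$se, tolerance = 1e-12)
  }

  # k = 2 reduces to two single-SNP Wald fits
  h2 <- random_harmonized(2, seed = 32)
  loo2 <- mr_leave_one_out(h2)
  expect_true(all(loo2$method == "wald_single"))

  # a gross outlier is exposed by the largest estimate shift at its exclusion
  h <- random_harmonized(12, seed = 33)
  h$beta_out[5] <- h$beta_out[5] + 30 * h$se_out[5]
  loo <- mr_leave_one_out(h)
  full <- mr_ivw(h)$beta
  expect_equal(which.max(abs(loo$beta - full)), 5L)
})

test_that("odds-ratio transform matches published conversions", {
  expect_equal(to_odds_ratio(0, 0.1)$or, 1)
  expect_equal(round(to_odds_ratio(-0.193, 0.069)$or, 3), 0.824)
  expect_equal(round(to_odds_ratio(0.072, 0.026)$or, 3), 1.075)
  # round trip through log is the identity on OR space
  ors <- c(0.5, 0.824, 1, 1.12, 2.3)
  expect_equal(to_odds_ratio(log(ors), 0.1)$or, ors)
  # exact normal quantile, not 1.96
  ci <- to_odds_ratio(0, 1)
  expect_equal(ci$ci_high, exp(qnorm(0.975)))
})

test_that("tidy and glance return one-row broom-style summaries", {
  fit <- mr_ivw(random_harmonized(10, seed = 55))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("exposure", "outcome", "method", "n_snp", "estimate",
                     "std.error", "statistic", "p.value", "or", "or.ci.low",
                     "or.ci.high"))
  gl <- glance(mr_egger(random_harmonized(10, seed = 56)))
  expect_true(is.finite(gl$egger_intercept))
})
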