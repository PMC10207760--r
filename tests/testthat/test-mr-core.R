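test_that("Wald ratio follows the delta method and ignores joint sign flips", {
  d <- data.frame(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.1, se_out = 0.02)
  est <- wald_ratio(d)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.04)
  neg <- transform(d, beta_exp = -beta_exp, beta_out = -beta_out)
  expect_equal(wald_ratio(neg)$beta, est$beta)
  expect_equal(wald_ratio(neg)$se, est$se)
  expect_equal(wald_ratio(transform(d, beta_out = 0))$beta, 0)
  expect_error(wald_ratio(transform(d, beta_exp = 0)), "nonzero")
})

test_that("IVW reduces to the Wald ratio and halves variance on replication", {
  d1 <- data.frame(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.1, se_out = 0.02)
  expect_warning(est1 <- mr_ivw(d1), "single instrument")
  expect_equal(est1$beta, wald_ratio(d1)$beta)
  d2 <- data.frame(beta_exp = c(1, 1), se_exp = 0.01,
                   beta_out = c(0.3, 0.3), se_out = 0.1)
  est2 <- mr_ivw(d2)
  expect_equal(est2$beta, 0.3)
  expect_equal(est2$se, 0.1 / sqrt(2))   # Q = 0, no inflation
  expect_equal(attr(est2, "Q"), 0)
  expect_error(mr_ivw(d2[0, ]), "at least 1")
})

test_that("fixed-effect IVW matches the closed-form oracle to 12 digits", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    d <- data.frame(beta_exp = runif(n, 0.2, 1), se_exp = runif(n, 0.005, 0.02),
                    beta_out = rnorm(n, 0.1, 0.05), se_out = runif(n, 0.02, 0.2))
    est <- mr_ivw(d, random_effects = FALSE)
    oracle <- oracle_ivw(d$beta_exp, d$beta_out, d$se_out)
    expect_equal(est$beta, oracle$beta, tolerance = 1e-12)
    expect_equal(est$se, oracle$se, tolerance = 1e-12)
    # algebraic identity: IVW = weighted mean of Wald ratios, w = x^2/se_out^2
    ratios <- d$beta_out / d$beta_exp
    w <- d$beta_exp^2 / d$se_out^2
    expect_equal(est$beta, sum(w * ratios) / sum(w), tolerance = 1e-12)
    # random-effects SE never below fixed-effect SE
    expect_gte(mr_ivw(d)$se, est$se)
  }
})

test_that("MR-Egger recovers slope and intercept exactly on noise-free data", {
  x <- c(0.3, 0.5, 0.8, 1.1, 1.4)
  d <- data.frame(beta_exp = x, se_exp = 0.01,
                  beta_out = 0.3 * x + 0.1, se_out = 0.05)
  fit <- mr_egger(d)
  expect_equal(fit$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, 0.1, tolerance = 1e-10)
  expect_equal(attr(fit$slope, "Q"), 0, tolerance = 1e-18)
  expect_error(mr_egger(d[1:2, ]), "at least 3")
})

test_that("estimators are invariant to joint sign flips of instrument subsets", {
  set.seed(42)
  d <- make_instruments(12, beta_causal = 0.25, seed = 7)
  flip <- c(2, 5, 9)
  d2 <- d
  d2$beta_exp[flip] <- -d2$beta_exp[flip]
  d2$beta_out[flip] <- -d2$beta_out[flip]
  expect_equal(mr_ivw(d2)$beta, mr_ivw(d)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(d2)$slope$beta, mr_egger(d)$slope$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(d2, seed = 1)$beta,
               mr_weighted_median(d, seed = 1)$beta, tolerance = 1e-12)
  m1 <- mr_mode(d, seed = 2); m2 <- mr_mode(d2, seed = 2)
  expect_equal(m2$simple_mode$beta, m1$simple_mode$beta, tolerance = 1e-12)
})

test_that("weighted median interpolates at half the total weight", {
  d <- data.frame(beta_exp = c(1, 1, 1), se_exp = 0.01,
                  beta_out = c(0.1, 0.2, 0.9), se_out = 0.1)
  est <- mr_weighted_median(d, n_boot = 200, seed = 5)
  expect_equal(est$beta, 0.2)
  # identical seed -> identical bootstrap SE; different seed differs
  est2 <- mr_weighted_median(d, n_boot = 200, seed = 5)
  expect_identical(est$se, est2$se)
  est3 <- mr_weighted_median(d, n_boot = 200, seed = 6)
  expect_false(identical(est$se, est3$se))
})

test_that("mode estimators find the dominant ratio cluster", {
  d <- data.frame(beta_exp = rep(1, 4), se_exp = 0.01,
                  beta_out = c(0.2, 0.2, 0.2, 0.9), se_out = 0.05)
  m <- mr_mode(d, n_boot = 100, seed = 3)
  expect_equal(m$simple_mode$beta, 0.2, tolerance = 0.05)
  expect_equal(m$weighted_mode$beta, 0.2, tolerance = 0.05)
  same <- data.frame(beta_exp = rep(1, 4), se_exp = 0.01,
                     beta_out = rep(0.3, 4), se_out = 0.05)
  ms <- mr_mode(same, n_boot = 100, seed = 3)
  expect_equal(ms$simple_mode$beta, 0.3)
  expect_equal(ms$weighted_mode$beta, 0.3)
  expect_lt(ms$simple_mode$se, 0.1)
})

test_that("weighted median tolerates <50% invalid weight where IVW does not", {
  set.seed(43)
  truth <- 0.2
  n <- 50; n_invalid <- 22           # 44% of equal weights
  reps <- 400
  wm <- ivw <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rep(1, n)
    alpha <- c(rep(0.1, n_invalid), rep(0, n - n_invalid))
    y <- rnorm(n, truth * x + alpha, 0.01)
    d <- data.frame(beta_exp = x, se_exp = 1e-6, beta_out = y, se_out = 0.01)
    wm[r] <- mrpipe:::weighted_median_point(y / x, (x / 0.01)^2)
    ivw[r] <- oracle_ivw(x, y, rep(0.01, n))$beta
  }
  expect_lt(abs(mean(wm) - truth), 0.1 * truth)     # < 10% bias
  expect_gt(abs(mean(ivw) - truth), 0.1 * truth)    # IVW detectably biased
  # breakdown: beyond 50% invalid weight the median degrades
  wm_broken <- replicate(200, {
    alpha <- c(rep(0.1, 30), rep(0, 20))
    y <- rnorm(50, truth + alpha, 0.01)
    mrpipe:::weighted_median_point(y, rep(1, 50))
  })
  expect_gt(abs(mean(wm_broken) - truth), 0.1 * truth)
})

test_that("scaling multiplies effect and CI, leaves the p-value unchanged", {
  est <- mr_estimate("IVW", 0.0041, 0.002, 100)
  s10 <- scale_estimate(est, 10)
  expect_equal(s10$beta, 0.041)
  expect_equal(s10$se, 0.02)
  expect_equal(s10$pval, est$pval)
  expect_equal(s10$ci_high - s10$ci_low, 10 * (est$ci_high - est$ci_low))
  expect_equal(scale_estimate(est, 1)$beta, est$beta)
  # negative factor (per-decrease reporting) keeps the CI ordered
  sneg <- scale_estimate(est, -10)
  expect_equal(sneg$beta, -0.041)
  expect_lte(sneg$ci_low, sneg$beta)
  expect_gte(sneg$ci_high, sneg$beta)
  expect_equal(sneg$pval, est$pval)
  expect_error(scale_estimate(est, 0), "nonzero")
})

test_that("Bonferroni thresholds match the reported roundings", {
  expect_equal(significance_threshold(2), 0.025)
  expect_equal(round(significance_threshold(3), 3), 0.017)
  expect_equal(significance_threshold(1), 0.05)
  expect_error(significance_threshold(0), ">= 1")
})

test_that("the CI half-width is 1.959964 standard errors", {
  est <- mr_estimate("x", 1, 0.5, 10)
  expect_equal(est$ci_high - est$ci_low, 2 * 1.959964 * 0.5, tolerance = 1e-6)
  expect_lte(est$ci_low, est$beta)
  expect_gte(est$ci_high, est$beta)
})
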