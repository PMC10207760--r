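#' Construct an MR estimate record
#'
#' One row per method: causal effect in outcome units per (scaled) exposure
#' unit, normal-approximation 95% CI, two-sided normal p-value, the number
#' of SNPs used, and the scale factor applied (mmHg per reported unit; a
#' negative factor expresses the effect per exposure decrease).
#'
#' @param method Method label.
#' @param beta,se Estimate and standard error.
#' @param n_snp Number of instruments used.
#' @param scale_factor Exposure units per reported unit (default 1).
#' @param pval Optional p-value override (e.g. kept fixed across rescaling);
#'   default is the two-sided normal test of `beta/se`.
#' @return A one-row data frame of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snp, scale_factor = 1, pval = NULL) {
  stopifnot(is.finite(beta), is.finite(se), se >= 0)
  pval <- pval %||% z_pval(beta, se)
  ci <- sort(c(beta - z95() * se, beta + z95() * se))
  structure(data.frame(method = method, beta = beta, se = se,
                       ci_low = ci[1], ci_high = ci[2], pval = pval,
                       n_snp = as.integer(n_snp), scale_factor = scale_factor,
                       stringsAsFactors = FALSE),
            class = c("mr_estimate", "data.frame"))
}

#' Wald ratio for a single instrument
#'
#' beta = beta_out / beta_exp with the first-order delta-method standard
#' error se_out / |beta_exp|. The base case used when a drug class yields a
#' single proxy variant.
#'
#' @param dat One-row instrument set (columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`).
#' @return An [mr_estimate].
#' @export
wald_ratio <- function(dat) {
  assert_instruments(dat, 1L, "wald_ratio")
  dat <- dat[1, ]
  if (dat$beta_exp == 0) stop("wald_ratio: beta_exp must be nonzero")
  mr_estimate("Wald ratio", dat$beta_out / dat$beta_exp,
              dat$se_out / abs(dat$beta_exp), 1L)
}

# Zero-intercept weighted least squares of y on x with weights w; the core
# of the IVW estimator. Returns the coefficient, its unit (fixed-effect)
# SE and Cochran's Q.
ivw_fit <- function(x, y, w) {
  sxx <- sum(w * x^2)
  bhat <- sum(w * x * y) / sxx
  q <- sum(w * (y - bhat * x)^2)
  list(beta = bhat, se_fixed = sqrt(1 / sxx), q = q)
}

#' Inverse-variance weighted estimator
#'
#' Zero-intercept weighted regression of SNP-outcome on SNP-exposure effects
#' with weights 1/se_out^2. The random-effects variant (the default, and
#' the primary estimator of the workflow) inflates the standard error
#' multiplicatively by max(1, sqrt(Q/(n-1))) — over-dispersion widens the
#' interval, under-dispersion never narrows it. With a single instrument it
#' falls back to the Wald ratio with a warning.
#'
#' @param dat Instrument set (data frame with `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`).
#' @param random_effects Use multiplicative random effects (default `TRUE`).
#' @return An [mr_estimate] with attributes `Q` and `Q_df`.
#' @export
mr_ivw <- function(dat, random_effects = TRUE) {
  assert_instruments(dat, 1L, "mr_ivw")
  n <- nrow(dat)
  if (n == 1) {
    warning("mr_ivw: single instrument; falling back to the Wald ratio")
    est <- wald_ratio(dat)
    est$method <- "IVW"
    return(est)
  }
  fit <- ivw_fit(dat$beta_exp, dat$beta_out, 1 / dat$se_out^2)
  infl <- if (random_effects) max(1, sqrt(fit$q / (n - 1))) else 1
  est <- mr_estimate(if (random_effects) "IVW" else "IVW (fixed)",
                     fit$beta, fit$se_fixed * infl, n)
  attr(est, "Q") <- fit$q
  attr(est, "Q_df") <- n - 1
  est
}

# Weighted least squares with intercept: returns coefficients, unit SEs
# from (X'WX)^{-1}, and the weighted RSS (Egger's Q on n-2 df).
egger_fit <- function(x, y, w) {
  X <- cbind(1, x)
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * y)))
  resid <- y - drop(X %*% coefs)
  q <- sum(w * resid^2)
  unit_se <- sqrt(diag(solve(xtwx)))
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = unit_se[1], se_slope = unit_se[2], q = q)
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects with a free
#' intercept (weights 1/se_out^2). The slope is the pleiotropy-adjusted
#' causal estimate; a nonzero intercept indicates directional horizontal
#' pleiotropy. Instruments are first oriented so every exposure effect is
#' positive (joint sign flips leave the model invariant). Both standard
#' errors are inflated multiplicatively by max(1, sqrt(Q/(n-2))).
#'
#' @param dat Instrument set; needs at least 3 instruments.
#' @return List with `slope` (an [mr_estimate]) and `intercept` (data frame
#'   `estimate`, `se`, `pval`), plus `Q`/`Q_df` attributes on the slope.
#' @export
mr_egger <- function(dat) {
  assert_instruments(dat, 3L, "mr_egger")
  n <- nrow(dat)
  flip <- sign(dat$beta_exp)
  flip[flip == 0] <- 1
  x <- dat$beta_exp * flip
  y <- dat$beta_out * flip
  fit <- egger_fit(x, y, 1 / dat$se_out^2)
  infl <- max(1, sqrt(fit$q / (n - 2)))
  slope <- mr_estimate("MR-Egger", fit$slope, fit$se_slope * infl, n)
  attr(slope, "Q") <- fit$q
  attr(slope, "Q_df") <- n - 2
  intercept <- data.frame(estimate = fit$intercept,
                          se = fit$se_intercept * infl,
                          pval = z_pval(fit$intercept, fit$se_intercept * infl))
  list(slope = slope, intercept = intercept)
}

# Weighted median of values v with weights w: order by v, form
# midpoint-adjusted cumulative weights, interpolate at 0.5.
weighted_median_point <- function(v, w) {
  ord <- order(v)
  v <- v[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  stats::approx(s, v, xout = 0.5, rule = 2)$y
}

#' Weighted median estimator
#'
#' The weighted median of per-SNP Wald ratios with weights proportional to
#' the inverse variance of each ratio. Consistent as long as valid
#' instruments contribute a majority of the weight. The standard error is a
#' seeded parametric bootstrap: exposure and outcome effects are resampled
#' from normal distributions centred at their observed values with their
#' reported standard errors.
#'
#' @param dat Instrument set; needs at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (RNG state is restored).
#' @return An [mr_estimate].
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = NULL) {
  assert_instruments(dat, 3L, "mr_weighted_median")
  ratios <- dat$beta_out / dat$beta_exp
  w <- (abs(dat$beta_exp) / dat$se_out)^2  # 1 / se(ratio)^2
  est <- weighted_median_point(ratios, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(dat), dat$beta_exp, dat$se_exp)
      by <- stats::rnorm(nrow(dat), dat$beta_out, dat$se_out)
      weighted_median_point(by / bx, (abs(bx) / dat$se_out)^2)
    }, numeric(1))
  })
  mr_estimate("Weighted median", est, stats::sd(boot), nrow(dat))
}

# Kernel-density mode of ratios with the given (normalised) weights;
# bandwidth = phi * modified-Silverman rule on the ratios.
kde_mode <- function(ratios, weights, phi = 1) {
  s <- 0.9 * min(stats::sd(ratios), stats::mad(ratios)) / length(ratios)^(1 / 5)
  h <- max(1e-8, s * phi)
  d <- stats::density(ratios, weights = weights / sum(weights), bw = h)
  d$x[which.max(d$y)]
}

#' Simple and weighted mode estimators
#'
#' The mode of the smoothed empirical density of per-SNP Wald ratios, with
#' equal weights (simple mode) or inverse-variance weights (weighted mode).
#' Kernel bandwidth follows the modified Silverman rule on the ratios,
#' scaled by `bandwidth_factor`. Standard errors come from a seeded
#' parametric bootstrap as in [mr_weighted_median()]. Consistent when the
#' largest group of instruments sharing the same ratio is valid.
#'
#' @param dat Instrument set; needs at least 3 instruments.
#' @param bandwidth_factor Multiplier on the Silverman bandwidth (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List of two [mr_estimate]s: `simple_mode` and `weighted_mode`.
#' @export
mr_mode <- function(dat, bandwidth_factor = 1, n_boot = 1000, seed = NULL) {
  assert_instruments(dat, 3L, "mr_mode")
  n <- nrow(dat)
  ratios <- dat$beta_out / dat$beta_exp
  w <- (abs(dat$beta_exp) / dat$se_out)^2
  if (stats::sd(ratios) == 0) {
    # degenerate: all ratios identical, the mode is that value
    simple <- weighted <- ratios[1]
    boot <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(i) {
        bx <- stats::rnorm(n, dat$beta_exp, dat$se_exp)
        by <- stats::rnorm(n, dat$beta_out, dat$se_out)
        br <- by / bx
        if (stats::sd(br) == 0) return(c(br[1], br[1]))
        bw <- (abs(bx) / dat$se_out)^2
        c(kde_mode(br, rep(1, n), bandwidth_factor),
          kde_mode(br, bw, bandwidth_factor))
      }, numeric(2)))
    })
  } else {
    simple <- kde_mode(ratios, rep(1, n), bandwidth_factor)
    weighted <- kde_mode(ratios, w, bandwidth_factor)
    boot <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(i) {
        bx <- stats::rnorm(n, dat$beta_exp, dat$se_exp)
        by <- stats::rnorm(n, dat$beta_out, dat$se_out)
        br <- by / bx
        bw <- (abs(bx) / dat$se_out)^2
        c(kde_mode(br, rep(1, n), bandwidth_factor),
          kde_mode(br, bw, bandwidth_factor))
      }, numeric(2)))
    })
  }
  list(simple_mode = mr_estimate("Simple mode", simple, stats::sd(boot[, 1]), n),
       weighted_mode = mr_estimate("Weighted mode", weighted, stats::sd(boot[, 2]), n))
}

#' Rescale an MR estimate to a different exposure increment
#'
#' Multiplies the effect, its standard error and the confidence interval by
#' `factor` (e.g. +10 to report per 10 mmHg SBP increase, -10 to report per
#' 10 mmHg SBP decrease). The p-value is scale-invariant and unchanged.
#'
#' @param est An [mr_estimate] in per-unit exposure scale.
#' @param factor Exposure units per reported unit; may be negative; must be
#'   nonzero.
#' @return The rescaled [mr_estimate].
#' @export
scale_estimate <- function(est, factor) {
  if (factor == 0) stop("scale_estimate: factor must be nonzero")
  out <- est
  out$beta <- est$beta * factor
  out$se <- est$se * abs(factor)
  ci <- sort(c(est$ci_low * factor, est$ci_high * factor))
  out$ci_low <- ci[1]
  out$ci_high <- ci[2]
  out$scale_factor <- est$scale_factor * factor
  out
}

#' Bonferroni significance threshold
#'
#' alpha = 0.05 / n for n parallel hypotheses (two blood-pressure indices:
#' 0.025; three drug classes: 0.017 after rounding).
#'
#' @param n_comparisons Number of comparisons (>= 1).
#' @return The per-comparison alpha.
#' @export
significance_threshold <- function(n_comparisons) {
  if (n_comparisons < 1) stop("significance_threshold: n_comparisons must be >= 1")
  0.05 / n_comparisons
}
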