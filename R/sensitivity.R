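#' Cochran's Q heterogeneity test
#'
#' Q = sum w_i (beta_out_i - fit_i)^2 with w = 1/se_out^2, where the fitted
#' values come from the zero-intercept weighted regression (IVW, df = n-1)
#' or the free-intercept weighted regression (MR-Egger, df = n-2). The
#' p-value is the upper tail of the chi-square distribution at df.
#'
#' @param dat Instrument set.
#' @param method `"ivw"` (default) or `"egger"`.
#' @return Data frame of class `heterogeneity_result` with columns `method`,
#'   `Q`, `df`, `pval`.
#' @export
cochran_q <- function(dat, method = c("ivw", "egger")) {
  method <- match.arg(method)
  assert_instruments(dat, if (method == "ivw") 2L else 3L, "cochran_q")
  n <- nrow(dat)
  w <- 1 / dat$se_out^2
  if (method == "ivw") {
    q <- ivw_fit(dat$beta_exp, dat$beta_out, w)$q
    df <- n - 1
    label <- "IVW"
  } else {
    flip <- sign(dat$beta_exp)
    flip[flip == 0] <- 1
    q <- egger_fit(dat$beta_exp * flip, dat$beta_out * flip, w)$q
    df <- n - 2
    label <- "MR-Egger"
  }
  structure(data.frame(method = label, Q = q, df = as.integer(df),
                       pval = stats::pchisq(q, df, lower.tail = FALSE),
                       stringsAsFactors = FALSE),
            class = c("heterogeneity_result", "data.frame"))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression with its standard error and
#' two-sided p-value; an intercept away from zero indicates directional
#' horizontal pleiotropy across the instruments.
#'
#' @param dat Instrument set; needs at least 3 instruments.
#' @return Data frame with columns `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(dat) {
  fit <- mr_egger(dat)
  data.frame(intercept = fit$intercept$estimate,
             se = fit$intercept$se,
             pval = fit$intercept$pval)
}

# Leave-one-out IVW coefficients for every i, computed from running sums in
# O(n): beta_(-i) = (Sxy - w_i x_i y_i) / (Sxx - w_i x_i^2).
loo_ivw_beta <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

# Weighted leave-one-out residual sum of squares for an outcome vector (or a
# matrix with one simulated outcome per row). For each SNP i the residual is
# taken against the IVW fit computed without SNP i, via running sums:
# beta_(-i) = (Sxy - w_i x_i y_i) / (Sxx - w_i x_i^2).
loo_rss <- function(x, ymat, w) {
  if (is.null(dim(ymat))) ymat <- matrix(ymat, nrow = 1)
  wx <- w * x
  sxx <- sum(wx * x)
  sxy <- drop(ymat %*% wx)                        # per-row sum w x y
  bloo <- (matrix(sxy, nrow(ymat), length(x)) - sweep(ymat, 2, wx, `*`)) /
    matrix(sxx - wx * x, nrow(ymat), length(x), byrow = TRUE)
  resid2 <- (ymat - sweep(bloo, 2, x, `*`))^2
  per_snp <- sweep(resid2, 2, w, `*`)
  list(per_snp = per_snp, rss = rowSums(per_snp))
}

#' MR-PRESSO: global pleiotropy, outlier and distortion tests
#'
#' Residual-sum-of-squares based outlier detection by parametric simulation:
#'
#' * global test — the observed weighted leave-one-out RSS of the IVW fit is
#'   compared against `n_sim` simulated RSS values drawn under the fitted
#'   model, beta_out_i ~ Normal(beta_hat * beta_exp_i, se_out_i); the
#'   empirical p uses the (1 + #\{sim >= obs\}) / (1 + n_sim) estimator and
#'   is therefore never exactly zero;
#' * outlier test — each SNP's observed weighted leave-one-out squared
#'   residual is compared against its own simulated distribution;
#'   Bonferroni-adjusted p-values below `outlier_alpha` flag the SNP;
#' * distortion test — the change in the IVW estimate after removing the
#'   flagged outliers is compared against the changes produced by removing
#'   random same-size instrument subsets.
#'
#' All randomness is driven by `seed`; the same seed reproduces the result
#' bit-identically.
#'
#' @param dat Instrument set; needs at least 4 instruments.
#' @param n_sim Number of parametric simulations (default 1000).
#' @param outlier_alpha Family-wise outlier significance level (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `presso_result`: list with `global_rss_pval`,
#'   `outliers` (data frame `snp`, `index`, `pval_bonferroni`),
#'   `distortion_pval`, `estimate_before`/`estimate_after` ([mr_estimate]s),
#'   `rss_obs`, `n_sim`, `seed`.
#' @export
mr_presso <- function(dat, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  assert_instruments(dat, 4L, "mr_presso: at least 4 instruments are required")
  n <- nrow(dat)
  x <- dat$beta_exp
  y <- dat$beta_out
  w <- 1 / dat$se_out^2
  obs <- loo_rss(x, y, w)
  bhat <- ivw_fit(x, y, w)$beta

  res <- with_seed(seed, {
    ysim <- matrix(stats::rnorm(n_sim * n, mean = rep(bhat * x, each = n_sim),
                                sd = rep(dat$se_out, each = n_sim)),
                   nrow = n_sim)
    sim <- loo_rss(x, ysim, w)
    global_p <- (1 + sum(sim$rss >= obs$rss)) / (1 + n_sim)
    per_snp_p <- (1 + colSums(sweep(sim$per_snp, 2, drop(obs$per_snp), `>=`))) /
      (1 + n_sim)
    p_bonf <- pmin(1, per_snp_p * n)
    out_idx <- which(p_bonf < outlier_alpha)

    est_before <- mr_ivw(dat)
    est_after <- NULL
    distortion_p <- NA_real_
    if (length(out_idx) > 0 && length(out_idx) < n - 1) {
      est_after <- mr_ivw(dat[-out_idx, , drop = FALSE])
      d_obs <- est_after$beta - est_before$beta
      k <- length(out_idx)
      d_null <- vapply(seq_len(n_sim), function(i) {
        drop_i <- sample.int(n, k)
        ivw_fit(x[-drop_i], y[-drop_i], w[-drop_i])$beta - est_before$beta
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
    }
    list(global_p = global_p, p_bonf = p_bonf, out_idx = out_idx,
         est_before = est_before, est_after = est_after,
         distortion_p = distortion_p)
  })

  outliers <- data.frame(
    snp = if ("snp" %in% names(dat)) dat$snp[res$out_idx] else
      as.character(res$out_idx),
    index = res$out_idx,
    pval_bonferroni = res$p_bonf[res$out_idx],
    stringsAsFactors = FALSE)
  structure(list(global_rss_pval = res$global_p,
                 outliers = outliers,
                 outlier_pvals = res$p_bonf,
                 distortion_pval = res$distortion_p,
                 estimate_before = res$est_before,
                 estimate_after = res$est_after,
                 rss_obs = obs$rss,
                 n_sim = n_sim,
                 seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat("MR-PRESSO (", x$n_sim, " simulations)\n",
      "  global RSS p = ", format(x$global_rss_pval, digits = 3), "\n",
      "  outliers flagged: ", nrow(x$outliers), "\n", sep = "")
  if (!is.na(x$distortion_pval)) {
    cat("  distortion p = ", format(x$distortion_pval, digits = 3), "\n", sep = "")
  }
  invisible(x)
}
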