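#' Build a multivariable MR instrument set
#'
#' Combines several exposures' summary statistics with one outcome into a
#' single table: one row per SNP carrying every exposure's effect on a
#' common effect allele. Instruments are the union of the supplied SNP ids
#' (typically each exposure's univariable instruments); a SNP missing from
#' any exposure or from the outcome is dropped and logged. The first
#' exposure's allele coding is the reference; other exposures and the
#' outcome are aligned to it with the same swap / strand-complement /
#' frequency rules as [harmonize()].
#'
#' @param exposure_sets Named list of [summary_stats] objects (>= 2).
#' @param outcome A [summary_stats] object.
#' @param snps Optional character vector of instrument ids; default is the
#'   union of all SNPs present in the first exposure.
#' @param af_window Palindromic intermediate-frequency window (see
#'   [harmonize()]).
#' @return A data frame of class `multi_instrument_set` with columns
#'   `snp`, `beta_exp.<label>`, `se_exp.<label>` per exposure, `beta_out`,
#'   `se_out`; attribute `dropped` lists discarded SNPs with reasons.
#' @export
build_multi_set <- function(exposure_sets, outcome, snps = NULL,
                            af_window = 0.08) {
  if (length(exposure_sets) < 2) {
    stop("build_multi_set: at least two exposures are required")
  }
  labels <- names(exposure_sets) %||% paste0("exposure", seq_along(exposure_sets))
  ref <- exposure_sets[[1]]
  snps <- snps %||% ref$snp
  snps <- unique(snps)

  # harmonize every other set (exposures and outcome) onto the reference coding
  aligned <- lapply(seq_along(exposure_sets)[-1], function(k) {
    harmonize(ref[ref$snp %in% snps, , drop = FALSE], exposure_sets[[k]],
              af_window = af_window)
  })
  h_out <- harmonize(ref[ref$snp %in% snps, , drop = FALSE], outcome,
                     af_window = af_window)

  keep <- Reduce(intersect, c(list(snps, h_out$snp), lapply(aligned, `[[`, "snp")))
  dropped <- setdiff(snps, keep)
  for (k in seq_along(exposure_sets)) {
    present <- if (k == 1) sum(snps %in% ref$snp) else
      sum(snps %in% exposure_sets[[k]]$snp)
    if (present < length(snps) / 2) {
      stop("build_multi_set: exposure '", labels[k], "' is missing ",
           length(snps) - present, " of ", length(snps), " instruments (> 50%)")
    }
  }
  if (length(dropped) > 0) {
    message("build_multi_set: dropped ", length(dropped),
            " SNP(s) absent or irreconcilable in some set")
  }

  refk <- ref[match(keep, ref$snp), , drop = FALSE]
  out <- data.frame(snp = keep, stringsAsFactors = FALSE)
  out[[paste0("beta_exp.", labels[1])]] <- refk$beta
  out[[paste0("se_exp.", labels[1])]] <- refk$se
  for (j in seq_along(aligned)) {
    hj <- aligned[[j]][match(keep, aligned[[j]]$snp), ]
    out[[paste0("beta_exp.", labels[j + 1])]] <- hj$beta_out
    out[[paste0("se_exp.", labels[j + 1])]] <- hj$se_out
  }
  ho <- h_out[match(keep, h_out$snp), ]
  out$beta_out <- ho$beta_out
  out$se_out <- ho$se_out
  structure(out,
            exposures = labels,
            dropped = dropped,
            class = c("multi_instrument_set", "data.frame"))
}

#' Multivariable IVW estimator
#'
#' Zero-intercept multiple weighted least squares of the SNP-outcome effects
#' on the matrix of SNP-exposure effects, weights 1/se_out^2, giving each
#' exposure's direct effect conditional on the others. Standard errors use
#' the same multiplicative random-effects inflation as the univariable IVW,
#' max(1, sqrt(Q/(n-k))). Conditional instrument-strength F-statistics are
#' attached as a diagnostic (no filtering is applied).
#'
#' @param multi A `multi_instrument_set` from [build_multi_set()], or any
#'   data frame with `beta_exp.<label>` / `se_exp.<label>` pairs plus
#'   `beta_out`, `se_out`.
#' @param random_effects Inflate SEs multiplicatively (default `TRUE`).
#' @return Data frame with one [mr_estimate] row per exposure; attributes
#'   `Q`, `Q_df` and `conditional_F` (named per exposure).
#' @export
mvmr_ivw <- function(multi, random_effects = TRUE) {
  bcols <- grep("^beta_exp\\.", names(multi), value = TRUE)
  labels <- sub("^beta_exp\\.", "", bcols)
  k <- length(bcols)
  if (k < 2) stop("mvmr_ivw: need at least two exposures")
  n <- nrow(multi)
  if (n <= k) stop("mvmr_ivw: need more instruments (", n, ") than exposures (", k, ")")
  X <- as.matrix(multi[, bcols])
  y <- multi$beta_out
  w <- 1 / multi$se_out^2
  # an exposure with identically zero effects is unidentified: fit without it
  # and report NA for its coefficient
  zero <- colSums(abs(X)) == 0
  if (any(zero)) {
    message("mvmr_ivw: exposure(s) with all-zero effects left unestimated: ",
            paste(labels[zero], collapse = ", "))
    sub <- mvmr_sub(multi, bcols[!zero], labels[!zero], random_effects)
    na_rows <- do.call(rbind, lapply(labels[zero], function(l) {
      e <- mr_estimate(paste0("MVMR IVW (", l, ")"), 0, 1, nrow(multi))
      e[, c("beta", "se", "ci_low", "ci_high", "pval")] <- NA_real_
      e$exposure <- l
      e
    }))
    out <- rbind(as.data.frame(sub), na_rows)
    out <- out[match(labels, out$exposure), ]
    rownames(out) <- NULL
    return(structure(out, Q = attr(sub, "Q"), Q_df = attr(sub, "Q_df"),
                     conditional_F = attr(sub, "conditional_F"),
                     class = c("mr_estimate", "data.frame")))
  }
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < k) {
    dep <- labels[qrX$pivot[(qrX$rank + 1):k]]
    stop("mvmr_ivw: exposure effect matrix is rank deficient; collinear exposure(s): ",
         paste(dep, collapse = ", "))
  }
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * y)))
  resid <- y - drop(X %*% coefs)
  q <- sum(w * resid^2)
  infl <- if (random_effects) max(1, sqrt(q / (n - k))) else 1
  ses <- sqrt(diag(solve(xtwx))) * infl

  # conditional F: strength of each exposure's effects not explained by the
  # other exposures (WLS of x_j on the rest, weights 1/se_exp_j^2)
  cond_f <- vapply(seq_len(k), function(j) {
    wj <- 1 / multi[[sub("beta", "se", bcols[j])]]^2
    Xo <- cbind(1, X[, -j, drop = FALSE])
    cj <- solve(crossprod(Xo, wj * Xo), crossprod(Xo, wj * X[, j]))
    rj <- X[, j] - drop(Xo %*% cj)
    sum(wj * rj^2) / (n - k)
  }, numeric(1))
  names(cond_f) <- labels

  est <- do.call(rbind, lapply(seq_len(k), function(j) {
    e <- mr_estimate(paste0("MVMR IVW (", labels[j], ")"), coefs[j], ses[j], n)
    e$exposure <- labels[j]
    e
  }))
  structure(est, Q = q, Q_df = n - k, conditional_F = cond_f,
            class = c("mr_estimate", "data.frame"))
}

# Fit on a subset of exposure columns (used when a column is identically
# zero); with one exposure left this is the univariable IVW.
mvmr_sub <- function(multi, bcols, labels, random_effects) {
  if (length(bcols) >= 2) {
    keep <- c(bcols, sub("^beta", "se", bcols), "beta_out", "se_out")
    return(mvmr_ivw(multi[, keep], random_effects))
  }
  d <- data.frame(beta_exp = multi[[bcols]],
                  se_exp = multi[[sub("^beta", "se", bcols)]],
                  beta_out = multi$beta_out, se_out = multi$se_out)
  e <- mr_ivw(d, random_effects)
  e$method <- paste0("MVMR IVW (", labels, ")")
  e$exposure <- labels
  structure(e, conditional_F = stats::setNames(
    mean(f_statistic(d$beta_exp, d$se_exp)), labels))
}
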