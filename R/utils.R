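#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so seeded helpers never perturb an
#' enclosing simulation.
#'
#' @param seed Integer seed, or `NULL` to run with the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Two-sided normal p-value for an estimate/SE pair.
z_pval <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

# 97.5% normal quantile used for every 95% CI in the package.
z95 <- function() stats::qnorm(0.975)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical unordered key for an LD pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

assert_instruments <- function(dat, min_n = 1L, caller = "estimator") {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(dat))
  if (length(miss) > 0) {
    stop(caller, ": instrument set lacks column(s) ", paste(miss, collapse = ", "))
  }
  if (nrow(dat) < min_n) {
    stop(caller, " requires at least ", min_n, " instrument(s); got ", nrow(dat))
  }
  if (any(!is.finite(dat$se_out)) || any(dat$se_out <= 0)) {
    stop(caller, ": all outcome standard errors must be finite and > 0")
  }
  if (any(!is.finite(dat$se_exp)) || any(dat$se_exp <= 0)) {
    stop(caller, ": all exposure standard errors must be finite and > 0")
  }
  invisible(dat)
}
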