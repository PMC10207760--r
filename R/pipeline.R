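#' Default analysis thresholds
#'
#' Every tunable threshold of the workflow in one list: genome-wide
#' significance 5e-8; clumping window 10000 kb at r2 < 0.001; drug-class
#' region pruning at r2 < 0.4 with a stricter 0.2 re-analysis;
#' weak-instrument cut F < 10; palindromic intermediate-frequency window
#' 0.08; exposure scaling +10 mmHg (SBP) and +5 mmHg (DBP), -10 mmHg for
#' drug classes; Bonferroni alpha 0.05/2 for the two BP indices and 0.05/3
#' for the three drug classes.
#'
#' @return Named list of defaults.
#' @export
paper_defaults <- function() {
  list(p_thresh = 5e-8,
       clump_kb = 10000,
       clump_r2 = 0.001,
       drug_r2 = c(0.4, 0.2),
       f_min = 10,
       af_window = 0.08,
       scale_sbp = 10,
       scale_dbp = 5,
       scale_drug = -10,
       alpha_bp = significance_threshold(2),
       alpha_drug = significance_threshold(3),
       n_boot = 1000,
       presso_nsim = 1000)
}

#' Load an analysis configuration from YAML
#'
#' The YAML may override any entry of [paper_defaults()] under a
#' `thresholds` key and must name the input paths (`exposures`, each with
#' `path`, `trait_sd`, `scale`; `outcome`; `ld_pairs`; `ld_variants`;
#' optional `regions`, `confounders`). Nothing outside the named paths is
#' ever read.
#'
#' @param path YAML file.
#' @return Config list with a fully populated `thresholds` entry.
#' @export
load_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- paper_defaults()
  for (nm in names(cfg$thresholds %||% list())) th[[nm]] <- cfg$thresholds[[nm]]
  cfg$thresholds <- th
  cfg
}

# Run every estimator on a harmonized set, scale, and stack the rows.
estimate_all <- function(dat, scale_factor, seed, n_boot = 1000) {
  if (nrow(dat) == 0) return(NULL)
  if (nrow(dat) == 1) {
    warning("estimate_all: single instrument; Wald ratio only")
    return(scale_estimate(wald_ratio(dat), scale_factor))
  }
  rows <- list(mr_ivw(dat))
  if (nrow(dat) >= 3) {
    eg <- mr_egger(dat)
    rows <- c(rows, list(eg$slope,
                         mr_weighted_median(dat, n_boot = n_boot, seed = seed),
                         mr_mode(dat, n_boot = n_boot, seed = seed + 1L)))
    rows <- c(rows[1:3], rows[[4]])
  }
  flat <- do.call(rbind, lapply(rows, as.data.frame))
  flat <- do.call(rbind, lapply(seq_len(nrow(flat)), function(i) {
    scale_estimate(structure(flat[i, ], class = c("mr_estimate", "data.frame")),
                   scale_factor)
  }))
  rownames(flat) <- NULL
  flat
}

# Heterogeneity/pleiotropy diagnostics block shaped like a summary table:
# one row per test.
diagnostics_block <- function(dat, label, presso_nsim, seed) {
  out <- list()
  if (nrow(dat) >= 3) {
    qe <- cochran_q(dat, "egger")
    out$egger_q <- data.frame(exposure = label, test = "Cochran Q (MR-Egger)",
                              statistic = qe$Q, df = qe$df, pval = qe$pval)
  }
  if (nrow(dat) >= 2) {
    qi <- cochran_q(dat, "ivw")
    out$ivw_q <- data.frame(exposure = label, test = "Cochran Q (IVW)",
                            statistic = qi$Q, df = qi$df, pval = qi$pval)
  }
  if (nrow(dat) >= 3) {
    it <- egger_intercept_test(dat)
    out$intercept <- data.frame(exposure = label, test = "MR-Egger intercept",
                                statistic = it$intercept, df = NA_integer_,
                                pval = it$pval)
  }
  if (nrow(dat) >= 4) {
    pr <- mr_presso(dat, n_sim = presso_nsim, seed = seed)
    out$presso <- data.frame(exposure = label, test = "MR-PRESSO global",
                             statistic = pr$rss_obs, df = NA_integer_,
                             pval = pr$global_rss_pval)
    attr(out, "presso") <- pr
  }
  out
}

#' Run the blood-pressure MR analysis end to end
#'
#' For each exposure (e.g. SBP, DBP): instrument selection (significance
#' filter, clumping, confounder screen, F filter), harmonization with the
#' outcome, the five estimators plus IVW, heterogeneity / pleiotropy /
#' MR-PRESSO diagnostics, then a joint multivariable IVW fit across the
#' exposures, with significance declared at 0.05/2.
#'
#' @param exposures Named list; each element a list with `stats` (a
#'   [summary_stats]), `scale` (mmHg per reported unit, e.g. 10 for SBP).
#' @param outcome Outcome [summary_stats].
#' @param ld An [ld_reference].
#' @param confounders Optional confounder table.
#' @param thresholds Threshold list, see [paper_defaults()].
#' @param seed Integer seed driving every stochastic step (bootstraps,
#'   MR-PRESSO).
#' @return List of class `mr_report`: `estimates` (stacked estimator rows
#'   with significance calls), `diagnostics` (heterogeneity/pleiotropy
#'   table), `selection` (per-exposure stage counts), `harmonization`
#'   (per-exposure audits), `mvmr` (joint estimates), `presso`
#'   (full MR-PRESSO results), `alpha`.
#' @export
run_bp_analysis <- function(exposures, outcome, ld, confounders = NULL,
                            thresholds = paper_defaults(), seed = 1L) {
  alpha <- significance_threshold(length(exposures))
  est_rows <- list()
  diag_rows <- list()
  selection <- list()
  harmon <- list()
  presso <- list()
  selected_sets <- list()

  for (nm in names(exposures)) {
    ex <- exposures[[nm]]
    sel <- select_instruments(ex$stats, ld, confounders,
                              p_thresh = thresholds$p_thresh,
                              window_kb = thresholds$clump_kb,
                              r2_max = thresholds$clump_r2,
                              f_min = thresholds$f_min)
    selection[[nm]] <- sel$report
    selected_sets[[nm]] <- sel$instruments
    if (nrow(sel$instruments) == 0) {
      stop("run_bp_analysis: no instrument survives selection for ", nm)
    }
    h <- harmonize(sel$instruments, outcome, af_window = thresholds$af_window)
    harmon[[nm]] <- list(n_intersection = attr(h, "n_intersection"),
                         dropped_palindromic = attr(h, "dropped_palindromic"),
                         dropped_irreconcilable = attr(h, "dropped_irreconcilable"),
                         n_retained = nrow(h))
    est <- estimate_all(h, ex$scale, seed = seed,
                        n_boot = thresholds$n_boot)
    est$exposure <- nm
    est$significant <- est$pval < alpha
    est_rows[[nm]] <- est
    db <- diagnostics_block(h, nm, thresholds$presso_nsim, seed)
    presso[[nm]] <- attr(db, "presso")
    diag_rows[[nm]] <- do.call(rbind, db)
  }

  mv <- NULL
  if (length(exposures) >= 2) {
    union_snps <- unique(unlist(lapply(selected_sets, `[[`, "snp")))
    multi <- build_multi_set(lapply(exposures, `[[`, "stats"), outcome,
                             snps = union_snps,
                             af_window = thresholds$af_window)
    mv <- mvmr_ivw(multi)
    mv <- do.call(rbind, lapply(seq_len(nrow(mv)), function(i) {
      scale_estimate(structure(mv[i, ], class = c("mr_estimate", "data.frame")),
                     exposures[[mv$exposure[i]]]$scale)
    }))
    mv$significant <- mv$pval < alpha
  }

  structure(list(estimates = do.call(rbind, est_rows),
                 diagnostics = do.call(rbind, diag_rows),
                 selection = selection,
                 harmonization = harmon,
                 mvmr = mv,
                 presso = presso,
                 alpha = alpha,
                 seed = seed),
            class = "mr_report")
}

#' Run the drug-target MR analysis end to end
#'
#' For each antihypertensive drug class (ACEI, BB, CCB) and each region LD
#' threshold (0.4 and the stricter 0.2): cis proxy selection inside the
#' class's target-gene regions, orientation to the SBP-lowering allele,
#' harmonization, estimation scaled per 10 mmHg SBP decrease, diagnostics,
#' and significance at 0.05/3. A class with a single proxy falls back to
#' the Wald ratio with a warning; a class with none is reported without
#' estimate rows.
#'
#' @param exposure SBP [summary_stats].
#' @param outcome Outcome [summary_stats].
#' @param regions Region table ([read_gene_regions()]).
#' @param ld An [ld_reference].
#' @param confounders Optional confounder table.
#' @param thresholds Threshold list, see [paper_defaults()].
#' @param seed Integer seed.
#' @return List of class `mr_report` with `estimates`, `diagnostics`,
#'   `proxy_counts`, `presso`, `alpha`.
#' @export
run_drug_analysis <- function(exposure, outcome, regions, ld,
                              confounders = NULL,
                              thresholds = paper_defaults(), seed = 1L) {
  classes <- intersect(c("ACEI", "BB", "CCB"), unique(regions$drug_class))
  alpha <- significance_threshold(3)
  est_rows <- list()
  diag_rows <- list()
  counts <- list()
  presso <- list()

  for (cls in classes) {
    for (r2_max in thresholds$drug_r2) {
      key <- sprintf("%s_r2_%g", cls, r2_max)
      prox <- select_drug_instruments(exposure, regions, cls, ld,
                                      p_thresh = thresholds$p_thresh,
                                      r2_max = r2_max)
      prox <- screen_confounders(prox, confounders, thresholds$p_thresh)
      prox <- filter_weak(prox, thresholds$f_min)
      counts[[key]] <- nrow(prox)
      if (nrow(prox) == 0) {
        warning("run_drug_analysis: no proxies for ", cls, " at r2 < ", r2_max)
        next
      }
      h <- harmonize(prox, outcome, af_window = thresholds$af_window)
      if (nrow(h) == 0) next
      est <- estimate_all(h, thresholds$scale_drug, seed = seed,
                          n_boot = thresholds$n_boot)
      est$drug_class <- cls
      est$ld_threshold <- r2_max
      est$significant <- est$pval < alpha
      est_rows[[key]] <- est
      db <- diagnostics_block(h, key, thresholds$presso_nsim, seed)
      presso[[key]] <- attr(db, "presso")
      if (length(db) > 0) diag_rows[[key]] <- do.call(rbind, db)
    }
  }

  structure(list(estimates = if (length(est_rows)) do.call(rbind, est_rows),
                 diagnostics = if (length(diag_rows)) do.call(rbind, diag_rows),
                 proxy_counts = unlist(counts),
                 presso = presso,
                 alpha = alpha,
                 seed = seed),
            class = "mr_report")
}

#' Write an analysis report to TSV and JSON
#'
#' @param report An `mr_report`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, prefix = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$estimates)) {
    utils::write.table(report$estimates,
                       file.path(dir, paste0(prefix, "_estimates.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$diagnostics)) {
    utils::write.table(report$diagnostics,
                       file.path(dir, paste0(prefix, "_diagnostics.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  keep <- report[!vapply(report, is.null, TRUE)]
  keep$presso <- NULL
  jsonlite::write_json(keep, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR analysis report (alpha = ", format(x$alpha, digits = 3), ")\n", sep = "")
  if (!is.null(x$estimates)) {
    print(x$estimates[, intersect(c("exposure", "drug_class", "ld_threshold",
                                    "method", "beta", "ci_low", "ci_high",
                                    "pval", "n_snp", "significant"),
                                  names(x$estimates))])
  }
  invisible(x)
}
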