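#' Genome-wide significance filter
#'
#' Retains variants whose association p-value is strictly below the
#' genome-wide threshold (default 5e-8).
#'
#' @param stats A [summary_stats] object.
#' @param p_thresh Significance threshold; the comparison is strict, so a
#'   variant at exactly the threshold is removed.
#' @return The filtered [summary_stats].
#' @export
filter_genome_wide <- function(stats, p_thresh = 5e-8) {
  keep <- stats$pval < p_thresh
  if (!any(keep)) message("filter_genome_wide: no variant passes p < ", p_thresh)
  stats[keep, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value as the
#' index and discards every remaining variant on the same chromosome within
#' `window_kb` (centre-to-centre) whose r2 with the index is >= `r2_max`.
#' Ties on p-value are broken by (chrom, pos, snp) so the output is
#' deterministic. A within-window pair whose LD is unknowable (a variant
#' missing from the reference panel) is discarded conservatively and the
#' event logged.
#'
#' @param stats A [summary_stats] object with chrom/pos on every variant.
#' @param ld An [ld_reference].
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param r2_max LD threshold; retained variants have pairwise r2 strictly
#'   below it within the window (default 0.001).
#' @return The clumped [summary_stats]; attribute `clump_removed` records
#'   each discarded variant, its index variant and the r2.
#' @export
clump <- function(stats, ld, window_kb = 10000, r2_max = 0.001) {
  if (nrow(stats) <= 1) return(stats)
  ord <- order(stats$pval, stats$chrom, stats$pos, stats$snp)
  df <- as.data.frame(stats)[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(df))
  keep <- logical(nrow(df))
  removed <- list()
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive &
                    df$chrom == df$chrom[i] &
                    abs(df$pos - df$pos[i]) <= window_kb * 1000)
    if (length(cand) == 0) next
    r2 <- ld_r2(ld, df$snp[i], df$snp[cand])
    unknown <- is.na(r2)
    if (any(unknown)) {
      message("clump: LD unknown for ", sum(unknown), " within-window pair(s) of index ",
              df$snp[i], "; treated as r2 = 1 (discarded)")
      r2[unknown] <- 1
    }
    drop <- cand[r2 >= r2_max]
    if (length(drop) > 0) {
      removed[[length(removed) + 1L]] <- data.frame(
        snp = df$snp[drop], index = df$snp[i], r2 = r2[r2 >= r2_max],
        stringsAsFactors = FALSE)
      alive[drop] <- FALSE
    }
  }
  out <- stats[ord[keep], , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$snp), , drop = FALSE]
  attr(out, "clump_removed") <- if (length(removed) > 0) {
    do.call(rbind, removed)
  } else {
    data.frame(snp = character(), index = character(), r2 = numeric())
  }
  out
}

#' Instrument strength F-statistic
#'
#' F = beta^2 / se^2 for a single-SNP instrument; values below 10
#' conventionally indicate a weak instrument.
#'
#' @param beta,se Effect size and its standard error (vectorised).
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("f_statistic: se must be > 0")
  beta^2 / se^2
}

#' Exposure variance explained by one instrument
#'
#' R^2 = 2 beta^2 EAF (1 - EAF) / SD^2, where beta is the per-allele effect,
#' EAF the effect-allele frequency and SD the phenotype standard deviation.
#'
#' @param beta Per-allele effect in trait units (vectorised).
#' @param eaf Effect-allele frequency in (0, 1).
#' @param trait_sd Phenotype standard deviation in the same units as `beta`.
#' @return Fraction of trait variance explained per variant.
#' @export
variance_explained <- function(beta, eaf, trait_sd) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop("variance_explained: eaf must lie in (0, 1)")
  }
  if (any(!is.finite(trait_sd)) || any(trait_sd <= 0)) {
    stop("variance_explained: trait_sd must be > 0")
  }
  2 * beta^2 * eaf * (1 - eaf) / trait_sd^2
}

#' Remove weak instruments
#'
#' Drops variants with F-statistic strictly below `f_min`; F equal to the
#' threshold is kept.
#'
#' @param stats A [summary_stats] object.
#' @param f_min Minimum instrument strength (default 10).
#' @return The filtered [summary_stats] with attribute `weak_removed`.
#' @export
filter_weak <- function(stats, f_min = 10) {
  f <- f_statistic(stats$beta, stats$se)
  keep <- f >= f_min
  out <- stats[keep, , drop = FALSE]
  attr(out, "weak_removed") <- data.frame(snp = stats$snp[!keep], f = f[!keep],
                                          stringsAsFactors = FALSE)
  out
}

#' Screen instruments against known confounders
#'
#' Removes variants carrying a genome-wide significant association
#' (p strictly below `p_thresh`) with any confounder trait in the local
#' lookup table.
#'
#' @param stats A [summary_stats] object.
#' @param table Confounder lookup (data frame `snp`, `trait`, `pval`), see
#'   [read_confounder_table()].
#' @param p_thresh Removal threshold (default 5e-8, strict).
#' @return The filtered [summary_stats] with attribute `confounder_removed`
#'   listing each removed variant and the trait that triggered it.
#' @export
screen_confounders <- function(stats, table, p_thresh = 5e-8) {
  if (is.null(table) || nrow(table) == 0) {
    attr(stats, "confounder_removed") <-
      data.frame(snp = character(), trait = character(), pval = numeric())
    return(stats)
  }
  hits <- table[table$pval < p_thresh & table$snp %in% stats$snp, , drop = FALSE]
  out <- stats[!stats$snp %in% hits$snp, , drop = FALSE]
  if (nrow(hits) > 0) {
    message("screen_confounders: removed ", length(unique(hits$snp)),
            " variant(s) associated with: ",
            paste(unique(hits$trait), collapse = ", "))
  }
  attr(out, "confounder_removed") <- hits[, c("snp", "trait", "pval")]
  out
}

#' Full instrument-selection pipeline for a genome-wide exposure
#'
#' Applies, in order: genome-wide significance filter, greedy LD clumping,
#' confounder screen, weak-instrument (F) filter — and reports the variant
#' count at every stage together with per-SNP exclusion reasons.
#'
#' @param stats Exposure [summary_stats].
#' @param ld An [ld_reference].
#' @param confounders Optional confounder table.
#' @param p_thresh Genome-wide threshold (default 5e-8).
#' @param window_kb,r2_max Clumping parameters (defaults 10000 kb, 0.001).
#' @param f_min Weak-instrument threshold (default 10).
#' @return List with `instruments` (the selected [summary_stats], including
#'   per-SNP `f_stat` and `r2_explained` columns) and `report` (stage counts
#'   and an exclusions data frame with machine-readable reason codes
#'   NOT_GWS / CLUMPED / CONFOUNDER / WEAK_F).
#' @export
select_instruments <- function(stats, ld, confounders = NULL,
                               p_thresh = 5e-8, window_kb = 10000,
                               r2_max = 0.001, f_min = 10) {
  excl <- list()
  note <- function(snps, code) {
    if (length(snps) > 0) {
      excl[[length(excl) + 1L]] <<- data.frame(snp = snps, reason = code,
                                               stringsAsFactors = FALSE)
    }
  }
  n_input <- nrow(stats)
  gws <- filter_genome_wide(stats, p_thresh)
  note(setdiff(stats$snp, gws$snp), "NOT_GWS")
  clumped <- clump(gws, ld, window_kb = window_kb, r2_max = r2_max)
  note(setdiff(gws$snp, clumped$snp), "CLUMPED")
  screened <- screen_confounders(clumped, confounders, p_thresh)
  note(setdiff(clumped$snp, screened$snp), "CONFOUNDER")
  strong <- filter_weak(screened, f_min)
  note(setdiff(screened$snp, strong$snp), "WEAK_F")
  strong$f_stat <- f_statistic(strong$beta, strong$se)
  trait_sd <- attr(stats, "trait_sd")
  strong$r2_explained <- if (!is.na(trait_sd)) {
    variance_explained(strong$beta, strong$eaf, trait_sd)
  } else {
    NA_real_
  }
  report <- list(
    counts = c(input = n_input,
               genome_wide = nrow(gws),
               post_clump = nrow(clumped),
               post_confounder = nrow(screened),
               post_f = nrow(strong)),
    exclusions = if (length(excl) > 0) do.call(rbind, excl) else
      data.frame(snp = character(), reason = character())
  )
  stopifnot(!is.unsorted(rev(report$counts)))  # stage counts non-increasing
  list(instruments = strong, report = report)
}
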