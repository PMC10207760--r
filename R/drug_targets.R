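#' Variants inside a drug class's target-gene regions
#'
#' Containment is 1-based inclusive on both ends against every gene body and
#' regulatory interval annotated to the class.
#'
#' @param stats A [summary_stats] object.
#' @param regions Region table from [read_gene_regions()].
#' @param drug_class One of the classes present in `regions` (e.g. `"CCB"`).
#' @return The subset of `stats` lying in any interval of the class, with a
#'   `gene` column naming the (first) containing interval's gene.
#' @export
variants_in_regions <- function(stats, regions, drug_class) {
  reg <- regions[regions$drug_class == drug_class, , drop = FALSE]
  if (nrow(reg) == 0) {
    warning("variants_in_regions: no regions annotated for class ", drug_class)
    out <- stats[0, , drop = FALSE]
    out$gene <- character(0)
    return(out)
  }
  gene <- rep(NA_character_, nrow(stats))
  inside <- rep(FALSE, nrow(stats))
  for (j in seq_len(nrow(reg))) {
    hit <- stats$chrom == reg$chrom[j] &
      stats$pos >= reg$start[j] & stats$pos <= reg$end[j]
    gene[hit & !inside] <- reg$gene[j]
    inside <- inside | hit
  }
  out <- stats[inside, , drop = FALSE]
  out$gene <- gene[inside]
  out
}

#' Exhaustive greedy LD pruning (no distance window)
#'
#' Same greedy rule as [clump()] — smallest p-value first, ties broken by
#' (chrom, pos, snp) — but every remaining pair is checked regardless of
#' chromosome or distance, as appropriate for compact cis regions.
#'
#' @inheritParams clump
#' @return The pruned [summary_stats].
#' @export
clump_region <- function(stats, ld, r2_max = 0.4) {
  if (nrow(stats) <= 1) return(stats)
  ord <- order(stats$pval, stats$chrom, stats$pos, stats$snp)
  df <- as.data.frame(stats)[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(df))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand) == 0) next
    r2 <- ld_r2(ld, df$snp[i], df$snp[cand])
    if (any(is.na(r2))) {
      message("clump_region: LD unknown for ", sum(is.na(r2)),
              " pair(s); treated as r2 = 1 (discarded)")
      r2[is.na(r2)] <- 1
    }
    alive[cand[r2 >= r2_max]] <- FALSE
  }
  out <- stats[ord[keep], , drop = FALSE]
  out[order(out$chrom, out$pos, out$snp), , drop = FALSE]
}

#' Select drug-class proxy instruments
#'
#' Builds the cis instrument set proxying the blood-pressure-lowering effect
#' of one antihypertensive drug class: variants inside the class's
#' target-gene or regulatory intervals, genome-wide significant for the
#' exposure, pruned by the exhaustive greedy rule at a deliberately lenient
#' LD threshold (0.4 by default; 0.2 for the stricter re-analysis), then
#' oriented so the recorded effect allele lowers the exposure.
#'
#' @param stats Exposure (SBP) [summary_stats].
#' @param regions Region table from [read_gene_regions()].
#' @param drug_class Class label, e.g. `"ACEI"`, `"BB"`, `"CCB"`.
#' @param ld An [ld_reference].
#' @param p_thresh Significance threshold (default 5e-8, strict).
#' @param r2_max Within-region LD threshold (0.4 or 0.2).
#' @param orient Orient instruments to the exposure-lowering allele
#'   (default `TRUE`).
#' @return A [summary_stats] of proxies (possibly empty, with a warning);
#'   carries a `gene` column.
#' @export
select_drug_instruments <- function(stats, regions, drug_class, ld,
                                    p_thresh = 5e-8, r2_max = 0.4,
                                    orient = TRUE) {
  cand <- variants_in_regions(stats, regions, drug_class)
  cand <- filter_genome_wide(cand, p_thresh)
  if (nrow(cand) == 0) {
    warning("select_drug_instruments: no significant variant in any ",
            drug_class, " region")
    return(cand)
  }
  pruned <- clump_region(cand, ld, r2_max = r2_max)
  if (orient) pruned <- orient_to_drug_effect(pruned) else pruned
}

#' Orient instruments to the exposure-lowering allele
#'
#' Re-expresses every variant so the recorded effect allele is the one that
#' LOWERS the exposure: where beta > 0 the alleles are swapped, beta negated
#' and the effect-allele frequency complemented. After orientation every
#' beta is negative (a positive beta is impossible); variants with beta = 0
#' carry no direction and are excluded with a warning. The operation is
#' idempotent and leaves all downstream Wald-ratio magnitudes unchanged.
#'
#' @param stats A [summary_stats] object.
#' @return The oriented [summary_stats] with a logical `flipped` column.
#' @export
orient_to_drug_effect <- function(stats) {
  zero <- stats$beta == 0
  if (any(zero)) {
    warning("orient_to_drug_effect: excluded ", sum(zero),
            " variant(s) with beta = 0 (no direction)")
    stats <- stats[!zero, , drop = FALSE]
  }
  flip <- stats$beta > 0
  out <- stats
  ea <- out$effect_allele
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- ea[flip]
  out$beta[flip] <- -out$beta[flip]
  out$eaf[flip] <- 1 - out$eaf[flip]
  if ("flipped" %in% names(out)) {
    out$flipped <- out$flipped | flip
  } else {
    out$flipped <- flip
  }
  out
}
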