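#' Is an allele pair palindromic?
#'
#' A biallelic SNP is palindromic when its two alleles are strand
#' complements of each other ({A,T} or {C,G}), so the strand cannot be
#' resolved from the alleles alone.
#'
#' @param a1,a2 Single-base allele vectors.
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  p <- paste(pmin(a1, a2), pmax(a1, a2))
  p == "A T" | p == "C G"
}

# Strand complement of single-base alleles.
allele_complement <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two summary-statistic sets onto identical effect alleles so the
#' per-SNP (exposure effect, outcome effect) pairs feeding the MR
#' estimators refer to the same allele. For each SNP in the intersection:
#'
#' 1. identical allele pairs pass through;
#' 2. swapped outcome alleles: outcome beta negated, outcome EAF
#'    complemented;
#' 3. strand-complement encodings (non-palindromic only): relabelled,
#'    with the swap rule applied on top when needed;
#' 4. palindromic SNPs: strand logic is ambiguous by construction, so
#'    alignment uses allele frequency. SNPs with intermediate frequency
#'    (within `af_window` of 0.5 on either side, or with a missing EAF) are
#'    dropped and counted; the rest are aligned so minor/major alleles
#'    correspond across the two sets;
#' 5. anything else is irreconcilable and dropped with a reason.
#'
#' @param exposure,outcome [summary_stats] objects sharing SNP ids.
#' @param af_window Half-width of the "intermediate frequency" window around
#'   0.5 within which a palindromic SNP is unresolvable (default 0.08).
#' @return Data frame of class `instrument_set` with columns `snp`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `beta_out`, `se_out`, `eaf_out`, `pval_exp`, `flipped`,
#'   `palindromic`; attributes `audit` (per-SNP action/reason),
#'   `n_intersection`, `dropped_palindromic`, `dropped_irreconcilable`, and
#'   the exposure/outcome trait labels.
#' @export
harmonize <- function(exposure, outcome, af_window = 0.08) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) {
    stop("harmonize: exposure and outcome share no snp ids")
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$snp), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$snp), ]

  n <- length(shared)
  keep <- rep(TRUE, n)
  flipped <- rep(FALSE, n)
  action <- rep("aligned", n)
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)

  beta_out <- ou$beta
  eaf_out <- ou$eaf

  flip_i <- function(i) {
    beta_out[i] <<- -beta_out[i]
    eaf_out[i] <<- 1 - eaf_out[i]
    flipped[i] <<- TRUE
  }

  for (i in seq_len(n)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    if (palin[i]) {
      # same allele set required; orientation by frequency
      if (!setequal(c(o1, o2), c(e1, e2))) {
        keep[i] <- FALSE; action[i] <- "irreconcilable"; next
      }
      if (is.na(ex$eaf[i]) || is.na(ou$eaf[i])) {
        keep[i] <- FALSE; action[i] <- "palindromic_dropped"; next
      }
      # EAF of the exposure effect allele on the outcome side
      eaf_out_as_is <- if (o1 == e1) ou$eaf[i] else 1 - ou$eaf[i]
      if (abs(ex$eaf[i] - 0.5) < af_window || abs(eaf_out_as_is - 0.5) < af_window) {
        keep[i] <- FALSE; action[i] <- "palindromic_dropped"; next
      }
      # two candidate alignments; pick the one matching minor/major alleles
      if (abs(ex$eaf[i] - eaf_out_as_is) <= abs(ex$eaf[i] - (1 - eaf_out_as_is))) {
        if (o1 != e1) flip_i(i)  # stored swapped but frequencies already agree
      } else {
        if (o1 == e1) flip_i(i)
        action[i] <- "palindromic_freq_flipped"
      }
      next
    }
    if (o1 == e1 && o2 == e2) next
    if (o1 == e2 && o2 == e1) { flip_i(i); action[i] <- "swapped"; next }
    c1 <- allele_complement(o1); c2 <- allele_complement(o2)
    if (identical(unname(c1), e1) && identical(unname(c2), e2)) {
      action[i] <- "strand_flipped"; next
    }
    if (identical(unname(c1), e2) && identical(unname(c2), e1)) {
      flip_i(i); action[i] <- "strand_flipped_swapped"; next
    }
    keep[i] <- FALSE; action[i] <- "irreconcilable"
  }

  out <- data.frame(
    snp = shared, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf, pval_exp = ex$pval,
    beta_out = beta_out, se_out = ou$se, eaf_out = eaf_out,
    flipped = flipped, palindromic = palin,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL

  audit <- data.frame(snp = shared, action = action, retained = keep,
                      stringsAsFactors = FALSE)
  n_pal <- sum(action == "palindromic_dropped")
  n_irr <- sum(action == "irreconcilable")
  stopifnot(n == nrow(out) + n_pal + n_irr)  # count conservation
  structure(out,
            audit = audit,
            n_intersection = n,
            dropped_palindromic = n_pal,
            dropped_irreconcilable = n_irr,
            exposure_label = attr(exposure, "trait_label"),
            outcome_label = attr(outcome, "trait_label"),
            class = c("instrument_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Harmonized instrument set: ", attr(x, "exposure_label") %||% "exposure",
      " -> ", attr(x, "outcome_label") %||% "outcome",
      " (", nrow(x), " SNPs; dropped ", attr(x, "dropped_palindromic") %||% 0,
      " palindromic, ", attr(x, "dropped_irreconcilable") %||% 0,
      " irreconcilable)\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Write a harmonized instrument set with its audit columns
#'
#' @param x An `instrument_set` from [harmonize()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_instrument_set <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
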