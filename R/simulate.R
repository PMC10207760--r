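#' Scenario configuration for the synthetic two-sample GWAS generator
#'
#' Defaults emulate the study conditions of a large European blood-pressure
#' GWAS meta-analysis used as the exposure sample (757,601 participants,
#' SBP SD 21.5 mmHg) and a disease-modifier GWAS used as the outcome sample
#' (9,064 patients; residual age at onset in years). Roughly 450 independent
#' instruments jointly explaining ~1.6% of exposure variance give per-SNP
#' F-statistics in the realistic 20-120 range. Per-SNP standard errors
#' follow the standard GWAS approximation se = SD / sqrt(2 EAF (1-EAF) N);
#' the default outcome SD (0.5 years) is the value that makes the outcome
#' sample's per-SNP precision — and hence the width of the final causal
#' CIs — consistent with the confidence intervals such an analysis reports
#' given its 9,064-patient cohort and the instruments' variance explained.
#'
#' @param n_snps Number of variants to simulate.
#' @param n_exposure,n_outcome GWAS sample sizes for the two samples.
#' @param trait_sd Exposure phenotype SD in trait units (mmHg).
#' @param outcome_sd Outcome phenotype SD (years of residual age at onset).
#' @param r2_target Total exposure variance explained by all variants.
#' @param eaf_shape1,eaf_shape2 Beta-distribution parameters for effect
#'   allele frequencies (truncated to `eaf_range`).
#' @param eaf_range Allowed EAF range.
#' @param palindromic_fraction Fraction of variants given A/T or C/G allele
#'   pairs.
#' @param strand_scramble_fraction Fraction of outcome records re-encoded on
#'   the opposite strand (non-palindromic variants only).
#' @param swap_fraction Fraction of outcome records stored with the allele
#'   order swapped (beta negated, EAF complemented) — an equivalent coding
#'   the harmonizer must undo.
#' @param ld_blocks List: `n_blocks`, `block_size`, `within_r2` — variants
#'   are laid out in LD blocks; within-block pairwise r2 equals `within_r2`,
#'   blocks are independent and separated by more than the clumping window.
#' @param block_span_bp Physical span of one block in bp.
#' @param outlier_shift Displacement of planted outliers, in multiples of
#'   the outcome standard error.
#' @param gene_regions Optional named list (per drug class) of lists with
#'   `gene`, `n_snps`, `within_r2` describing cis regions to plant (used by
#'   the drug-target scenarios); `NULL` for none.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_snps = 450,
                            n_exposure = 757601,
                            n_outcome = 9064,
                            trait_sd = 21.5,
                            outcome_sd = 0.5,
                            r2_target = 0.016,
                            eaf_shape1 = 2, eaf_shape2 = 2,
                            eaf_range = c(0.05, 0.95),
                            palindromic_fraction = 0.16,
                            strand_scramble_fraction = 0.10,
                            swap_fraction = 0.30,
                            ld_blocks = list(n_blocks = NULL, block_size = 1,
                                             within_r2 = 0.5),
                            block_span_bp = 50000,
                            outlier_shift = 10,
                            gene_regions = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_snps >= 1,
            trait_sd > 0, outcome_sd > 0,
            r2_target > 0, r2_target < 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            strand_scramble_fraction >= 0, strand_scramble_fraction <= 1,
            swap_fraction >= 0, swap_fraction <= 1)
  structure(cfg, class = "scenario_config")
}

#' Ground truth for a synthetic scenario
#'
#' @param beta_causal True causal effect in outcome units per exposure unit
#'   (years per mmHg).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects with mean
#'   zero) or `"directional"` (positive-mean direct effects).
#' @param pleiotropy_sd SD of the per-SNP direct (pleiotropic) effects.
#' @param pleiotropy_mean Mean direct effect under `"directional"`.
#' @param invalid_fraction Share of the total instrument weight carried by
#'   invalid (pleiotropic) variants; 0 <= value < 1.
#' @param n_outliers Number of planted gross outliers.
#' @param seed Integer seed; the same truth + config + seed reproduces the
#'   data bit-identically.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(beta_causal = 0.0041,
                            pleiotropy_mode = c("none", "balanced", "directional"),
                            pleiotropy_sd = 0,
                            pleiotropy_mean = 0,
                            invalid_fraction = 0,
                            n_outliers = 0,
                            seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (invalid_fraction < 0 || invalid_fraction >= 1) {
    stop("synthetic_truth: invalid_fraction must lie in [0, 1)")
  }
  if (invalid_fraction > 0 && pleiotropy_mode == "none") {
    stop("synthetic_truth: invalid_fraction > 0 requires a pleiotropy mode")
  }
  structure(list(beta_causal = beta_causal,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 invalid_fraction = invalid_fraction,
                 n_outliers = n_outliers,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Non-palindromic allele pairs (ordered): everything except {A,T} and {C,G}.
nonpal_pairs <- function() {
  all <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
  all <- all[all$a != all$b, ]
  all[!is_palindromic(all$a, all$b), ]
}

#' Generate a synthetic two-sample GWAS dataset with known truth
#'
#' Generative model per variant i: a true exposure effect gamma_i (normal,
#' rescaled so the variants jointly explain `r2_target` of the exposure
#' variance); observed exposure effect beta_exp_i ~ N(gamma_i, se_exp_i);
#' observed outcome effect beta_out_i ~ N(beta_causal * gamma_i + alpha_i,
#' se_out_i) where alpha_i is the per-SNP direct (pleiotropic) effect —
#' zero for valid instruments, drawn per `pleiotropy_mode` for the invalid
#' set, whose membership is chosen so it carries ~`invalid_fraction` of the
#' total instrument weight. Planted outliers are displaced by
#' `outlier_shift` outcome standard errors. The outcome copy is re-encoded
#' (allele swaps, strand scrambling, palindromic ambiguity) so harmonization
#' is exercised, and an LD reference consistent with the block layout is
#' emitted.
#'
#' @param config A [scenario_config].
#' @param truth A [synthetic_truth].
#' @return List with `exposure` and `outcome` ([summary_stats]), `ld`
#'   ([ld_reference]), `regions` (drug-target regions, or `NULL`), and
#'   `truth` — the input truth echoed back with the realised `gamma`,
#'   `alpha`, `invalid_idx`, `outlier_idx` and the bookkeeping count
#'   `n_palindromic_intermediate` (palindromic variants whose EAF falls in
#'   the harmonizer's intermediate window on either side).
#' @export
generate_two_sample <- function(config = scenario_config(),
                                truth = synthetic_truth()) {
  stopifnot(inherits(config, "scenario_config"), inherits(truth, "synthetic_truth"))
  with_seed(truth$seed, generate_two_sample_impl(config, truth))
}

generate_two_sample_impl <- function(config, truth) {
  n <- config$n_snps
  blocks <- config$ld_blocks
  block_size <- max(1L, as.integer(blocks$block_size %||% 1L))

  # --- layout: blocks of variants, far enough apart to be clump-independent
  gene_spec <- config$gene_regions
  n_gene <- if (!is.null(gene_spec)) sum(vapply(gene_spec, `[[`, 0, "n_snps")) else 0L
  n_bg <- n - n_gene
  if (n_bg < 0) stop("generate_two_sample: gene regions demand more SNPs than n_snps")
  block_id <- if (n_bg > 0) rep(seq_len(ceiling(n_bg / block_size)),
                                each = block_size)[seq_len(n_bg)] else integer(0)
  n_blocks <- if (n_bg > 0) max(block_id) else 0L
  # 22 autosomes; blocks spaced 25 Mb apart (beyond the 10 Mb clump window)
  chrom_bg <- as.character(((seq_len(n_blocks) - 1L) %% 22L) + 1L)[block_id]
  block_start <- (((seq_len(n_blocks) - 1L) %/% 22L) * 25e6 + 1e6)[block_id]
  within <- stats::ave(seq_along(block_id), block_id, FUN = seq_along)
  pos_bg <- block_start + (within - 1L) *
    max(1L, config$block_span_bp %/% max(1L, block_size))

  chrom <- chrom_bg
  pos <- pos_bg
  region_rows <- NULL
  region_of <- rep(NA_character_, n_bg)
  if (n_gene > 0) {
    # illustrative target genes per drug class, one region per class
    gene_chrom <- c(ACEI = "17", BB = "10", CCB = "12")
    gstart <- 61e6
    for (cls in names(gene_spec)) {
      spec <- gene_spec[[cls]]
      m <- spec$n_snps
      gchrom <- gene_chrom[[cls]] %||% "20"
      gpos <- gstart + seq_len(m) * 2000
      chrom <- c(chrom, rep(gchrom, m))
      pos <- c(pos, gpos)
      region_of <- c(region_of, rep(cls, m))
      region_rows <- rbind(region_rows, data.frame(
        chrom = gchrom, start = gstart, end = gstart + (m + 1) * 2000,
        gene = spec$gene %||% cls, drug_class = cls, type = "gene",
        stringsAsFactors = FALSE))
    }
  }
  ord <- order(as.numeric(chrom), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; region_of <- region_of[ord]
  snp <- sprintf("rs%06d", seq_len(n))

  # --- frequencies and standard errors
  eaf <- stats::rbeta(n, config$eaf_shape1, config$eaf_shape2)
  eaf <- pmin(pmax(eaf, config$eaf_range[1]), config$eaf_range[2])
  se_exp <- config$trait_sd / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
  se_out <- config$outcome_sd / sqrt(2 * eaf * (1 - eaf) * config$n_outcome)

  # --- true exposure effects scaled to the target variance explained
  g <- stats::rnorm(n)
  scale <- config$trait_sd *
    sqrt(config$r2_target / sum(2 * eaf * (1 - eaf) * g^2))
  gamma <- g * scale
  if (!is.null(gene_spec)) {
    # target-gene proxies are preselected strong signals; scale them up so
    # essentially all pass the genome-wide significance filter
    for (cls in names(gene_spec)) {
      idx <- !is.na(region_of) & region_of == cls
      gamma[idx] <- gamma[idx] * (gene_spec[[cls]]$gamma_scale %||% 3)
    }
  }

  # --- pleiotropy: invalid set chosen to carry ~invalid_fraction of weight
  alpha <- rep(0, n)
  invalid_idx <- integer(0)
  if (truth$invalid_fraction > 0) {
    wgt <- gamma^2 / se_out^2
    ord_w <- sample.int(n)  # random order, accumulate weight share
    cum <- cumsum(wgt[ord_w]) / sum(wgt)
    invalid_idx <- sort(ord_w[seq_len(max(1, which(cum >= truth$invalid_fraction)[1]))])
  } else if (truth$pleiotropy_mode != "none") {
    invalid_idx <- seq_len(n)
  }
  if (truth$pleiotropy_mode == "balanced") {
    alpha[invalid_idx] <- stats::rnorm(length(invalid_idx), 0, truth$pleiotropy_sd)
  } else if (truth$pleiotropy_mode == "directional") {
    alpha[invalid_idx] <- stats::rnorm(length(invalid_idx),
                                       truth$pleiotropy_mean, truth$pleiotropy_sd)
  }

  # --- observed effects; drug-class regions may carry their own causal slope
  beta_c <- rep(truth$beta_causal, n)
  if (!is.null(gene_spec)) {
    for (cls in names(gene_spec)) {
      if (!is.null(gene_spec[[cls]]$beta_causal)) {
        beta_c[!is.na(region_of) & region_of == cls] <- gene_spec[[cls]]$beta_causal
      }
    }
  }
  beta_exp <- stats::rnorm(n, gamma, se_exp)
  mu_out <- beta_c * gamma + alpha
  beta_out <- stats::rnorm(n, mu_out, se_out)
  outlier_idx <- integer(0)
  if (truth$n_outliers > 0) {
    outlier_idx <- sort(sample.int(n, truth$n_outliers))
    beta_out[outlier_idx] <- beta_out[outlier_idx] +
      config$outlier_shift * se_out[outlier_idx]
  }
  pval_exp <- 2 * stats::pnorm(-abs(beta_exp / se_exp))
  pval_out <- 2 * stats::pnorm(-abs(beta_out / se_out))
  pval_exp <- pmax(pval_exp, .Machine$double.xmin)
  pval_out <- pmax(pval_out, .Machine$double.xmin)

  # --- alleles: palindromic fraction, the rest non-palindromic
  np <- nonpal_pairs()
  pal <- stats::runif(n) < config$palindromic_fraction
  a1 <- a2 <- character(n)
  pal_kind <- sample(c("AT", "CG"), n, replace = TRUE)
  a1[pal] <- ifelse(pal_kind[pal] == "AT", "A", "C")
  a2[pal] <- ifelse(pal_kind[pal] == "AT", "T", "G")
  pick <- sample.int(nrow(np), n, replace = TRUE)
  a1[!pal] <- np$a[pick[!pal]]
  a2[!pal] <- np$b[pick[!pal]]

  exposure <- summary_stats(
    data.frame(snp = snp, chrom = chrom, pos = pos,
               effect_allele = a1, other_allele = a2,
               eaf = eaf, beta = beta_exp, se = se_exp, pval = pval_exp,
               stringsAsFactors = FALSE),
    trait_label = "exposure", trait_sd = config$trait_sd)

  # --- outcome copy: perturbed EAF, scrambled encodings
  eaf_out <- pmin(pmax(eaf + stats::rnorm(n, 0, 0.01), 0.01), 0.99)
  o1 <- a1; o2 <- a2
  b_out_enc <- beta_out
  swap <- stats::runif(n) < config$swap_fraction
  o1[swap] <- a2[swap]; o2[swap] <- a1[swap]
  b_out_enc[swap] <- -b_out_enc[swap]
  eaf_out[swap] <- 1 - eaf_out[swap]
  scram <- stats::runif(n) < config$strand_scramble_fraction & !pal
  o1[scram] <- unname(allele_complement(o1[scram]))
  o2[scram] <- unname(allele_complement(o2[scram]))

  outcome <- summary_stats(
    data.frame(snp = snp, chrom = chrom, pos = pos,
               effect_allele = o1, other_allele = o2,
               eaf = eaf_out, beta = b_out_enc, se = se_out, pval = pval_out,
               stringsAsFactors = FALSE),
    trait_label = "outcome", trait_sd = config$outcome_sd)

  # --- LD reference consistent with the block / region layout
  pairs <- list()
  # `r2` may be a scalar (constant within-block LD) or a length-2 range from
  # which per-pair values are drawn
  add_block_pairs <- function(ids, r2) {
    if (length(ids) < 2 || max(r2) <= 0) return(invisible())
    cmb <- utils::combn(ids, 2)
    vals <- if (length(r2) == 2) stats::runif(ncol(cmb), r2[1], r2[2]) else
      rep(r2, ncol(cmb))
    pairs[[length(pairs) + 1L]] <<- data.frame(
      snp_a = cmb[1, ], snp_b = cmb[2, ], r2 = vals, stringsAsFactors = FALSE)
  }
  if (block_size > 1 && n_bg > 0) {
    bg_ids <- snp[is.na(region_of)]
    # block membership recovered from the position layout (post-sort)
    bg_chrom <- chrom[is.na(region_of)]
    bg_pos <- pos[is.na(region_of)]
    grp <- paste(bg_chrom, floor(bg_pos / 25e6))
    for (gset in split(bg_ids, grp)) add_block_pairs(gset, blocks$within_r2 %||% 0.5)
  }
  if (!is.null(gene_spec)) {
    for (cls in names(gene_spec)) {
      add_block_pairs(snp[!is.na(region_of) & region_of == cls],
                      gene_spec[[cls]]$within_r2 %||% 0.3)
    }
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  ld <- ld_reference(pairs, data.frame(snp = snp, chrom = chrom, pos = pos,
                                       stringsAsFactors = FALSE))

  # bookkeeping: palindromic variants unresolvable at the default 0.08 window
  n_pal_int <- sum(pal & (abs(eaf - 0.5) < 0.08 | abs(eaf_out - 0.5) < 0.08))

  truth_echo <- truth
  truth_echo$beta_causal_per_snp <- beta_c
  truth_echo$gamma <- gamma
  truth_echo$alpha <- alpha
  truth_echo$invalid_idx <- invalid_idx
  truth_echo$outlier_idx <- outlier_idx
  truth_echo$snp <- snp
  truth_echo$region_of <- region_of
  truth_echo$n_palindromic_intermediate <- n_pal_int

  list(exposure = exposure, outcome = outcome, ld = ld,
       regions = region_rows, truth = truth_echo)
}

#' Generate two correlated exposures and one outcome for multivariable MR
#'
#' Simulates a shared variant panel with two exposures (e.g. SBP and DBP)
#' whose true per-SNP effects are bivariate normal with correlation `rho`,
#' each scaled to its own variance-explained target, and an outcome whose
#' mean is the linear combination `sum_j beta_causal[j] * gamma_ij` (no
#' pleiotropy). Alleles are shared across all three sets; the outcome copy
#' is re-encoded exactly as in [generate_two_sample()] so harmonization is
#' exercised.
#'
#' @param config A [scenario_config]; `trait_sd` may be a vector (one per
#'   exposure), as may `r2_target`.
#' @param beta_causal Named numeric vector of true direct effects, one per
#'   exposure (outcome units per exposure unit).
#' @param rho Correlation of the two exposures' true effects across SNPs.
#' @param seed Integer seed.
#' @return List with `exposures` (named list of [summary_stats]), `outcome`,
#'   `ld`, and `truth` (gammas and inputs echoed).
#' @export
generate_multi_exposure <- function(config = scenario_config(),
                                    beta_causal = c(SBP = 0.0041, DBP = 0.0138),
                                    rho = 0.5, seed = 1L) {
  k <- length(beta_causal)
  stopifnot(k == 2, abs(rho) < 1)
  labels <- names(beta_causal) %||% paste0("exposure", seq_len(k))
  trait_sd <- rep_len(config$trait_sd, k)
  r2_target <- rep_len(config$r2_target, k)
  with_seed(seed, {
    n <- config$n_snps
    chrom <- as.character(((seq_len(n) - 1L) %% 22L) + 1L)
    pos <- (((seq_len(n) - 1L) %/% 22L) * 25e6) + 1e6
    snp <- sprintf("rs%06d", seq_len(n))
    eaf <- pmin(pmax(stats::rbeta(n, config$eaf_shape1, config$eaf_shape2),
                     config$eaf_range[1]), config$eaf_range[2])
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    gam <- cbind(z1, z2)
    for (j in 1:2) {
      gam[, j] <- gam[, j] * trait_sd[j] *
        sqrt(r2_target[j] / sum(2 * eaf * (1 - eaf) * gam[, j]^2))
    }
    se_out <- config$outcome_sd / sqrt(2 * eaf * (1 - eaf) * config$n_outcome)
    mu_out <- drop(gam %*% beta_causal)
    beta_out <- stats::rnorm(n, mu_out, se_out)

    np <- nonpal_pairs()
    pal <- stats::runif(n) < config$palindromic_fraction
    pal_kind <- sample(c("AT", "CG"), n, replace = TRUE)
    a1 <- a2 <- character(n)
    a1[pal] <- ifelse(pal_kind[pal] == "AT", "A", "C")
    a2[pal] <- ifelse(pal_kind[pal] == "AT", "T", "G")
    pick <- sample.int(nrow(np), n, replace = TRUE)
    a1[!pal] <- np$a[pick[!pal]]
    a2[!pal] <- np$b[pick[!pal]]

    exposures <- list()
    for (j in 1:2) {
      se_j <- trait_sd[j] / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
      b_j <- stats::rnorm(n, gam[, j], se_j)
      p_j <- pmax(2 * stats::pnorm(-abs(b_j / se_j)), .Machine$double.xmin)
      exposures[[labels[j]]] <- summary_stats(
        data.frame(snp = snp, chrom = chrom, pos = pos,
                   effect_allele = a1, other_allele = a2,
                   eaf = eaf, beta = b_j, se = se_j, pval = p_j,
                   stringsAsFactors = FALSE),
        trait_label = labels[j], trait_sd = trait_sd[j])
    }

    eaf_out <- pmin(pmax(eaf + stats::rnorm(n, 0, 0.01), 0.01), 0.99)
    o1 <- a1; o2 <- a2
    b_enc <- beta_out
    swap <- stats::runif(n) < config$swap_fraction
    o1[swap] <- a2[swap]; o2[swap] <- a1[swap]
    b_enc[swap] <- -b_enc[swap]
    eaf_out[swap] <- 1 - eaf_out[swap]
    scram <- stats::runif(n) < config$strand_scramble_fraction & !pal
    o1[scram] <- unname(allele_complement(o1[scram]))
    o2[scram] <- unname(allele_complement(o2[scram]))
    p_out <- pmax(2 * stats::pnorm(-abs(beta_out / se_out)), .Machine$double.xmin)
    outcome <- summary_stats(
      data.frame(snp = snp, chrom = chrom, pos = pos,
                 effect_allele = o1, other_allele = o2,
                 eaf = eaf_out, beta = b_enc, se = se_out, pval = p_out,
                 stringsAsFactors = FALSE),
      trait_label = "outcome", trait_sd = config$outcome_sd)

    ld <- ld_reference(data.frame(snp_a = character(), snp_b = character(),
                                  r2 = numeric()),
                       data.frame(snp = snp, chrom = chrom, pos = pos,
                                  stringsAsFactors = FALSE))
    list(exposures = exposures, outcome = outcome, ld = ld,
         truth = list(beta_causal = beta_causal, rho = rho, gamma = gam,
                      snp = snp, seed = seed))
  })
}

#' Generate a confounder lookup table with planted hits
#'
#' Designated SNPs receive a genome-wide significant association with a
#' named confounder trait; all other listed SNPs sit far above the
#' screening threshold.
#'
#' @param snps All SNP ids.
#' @param confounded Character vector of SNP ids to plant as confounded.
#' @param traits Confounder trait names to cycle through.
#' @param p_hit P-value assigned to planted hits (default 1e-9).
#' @param seed Integer seed for the null p-values.
#' @return Data frame (`snp`, `trait`, `pval`) usable by
#'   [screen_confounders()].
#' @export
generate_confounder_table <- function(snps, confounded = character(0),
                                      traits = c("coffee consumption",
                                                 "lifetime smoking index",
                                                 "telomere length"),
                                      p_hit = 1e-9, seed = 1L) {
  stopifnot(all(confounded %in% snps))
  with_seed(seed, {
    tab <- data.frame(snp = snps,
                      trait = rep(traits, length.out = length(snps)),
                      pval = stats::runif(length(snps), 0.05, 1),
                      stringsAsFactors = FALSE)
    tab$pval[tab$snp %in% confounded] <- p_hit
    tab
  })
}

#' Write a synthetic scenario to disk in the formats the readers consume
#'
#' @param sim Output of [generate_two_sample()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_stats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_reference(sim$ld, file.path(dir, "ld_pairs.tsv"),
                     file.path(dir, "ld_variants.tsv"))
  if (!is.null(sim$regions)) {
    write_gene_regions(sim$regions, file.path(dir, "regions.bed"))
  }
  invisible(dir)
}
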