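# Shared fixtures and independent oracles used across the test files.
# Everything is built in code; no binary fixtures.

# A small well-formed summary-stat data frame.
make_stats_df <- function(n = 5, chrom = "1", pos = NULL, pval = NULL,
                          beta = NULL, eaf = NULL, snp = NULL) {
  data.frame(
    snp = snp %||% sprintf("rs%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    pos = pos %||% seq(1e6, by = 1e5, length.out = n),
    effect_allele = rep_len(c("A", "C", "G", "T", "A"), n),
    other_allele = rep_len(c("G", "T", "A", "C", "C"), n),
    eaf = eaf %||% rep_len(c(0.2, 0.3, 0.4, 0.25, 0.35), n),
    beta = beta %||% rep_len(c(0.10, -0.08, 0.12, 0.09, -0.11), n),
    se = rep_len(0.02, n),
    pval = pval %||% rep_len(1e-10, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_stats <- function(...) mrpipe::summary_stats(make_stats_df(...),
                                                  trait_label = "SBP",
                                                  trait_sd = 21.5)

# LD reference where every within-fixture pair is explicitly known.
make_ld <- function(stats, pairs = NULL) {
  pairs <- pairs %||% data.frame(snp_a = character(), snp_b = character(),
                                 r2 = numeric())
  mrpipe::ld_reference(pairs, data.frame(snp = stats$snp, chrom = stats$chrom,
                                         pos = stats$pos))
}

# Independent brute-force clumping oracle: literal restatement of the greedy
# rule using repeated scans over an explicit candidate set, with no shared
# code with the implementation.
oracle_clump <- function(df, r2_lookup, window_kb = 10000, r2_max = 0.001,
                         use_window = TRUE) {
  remaining <- df[order(df$pval, df$chrom, df$pos, df$snp), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    index <- remaining[1, ]
    kept <- c(kept, index$snp)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (j in seq_len(nrow(remaining))) {
      in_window <- !use_window ||
        (remaining$chrom[j] == index$chrom &&
           abs(remaining$pos[j] - index$pos) <= window_kb * 1000)
      if (in_window && r2_lookup(index$snp, remaining$snp[j]) >= r2_max) {
        drop[j] <- TRUE
      }
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}

# r2 lookup closure from a pairs data frame (symmetric; absent pair -> 0).
lookup_from_pairs <- function(pairs) {
  function(a, b) {
    hit <- (pairs$snp_a == a & pairs$snp_b == b) |
      (pairs$snp_a == b & pairs$snp_b == a)
    if (any(hit)) pairs$r2[which(hit)[1]] else 0
  }
}

# Closed-form fixed-effect IVW oracle: beta = sum(w x y) / sum(w x^2),
# w = 1/se_out^2, se = sqrt(1/sum(w x^2)).
oracle_ivw <- function(x, y, se_out) {
  w <- 1 / se_out^2
  b <- sum(w * x * y) / sum(w * x^2)
  list(beta = b, se = sqrt(1 / sum(w * x^2)),
       q = sum(w * (y - b * x)^2))
}

# A harmonization-ready instrument table (already aligned).
make_instruments <- function(n = 10, beta_causal = 0.2, se_out = 0.05,
                             seed = 1, pleiotropy = rep(0, n)) {
  set.seed(seed)
  x <- stats::runif(n, 0.5, 1.5)
  se_exp <- rep(0.01, n)
  data.frame(
    snp = sprintf("rs%03d", seq_len(n)),
    beta_exp = x,
    se_exp = se_exp,
    beta_out = beta_causal * x + pleiotropy,
    se_out = rep_len(se_out, n),
    stringsAsFactors = FALSE
  )
}

# Equivalent re-encoding of an association on the opposite strand with the
# allele order swapped: complement both alleles, negate beta, complement EAF.
flip_encoding <- function(stats) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- as.data.frame(stats)
  e <- out$effect_allele
  out$effect_allele <- unname(comp[out$other_allele])
  out$other_allele <- unname(comp[e])
  out$beta <- -out$beta
  out$eaf <- 1 - out$eaf
  mrpipe::summary_stats(out, trait_label = attr(stats, "trait_label"),
                        trait_sd = attr(stats, "trait_sd"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
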