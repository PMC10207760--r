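outcome_from <- function(exposure, beta_out = NULL, eaf = NULL) {
  df <- as.data.frame(exposure)
  df$beta <- beta_out %||% (0.2 * df$beta)
  df$se <- 0.05
  df$eaf <- eaf %||% df$eaf
  summary_stats(df, trait_label = "outcome", trait_sd = 1)
}

test_that("palindromy detection covers all pairs", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
})

test_that("swapped outcome alleles flip beta and complement eaf", {
  ex <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                 effect_allele = "A", other_allele = "G",
                                 eaf = 0.3, beta = 0.10, se = 0.02, pval = 1e-9))
  ou <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                 effect_allele = "G", other_allele = "A",
                                 eaf = 0.7, beta = 0.05, se = 0.01, pval = 0.1))
  h <- harmonize(ex, ou)
  expect_equal(h$beta_out, -0.05)
  expect_equal(h$eaf_out, 0.3)
  expect_true(h$flipped)
})

test_that("strand-complement encodings are relabelled for non-palindromic SNPs", {
  ex <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                 effect_allele = "A", other_allele = "G",
                                 eaf = 0.3, beta = 0.10, se = 0.02, pval = 1e-9))
  # same variant reported on the other strand: T/C
  ou <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                 effect_allele = "T", other_allele = "C",
                                 eaf = 0.3, beta = 0.05, se = 0.01, pval = 0.1))
  h <- harmonize(ex, ou)
  expect_equal(h$beta_out, 0.05)
  expect_false(h$flipped)
  # other strand AND swapped: C/T with complemented frequency
  ou2 <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                  effect_allele = "C", other_allele = "T",
                                  eaf = 0.7, beta = 0.05, se = 0.01, pval = 0.1))
  h2 <- harmonize(ex, ou2)
  expect_equal(h2$beta_out, -0.05)
  expect_equal(h2$eaf_out, 0.3)
})

test_that("palindromic SNPs with intermediate frequency are dropped and counted", {
  ex <- summary_stats(data.frame(snp = c("rs1", "rs2"), chrom = "1",
                                 pos = c(100, 200),
                                 effect_allele = c("A", "A"),
                                 other_allele = c("T", "G"),
                                 eaf = c(0.50, 0.30), beta = 0.1, se = 0.02,
                                 pval = 1e-9))
  ou <- outcome_from(ex)
  h <- harmonize(ex, ou)
  expect_equal(h$snp, "rs2")
  expect_equal(attr(h, "dropped_palindromic"), 1L)
  # intermediate on the OUTCOME side only also drops
  ex2 <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                  effect_allele = "A", other_allele = "T",
                                  eaf = 0.10, beta = 0.1, se = 0.02, pval = 1e-9))
  ou2 <- outcome_from(ex2, eaf = 0.49)
  expect_equal(nrow(harmonize(ex2, ou2)), 0)
})

test_that("resolvable palindromic SNPs align by matching minor alleles", {
  ex <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                 effect_allele = "A", other_allele = "T",
                                 eaf = 0.10, beta = 0.1, se = 0.02, pval = 1e-9))
  # outcome stores the same allele as effect with a matching frequency:
  # enumeration oracle picks the as-is alignment (|0.10-0.12| < |0.10-0.88|)
  ou_as_is <- outcome_from(ex, beta_out = 0.03, eaf = 0.12)
  h1 <- harmonize(ex, ou_as_is)
  expect_equal(h1$beta_out, 0.03)
  expect_equal(h1$eaf_out, 0.12)
  # outcome stores the opposite orientation (frequency 0.88 for the A allele):
  # the flipped alignment wins and beta is negated
  ou_flip <- outcome_from(ex, beta_out = 0.03, eaf = 0.88)
  h2 <- harmonize(ex, ou_flip)
  expect_equal(h2$beta_out, -0.03)
  expect_equal(h2$eaf_out, 0.12)
})

test_that("irreconcilable allele pairs are dropped with a reason", {
  ex <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                 effect_allele = "A", other_allele = "G",
                                 eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-9))
  ou <- summary_stats(data.frame(snp = "rs1", chrom = "1", pos = 100,
                                 effect_allele = "A", other_allele = "C",
                                 eaf = 0.3, beta = 0.05, se = 0.01, pval = 0.1))
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "dropped_irreconcilable"), 1L)
  expect_error(harmonize(ex, ou[0, ]), "no snp ids")
})

test_that("harmonization is invariant to double-flipped outcome encodings", {
  set.seed(31)
  sim <- generate_two_sample(scenario_config(n_snps = 80),
                             synthetic_truth(seed = 13))
  h1 <- harmonize(sim$exposure, sim$outcome)
  h2 <- harmonize(sim$exposure, flip_encoding(sim$outcome))
  expect_equal(h1$snp, h2$snp)
  expect_equal(h1$beta_exp, h2$beta_exp)
  expect_equal(h1$beta_out, h2$beta_out)
  expect_equal(attr(h1, "dropped_palindromic"), attr(h2, "dropped_palindromic"))
})

test_that("harmonizing an already-harmonized pair changes nothing", {
  set.seed(32)
  sim <- generate_two_sample(scenario_config(n_snps = 60),
                             synthetic_truth(seed = 14))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild an outcome set in the harmonized coding and run again
  ou2 <- summary_stats(data.frame(snp = h1$snp, chrom = h1$chrom, pos = h1$pos,
                                  effect_allele = h1$effect_allele,
                                  other_allele = h1$other_allele,
                                  eaf = h1$eaf_out, beta = h1$beta_out,
                                  se = h1$se_out, pval = 0.5),
                       trait_label = "outcome")
  ex2 <- sim$exposure[sim$exposure$snp %in% h1$snp, ]
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$snp, h1$snp)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
  expect_false(any(h2$flipped))
})

test_that("intersection counts are conserved across retained and dropped", {
  set.seed(33)
  for (s in 1:5) {
    sim <- generate_two_sample(
      scenario_config(n_snps = 50, palindromic_fraction = 0.4),
      synthetic_truth(seed = s))
    h <- harmonize(sim$exposure, sim$outcome)
    expect_equal(attr(h, "n_intersection"),
                 nrow(h) + attr(h, "dropped_palindromic") +
                   attr(h, "dropped_irreconcilable"))
  }
})
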