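test_that("genome-wide filter is strict at the boundary", {
  stats <- make_stats(3, pval = c(4e-8, 5e-8, 6e-8))
  kept <- filter_genome_wide(stats)
  expect_equal(kept$pval, 4e-8)
  expect_equal(nrow(filter_genome_wide(stats[0, ])), 0)
  all_in <- make_stats(3, pval = rep(1e-10, 3))
  expect_equal(nrow(filter_genome_wide(all_in)), 3)
})

test_that("clumping keeps the smaller p-value of a correlated nearby pair", {
  stats <- make_stats(2, pos = c(1e6, 1e6 + 5000), pval = c(1e-9, 1e-10))
  ld <- make_ld(stats, data.frame(snp_a = "rs001", snp_b = "rs002", r2 = 0.5))
  kept <- clump(stats, ld)
  expect_equal(kept$snp, "rs002")  # the p = 1e-10 variant
  one <- make_stats(1)
  expect_equal(clump(one, make_ld(one))$snp, one$snp)
})

test_that("clumping matches the brute-force oracle on a 6-variant chain", {
  pos <- c(1e6, 1.5e6, 2e6, 2.5e6, 20e6, 20.4e6)
  stats <- make_stats(6, pos = pos,
                      pval = c(1e-12, 1e-9, 1e-11, 1e-8, 1e-10, 1e-13))
  pairs <- data.frame(
    snp_a = c("rs001", "rs001", "rs002", "rs003", "rs005"),
    snp_b = c("rs002", "rs003", "rs003", "rs004", "rs006"),
    r2    = c(0.80,    0.0005,  0.30,    0.95,    0.02))
  ld <- make_ld(stats, pairs)
  kept <- clump(stats, ld, window_kb = 1000, r2_max = 0.001)
  expect_equal(sort(kept$snp),
               oracle_clump(as.data.frame(stats), lookup_from_pairs(pairs),
                            window_kb = 1000, r2_max = 0.001))
})

test_that("clumped output obeys the pairwise r2 bound on random instances", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 8
    stats <- make_stats(n, pos = sort(round(runif(n, 1e6, 6e6))),
                        pval = runif(n, 1e-12, 1e-6))
    cmb <- combn(stats$snp, 2)
    pairs <- data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                        r2 = round(runif(ncol(cmb)), 3))
    ld <- make_ld(stats, pairs)
    kept <- clump(stats, ld, window_kb = 10000, r2_max = 0.3)
    expect_equal(sort(kept$snp),
                 oracle_clump(as.data.frame(stats), lookup_from_pairs(pairs),
                              window_kb = 10000, r2_max = 0.3))
    # direct pairwise verification of the post-condition
    if (nrow(kept) > 1) {
      km <- combn(kept$snp, 2)
      lk <- lookup_from_pairs(pairs)
      for (j in seq_len(ncol(km))) {
        expect_lt(lk(km[1, j], km[2, j]), 0.3)
      }
    }
  }
})

test_that("a within-window pair with unknowable LD is discarded, not kept", {
  stats <- make_stats(2, pos = c(1e6, 1.1e6), pval = c(1e-10, 1e-9))
  # panel knows nothing about rs002
  ld <- ld_reference(data.frame(snp_a = character(), snp_b = character(),
                                r2 = numeric()),
                     data.frame(snp = "rs001", chrom = "1", pos = 1e6))
  kept <- suppressMessages(clump(stats, ld))
  expect_equal(kept$snp, "rs001")
})

test_that("F statistic and variance explained follow their formulas exactly", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.05), 0)
  expect_equal(f_statistic(-0.3, 0.1), 9)
  expect_error(f_statistic(0.1, 0), "se")

  expect_equal(variance_explained(0.5, 0.5, 1), 0.125)
  expect_lt(variance_explained(0.5, 1e-9, 1), 1e-8)  # vanishes as eaf -> 0
  expect_error(variance_explained(0.5, 0, 1), "eaf")
  expect_error(variance_explained(0.5, 0.5, 0), "trait_sd")

  # agreement with independent re-computation to 12 significant digits
  set.seed(4)
  beta <- rnorm(50); se <- runif(50, 0.01, 0.1); eaf <- runif(50, 0.05, 0.95)
  expect_equal(f_statistic(beta, se), (beta / se)^2, tolerance = 1e-12)
  expect_equal(variance_explained(beta, eaf, 21.5),
               2 * beta^2 * eaf * (1 - eaf) / 21.5^2, tolerance = 1e-12)
})

test_that("the F >= 10 boundary is kept, F < 10 removed", {
  stats <- make_stats(3)
  stats$beta <- c(0.0632455532, 0.0633, -0.3)   # F just under 10, just over, 225
  stats$se <- c(0.02, 0.02, 0.02)
  f <- f_statistic(stats$beta, stats$se)
  expect_lt(f[1], 10); expect_gt(f[2], 10)
  kept <- filter_weak(stats, 10)
  expect_equal(kept$snp, c("rs002", "rs003"))
  exact <- make_stats(1, beta = 10 * 0.02 / sqrt(10))  # F = 10 exactly... beta^2/se^2
  exact$beta <- sqrt(10) * exact$se
  expect_equal(nrow(filter_weak(exact, 10)), 1)        # removal is strict <
})

test_that("confounder screening removes hits below the threshold only", {
  stats <- make_stats(3)
  tab <- data.frame(snp = c("rs001", "rs002"),
                    trait = c("coffee consumption", "telomere length"),
                    pval = c(1e-9, 1e-6))
  kept <- suppressMessages(screen_confounders(stats, tab))
  expect_equal(kept$snp, c("rs002", "rs003"))
  expect_equal(attr(kept, "confounder_removed")$trait, "coffee consumption")
  expect_equal(nrow(screen_confounders(stats, NULL)), 3)
  empty <- data.frame(snp = character(), trait = character(), pval = numeric())
  expect_equal(nrow(screen_confounders(stats, empty)), 3)
})

test_that("the selection pipeline reports monotone stage counts and reasons", {
  set.seed(2)
  sim <- generate_two_sample(scenario_config(n_snps = 120),
                             synthetic_truth(seed = 5))
  conf <- generate_confounder_table(sim$exposure$snp,
                                    confounded = sim$exposure$snp[1:3])
  sel <- suppressMessages(select_instruments(sim$exposure, sim$ld, conf))
  cnt <- sel$report$counts
  expect_equal(unname(cnt["input"]), 120)
  expect_true(all(diff(cnt) <= 0))
  expect_true(all(sel$report$exclusions$reason %in%
                    c("NOT_GWS", "CLUMPED", "CONFOUNDER", "WEAK_F")))
  # exclusions + retained account for every input variant
  expect_equal(nrow(sel$instruments) + nrow(sel$report$exclusions), 120)
  # selected instruments all genome-wide significant and strong
  expect_true(all(sel$instruments$pval < 5e-8))
  expect_true(all(sel$instruments$f_stat >= 10))
})
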