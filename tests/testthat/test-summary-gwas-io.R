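test_that("a well-formed TSV loads identically and round-trips", {
  df <- make_stats_df(3)
  path <- write_tsv(df, withr::local_tempfile(fileext = ".tsv"))
  got <- read_summary_stats(path, trait_label = "SBP", trait_sd = 21.5)
  expect_s3_class(got, "summary_stats")
  expect_equal(nrow(got), 3)
  expect_equal(got$snp, df$snp)
  expect_equal(got$beta, df$beta)
  expect_equal(attr(got, "trait_sd"), 21.5)

  # full-precision round trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(got, out)
  again <- read_summary_stats(out, trait_label = "SBP", trait_sd = 21.5)
  expect_identical(as.data.frame(again), as.data.frame(got))
})

test_that("duplicate snp ids keep the smallest p-value", {
  df <- make_stats_df(3)
  dup <- df[1, ]
  dup$pval <- 1e-8
  df$pval[1] <- 1e-9
  path <- write_tsv(rbind(df, dup), withr::local_tempfile(fileext = ".tsv"))
  got <- suppressMessages(read_summary_stats(path))
  expect_equal(nrow(got), 3)
  expect_equal(got$pval[got$snp == df$snp[1]], 1e-9)
  expect_equal(attr(got, "duplicates_removed"), 1L)
})

test_that("invalid rows are rejected with their file line number and counted", {
  df <- make_stats_df(4)
  df$eaf[2] <- 1.2
  df$se[4] <- -1
  path <- write_tsv(df, withr::local_tempfile(fileext = ".tsv"))
  got <- suppressMessages(read_summary_stats(path))
  expect_equal(nrow(got), 2)
  rej <- attr(got, "rejects")
  expect_equal(sort(rej$line), c(3L, 5L))  # header is line 1
  expect_match(rej$reason[rej$line == 3L], "eaf")
  # nothing dropped silently: input = loaded + rejected
  expect_equal(attr(got, "n_input"), nrow(got) + nrow(rej))
})

test_that("a missing required column is fatal and names the column", {
  df <- make_stats_df(2)
  df$se <- NULL
  path <- write_tsv(df, withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_summary_stats(path), "se")
})

test_that("a dialect maps arbitrary column names, from a YAML file too", {
  df <- make_stats_df(3)
  names(df) <- c("rsid", "CHR", "BP", "A1", "A2", "FREQ", "BETA", "SE", "P")
  path <- write_tsv(df, withr::local_tempfile(fileext = ".tsv"))
  dialect <- c(snp = "rsid", chrom = "CHR", pos = "BP", effect_allele = "A1",
               other_allele = "A2", eaf = "FREQ", beta = "BETA", se = "SE",
               pval = "P")
  got <- read_summary_stats(path, dialect)
  expect_equal(got$snp, make_stats_df(3)$snp)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(as.list(dialect), ypath)
  got2 <- read_summary_stats(path, ypath)
  expect_identical(as.data.frame(got2), as.data.frame(got))
})

test_that("multi-base (indel) alleles are rejected", {
  df <- make_stats_df(2)
  df$effect_allele[1] <- "AT"
  path <- write_tsv(df, withr::local_tempfile(fileext = ".tsv"))
  got <- suppressMessages(read_summary_stats(path))
  expect_equal(nrow(got), 1)
  expect_match(attr(got, "rejects")$reason, "allele")
})

test_that("LD lookups are symmetric, self-r2 is 1, covered absent pairs are 0", {
  pairs <- data.frame(snp_a = "a", snp_b = "b", r2 = 0.5)
  vars <- data.frame(snp = c("a", "b", "c"), chrom = "1",
                     pos = c(1e6, 2e6, 50e6))
  ld <- ld_reference(pairs, vars)
  expect_equal(ld_r2(ld, "a", "b"), 0.5)
  expect_equal(ld_r2(ld, "b", "a"), 0.5)
  expect_equal(ld_r2(ld, "a", "a"), 1)
  expect_equal(ld_r2(ld, "a", "c"), 0)       # distant pair absent -> 0
  expect_true(is.na(ld_r2(ld, "a", "zzz")))  # variant unknown to the panel

  # round trip through the long-format files
  pp <- withr::local_tempfile(fileext = ".tsv")
  vp <- withr::local_tempfile(fileext = ".tsv")
  write_ld_reference(ld, pp, vp)
  ld2 <- read_ld_reference(pp, vp)
  expect_equal(ld_r2(ld2, "b", "a"), 0.5)
})

test_that("out-of-range r2 is fatal", {
  expect_error(ld_reference(data.frame(snp_a = "a", snp_b = "b", r2 = 1.2),
                            data.frame(snp = c("a", "b"), chrom = "1",
                                       pos = c(1, 2))),
               "r2")
})

test_that("BED gene regions convert to 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr12\t1999\t3000\tCACNA1C\tCCB",
               "chr17\t500\t900\tACE\tACEI\tregulatory"), path)
  reg <- read_gene_regions(path)
  expect_equal(reg$start, c(2000L, 501L))
  expect_equal(reg$end, c(3000L, 900L))
  expect_equal(reg$type, c("gene", "regulatory"))

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_gene_regions(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1\t10\tGENE\tXYZ", bad)
  expect_error(read_gene_regions(bad), "XYZ.*line 1")
})

test_that("the shipped example region fixture loads and covers all classes", {
  bed <- system.file("extdata", "drug_target_regions_example.bed",
                     package = "mrpipe")
  reg <- read_gene_regions(bed)
  expect_setequal(unique(reg$drug_class), c("ACEI", "BB", "CCB"))
  expect_true(all(reg$start <= reg$end))
  expect_true("CACNA1C" %in% reg$gene)
})

test_that("confounder tables validate p-values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(snp = "rs1", trait = "coffee consumption", pval = 1e-9),
            path)
  tab <- read_confounder_table(path)
  expect_equal(tab$pval, 1e-9)
  write_tsv(data.frame(snp = "rs1", trait = "x", pval = 0), path)
  expect_error(read_confounder_table(path), "p-values")
})
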