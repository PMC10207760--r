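#' GWAS summary-statistic sets
#'
#' A `summary_stats` object is a data frame of per-variant associations with
#' one trait, one row per SNP, with columns `snp`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`. The trait
#' label and the phenotype standard deviation (needed for the variance
#' explained by an instrument, R^2 = 2 beta^2 EAF (1-EAF) / SD^2) travel as
#' attributes.
#'
#' @param records Data frame with the columns listed above.
#' @param trait_label Character scalar naming the trait (e.g. `"SBP"`).
#' @param trait_sd Phenotype standard deviation in trait units (e.g. 21.5
#'   mmHg for systolic blood pressure); `NA` if unknown.
#' @param validate If `TRUE` (default) every row is checked against the
#'   variant invariants and offending rows raise an error.
#' @return A data frame of class `summary_stats`.
#' @export
summary_stats <- function(records, trait_label = "trait", trait_sd = NA_real_,
                          validate = TRUE) {
  need <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("summary_stats: missing required column(s): ", paste(miss, collapse = ", "))
  }
  records <- as.data.frame(records)[, need]
  records$snp <- as.character(records$snp)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  if (validate) {
    bad <- validate_associations(records)
    if (nrow(bad) > 0) {
      stop("summary_stats: ", nrow(bad), " invalid row(s), first: row ",
           bad$row[1], " (", bad$snp[1], "): ", bad$reason[1])
    }
    if (anyDuplicated(records$snp)) {
      stop("summary_stats: duplicate snp ids: ",
           paste(unique(records$snp[duplicated(records$snp)]), collapse = ", "))
    }
  }
  if (!is.na(trait_sd) && trait_sd <= 0) stop("summary_stats: trait_sd must be > 0")
  rownames(records) <- NULL
  structure(records,
            trait_label = trait_label,
            trait_sd = trait_sd,
            class = c("summary_stats", "data.frame"))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("GWAS summary statistics: ", attr(x, "trait_label"),
      " (", nrow(x), " variants, trait SD ", attr(x, "trait_sd"), ")\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

# Subsetting keeps the class and trait attributes.
#' @export
`[.summary_stats` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "trait_label") <- attr(x, "trait_label")
    attr(out, "trait_sd") <- attr(x, "trait_sd")
    class(out) <- c("summary_stats", "data.frame")
  }
  out
}

# Row-level invariant checks; returns a data frame of rejects
# (row, snp, reason), empty when everything passes.
validate_associations <- function(df) {
  snp <- as.character(df$snp)
  reasons <- character(nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- why
  }
  single_base <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  flag(is.na(snp) | snp == "", "missing snp id")
  flag(is.na(df$chrom) | df$chrom == "", "missing chromosome")
  flag(!is.finite(df$pos) | df$pos < 1 | df$pos != round(df$pos),
       "position must be a positive integer")
  flag(!single_base(df$effect_allele),
       "effect allele not a single base in {A,C,G,T}")
  flag(!single_base(df$other_allele),
       "other allele not a single base in {A,C,G,T}")
  flag(df$effect_allele == df$other_allele, "effect and other allele identical")
  flag(!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1, "eaf outside (0,1)")
  flag(!is.finite(df$beta), "beta not finite")
  flag(!is.finite(df$se) | df$se <= 0, "se not > 0")
  flag(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0,1]")
  keep <- reasons != ""
  data.frame(row = which(keep), snp = snp[keep], reason = reasons[keep],
             stringsAsFactors = FALSE)
}

default_dialect <- function() {
  c(snp = "snp", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval")
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated file with a header row (gzip handled
#' transparently), maps its columns onto the internal schema through a
#' dialect, validates every row, and resolves duplicate SNP ids by keeping
#' the row with the smallest p-value. Rejected rows never disappear
#' silently: they are returned in the `rejects` attribute with the 1-based
#' file line number and a reason.
#'
#' @param path File path.
#' @param dialect Named character vector (or path to a YAML/JSON file
#'   containing one) mapping internal column names (`snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`) to the
#'   file's column names. `NULL` means the file already uses the internal
#'   names.
#' @param trait_label,trait_sd Trait metadata, see [summary_stats()].
#' @return A [summary_stats] object with attributes `rejects` (data frame
#'   of dropped rows with file line numbers and reasons), `n_input` (rows
#'   in the file) and `duplicates_removed`.
#' @export
read_summary_stats <- function(path, dialect = NULL,
                               trait_label = "trait", trait_sd = NA_real_) {
  if (!file.exists(path)) stop("read_summary_stats: no such file: ", path)
  dialect <- load_dialect(dialect)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  miss <- setdiff(unname(dialect), names(raw))
  if (length(miss) > 0) {
    stop("read_summary_stats: required column(s) missing from file: ",
         paste(miss, collapse = ", "))
  }
  df <- stats::setNames(raw[, unname(dialect)], names(dialect))
  df$snp <- as.character(df$snp)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  n_input <- nrow(df)
  bad <- validate_associations(df)
  bad$line <- bad$row + 1L  # header occupies line 1
  if (nrow(bad) > 0) {
    message("read_summary_stats: rejected ", nrow(bad), " invalid row(s), e.g. line ",
            bad$line[1], ": ", bad$reason[1])
    df <- df[-bad$row, , drop = FALSE]
  }
  dup_removed <- 0L
  if (anyDuplicated(df$snp)) {
    ord <- order(df$pval, seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    dup <- duplicated(df$snp)
    dup_removed <- sum(dup)
    message("read_summary_stats: ", dup_removed,
            " duplicate snp id(s) resolved by keeping the smallest p-value")
    df <- df[!dup, , drop = FALSE]
    df <- df[order(df$chrom, df$pos, df$snp), , drop = FALSE]
  }
  out <- summary_stats(df, trait_label = trait_label, trait_sd = trait_sd,
                       validate = FALSE)
  attr(out, "rejects") <- bad[, c("line", "snp", "reason")]
  attr(out, "n_input") <- n_input
  attr(out, "duplicates_removed") <- dup_removed
  out
}

load_dialect <- function(dialect) {
  if (is.null(dialect)) return(default_dialect())
  if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect)) {
    dialect <- if (grepl("\\.json$", dialect)) {
      unlist(jsonlite::read_json(dialect, simplifyVector = TRUE))
    } else {
      unlist(yaml::read_yaml(dialect))
    }
  }
  dialect <- unlist(dialect)
  full <- default_dialect()
  full[names(dialect)] <- dialect
  miss <- setdiff(names(default_dialect()), names(full))
  if (length(miss) > 0) {
    stop("dialect does not map required column(s): ", paste(miss, collapse = ", "))
  }
  full
}

#' Write GWAS summary statistics to a TSV file
#'
#' Numeric columns are written with 17 significant digits so a write/read
#' round trip reproduces every field exactly.
#'
#' @param x A [summary_stats] object.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  out <- as.data.frame(x)
  for (col in c("pos", "eaf", "beta", "se", "pval")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  out$pos <- sprintf("%d", as.integer(as.data.frame(x)$pos))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
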