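#' Pairwise LD reference
#'
#' Holds pairwise r-squared values between variants together with a variant
#' position table, as used by LD clumping. The container is sparse: only
#' pairs in appreciable LD need to be listed. Lookup semantics for a pair
#' (a, b):
#'
#' * `a == b`: r2 = 1;
#' * pair listed: its r2 (symmetric, whichever order was stored);
#' * pair unlisted but both variants present in the panel's variant table:
#'   r2 = 0 (the panel covered both variants and found no appreciable LD);
#' * either variant absent from the panel: r2 = `NA` (unknown). Clumping
#'   treats an unknown pair inside its window as r2 = 1, so a variant whose
#'   LD with the index cannot be established is never retained.
#'
#' @param pairs Data frame with columns `snp_a`, `snp_b`, `r2`.
#' @param variants Data frame with columns `snp`, `chrom`, `pos`.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(pairs, variants) {
  need_p <- c("snp_a", "snp_b", "r2")
  need_v <- c("snp", "chrom", "pos")
  if (length(setdiff(need_p, names(pairs))) > 0) {
    stop("ld_reference: pairs needs columns snp_a, snp_b, r2")
  }
  if (length(setdiff(need_v, names(variants))) > 0) {
    stop("ld_reference: variants needs columns snp, chrom, pos")
  }
  if (any(!is.finite(pairs$r2)) || any(pairs$r2 < 0) || any(pairs$r2 > 1)) {
    stop("ld_reference: r2 values must lie in [0, 1]")
  }
  r2 <- stats::setNames(pairs$r2,
                        pair_key(as.character(pairs$snp_a), as.character(pairs$snp_b)))
  # last write wins for duplicated keys
  r2 <- r2[!duplicated(names(r2), fromLast = TRUE)]
  env <- new.env(parent = emptyenv())
  assign("r2", r2, envir = env)
  variants <- data.frame(snp = as.character(variants$snp),
                         chrom = as.character(variants$chrom),
                         pos = as.numeric(variants$pos),
                         stringsAsFactors = FALSE)
  structure(list(lookup = env, variants = variants), class = "ld_reference")
}

#' Read an LD reference from long-format files
#'
#' @param pairs_path TSV with header `snp_a`, `snp_b`, `r2`.
#' @param variants_path TSV with header `snp`, `chrom`, `pos`.
#' @return An [ld_reference] object.
#' @export
read_ld_reference <- function(pairs_path, variants_path) {
  pairs <- utils::read.table(pairs_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  variants <- utils::read.table(variants_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  ld_reference(pairs, variants)
}

#' Query pairwise r-squared
#'
#' Vectorised over `a` and `b` (recycled to common length). See
#' [ld_reference()] for the lookup semantics.
#'
#' @param ld An [ld_reference].
#' @param a,b Variant id vectors.
#' @return Numeric vector of r2 values, `NA` where the LD is unknowable.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  tab <- get("r2", envir = ld$lookup)
  out <- unname(tab[pair_key(a, b)])
  known <- ld$variants$snp
  covered <- a %in% known & b %in% known
  out[is.na(out) & covered] <- 0
  out[a == b] <- 1
  out
}

#' Write an LD reference to long-format files
#'
#' @param ld An [ld_reference].
#' @param pairs_path,variants_path Output TSV paths.
#' @return `pairs_path`, invisibly.
#' @export
write_ld_reference <- function(ld, pairs_path, variants_path) {
  tab <- get("r2", envir = ld$lookup)
  keys <- strsplit(names(tab), "\r", fixed = TRUE)
  pairs <- data.frame(snp_a = vapply(keys, `[`, "", 1L),
                      snp_b = vapply(keys, `[`, "", 2L),
                      r2 = sprintf("%.17g", unname(tab)),
                      stringsAsFactors = FALSE)
  utils::write.table(pairs, pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ld$variants, variants_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(pairs_path)
}

#' @export
print.ld_reference <- function(x, ...) {
  cat("LD reference: ", nrow(x$variants), " variants, ",
      length(get("r2", envir = x$lookup)), " stored pairs\n", sep = "")
  invisible(x)
}
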