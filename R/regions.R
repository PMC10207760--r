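#' Read drug-target gene and regulatory regions
#'
#' Reads a BED-like file whose rows are genomic intervals annotated with a
#' gene symbol and an antihypertensive drug class. BED coordinates on disk
#' are 0-based half-open; they are converted once, at this boundary, to the
#' 1-based inclusive convention used internally (matching GWAS summary
#' files). An optional sixth column tags the interval as the gene body
#' (`gene`) or a regulatory element (`regulatory`); absent, `gene` is
#' assumed.
#'
#' @param path BED-like file: `chrom start end gene class [type]`,
#'   whitespace-separated, no header.
#' @param classes Allowed drug classes.
#' @return Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `gene`, `drug_class`, `type`.
#' @examples
#' # illustrative target-gene regions shipped with the package (GRCh37-like
#' # coordinates; real analyses should supply curated region definitions)
#' bed <- system.file("extdata", "drug_target_regions_example.bed",
#'                    package = "mrpipe")
#' read_gene_regions(bed)
#' @export
read_gene_regions <- function(path, classes = c("ACEI", "BB", "CCB")) {
  if (!file.exists(path)) stop("read_gene_regions: no such file: ", path)
  if (file.size(path) == 0) return(empty_regions())
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#", fill = TRUE)
  if (ncol(raw) < 5) {
    stop("read_gene_regions: expected at least 5 columns (chrom start end gene class)")
  }
  if (ncol(raw) < 6) raw$V6 <- "gene"
  names(raw)[1:6] <- c("chrom", "start", "end", "gene", "drug_class", "type")
  raw$type[is.na(raw$type) | raw$type == ""] <- "gene"
  bad <- which(!raw$drug_class %in% classes)
  if (length(bad) > 0) {
    stop("read_gene_regions: unknown drug class '", raw$drug_class[bad[1]],
         "' on line ", bad[1])
  }
  if (any(raw$start < 0) || any(raw$end <= raw$start)) {
    stop("read_gene_regions: malformed interval (need 0 <= start < end)")
  }
  regions <- data.frame(chrom = as.character(raw$chrom),
                        start = as.integer(raw$start) + 1L,  # BED -> 1-based
                        end = as.integer(raw$end),
                        gene = as.character(raw$gene),
                        drug_class = as.character(raw$drug_class),
                        type = as.character(raw$type),
                        stringsAsFactors = FALSE)
  regions
}

empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             gene = character(), drug_class = character(), type = character(),
             stringsAsFactors = FALSE)
}

#' Write gene regions back to BED (0-based half-open)
#'
#' @param regions Data frame as returned by [read_gene_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_regions <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    gene = regions$gene,
                    drug_class = regions$drug_class,
                    type = regions$type)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a confounder-association lookup table
#'
#' A local stand-in for an online variant-phenotype lookup: rows of
#' (snp, confounder trait, association p-value) used to screen instruments
#' for associations with known confounders.
#'
#' @param path TSV with header `snp`, `trait`, `pval`.
#' @return Data frame with those columns.
#' @export
read_confounder_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("snp", "trait", "pval")
  if (length(setdiff(need, names(tab))) > 0) {
    stop("read_confounder_table: need columns snp, trait, pval")
  }
  if (any(!is.finite(tab$pval)) || any(tab$pval <= 0) || any(tab$pval > 1)) {
    stop("read_confounder_table: p-values must lie in (0, 1]")
  }
  tab[, need]
}
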