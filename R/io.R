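#' Write genotypes as a minimal VCF (v4.2, GT field)
#'
#' Variant ids must follow the `chrom:pos:ref:alt` convention (1-based).
#' Autosomal and female X genotypes are written as unphased diploid calls;
#' male calls on the X non-pseudo-autosomal region are written haploid
#' (`0` / `1`).
#'
#' @param genotypes samples x variants raw dosage matrix (male X non-PAR
#'   haploid), with variant-id column names and sample row names.
#' @param chrom_class per-variant chromosome class (as in [encode_burden()]).
#' @param sex per-sample `"male"`/`"female"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, chrom_class, sex, path) {
  g <- as.matrix(genotypes)
  ids <- colnames(g)
  if (is.null(ids)) stop("genotype columns must be named by variant id")
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("variant ids must be chrom:pos:ref:alt")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  pos <- vapply(parts, `[[`, character(1), 2L)
  ref <- vapply(parts, `[[`, character(1), 3L)
  alt <- vapply(parts, `[[`, character(1), 4L)
  male <- as.character(sex) == "male"
  xnp <- chrom_class == "X_nonPAR"
  dip <- c("0/0", "0/1", "1/1")
  hap <- c("0", "1")
  gt_col <- function(j) {
    x <- g[, j]
    out <- character(length(x))
    if (xnp[j]) {
      out[male] <- ifelse(is.na(x[male]), ".", hap[x[male] + 1L])
      out[!male] <- ifelse(is.na(x[!male]), "./.", dip[x[!male] + 1L])
    } else {
      out <- ifelse(is.na(x), "./.", dip[x + 1L])
    }
    out
  }
  gt <- vapply(seq_len(ncol(g)), gt_col, character(nrow(g)))
  samples <- rownames(g)
  if (is.null(samples)) samples <- sprintf("S%05d", seq_len(nrow(g)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(ncol(g)), function(j)
    paste(c(chrom[j], pos[j], ids[j], ref[j], alt[j], ".", "PASS", ".",
            "GT", gt[, j]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read a sample x variant dosage matrix as TSV
#'
#' First column `sample_id`, one column per variant.
#'
#' @param genotypes samples x variants numeric matrix.
#' @param path TSV file.
#' @return the path (writer, invisibly) or the matrix (reader).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes) %||%
                     sprintf("S%05d", seq_len(nrow(genotypes))),
                   as.data.frame(genotypes, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a sample-annotated numeric table (metabolites, covariates) as TSV
#'
#' @param x matrix or data.frame with sample row names.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x) %||%
                     sprintf("S%05d", seq_len(nrow(x))),
                   as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
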