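#' @name qv_masks
#' @title Qualifying-variant masks
#' @description
#' Two complementary masks select rare (MAF < 1%), putatively damaging
#' variants on canonical transcripts for gene-based aggregation:
#'
#' * `LoF_mis`: high-confidence loss-of-function variants, missense variants
#'   with MetaSVM score > 0, or in-frame nonsynonymous variants with
#'   fathmm-XF coding score > 0.5.
#' * `HI_mis`: high-impact consequences (transcript ablation/amplification,
#'   splice acceptor/donor, stop gained, frameshift, start/stop lost), or
#'   missense variants with REVEL > 0.5, CADD PHRED > 20 or M-CAP > 0.025.
#'
#' All cutoffs are strict inequalities; a missing score never exceeds a
#' cutoff. A gene is retained for testing only if it holds more than three
#' qualifying variants in at least one mask.
NULL

.hi_consequences <- c(
  "transcript_ablation", "transcript_amplification",
  "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "frameshift_variant", "start_lost", "stop_lost"
)
.inframe_consequences <- c(
  "inframe_insertion", "inframe_deletion", "protein_altering_variant"
)
.other_consequences <- c(
  "missense_variant", "synonymous_variant", "splice_region_variant",
  "intron_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant"
)

#' Controlled vocabulary of variant consequence terms
#'
#' VEP-style consequence terms recognized by the mask rules.
#' @return character vector of terms.
#' @export
consequence_vocabulary <- function() {
  c(.hi_consequences, .inframe_consequences, .other_consequences)
}

.exceeds <- function(score, cutoff) !is.na(score) & score > cutoff

.check_annotations <- function(ann) {
  required <- c("variant_id", "gene", "canonical", "chrom_class", "maf",
                "consequence", "lof_confidence")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (sc in c("metasvm", "fathmm_xf", "revel", "cadd_phred", "mcap"))
    if (is.null(ann[[sc]])) ann[[sc]] <- NA_real_
  bad_maf <- !is.na(ann$maf) & (ann$maf < 0 | ann$maf > 0.5)
  if (any(bad_maf)) stop("MAF outside [0, 0.5] for ",
                         paste(utils::head(ann$variant_id[bad_maf], 3L), collapse = ", "))
  unknown <- setdiff(unique(ann$consequence), consequence_vocabulary())
  if (length(unknown))
    stop("consequence term(s) outside the controlled vocabulary: ",
         paste(unknown, collapse = ", "))
  ann
}

#' Does a variant qualify for a mask?
#'
#' Vectorized over the rows of a VEP-like annotation table. A variant
#' qualifies only if its MAF is below 1%, it is on the canonical transcript,
#' and it passes the mask's consequence/score rule (see [qv_masks]).
#'
#' @param annotations data.frame with columns `variant_id`, `gene`,
#'   `canonical` (logical), `chrom_class`, `maf`, `consequence`,
#'   `lof_confidence` (`"high_confidence"`, `"low_confidence"` or `"none"`),
#'   and optional scores `metasvm`, `fathmm_xf`, `revel`, `cadd_phred`,
#'   `mcap` (NA = missing).
#' @param mask `"LoF_mis"` or `"HI_mis"`.
#' @param maf_cutoff frequency cutoff (default 0.01, strict).
#' @return logical vector, one element per annotation row.
#' @export
qualifies <- function(annotations, mask = c("LoF_mis", "HI_mis"),
                      maf_cutoff = 0.01) {
  mask <- match.arg(mask)
  ann <- .check_annotations(as.data.frame(annotations))
  rare <- !is.na(ann$maf) & ann$maf < maf_cutoff
  canonical <- !is.na(ann$canonical) & ann$canonical
  missense <- ann$consequence == "missense_variant"
  rule <- if (mask == "LoF_mis") {
    (!is.na(ann$lof_confidence) & ann$lof_confidence == "high_confidence") |
      (missense & .exceeds(ann$metasvm, 0)) |
      (ann$consequence %in% .inframe_consequences &
         .exceeds(ann$fathmm_xf, 0.5))
  } else {
    (ann$consequence %in% .hi_consequences) |
      (missense & (.exceeds(ann$revel, 0.5) |
                     .exceeds(ann$cadd_phred, 20) |
                     .exceeds(ann$mcap, 0.025)))
  }
  rare & canonical & rule
}

#' Build per-gene qualifying-variant sets for both masks
#'
#' Applies [qualifies()] for each mask, groups qualifying variants by gene,
#' and retains a gene if it has more than `min_qvs` QVs in at least one mask
#' (strict; a gene with exactly `min_qvs` in both masks is dropped). Both
#' masks of a retained gene are emitted, even the smaller one. Variants with
#' a missing gene symbol or a non-canonical transcript are skipped and
#' counted.
#'
#' @param annotations as in [qualifies()].
#' @param masks masks to evaluate.
#' @param min_qvs retention cutoff; genes need strictly more than this many
#'   QVs in some mask (default 3).
#' @return an object of class `gene_mask_sets`: a list with
#'   \describe{
#'     \item{sets}{data.frame `gene, mask, variant_id, maf` of QV membership
#'       for retained genes}
#'     \item{genes}{data.frame per gene x mask: `gene, mask, n_qvs, cmaf,
#'       retained, reason`}
#'     \item{n_skipped}{count of variants skipped for missing gene symbol or
#'       non-canonical transcript}
#'   }
#' @export
build_mask_sets <- function(annotations, masks = c("LoF_mis", "HI_mis"),
                            min_qvs = 3L) {
  ann <- .check_annotations(as.data.frame(annotations))
  skip <- is.na(ann$gene) | ann$gene == "" |
    is.na(ann$canonical) | !ann$canonical
  n_skipped <- sum(skip)
  ann <- ann[!skip, , drop = FALSE]
  if (nrow(ann) == 0L) {
    empty_sets <- data.frame(gene = character(), mask = character(),
                             variant_id = character(), maf = numeric())
    out <- list(sets = empty_sets,
                genes = data.frame(gene = character(), mask = character(),
                                   n_qvs = integer(), cmaf = numeric(),
                                   retained = logical(), reason = character()),
                n_skipped = n_skipped)
    class(out) <- "gene_mask_sets"
    return(out)
  }
  member <- do.call(rbind, lapply(masks, function(m) {
    ok <- qualifies(ann, m)
    data.frame(gene = ann$gene[ok], mask = m,
               variant_id = ann$variant_id[ok], maf = ann$maf[ok],
               stringsAsFactors = FALSE)
  }))
  # order-independent output
  member <- member[order(member$gene, member$mask, member$variant_id), ,
                   drop = FALSE]
  rownames(member) <- NULL
  all_genes <- sort(unique(ann$gene))
  genes <- expand.grid(gene = all_genes, mask = masks,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(member$gene, member$mask)
  genes$n_qvs <- as.integer(table(factor(key, paste(genes$gene, genes$mask))))
  genes$cmaf <- as.numeric(tapply(member$maf, factor(key, paste(genes$gene, genes$mask)),
                                  sum, default = 0))
  max_per_gene <- tapply(genes$n_qvs, genes$gene, max)
  genes$retained <- max_per_gene[genes$gene] > min_qvs
  genes$reason <- ifelse(genes$retained, "",
                         sprintf("<= %d QVs in every mask", min_qvs))
  member <- member[member$gene %in% genes$gene[genes$retained], , drop = FALSE]
  out <- list(sets = member, genes = genes, n_skipped = n_skipped)
  class(out) <- "gene_mask_sets"
  out
}

#' @export
print.gene_mask_sets <- function(x, ...) {
  kept <- unique(x$genes$gene[x$genes$retained])
  cat("gene_mask_sets:", length(kept), "gene(s) retained,",
      length(unique(x$genes$gene)) - length(kept), "dropped,",
      x$n_skipped, "variant(s) skipped\n")
  invisible(x)
}

#' Read a VEP-like annotation table from TSV
#'
#' One row per variant-transcript; expects the column names used by
#' [qualifies()]. Empty fields become `NA`.
#'
#' @param path TSV file with a header line.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (!is.null(ann$canonical) && !is.logical(ann$canonical))
    ann$canonical <- ann$canonical %in% c("TRUE", "true", "yes", "1")
  .check_annotations(ann)
}

#' Write qualifying-variant mask membership to TSV
#'
#' @param mask_sets a `gene_mask_sets` object from [build_mask_sets()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_sets <- function(mask_sets, path) {
  stopifnot(inherits(mask_sets, "gene_mask_sets"))
  utils::write.table(mask_sets$sets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
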