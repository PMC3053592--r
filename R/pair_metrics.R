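# Per-pair scalar statistics: transcription control similarity (TCS),
# normalized genomic distance, and mutual-rank retrieval.

#' Transcription control similarity of two genes
#'
#' One minus the number of transcription factors binding one but not both
#' genes, divided by the sum of the two genes' regulator counts:
#' `1 - |A xor B| / (|A| + |B|)`, equivalently `2|A & B| / (|A| + |B|)`.
#' 1 means identical regulator sets, 0 disjoint ones.
#'
#' @param tfs_a,tfs_b character vectors of TF ids (treated as sets).
#' @return scalar in `[0, 1]`.
#' @export
tcs <- function(tfs_a, tfs_b) {
  a <- unique(tfs_a); b <- unique(tfs_b)
  na <- length(a); nb <- length(b)
  if (na + nb == 0L)
    stop_chromex("TCS is undefined when both TF sets are empty",
                 class = "chromex_undefined_tcs_error")
  n_common <- length(intersect(a, b))
  1 - (na + nb - 2 * n_common) / (na + nb)
}

#' Normalized genomic distance of two same-chromosome genes
#'
#' Absolute distance between the gene-body midpoints divided by the
#' chromosome length; lies in `[0, 1)`.
#'
#' @param gene_a,gene_b one-row data.frames with `chrom`, `start`, `end`.
#' @param sizes named chromosome-length vector (see [read_chrom_sizes()]).
#' @return scalar in `[0, 1)`.
#' @export
normalized_distance <- function(gene_a, gene_b, sizes) {
  if (!identical(gene_a$chrom, gene_b$chrom))
    stop_chromex("normalized_distance requires genes on one chromosome",
                 class = "chromex_usage_error")
  len <- sizes[[gene_a$chrom]]
  if (is.null(len))
    stop_chromex("unknown chromosome '", gene_a$chrom, "'",
                 class = "chromex_validation_error")
  abs((gene_a$start + gene_a$end) / 2 - (gene_b$start + gene_b$end) / 2) / len
}

#' Look up the mutual rank of an unordered gene pair
#'
#' @param table a `CoexpressionTable`.
#' @param a,b distinct gene ids; order is irrelevant.
#' @return the stored mutual rank, or `NA` when the pair is absent.
#' @export
lookup_mutual_rank <- function(table, a, b) {
  if (identical(a, b))
    stop_chromex("mutual rank of a gene with itself is undefined",
                 class = "chromex_usage_error")
  v <- table$mr[pair_key(a, b)]
  if (is.na(v)) NA_real_ else unname(v)
}
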