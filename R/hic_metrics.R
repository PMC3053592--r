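# Contact-matrix computation: expected-by-distance, observed/expected, the
# Pearson-correlation (PC) matrix, gene-to-bin weights, gene-pair interaction
# values and percentile ranks.

#' Mean contact at each genomic-distance offset
#'
#' `e[d] = mean(counts[i, i + d])` over all rows `i` with `i + d <= n_bins`,
#' for offsets `d = 0 .. n_bins - 1`. This is the distance-decay profile used
#' to normalize observed counts.
#'
#' @param m a `ContactMatrix`.
#' @return numeric vector of length `n_bins`; element `d + 1` is the mean at
#'   offset `d`.
#' @export
expected_by_distance <- function(m) {
  n <- m$n_bins
  counts <- m$counts
  vapply(0:(n - 1L), function(d) {
    i <- seq_len(n - d)
    mean(counts[cbind(i, i + d)])
  }, numeric(1))
}

#' Observed-over-expected normalization
#'
#' Divides every cell by the mean contact at its distance offset. Cells on
#' offsets whose expected value is zero become `NA` (a zero expectation means
#' every observation at that offset was zero; marking them missing keeps them
#' from masquerading as depleted contacts).
#'
#' @param m a `ContactMatrix`.
#' @return square numeric matrix, possibly with `NA` cells.
#' @export
observed_over_expected <- function(m) {
  e <- expected_by_distance(m)
  n <- m$n_bins
  offs <- abs(row(m$counts) - col(m$counts))
  em <- matrix(e[offs + 1L], n, n)
  oe <- m$counts / em
  oe[em == 0] <- NA_real_
  oe
}

#' Bin-bin Pearson correlation matrix from an O/E matrix
#'
#' `PC[i, j]` is the Pearson correlation of rows `i` and `j` of the O/E
#' matrix over the columns defined in both rows. Entries with fewer than
#' `min_shared` shared defined columns, or with zero variance over the shared
#' columns, are `NA`. The diagonal is forced to 1.
#'
#' @param oe O/E matrix (possibly containing `NA`).
#' @param min_shared minimum shared defined columns for a defined entry.
#' @return symmetric matrix with unit diagonal and entries in `[-1, 1]` or `NA`.
#' @export
correlation_matrix <- function(oe, min_shared = 3L) {
  pc <- suppressWarnings(stats::cor(t(oe), use = "pairwise.complete.obs"))
  ok <- !is.na(oe)
  shared <- tcrossprod(ok * 1)
  pc[shared < min_shared] <- NA_real_
  # guard against floating drift outside [-1, 1]
  pc[!is.na(pc)] <- pmin(1, pmax(-1, pc[!is.na(pc)]))
  diag(pc) <- 1
  pc
}

#' Overlap-proportional gene-to-bin weights
#'
#' Bin `k` covers `[k * resolution, (k + 1) * resolution)`. The weight of bin
#' `k` is the fraction of the gene body overlapping it, so weights sum to 1.
#'
#' @param gene one-row data.frame (or list) with `start`, `end`.
#' @param resolution bin width in bp.
#' @param n_bins number of bins in the chromosome's matrix.
#' @return named numeric vector; names are 0-based bin indices, values the
#'   overlap fractions. Bins with zero overlap are absent.
#' @export
gene_bin_weights <- function(gene, resolution, n_bins) {
  start <- gene$start; end <- gene$end
  if (end > n_bins * resolution || start < 0)
    stop_chromex("gene interval [", start, ", ", end,
                 ") outside the contact-matrix span",
                 class = "chromex_validation_error")
  k <- seq.int(floor(start / resolution), floor((end - 1) / resolution))
  ov <- pmin(end, (k + 1) * resolution) - pmax(start, k * resolution)
  stats::setNames(ov / (end - start), k)
}

#' Weighted bin-level interaction of a gene pair
#'
#' The weighted average `sum_k sum_l w_a[k] w_b[l] mat[k, l]` of the contact
#' (or correlation) cells spanned by the two gene bodies. When some
#' contributing cells are missing the average is taken over the defined cells
#' with weights renormalized; when all are missing the result is `NA`.
#'
#' @param gene_a,gene_b one-row data.frames with `chrom`, `start`, `end`.
#' @param mat square matrix (contact counts or PC), possibly with `NA`.
#' @param resolution bin width in bp.
#' @return scalar interaction value or `NA`.
#' @export
gene_pair_interaction <- function(gene_a, gene_b, mat, resolution) {
  if (!identical(gene_a$chrom, gene_b$chrom))
    stop_chromex("gene_pair_interaction is intra-chromosomal only",
                 class = "chromex_usage_error")
  n_bins <- nrow(mat)
  wa <- gene_bin_weights(gene_a, resolution, n_bins)
  wb <- gene_bin_weights(gene_b, resolution, n_bins)
  cells <- mat[as.integer(names(wa)) + 1L, as.integer(names(wb)) + 1L,
               drop = FALSE]
  w <- outer(unname(wa), unname(wb))
  def <- !is.na(cells)
  if (!any(def)) return(NA_real_)
  sum(w[def] * cells[def]) / sum(w[def])
}

#' Percentile ranks with tie averaging
#'
#' Average ranks divided by the number of non-missing values, giving values
#' in `(0, 1]`. Missing inputs get missing ranks.
#'
#' @param values numeric vector; `NA`/`NaN` treated as missing.
#' @return numeric vector of percentile ranks in `(0, 1]`, `NA` where missing.
#' @export
percentile_ranks <- function(values) {
  miss <- is.na(values)
  n <- sum(!miss)
  if (n == 0L)
    stop_chromex("percentile_ranks requires at least one non-missing value",
                 class = "chromex_usage_error")
  rank(values, ties.method = "average", na.last = "keep") / n
}
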