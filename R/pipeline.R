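# Pipeline orchestration: pair assembly, cross-cell-type rank matching,
# stratification, 20-group binned correlation tests with Bonferroni
# correction, and the co-expressed-vs-all Welch t-test.

default_thresholds <- function() {
  list(rank_match = 0.05, distant = 0.2, mr_coexpressed = 50,
       n_groups = 20L, alpha = 0.05, rank_measure = "oh",
       min_shared_cols = 3L)
}

# Gene x bin weight matrix for one chromosome (rows = genes, cols = bins).
gene_weight_matrix <- function(genes, resolution, n_bins) {
  W <- matrix(0, nrow(genes), n_bins)
  for (i in seq_len(nrow(genes))) {
    w <- gene_bin_weights(genes[i, ], resolution, n_bins)
    W[i, as.integer(names(w)) + 1L] <- w
  }
  W
}

# Vectorized gene-pair interaction: weighted average over defined cells with
# weights renormalized, NA when every contributing cell is missing. Returns
# the full gene x gene matrix.
pairwise_interaction_matrix <- function(W, mat) {
  def <- !is.na(mat)
  m0 <- mat
  m0[!def] <- 0
  numer <- W %*% m0 %*% t(W)
  denom <- W %*% (def * 1) %*% t(W)
  out <- numer / denom
  out[denom <= 1e-12] <- NA_real_
  out
}

#' Assemble the gene-pair table
#'
#' Restricts the annotation to genes that appear in the co-expression table
#' (in at least one pair) and in the regulatory network as a target, then
#' builds one record per unordered intra-chromosomal pair of retained genes,
#' populated with the weighted bin-level interaction (OH) and the PC-derived
#' interaction per cell type, the mutual rank, TCS, normalized distance,
#' percentile ranks of the chosen measure per cell type, and (optionally) the
#' Wang GO gene similarity.
#'
#' @param ann a `GeneAnnotation`.
#' @param matrices named list: cell type -> named list: chromosome ->
#'   `ContactMatrix`.
#' @param coexpr a `CoexpressionTable`.
#' @param net a `RegulatoryNetwork`.
#' @param goann optional `GeneGoAnnotation`.
#' @param dag optional `GoDAG` (required when `goann` is given).
#' @param config list; honours `rank_measure` (`"oh"` or `"pc"`) and
#'   `min_shared_cols` for the PC matrix.
#' @return a `GenePairTable`.
#' @export
build_pair_table <- function(ann, matrices, coexpr, net, goann = NULL,
                             dag = NULL, config = list()) {
  cfg <- utils::modifyList(default_thresholds(), config)
  cell_types <- names(matrices)
  genes <- ann$genes
  in_coexpr <- unique(unlist(strsplit(names(coexpr$mr), "\x1f", fixed = TRUE)))
  keep <- genes$id %in% in_coexpr & genes$id %in% names(net$tf_sets)
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) < 2L)
    stop_chromex("no retained gene pairs: fewer than two genes are present ",
                 "in both the co-expression table and the TF network",
                 class = "chromex_empty_cohort_error")

  chrom_tables <- list()
  for (chrom in unique(genes$chrom)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) next
    iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    a <- g$id[iu[, 1L]]; b <- g$id[iu[, 2L]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    mid <- (g$start + g$end) / 2
    df <- data.frame(gene_a = a, gene_b = b, chrom = chrom,
                     stringsAsFactors = FALSE)
    df$norm_dist <- abs(mid[iu[, 1L]] - mid[iu[, 2L]]) / ann$sizes[[chrom]]
    for (ct in cell_types) {
      m <- matrices[[ct]][[chrom]]
      if (is.null(m))
        stop_chromex("no contact matrix for ", chrom, " in cell type ", ct,
                     class = "chromex_usage_error")
      W <- gene_weight_matrix(g, m$resolution, m$n_bins)
      oh <- pairwise_interaction_matrix(W, m$counts)
      pc_mat <- correlation_matrix(observed_over_expected(m),
                                   min_shared = cfg$min_shared_cols)
      pc <- pairwise_interaction_matrix(W, pc_mat)
      df[[paste0("oh_", ct)]] <- oh[iu]
      df[[paste0("pc_", ct)]] <- pc[iu]
    }
    chrom_tables[[chrom]] <- df
  }
  if (!length(chrom_tables))
    stop_chromex("no chromosome holds two or more retained genes",
                 class = "chromex_empty_cohort_error")
  pairs <- do.call(rbind, unname(chrom_tables))

  pairs$mutual_rank <- unname(coexpr$mr[pair_key(pairs$gene_a, pairs$gene_b)])

  # TCS via the genes x TFs incidence matrix: the pairwise intersection sizes
  # are its cross-product, and TCS = 2|A & B| / (|A| + |B|).
  ids <- unique(c(pairs$gene_a, pairs$gene_b))
  tfs <- unique(unlist(net$tf_sets[ids], use.names = FALSE))
  inc <- matrix(0, length(ids), length(tfs), dimnames = list(ids, tfs))
  for (gid in ids) inc[gid, net$tf_sets[[gid]]] <- 1
  deg <- rowSums(inc)
  inter <- tcrossprod(inc)
  denom <- deg[pairs$gene_a] + deg[pairs$gene_b]
  tcs_val <- 2 * inter[cbind(pairs$gene_a, pairs$gene_b)] / denom
  tcs_val[denom == 0] <- NA_real_
  pairs$tcs <- unname(tcs_val)

  for (ct in cell_types) {
    measure <- pairs[[paste0(cfg$rank_measure, "_", ct)]]
    pairs[[paste0("rank_pct_", ct)]] <- percentile_ranks(measure)
  }

  if (!is.null(goann)) {
    if (is.null(dag))
      stop_chromex("a GoDAG is required to score GO similarity",
                   class = "chromex_usage_error")
    pairs$go_sim <- pairwise_gene_similarity(dag, goann, pairs$gene_a,
                                             pairs$gene_b)
  } else {
    pairs$go_sim <- NA_real_
  }

  new_gene_pair_table(pairs, meta = list(
    cell_types = cell_types,
    resolution = matrices[[1L]][[1L]]$resolution,
    rank_measure = cfg$rank_measure,
    n_genes = nrow(genes),
    filters = list()))
}

# Vectorized BMA gene similarity over many pairs, sharing one term-similarity
# matrix across all annotated terms.
pairwise_gene_similarity <- function(dag, ann, genes_a, genes_b) {
  used <- unique(unlist(ann[unique(c(genes_a, genes_b))], use.names = FALSE))
  if (!length(used)) return(rep(NA_real_, length(genes_a)))
  tsm <- go_term_similarity_matrix(dag, used)
  vapply(seq_along(genes_a), function(i) {
    ta <- ann[[genes_a[i]]]; tb <- ann[[genes_b[i]]]
    if (is.null(ta) || is.null(tb) || !length(ta) || !length(tb))
      return(NA_real_)
    bma_combine(tsm[ta, tb, drop = FALSE])
  }, numeric(1))
}

#' Cross-cell-type interaction rank matching
#'
#' Retains gene pairs whose percentile ranks of the interaction measure in
#' the two cell types differ by strictly less than `threshold`. Pairs with a
#' missing rank in either cell type are dropped.
#'
#' @param table a `GenePairTable` with `rank_pct_*` columns populated.
#' @param cell_a,cell_b cell-type labels.
#' @param threshold rank-difference threshold in `(0, 1]`.
#' @return the filtered `GenePairTable`; provenance records the filter.
#' @export
rank_match_filter <- function(table, cell_a, cell_b, threshold = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop_chromex("rank-match threshold must lie in (0, 1]",
                 class = "chromex_config_error")
  ra <- table$pairs[[paste0("rank_pct_", cell_a)]]
  rb <- table$pairs[[paste0("rank_pct_", cell_b)]]
  if (is.null(ra) || is.null(rb))
    stop_chromex("percentile ranks missing for cell type ",
                 if (is.null(ra)) cell_a else cell_b,
                 class = "chromex_usage_error")
  keep <- !is.na(ra) & !is.na(rb) & abs(ra - rb) < threshold
  meta <- table$meta
  meta$filters$rank_match <- list(cell_a = cell_a, cell_b = cell_b,
                                  threshold = threshold,
                                  measure = meta$rank_measure,
                                  n_before = nrow(table$pairs),
                                  n_after = sum(keep))
  new_gene_pair_table(table$pairs[keep, , drop = FALSE], meta)
}

#' Stratify a pair table
#'
#' Rules: `distant` keeps pairs with normalized distance strictly greater
#' than the threshold; `tcs_zero` / `tcs_nonzero` split pairs with a defined
#' TCS at zero; `coexpressed` keeps pairs with mutual rank \eqn{\le} the
#' threshold (default 50).
#'
#' @param table a `GenePairTable`.
#' @param rule one of `"distant"`, `"tcs_zero"`, `"tcs_nonzero"`,
#'   `"coexpressed"`.
#' @param threshold rule threshold; defaults to 0.2 for `distant` and 50 for
#'   `coexpressed`.
#' @return the filtered `GenePairTable`.
#' @export
stratify <- function(table, rule, threshold = NULL) {
  p <- table$pairs
  keep <- switch(rule,
    distant = {
      threshold <- threshold %||% 0.2
      !is.na(p$norm_dist) & p$norm_dist > threshold
    },
    tcs_zero = !is.na(p$tcs) & p$tcs == 0,
    tcs_nonzero = !is.na(p$tcs) & p$tcs > 0,
    coexpressed = {
      threshold <- threshold %||% 50
      !is.na(p$mutual_rank) & p$mutual_rank <= threshold
    },
    stop_chromex("unknown stratification rule '", rule, "'",
                 class = "chromex_config_error"))
  meta <- table$meta
  meta$filters[[rule]] <- list(threshold = threshold,
                               n_before = nrow(p), n_after = sum(keep))
  new_gene_pair_table(p[keep, , drop = FALSE], meta)
}

#' Equal-size group assignment that never splits ties
#'
#' Samples are sorted by `x` and cut at quantile boundaries
#' (`prelim(i) = ceiling(i * n_groups / n)` for sorted position `i`); every
#' sample sharing an `x` value is assigned the group of the tie block's first
#' sorted position, so ties never split and some group indices may end up
#' empty ("missing groups"). With all-distinct `x`, group sizes differ by at
#' most 1.
#'
#' @param x finite numeric vector.
#' @param n_groups number of groups (>= 2).
#' @return integer vector of group indices in `1..n_groups`, same order as `x`.
#' @export
equal_size_binning <- function(x, n_groups = 20L) {
  if (!is_count(n_groups) || n_groups < 2L)
    stop_chromex("n_groups must be an integer >= 2",
                 class = "chromex_config_error")
  if (length(x) == 0L || any(!is.finite(x)))
    stop_chromex("x must be non-empty and finite",
                 class = "chromex_usage_error")
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  prelim <- ceiling(seq_len(n) * n_groups / n)
  block <- cumsum(!duplicated(xs))
  first_pos <- match(unique(block), block)
  grp_sorted <- prelim[first_pos][block]
  g <- integer(n)
  g[o] <- grp_sorted
  g
}

# Per-group n, mean x, mean y, standard error of y; one row per group index,
# empty groups carried as NA rows.
binned_series <- function(x, y, groups, n_groups) {
  out <- data.frame(group = seq_len(n_groups), n = 0L,
                    mean_x = NA_real_, mean_y = NA_real_, se_y = NA_real_)
  tab <- table(factor(groups, levels = seq_len(n_groups)))
  out$n <- as.integer(tab)
  nz <- which(out$n > 0L)
  out$mean_x[nz] <- tapply(x, groups, mean)[as.character(nz)]
  out$mean_y[nz] <- tapply(y, groups, mean)[as.character(nz)]
  sds <- tapply(y, groups, stats::sd)[as.character(nz)]
  out$se_y[nz] <- sds / sqrt(out$n[nz])
  out
}

#' Binned correlation test on group means
#'
#' Assigns samples to equal-size groups by `x` (ties never split), computes
#' per-group means of `x` and `y`, and tests the Pearson (or Spearman)
#' correlation of the nonempty groups' mean points, two-sided.
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value in
#'   either are dropped before binning.
#' @param n_groups number of groups (default 20).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a `PanelResult` list: `r`, `p`, `n`, `n_groups`,
#'   `n_nonempty_groups`, `method`, and the per-group `series` data.frame.
#' @export
binned_correlation_test <- function(x, y, n_groups = 20L,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x))
    stop_chromex("no complete (x, y) samples",
                 class = "chromex_insufficient_groups_error")
  groups <- equal_size_binning(x, n_groups)
  series <- binned_series(x, y, groups, n_groups)
  nz <- series$n > 0L
  if (sum(nz) < 3L)
    stop_chromex("binned correlation test needs >= 3 nonempty groups, got ",
                 sum(nz), class = "chromex_insufficient_groups_error")
  ct <- stats::cor.test(series$mean_x[nz], series$mean_y[nz],
                        method = method, alternative = "two.sided",
                        exact = FALSE)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n = length(x), n_groups = n_groups,
                 n_nonempty_groups = sum(nz), method = method,
                 series = series),
            class = "PanelResult")
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise error rate in `(0, 1)`.
#' @param n_tests number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_chromex("alpha must lie in (0, 1)", class = "chromex_config_error")
  if (!is_count(n_tests))
    stop_chromex("n_tests must be a positive integer",
                 class = "chromex_config_error")
  alpha / n_tests
}

#' Welch t-test of co-expressed pairs against all remaining pairs
#'
#' Compares the interaction measure between the co-expressed stratum (mutual
#' rank <= `mr_threshold`) and its complement with a two-sided
#' unequal-variance t-test. The two groups are disjoint.
#'
#' @param table a `GenePairTable`.
#' @param measure `"oh"` or `"pc"`.
#' @param cell_type cell-type label.
#' @param mr_threshold mutual-rank cut-off for the co-expressed stratum.
#' @return list with `statistic`, `p`, `df`, group means and sizes.
#' @export
coexpressed_vs_all_ttest <- function(table, measure, cell_type,
                                     mr_threshold = 50) {
  col <- paste0(measure, "_", cell_type)
  p <- table$pairs
  if (is.null(p[[col]]))
    stop_chromex("no column ", col, " in the pair table",
                 class = "chromex_usage_error")
  vals <- p[[col]]
  ok <- !is.na(vals) & !is.na(p$mutual_rank)
  coexpr <- vals[ok & p$mutual_rank <= mr_threshold]
  rest <- vals[ok & p$mutual_rank > mr_threshold]
  if (length(coexpr) < 2L || length(rest) < 2L)
    stop_chromex("each t-test group needs >= 2 members (got ",
                 length(coexpr), " co-expressed, ", length(rest), " rest)",
                 class = "chromex_insufficient_data_error")
  tt <- stats::t.test(coexpr, rest, var.equal = FALSE,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_coexpressed = mean(coexpr), mean_rest = mean(rest),
       n_coexpressed = length(coexpr), n_rest = length(rest),
       mr_threshold = mr_threshold)
}

panel_from_test <- function(pr, measure, cell_type, threshold, stratum) {
  list(panel = paste(stratum, measure, cell_type, sep = "_"),
       measure = measure, cell_type = cell_type, stratum = stratum,
       r = pr$r, p = pr$p, n = pr$n,
       n_nonempty_groups = pr$n_nonempty_groups,
       significant = is.finite(pr$p) && pr$p < threshold,
       method = pr$method)
}

#' Run every stratified panel and t-test on an assembled pair table
#'
#' Applies the cross-cell-type rank-match filter, builds the strata (all,
#' distant, TCS zero / nonzero, co-expressed), and for each stratum runs the
#' binned correlation test of each interaction measure (y) against the mutual
#' rank (x) per cell type; adds the GO-similarity panels (GO similarity
#' against each interaction measure, and against the mutual rank) when the
#' table carries GO scores, plus the co-expressed-vs-all Welch t-tests.
#' Significance uses the Bonferroni threshold for the four-panel family
#' (`alpha / 4` with the defaults, i.e. 0.0125).
#'
#' @param table a `GenePairTable` from [build_pair_table()].
#' @param config list overriding [default_thresholds()] entries.
#' @return an `AnalysisResults` list with `metadata`, `counts`, `strata`
#'   (panels per stratum), `go_panels`, and `ttests`.
#' @export
analyze_pair_table <- function(table, config = list()) {
  cfg <- utils::modifyList(default_thresholds(), config)
  cts <- table$meta$cell_types
  if (length(cts) != 2L)
    stop_chromex("the analysis expects exactly two cell types, got ",
                 length(cts), class = "chromex_config_error")
  thr <- bonferroni_threshold(cfg$alpha, 4L)

  matched <- rank_match_filter(table, cts[1L], cts[2L], cfg$rank_match)
  strata_tables <- list(
    all = matched,
    distant = stratify(matched, "distant", cfg$distant),
    tcs_zero = stratify(matched, "tcs_zero"),
    tcs_nonzero = stratify(matched, "tcs_nonzero"),
    coexpressed = stratify(matched, "coexpressed", cfg$mr_coexpressed))

  run_panel <- function(x, y, measure, ct, stratum) {
    res <- tryCatch(
      binned_correlation_test(x, y, cfg$n_groups),
      chromex_insufficient_groups_error = function(e) NULL)
    if (is.null(res))
      return(list(panel = paste(stratum, measure, ct, sep = "_"),
                  measure = measure, cell_type = ct, stratum = stratum,
                  r = NA, p = NA, n = sum(is.finite(x) & is.finite(y)),
                  n_nonempty_groups = NA, significant = FALSE,
                  method = "pearson", error = "insufficient groups"))
    panel_from_test(res, measure, ct, thr, stratum)
  }

  strata <- lapply(names(strata_tables), function(st) {
    p <- strata_tables[[st]]$pairs
    panels <- list()
    for (measure in c("oh", "pc")) for (ct in cts) {
      panels[[paste(measure, ct, sep = "_")]] <-
        run_panel(p$mutual_rank, p[[paste0(measure, "_", ct)]],
                  measure, ct, st)
    }
    list(n_pairs = nrow(p), panels = panels)
  })
  names(strata) <- names(strata_tables)

  go_panels <- NULL
  if (any(!is.na(matched$pairs$go_sim))) {
    p <- matched$pairs
    go_panels <- list()
    for (measure in c("oh", "pc")) for (ct in cts) {
      go_panels[[paste(measure, ct, sep = "_")]] <-
        run_panel(p[[paste0(measure, "_", ct)]], p$go_sim, measure, ct,
                  paste0("go_vs_", measure))
    }
    go_panels$coexpression <- run_panel(p$mutual_rank, p$go_sim,
                                        "go_sim", "pooled",
                                        "go_vs_coexpression")
  }

  ttests <- list()
  for (measure in c("oh", "pc")) for (ct in cts) {
    ttests[[paste(measure, ct, sep = "_")]] <- tryCatch(
      coexpressed_vs_all_ttest(matched, measure, ct, cfg$mr_coexpressed),
      chromex_insufficient_data_error = function(e)
        list(error = conditionMessage(e)))
  }

  counts <- c(list(genes = table$meta$n_genes,
                   pairs_total = nrow(table$pairs)),
              stats::setNames(lapply(strata_tables,
                                     function(t) nrow(t$pairs)),
                              paste0("pairs_", names(strata_tables))))

  structure(list(
    metadata = list(thresholds = cfg[c("rank_match", "distant",
                                       "mr_coexpressed", "n_groups",
                                       "alpha", "rank_measure")],
                    bonferroni_family = 4L,
                    bonferroni_threshold = thr,
                    cell_types = cts,
                    combine_rule = "BMA",
                    correlation_method = "pearson",
                    ttest = "welch_two_sided"),
    counts = counts,
    strata = strata,
    go_panels = go_panels,
    ttests = ttests), class = "AnalysisResults")
}

#' Run the full analysis from a configuration
#'
#' The configuration is a list (or path to a JSON file) with sections:
#' \describe{
#'   \item{inputs}{`genes` (BED6), `sizes` (chrom.sizes TSV), `contacts`
#'     (cell type -> chromosome -> contact TSV path), `dialect`,
#'     `resolution`, `tf_targets`, `mutual_ranks`, optional `obo` +
#'     `gene_go`.}
#'   \item{thresholds}{overrides of [default_thresholds()].}
#'   \item{seed}{integer seed recorded in the metadata (the analysis itself
#'     is deterministic).}
#' }
#' When `out_dir` is given, writes `results.json`, `pair_table.tsv`, and one
#' `groups_<stratum>_<measure>_<celltype>.tsv` of group means per panel.
#'
#' @param config list or JSON path.
#' @param out_dir optional output directory.
#' @return an `AnalysisResults` list (invisibly when writing).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  resolve <- function(p) if (startsWith(p, "/")) p else file.path(base, p)
  inp <- config$inputs
  for (f in c("genes", "sizes", "tf_targets", "mutual_ranks", "obo",
              "gene_go"))
    if (!is.null(inp[[f]])) inp[[f]] <- resolve(inp[[f]])
  inp$contacts <- lapply(inp$contacts, function(x) lapply(as.list(x), resolve))
  thresholds <- config$thresholds %||% list()
  sizes <- read_chrom_sizes(inp$sizes)
  ann <- read_gene_annotation(inp$genes, inp$sizes)
  dialect <- inp$dialect %||% "dense"
  matrices <- lapply(stats::setNames(nm = names(inp$contacts)), function(ct) {
    paths <- inp$contacts[[ct]]
    lapply(stats::setNames(nm = names(paths)), function(chrom)
      read_contact_matrix(paths[[chrom]], chrom, ct, inp$resolution,
                          sizes[[chrom]], dialect))
  })
  coexpr <- read_mutual_ranks(inp$mutual_ranks)
  net <- read_tf_targets(inp$tf_targets)
  goann <- NULL; dag <- NULL
  if (!is.null(inp$obo)) {
    dag <- read_obo_subset(inp$obo)
    goann <- read_gene_go(inp$gene_go, dag)
  }
  table <- build_pair_table(ann, matrices, coexpr, net, goann, dag,
                            thresholds)
  results <- analyze_pair_table(table, thresholds)
  results$metadata$seed <- config$seed %||% NA
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(results, file.path(out_dir, "results.json"))
    write_pair_table(table, file.path(out_dir, "pair_table.tsv"))
    cts <- table$meta$cell_types
    matched <- rank_match_filter(table, cts[1L], cts[2L],
                                 (utils::modifyList(default_thresholds(),
                                                    thresholds))$rank_match)
    write_panel_series(matched, results, out_dir)
  }
  results
}

# Group-mean TSV per stratum/measure/cell-type panel.
write_panel_series <- function(matched, results, out_dir) {
  cfg <- results$metadata$thresholds
  tabs <- list(all = matched,
               distant = stratify(matched, "distant", cfg$distant),
               tcs_zero = stratify(matched, "tcs_zero"),
               tcs_nonzero = stratify(matched, "tcs_nonzero"),
               coexpressed = stratify(matched, "coexpressed",
                                      cfg$mr_coexpressed))
  for (st in names(tabs)) {
    p <- tabs[[st]]$pairs
    for (measure in c("oh", "pc")) for (ct in results$metadata$cell_types) {
      y <- p[[paste0(measure, "_", ct)]]
      ok <- is.finite(p$mutual_rank) & is.finite(y)
      if (sum(ok) < 3L) next
      groups <- equal_size_binning(p$mutual_rank[ok], cfg$n_groups)
      series <- binned_series(p$mutual_rank[ok], y[ok], groups, cfg$n_groups)
      utils::write.table(series,
                         file.path(out_dir, sprintf("groups_%s_%s_%s.tsv",
                                                    st, measure, ct)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(NULL)
}
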