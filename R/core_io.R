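# Domain types and readers/writers for every external format the pipeline
# touches. Coordinates are BED-convention 0-based half-open throughout; bin k
# covers [k*res, (k+1)*res). Strand is read but ignored downstream.

#' Read a two-column chromosome sizes table
#'
#' @param path tab-separated file with columns chromosome name and length (bp).
#' @return named integer-valued numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"),
                          col.names = c("chrom", "length"))
  if (anyDuplicated(df$chrom))
    stop_chromex("duplicate chromosome name in ", path,
                 class = "chromex_validation_error")
  if (any(!is.finite(df$length) | df$length <= 0 | df$length != floor(df$length)))
    stop_chromex("chromosome lengths must be positive integers in ", path,
                 class = "chromex_validation_error")
  stats::setNames(df$length, df$chrom)
}

new_gene_annotation <- function(genes, sizes) {
  structure(list(genes = genes, sizes = sizes), class = "GeneAnnotation")
}

#' Read a BED6 gene annotation
#'
#' Parses a 6-column BED file (chrom, start, end, name, score, strand;
#' 0-based half-open) and validates every gene against the accompanying
#' chromosome sizes: `0 <= start < end <= chrom_length`, known chromosome,
#' unique gene id, strand in `+`, `-`, `.`.
#'
#' @param path BED6 file.
#' @param sizes_path two-column chrom sizes TSV (see [read_chrom_sizes()]).
#' @return a `GeneAnnotation`: list with `genes` (data.frame `id`, `chrom`,
#'   `start`, `end`, `strand`, sorted by chromosome then start) and `sizes`.
#' @export
read_gene_annotation <- function(path, sizes_path) {
  sizes <- read_chrom_sizes(sizes_path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(new_gene_annotation(
      data.frame(id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(),
                 stringsAsFactors = FALSE), sizes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 6L))
    stop_chromex("BED6 parse error at line ", which(n_fields != 6L)[1L],
                 ": expected 6 tab-separated fields, got ",
                 n_fields[which(n_fields != 6L)[1L]],
                 class = "chromex_parse_error")
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop_chromex("BED6 parse error at line ", bad[1L],
                 ": non-numeric coordinate", class = "chromex_parse_error")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop_chromex("BED6 validation error at line ", bad[1L],
                 ": requires 0 <= start < end",
                 class = "chromex_validation_error")
  bad <- which(!(m[, 6L] %in% c("+", "-", ".")))
  if (length(bad))
    stop_chromex("BED6 parse error at line ", bad[1L], ": bad strand '",
                 m[bad[1L], 6L], "'", class = "chromex_parse_error")
  bad <- which(!(m[, 1L] %in% names(sizes)))
  if (length(bad))
    stop_chromex("BED6 validation error at line ", bad[1L],
                 ": unknown chromosome '", m[bad[1L], 1L], "'",
                 class = "chromex_validation_error")
  bad <- which(end > sizes[m[, 1L]])
  if (length(bad))
    stop_chromex("BED6 validation error at line ", bad[1L],
                 ": gene interval exceeds chromosome length",
                 class = "chromex_validation_error")
  if (anyDuplicated(m[, 4L]))
    stop_chromex("duplicate gene id '", m[duplicated(m[, 4L]), 4L][1L], "'",
                 class = "chromex_validation_error")
  genes <- data.frame(id = m[, 4L], chrom = m[, 1L], start = start, end = end,
                      strand = m[, 6L], stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  new_gene_annotation(genes, sizes)
}

new_contact_matrix <- function(counts, chrom, cell_type, resolution, n_bins) {
  if (!is.matrix(counts) || nrow(counts) != n_bins || ncol(counts) != n_bins)
    stop_chromex("contact matrix must be ", n_bins, "x", n_bins,
                 class = "chromex_validation_error")
  if (any(!is.finite(counts)))
    stop_chromex("contact matrix entries must be finite",
                 class = "chromex_validation_error")
  if (any(counts < 0))
    stop_chromex("contact matrix entries must be non-negative",
                 class = "chromex_validation_error")
  if (max(abs(counts - t(counts))) > 1e-9)
    stop_chromex("contact matrix is asymmetric beyond tolerance 1e-9",
                 class = "chromex_validation_error")
  dimnames(counts) <- NULL
  storage.mode(counts) <- "double"
  structure(list(chrom = chrom, cell_type = cell_type,
                 resolution = resolution, counts = counts, n_bins = n_bins),
            class = "ContactMatrix")
}

#' Read a per-chromosome Hi-C contact matrix
#'
#' Two dialects are supported. `dense`: a square tab-separated matrix whose
#' first row and first column carry the bin start coordinates. `coo`: a
#' three-column TSV of (bin_i, bin_j, count) with 0-based bin indices; entries
#' are mirrored across the diagonal and absent cells are zero.
#'
#' @param path input file.
#' @param chrom chromosome name.
#' @param cell_type cell-type label.
#' @param resolution bin width in bp.
#' @param chrom_length chromosome length in bp; `n_bins = ceiling(length/res)`.
#' @param dialect `"dense"` or `"coo"`.
#' @return a `ContactMatrix` (symmetric, non-negative, finite).
#' @export
read_contact_matrix <- function(path, chrom, cell_type, resolution,
                                chrom_length, dialect = c("dense", "coo")) {
  dialect <- match.arg(dialect)
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  if (dialect == "dense") {
    raw <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    counts <- raw[-1L, -1L, drop = FALSE]
    storage.mode(counts) <- "double"
    if (nrow(counts) != n_bins || ncol(counts) != n_bins)
      stop_chromex("dense matrix in ", path, " is ", nrow(counts), "x",
                   ncol(counts), ", expected ", n_bins, "x", n_bins,
                   class = "chromex_validation_error")
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("i", "j", "count"))
    if (nrow(df) && (any(df$i != floor(df$i)) || any(df$j != floor(df$j))))
      stop_chromex("coo bin indices must be integers",
                   class = "chromex_validation_error")
    if (nrow(df) && (any(df$i < 0) || any(df$j < 0) ||
                     any(df$i >= n_bins) || any(df$j >= n_bins)))
      stop_chromex("coo bin index out of range [0, ", n_bins - 1L, "]",
                   class = "chromex_validation_error")
    if (nrow(df) && any(df$count < 0))
      stop_chromex("negative contact count in ", path,
                   class = "chromex_validation_error")
    key <- pair_key(df$i, df$j)
    if (anyDuplicated(key))
      stop_chromex("duplicate coo cell (after mirroring) in ", path,
                   class = "chromex_validation_error")
    counts <- matrix(0, n_bins, n_bins)
    counts[cbind(df$i + 1L, df$j + 1L)] <- df$count
    counts[cbind(df$j + 1L, df$i + 1L)] <- df$count
  }
  new_contact_matrix(counts, chrom, cell_type, resolution, n_bins)
}

#' Write a contact matrix in the dense dialect
#'
#' @param m a `ContactMatrix`.
#' @param path output path.
#' @export
write_contact_matrix <- function(m, path) {
  starts <- (seq_len(m$n_bins) - 1L) * m$resolution
  out <- rbind(c(NA, starts), cbind(starts, m$counts))
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "bin")
  invisible(path)
}

#' Read a TF-to-target edge list
#'
#' Two-column TSV (tf_id, target_gene_id). Exact duplicate edges are dropped
#' with a warning.
#'
#' @param path input TSV.
#' @return a `RegulatoryNetwork`: list with `edges` data.frame and a
#'   precomputed `tf_sets` (named list gene id -> character vector of TFs).
#' @export
read_tf_targets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("tf", "target"))
  new_regulatory_network(df)
}

new_regulatory_network <- function(edges) {
  if (any(!nzchar(edges$tf)) || any(!nzchar(edges$target)))
    stop_chromex("TF and target ids must be non-empty strings",
                 class = "chromex_validation_error")
  dup <- duplicated(paste(edges$tf, edges$target, sep = "\x1f"))
  if (any(dup)) {
    warning(sum(dup), " duplicate TF-target edge(s) dropped",
            call. = FALSE)
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 tf_sets = split(edges$tf, edges$target)),
            class = "RegulatoryNetwork")
}

#' TF set of one gene
#'
#' @param net a `RegulatoryNetwork`.
#' @param gene gene id.
#' @return character vector of TF ids regulating `gene` (possibly empty).
#' @export
tf_set <- function(net, gene) {
  net$tf_sets[[gene]] %||% character()
}

#' Read a mutual-rank co-expression table
#'
#' Three-column TSV (gene_a, gene_b, mutual_rank). Keys are unordered; a pair
#' stored twice with the same value is deduplicated, with conflicting values
#' it is an error. Mutual ranks must be >= 1.
#'
#' @param path input TSV.
#' @return a `CoexpressionTable`.
#' @export
read_mutual_ranks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "character", "numeric"),
                          col.names = c("a", "b", "mr"))
  key <- pair_key(df$a, df$b)
  if (anyDuplicated(key)) {
    agg <- tapply(df$mr, key, function(v) diff(range(v)))
    if (any(agg > 1e-9))
      stop_chromex("conflicting mutual-rank values for pair ",
                   gsub("\x1f", "/", names(agg)[agg > 1e-9][1L]),
                   class = "chromex_validation_error")
    keep <- !duplicated(key)
    df <- df[keep, , drop = FALSE]
    key <- key[keep]
  }
  new_coexpression_table(stats::setNames(df$mr, key))
}

new_coexpression_table <- function(mr) {
  if (length(mr) && any(!is.finite(mr) | mr < 1))
    stop_chromex("mutual ranks must be finite and >= 1",
                 class = "chromex_validation_error")
  structure(list(mr = mr), class = "CoexpressionTable")
}

#' Write a mutual-rank table (inverse of [read_mutual_ranks()])
#' @param table a `CoexpressionTable`.
#' @param path output TSV path.
#' @export
write_mutual_ranks <- function(table, path) {
  parts <- strsplit(names(table$mr), "\x1f", fixed = TRUE)
  df <- data.frame(a = vapply(parts, `[[`, "", 1L),
                   b = vapply(parts, `[[`, "", 2L),
                   mr = format(unname(table$mr), digits = 15,
                               scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GO DAG from an OBO subset
#'
#' Parses `[Term]` stanzas recognising `id:`, `is_a:`,
#' `relationship: part_of`, and (when present) `namespace:`, which must be
#' `biological_process`. Edge endpoints must be declared terms and the graph
#' must be acyclic.
#'
#' @param path OBO file.
#' @param weights named semantic-contribution weights per relation, each
#'   strictly inside (0, 1). Defaults are the Wang-method constants.
#' @return a `GoDAG`: list with `terms`, `edges` (data.frame `child`,
#'   `parent`, `relation`), `weights`, `roots`, and parent/child adjacency.
#' @export
read_obo_subset <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
  lines <- trimws(readLines(path))
  in_term <- FALSE
  cur <- NULL
  terms <- character()
  child <- character(); parent <- character(); relation <- character()
  flush_ns <- function(ns, id) {
    if (!is.null(ns) && ns != "biological_process")
      stop_chromex("term ", id, " is in namespace '", ns,
                   "'; only biological_process is supported",
                   class = "chromex_validation_error")
  }
  ns <- NULL
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      flush_ns(ns, cur); ns <- NULL; cur <- NULL
      in_term <- identical(ln, "[Term]")
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur)
    } else if (startsWith(ln, "namespace:")) {
      ns <- trimws(sub("^namespace:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      child <- c(child, cur); parent <- c(parent, tgt)
      relation <- c(relation, "is_a")
    } else if (startsWith(ln, "relationship:")) {
      rest <- trimws(sub("^relationship:", "", ln))
      toks <- strsplit(sub("!.*$", "", rest), "[ \t]+")[[1L]]
      if (length(toks) >= 2L && toks[1L] == "part_of") {
        child <- c(child, cur); parent <- c(parent, toks[2L])
        relation <- c(relation, "part_of")
      }
    }
  }
  flush_ns(ns, cur)
  edges <- data.frame(child = child, parent = parent, relation = relation,
                      stringsAsFactors = FALSE)
  new_go_dag(terms, edges, weights)
}

new_go_dag <- function(terms, edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (anyDuplicated(terms))
    stop_chromex("duplicate term id", class = "chromex_validation_error")
  if (any(weights <= 0) || any(weights >= 1))
    stop_chromex("edge weights must be strictly between 0 and 1",
                 class = "chromex_validation_error")
  unknown <- setdiff(c(edges$child, edges$parent), terms)
  if (length(unknown))
    stop_chromex("edge endpoint '", unknown[1L], "' is not a declared term",
                 class = "chromex_validation_error")
  if (nrow(edges) && any(!edges$relation %in% names(weights)))
    stop_chromex("edge relation without a weight",
                 class = "chromex_validation_error")
  parents_of <- split(edges$parent, edges$child)
  children_of <- split(edges$child, edges$parent)
  # Kahn's algorithm, peeling leaves upward: a term is removable once every
  # term listing it as a parent has been removed.
  cnt <- stats::setNames(integer(length(terms)), terms)
  tab <- table(edges$parent)
  cnt[names(tab)] <- as.integer(tab)
  queue <- terms[cnt[terms] == 0L]
  seen <- 0L
  while (length(queue)) {
    t0 <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in parents_of[[t0]] %||% character()) {
      cnt[[p]] <- cnt[[p]] - 1L
      if (cnt[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(terms))
    stop_chromex("GO graph contains a cycle",
                 class = "chromex_validation_error")
  roots <- setdiff(terms, unique(edges$child))
  structure(list(terms = terms, edges = edges, weights = weights,
                 roots = roots, parents_of = parents_of,
                 children_of = children_of),
            class = "GoDAG")
}

#' Read gene-to-GO-term annotations
#'
#' @param path two-column TSV (gene id, term id).
#' @param dag the `GoDAG` the terms must belong to.
#' @return a `GeneGoAnnotation`: named list gene id -> character vector of
#'   term ids.
#' @export
read_gene_go <- function(path, dag) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("gene", "term"))
  unknown <- setdiff(df$term, dag$terms)
  if (length(unknown))
    stop_chromex("annotation to unknown term '", unknown[1L], "'",
                 class = "chromex_validation_error")
  ann <- lapply(split(df$term, df$gene), unique)
  structure(ann, class = "GeneGoAnnotation")
}

# Fixed column order of the pair-table TSV. Per-cell-type columns
# (oh_<ct>, pc_<ct>, rank_pct_<ct>) are inserted after `chrom`.
pair_table_scalar_cols <- c("mutual_rank", "tcs", "norm_dist", "go_sim")

#' Write a gene-pair table as a headered TSV
#'
#' Column order: gene_a, gene_b, chrom, then oh_/pc_/rank_pct_ per cell type,
#' then mutual_rank, tcs, norm_dist, go_sim.
#'
#' @param table a `GenePairTable`.
#' @param path output path.
#' @export
write_pair_table <- function(table, path) {
  df <- table$pairs
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), NA, format(x, digits = 15, scientific = FALSE,
                                trim = TRUE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Re-read a pair table written by [write_pair_table()]
#'
#' @param path TSV path.
#' @param meta optional provenance list to attach.
#' @return a `GenePairTable`.
#' @export
read_pair_table <- function(path, meta = list()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  for (col in names(df)) {
    if (col %in% c("gene_a", "gene_b", "chrom"))
      df[[col]] <- as.character(df[[col]])
    else
      df[[col]] <- as.numeric(df[[col]])
  }
  new_gene_pair_table(df, meta)
}

new_gene_pair_table <- function(pairs, meta = list()) {
  if (nrow(pairs) && any(pairs$gene_a >= pairs$gene_b))
    stop_chromex("pair records must satisfy gene_a < gene_b",
                 class = "chromex_validation_error")
  if (anyDuplicated(pair_key(pairs$gene_a, pairs$gene_b)))
    stop_chromex("duplicate unordered gene pair",
                 class = "chromex_validation_error")
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, meta = meta), class = "GenePairTable")
}

#' @export
print.GenePairTable <- function(x, ...) {
  cat("GenePairTable:", nrow(x$pairs), "pairs,",
      length(x$meta$cell_types %||% character()), "cell type(s)\n")
  if (length(x$meta$filters))
    cat("filters:", paste(names(x$meta$filters), collapse = ", "), "\n")
  invisible(x)
}

#' Write analysis results as JSON
#'
#' @param results an `AnalysisResults` list as produced by
#'   [analyze_pair_table()] / [run_full_analysis()].
#' @param path output JSON path.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(unclass(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       na = "null")
  invisible(path)
}
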