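# Independent reference implementations (loops, enumeration, counting) used
# to cross-check the vectorized package code, plus tiny fixture builders.

make_gene <- function(id, chrom, start, end, strand = "+") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

make_contact <- function(counts, chrom = "chr1", cell_type = "cellA",
                         resolution = 10) {
  chromex:::new_contact_matrix(counts, chrom, cell_type, resolution,
                               nrow(counts))
}

random_symmetric_counts <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rpois(n * n, 8), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# --- hic_metrics oracles ----------------------------------------------------

oracle_expected_by_distance <- function(counts) {
  n <- nrow(counts)
  e <- numeric(n)
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in 1:(n - d)) vals <- c(vals, counts[i, i + d])
    e[d + 1] <- mean(vals)
  }
  e
}

# Pearson of two rows over columns defined in both; NA below 3 shared points
# or at zero variance.
oracle_two_row_pearson <- function(oe, i, j) {
  ok <- !is.na(oe[i, ]) & !is.na(oe[j, ])
  if (sum(ok) < 3) return(NA_real_)
  a <- oe[i, ok]; b <- oe[j, ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Nested-loop gene-pair interaction: explicit per-bin overlap arithmetic.
oracle_gene_pair_interaction <- function(gene_a, gene_b, mat, resolution) {
  overlap <- function(g, k)
    max(0, min(g$end, (k + 1) * resolution) - max(g$start, k * resolution))
  n_bins <- nrow(mat)
  num <- 0; den <- 0
  for (k in 0:(n_bins - 1)) for (l in 0:(n_bins - 1)) {
    wa <- overlap(gene_a, k) / (gene_a$end - gene_a$start)
    wb <- overlap(gene_b, l) / (gene_b$end - gene_b$start)
    if (wa == 0 || wb == 0) next
    v <- mat[k + 1, l + 1]
    if (is.na(v)) next
    num <- num + wa * wb * v
    den <- den + wa * wb
  }
  if (den == 0) NA_real_ else num / den
}

# --- pair_metrics oracle ----------------------------------------------------

oracle_tcs <- function(a, b) {
  a <- unique(a); b <- unique(b)
  sym <- length(setdiff(a, b)) + length(setdiff(b, a))
  1 - sym / (length(a) + length(b))
}

# --- go_semsim oracles ------------------------------------------------------

# Random DAG: edges always point to lower-numbered terms, hence acyclic.
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(n_terms))
  child <- character(); parent <- character(); rel <- character()
  for (i in 2:n_terms) {
    k <- sample(seq_len(min(2L, i - 1L)), 1L)
    ps <- sample(seq_len(i - 1L), k)
    child <- c(child, rep(terms[i], k))
    parent <- c(parent, terms[ps])
    rel <- c(rel, sample(c("is_a", "part_of"), k, replace = TRUE))
  }
  chromex:::new_go_dag(terms, data.frame(child = child, parent = parent,
                                         relation = rel,
                                         stringsAsFactors = FALSE))
}

# Exhaustive path enumeration: S_A(t) = max over all directed paths a -> t of
# the product of edge weights along the path.
oracle_s_values <- function(dag, a) {
  best <- new.env(parent = emptyenv())
  assign(a, 1, envir = best)
  dfs <- function(term, prod) {
    es <- dag$edges[dag$edges$child == term, , drop = FALSE]
    for (r in seq_len(nrow(es))) {
      p <- es$parent[r]
      np <- prod * dag$weights[[es$relation[r]]]
      old <- if (exists(p, envir = best)) get(p, envir = best) else -Inf
      if (np > old) assign(p, np, envir = best)
      dfs(p, np)
    }
  }
  dfs(a, 1)
  unlist(as.list(best))
}

oracle_term_similarity <- function(dag, a, b) {
  sa <- oracle_s_values(dag, a)
  sb <- oracle_s_values(dag, b)
  shared <- intersect(names(sa), names(sb))
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# --- synthetic_data oracle --------------------------------------------------

# Counting-based double ranking: rank of h among g's partners is one plus the
# number of strictly larger correlations, plus half the ties.
oracle_mutual_ranks <- function(expr) {
  cc <- cor(t(expr))
  ids <- rownames(expr)
  n <- length(ids)
  rk <- function(g, h) {
    others <- setdiff(seq_len(n), g)
    v <- cc[g, others]
    x <- cc[g, h]
    1 + sum(v > x) + (sum(v == x) - 1) / 2
  }
  out <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    out[chromex:::pair_key(ids[i], ids[j])] <- sqrt(rk(i, j) * rk(j, i))
  }
  out
}

# --- binning oracle ---------------------------------------------------------

# Sorted sweep: walk samples in x order; every tie block is assigned, whole,
# to the quantile group of its first sorted position.
oracle_binning <- function(x, n_groups) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  g <- integer(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && xs[j + 1] == xs[i]) j <- j + 1
    g[o[i:j]] <- ceiling(i * n_groups / n)
    i <- j + 1
  }
  g
}

# Pair table with hand-assigned columns, for filter/stratum tests.
hand_pair_table <- function(df, cell_types = c("cellA", "cellB")) {
  chromex:::new_gene_pair_table(df, meta = list(cell_types = cell_types,
                                                rank_measure = "oh",
                                                n_genes = NA,
                                                filters = list()))
}
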