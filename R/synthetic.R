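# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes: intra-chromosomal contact decay with distance, compartment
# block structure shared (or not) between two cell types, expression profiles
# whose pairwise correlation is coupled to compartment membership with
# tunable strength beta, a sparse bipartite TF network, and a small GO DAG
# whose annotation sharing is optionally coupled to spatial proximity (gamma).
#
# Each top-level simulate_* call seeds the RNG from cfg$seed plus a fixed
# per-component offset, so individual components and whole bundles are both
# reproducible.

#' Simulation configuration
#'
#' Defaults define the package's stated world: 2 chromosomes of 30 Mb at 1 Mb
#' bins, 300 genes, 40 TFs with mean out-degree 17, 60 expression conditions,
#' power-law contact decay with exponent 1, 6 compartment segments per
#' chromosome with contact boost kappa = 3, base diagonal intensity 100
#' counts, GO tree of depth 4 / branching 3 with 20% part_of edges.
#' `beta = 0` is the null regime (expression decoupled from chromatin);
#' `beta = 0.9` is the documented strong-coupling preset.
#'
#' @param n_chromosomes,chrom_length,resolution genome shape.
#' @param n_genes,n_tfs,tf_mean_degree,n_conditions cohort sizes.
#' @param decay_alpha contact decay exponent (> 0).
#' @param n_blocks compartment segments per chromosome.
#' @param kappa same-compartment contact boost (>= 1).
#' @param base_contacts Poisson intensity at the diagonal.
#' @param beta contact-to-expression coupling strength in `[0, 1]`: expected
#'   expression correlation of same-compartment genes (with `sigma = 1`).
#' @param sigma expression noise scale; the within-compartment correlation is
#'   `beta / (beta + (1 - beta) * sigma^2)`.
#' @param shared_fraction fraction of compartment segments shared between the
#'   two cell types.
#' @param gamma probability that a gene copies a same-compartment neighbour's
#'   GO leaf annotation (0 = no functional-proximity coupling).
#' @param go_depth,go_branching,go_part_of_fraction GO DAG shape.
#' @param tf_block_bias probability that a TF's targets are drawn from a
#'   single compartment (regulatory-proximity coupling).
#' @param seed integer seed.
#' @return a validated `SimulationConfig` list.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length = 30e6,
                       resolution = 1e6, n_genes = 300L, n_tfs = 40L,
                       tf_mean_degree = 17, n_conditions = 60L,
                       decay_alpha = 1, n_blocks = 6L, kappa = 3,
                       base_contacts = 100, beta = 0, sigma = 1,
                       shared_fraction = 1, gamma = 0, go_depth = 4L,
                       go_branching = 3L, go_part_of_fraction = 0.2,
                       tf_block_bias = 0, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, resolution = resolution,
              n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              tf_mean_degree = tf_mean_degree,
              n_conditions = as.integer(n_conditions),
              decay_alpha = decay_alpha, n_blocks = as.integer(n_blocks),
              kappa = kappa, base_contacts = base_contacts, beta = beta,
              sigma = sigma, shared_fraction = shared_fraction,
              gamma = gamma, go_depth = as.integer(go_depth),
              go_branching = as.integer(go_branching),
              go_part_of_fraction = go_part_of_fraction,
              tf_block_bias = tf_block_bias, seed = as.integer(seed))
  for (f in c("n_chromosomes", "chrom_length", "resolution", "n_tfs",
              "tf_mean_degree", "n_conditions", "n_blocks", "go_depth",
              "go_branching"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_chromex(f, " must be positive", class = "chromex_config_error")
  if (cfg$n_genes < 0)
    stop_chromex("n_genes must be non-negative",
                 class = "chromex_config_error")
  if (cfg$resolution > cfg$chrom_length)
    stop_chromex("resolution must not exceed chrom_length",
                 class = "chromex_config_error")
  if (cfg$beta < 0 || cfg$beta > 1)
    stop_chromex("beta must lie in [0, 1]", class = "chromex_config_error")
  if (cfg$decay_alpha <= 0)
    stop_chromex("decay_alpha must be > 0", class = "chromex_config_error")
  if (cfg$kappa < 1)
    stop_chromex("kappa must be >= 1", class = "chromex_config_error")
  if (cfg$gamma < 0 || cfg$gamma > 1 || cfg$shared_fraction < 0 ||
      cfg$shared_fraction > 1)
    stop_chromex("gamma and shared_fraction must lie in [0, 1]",
                 class = "chromex_config_error")
  structure(cfg, class = "SimulationConfig")
}

seed_for <- function(cfg, component) {
  offset <- match(component, c("genome", "compartments", "contacts_a",
                               "contacts_b", "expression", "tf", "go"))
  set.seed((cfg$seed %% 20000000L) * 101L + offset)
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chromosomes))

#' Simulate a gene annotation
#'
#' Genes are divided evenly across chromosomes; lengths are log-uniform in
#' `[5 kb, 200 kb]`; placement is uniform without overlap (sorted uniform
#' gaps plus cumulative lengths, an exact non-overlapping scheme).
#'
#' @param cfg a `SimulationConfig`.
#' @return a `GeneAnnotation`.
#' @export
simulate_genome <- function(cfg) {
  seed_for(cfg, "genome")
  chroms <- sim_chrom_names(cfg)
  sizes <- stats::setNames(rep(cfg$chrom_length, length(chroms)), chroms)
  if (cfg$n_genes == 0L)
    return(new_gene_annotation(
      data.frame(id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(),
                 stringsAsFactors = FALSE), sizes))
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out =
                                length(chroms) + 1L)))
  rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    len <- round(10^stats::runif(n, log10(5e3), log10(2e5)))
    if (sum(len) >= cfg$chrom_length)
      stop_chromex("gene density too high: total gene length exceeds the ",
                   "chromosome", class = "chromex_config_error")
    gaps <- sort(stats::runif(n, 0, cfg$chrom_length - sum(len)))
    start <- round(gaps) + c(0, cumsum(len[-n]))
    rows[[ci]] <- data.frame(
      id = sprintf("g%04d", gid + seq_len(n)),
      chrom = chroms[ci], start = start, end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    gid <- gid + n
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  new_gene_annotation(genes, sizes)
}

#' Simulate compartment block assignments
#'
#' Each chromosome is split into `n_blocks` contiguous segments of bins; each
#' segment gets compartment label 1 or 2 (open/closed stand-in). Returns the
#' per-bin label vector per chromosome.
#'
#' @param cfg a `SimulationConfig`.
#' @return named list: chromosome -> integer vector (one label per bin).
#' @export
simulate_compartments <- function(cfg) {
  seed_for(cfg, "compartments")
  n_bins <- as.integer(ceiling(cfg$chrom_length / cfg$resolution))
  out <- lapply(sim_chrom_names(cfg), function(chrom) {
    seg <- as.integer(cut(seq_len(n_bins), cfg$n_blocks, labels = FALSE))
    labels <- sample(1:2, cfg$n_blocks, replace = TRUE)
    labels[seg]
  })
  stats::setNames(out, sim_chrom_names(cfg))
}

#' Derive a second cell type's compartments
#'
#' Keeps each segment's label with probability `shared_fraction`, otherwise
#' redraws it, modelling partially conserved compartmentalization between
#' cell types.
#'
#' @param cfg a `SimulationConfig`.
#' @param blocks compartments of the first cell type
#'   (from [simulate_compartments()]).
#' @return same shape as `blocks`.
#' @export
perturb_compartments <- function(cfg, blocks) {
  seed_for(cfg, "contacts_b")
  n_bins <- length(blocks[[1L]])
  lapply(blocks, function(lab) {
    seg <- as.integer(cut(seq_len(n_bins), cfg$n_blocks, labels = FALSE))
    seg_lab <- lab[match(seq_len(cfg$n_blocks), seg)]
    redraw <- stats::runif(cfg$n_blocks) > cfg$shared_fraction
    seg_lab[redraw] <- sample(1:2, sum(redraw), replace = TRUE)
    seg_lab[seg]
  })
}

#' Simulate per-chromosome contact matrices
#'
#' Counts are Poisson with mean
#' `base * (1 + |i - j|)^(-alpha) * kappa^[same compartment]`; the upper
#' triangle is sampled and mirrored.
#'
#' @param cfg a `SimulationConfig`.
#' @param blocks per-bin compartment labels per chromosome.
#' @param cell_type label stored in the matrices.
#' @return named list: chromosome -> `ContactMatrix`.
#' @export
simulate_contacts <- function(cfg, blocks, cell_type = "cellA") {
  seed_for(cfg, if (cell_type == "cellA") "contacts_a" else "contacts_b")
  n_bins <- as.integer(ceiling(cfg$chrom_length / cfg$resolution))
  out <- lapply(sim_chrom_names(cfg), function(chrom) {
    lab <- blocks[[chrom]]
    d <- abs(row(diag(n_bins)) - col(diag(n_bins)))
    same <- outer(lab, lab, "==")
    mu <- cfg$base_contacts * (1 + d)^(-cfg$decay_alpha) *
      ifelse(same, cfg$kappa, 1)
    counts <- matrix(0, n_bins, n_bins)
    ut <- upper.tri(counts, diag = TRUE)
    counts[ut] <- stats::rpois(sum(ut), mu[ut])
    counts <- counts + t(counts) - diag(diag(counts))
    new_contact_matrix(counts, chrom, cell_type, cfg$resolution, n_bins)
  })
  stats::setNames(out, sim_chrom_names(cfg))
}

gene_block_keys <- function(ann, blocks, resolution) {
  mid <- (ann$genes$start + ann$genes$end) / 2
  bin <- pmin(floor(mid / resolution) + 1L,
              lengths(blocks)[ann$genes$chrom])
  lab <- mapply(function(chrom, b) blocks[[chrom]][b],
                ann$genes$chrom, bin)
  stats::setNames(paste(ann$genes$chrom, lab, sep = ":"), ann$genes$id)
}

#' Simulate expression profiles coupled to compartments
#'
#' Gene `g`'s profile is `sqrt(beta) * f[key(g)] + sqrt(1 - beta) * sigma *
#' noise` with one standard-normal factor per (chromosome, compartment label)
#' and independent noise, so two genes sharing a compartment have expected
#' correlation `beta / (beta + (1 - beta) sigma^2)` (= `beta` at the default
#' `sigma = 1`) and unrelated genes 0.
#'
#' @param cfg a `SimulationConfig`.
#' @param ann a `GeneAnnotation`.
#' @param blocks per-bin compartment labels per chromosome.
#' @return numeric matrix genes x conditions, rownames = gene ids.
#' @export
simulate_expression <- function(cfg, ann, blocks) {
  seed_for(cfg, "expression")
  keys <- gene_block_keys(ann, blocks, cfg$resolution)
  ukeys <- unique(keys)
  factors <- matrix(stats::rnorm(length(ukeys) * cfg$n_conditions),
                    length(ukeys), cfg$n_conditions,
                    dimnames = list(ukeys, NULL))
  noise <- matrix(stats::rnorm(nrow(ann$genes) * cfg$n_conditions),
                  nrow(ann$genes), cfg$n_conditions)
  expr <- sqrt(cfg$beta) * factors[keys, , drop = FALSE] +
    sqrt(1 - cfg$beta) * cfg$sigma * noise
  rownames(expr) <- ann$genes$id
  expr
}

#' Mutual ranks from an expression matrix
#'
#' For each ordered pair, the rank of `cor(g, h)` among `g`'s partners
#' (rank 1 = highest correlation, average ranks on ties); the mutual rank is
#' the geometric mean `sqrt(rank_g(h) * rank_h(g))`, stored per unordered
#' pair. Genes with constant profiles have undefined correlations and their
#' pairs are omitted.
#'
#' @param expr genes x conditions matrix with unique rownames.
#' @return a `CoexpressionTable`.
#' @export
mutual_ranks_from_expression <- function(expr) {
  if (ncol(expr) < 3L)
    stop_chromex("mutual ranks need >= 3 conditions",
                 class = "chromex_usage_error")
  cc <- suppressWarnings(stats::cor(t(expr)))
  diag(cc) <- NA_real_
  rk <- t(apply(-cc, 1L, rank, ties.method = "average", na.last = "keep"))
  # rank() places NAs last but still counts them when na.last = TRUE; with
  # na.last = "keep" they stay NA and non-missing ranks are 1..n_defined.
  mr <- sqrt(rk * t(rk))
  ids <- rownames(expr)
  iu <- which(upper.tri(mr), arr.ind = TRUE)
  vals <- mr[iu]
  ok <- !is.na(vals)
  new_coexpression_table(stats::setNames(
    vals[ok], pair_key(ids[iu[ok, 1L]], ids[iu[ok, 2L]])))
}

#' Simulate a sparse bipartite TF-target network
#'
#' Each TF regulates `max(1, Poisson(mean degree))` distinct genes. With
#' probability `tf_block_bias` a TF's targets are drawn from a single
#' (chromosome, compartment) key, coupling shared regulation to proximity.
#'
#' @param cfg a `SimulationConfig`.
#' @param ann a `GeneAnnotation`.
#' @param blocks compartments (only needed when `tf_block_bias > 0`).
#' @return a `RegulatoryNetwork`.
#' @export
simulate_tf_network <- function(cfg, ann, blocks = NULL) {
  seed_for(cfg, "tf")
  ids <- ann$genes$id
  keys <- if (!is.null(blocks)) gene_block_keys(ann, blocks, cfg$resolution)
  edges <- list()
  for (ti in seq_len(cfg$n_tfs)) {
    tf_id <- sprintf("tf%03d", ti)
    pool <- ids
    if (!is.null(keys) && cfg$tf_block_bias > 0 &&
        stats::runif(1) < cfg$tf_block_bias) {
      k <- sample(unique(keys), 1L)
      pool <- ids[keys == k]
    }
    deg <- min(length(pool), max(1L, stats::rpois(1L, cfg$tf_mean_degree)))
    edges[[ti]] <- data.frame(tf = tf_id,
                              target = sample(pool, deg),
                              stringsAsFactors = FALSE)
  }
  new_regulatory_network(do.call(rbind, edges))
}

#' Simulate a GO DAG and gene annotations
#'
#' The DAG is a rooted tree of the configured depth and branching with is_a
#' edges, a random fraction of which are relabelled part_of. Genes are
#' annotated to 1-3 leaves; with probability `gamma` a gene copies the leaf
#' of the first annotated gene in its compartment (its "neighbourhood
#' function"), so same-compartment pairs share a term with probability about
#' `gamma^2`, coupling functional similarity to spatial proximity.
#'
#' @param cfg a `SimulationConfig`.
#' @param ann a `GeneAnnotation`.
#' @param blocks per-bin compartment labels per chromosome.
#' @return list with elements `dag` (a `GoDAG`) and `ann`
#'   (a `GeneGoAnnotation`).
#' @export
simulate_go <- function(cfg, ann, blocks) {
  seed_for(cfg, "go")
  # breadth-first tree ids: level l has branching^l terms
  levels <- lapply(0:cfg$go_depth, function(l) cfg$go_branching^l)
  total <- sum(unlist(levels))
  terms <- sprintf("GO:%07d", seq_len(total))
  child <- character(); parent <- character()
  offset <- 1L
  for (l in seq_len(cfg$go_depth)) {
    n_parent <- cfg$go_branching^(l - 1L)
    n_child <- cfg$go_branching^l
    parents_lvl <- terms[offset:(offset + n_parent - 1L)]
    children_lvl <- terms[(offset + n_parent):(offset + n_parent + n_child - 1L)]
    child <- c(child, children_lvl)
    parent <- c(parent, rep(parents_lvl, each = cfg$go_branching))
    offset <- offset + n_parent
  }
  relation <- rep("is_a", length(child))
  n_po <- round(cfg$go_part_of_fraction * length(relation))
  if (n_po > 0) relation[sample(length(relation), n_po)] <- "part_of"
  dag <- new_go_dag(terms, data.frame(child = child, parent = parent,
                                      relation = relation,
                                      stringsAsFactors = FALSE))
  leaves <- setdiff(terms, unique(parent))
  keys <- gene_block_keys(ann, blocks, cfg$resolution)
  go_ann <- list()
  block_leaf <- list()  # canonical leaf per compartment key
  for (gid in ann$genes$id) {
    n_terms <- sample(1:3, 1L)
    picked <- sample(leaves, n_terms)
    key <- keys[[gid]]
    if (is.null(block_leaf[[key]])) block_leaf[[key]] <- picked[1L]
    if (cfg$gamma > 0 && stats::runif(1) < cfg$gamma) {
      picked[1L] <- block_leaf[[key]]
      picked <- unique(picked)
    }
    go_ann[[gid]] <- picked
  }
  list(dag = dag, ann = structure(go_ann, class = "GeneGoAnnotation"))
}

#' Simulate a complete in-memory input bundle
#'
#' Runs every generator in a fixed order under the configuration seed and
#' returns all pipeline inputs: annotation, compartments and contact matrices
#' for two cell types, the expression matrix and its mutual-rank table, the
#' TF network, and (optionally, `with_go = TRUE`) the GO DAG and annotations.
#'
#' @param cfg a `SimulationConfig`.
#' @param with_go also simulate the GO inputs (slower; off by default).
#' @return list with `cfg`, `ann`, `blocks` (per cell type), `contacts`
#'   (cell type -> chromosome -> `ContactMatrix`), `expr`, `coexpr`, `net`,
#'   `go` (or `NULL`).
#' @export
simulate_bundle <- function(cfg, with_go = FALSE) {
  ann <- simulate_genome(cfg)
  blocks_a <- simulate_compartments(cfg)
  blocks_b <- perturb_compartments(cfg, blocks_a)
  contacts <- list(cellA = simulate_contacts(cfg, blocks_a, "cellA"),
                   cellB = simulate_contacts(cfg, blocks_b, "cellB"))
  expr <- simulate_expression(cfg, ann, blocks_a)
  coexpr <- mutual_ranks_from_expression(expr)
  net <- simulate_tf_network(cfg, ann, blocks_a)
  go <- if (with_go) simulate_go(cfg, ann, blocks_a) else NULL
  list(cfg = cfg, ann = ann, blocks = list(cellA = blocks_a,
                                           cellB = blocks_b),
       contacts = contacts, expr = expr, coexpr = coexpr, net = net,
       go = go)
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' Emits genes.bed, chrom.sizes, one dense contact TSV per cell type and
#' chromosome, tf_targets.tsv, mutual_ranks.tsv, optionally go.obo and
#' gene_go.tsv, an `analysis_config.json` directly consumable by
#' [run_full_analysis()], and a manifest JSON with the configuration and MD5
#' checksums of every file.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- bundle$ann
  paths <- character()
  p <- file.path(dir, "chrom.sizes")
  utils::write.table(data.frame(names(ann$sizes),
                                format(ann$sizes, scientific = FALSE,
                                       trim = TRUE)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  paths["sizes"] <- p
  p <- file.path(dir, "genes.bed")
  utils::write.table(data.frame(ann$genes$chrom,
                                format(ann$genes$start, scientific = FALSE,
                                       trim = TRUE),
                                format(ann$genes$end, scientific = FALSE,
                                       trim = TRUE),
                                ann$genes$id, 0L, ann$genes$strand),
                     p, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  paths["genes"] <- p
  contact_paths <- list()
  for (ct in names(bundle$contacts)) {
    contact_paths[[ct]] <- list()
    for (chrom in names(bundle$contacts[[ct]])) {
      p <- file.path(dir, sprintf("contacts_%s_%s.tsv", ct, chrom))
      write_contact_matrix(bundle$contacts[[ct]][[chrom]], p)
      contact_paths[[ct]][[chrom]] <- p
      paths[sprintf("contacts_%s_%s", ct, chrom)] <- p
    }
  }
  p <- file.path(dir, "tf_targets.tsv")
  utils::write.table(bundle$net$edges, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths["tf_targets"] <- p
  p <- file.path(dir, "mutual_ranks.tsv")
  write_mutual_ranks(bundle$coexpr, p)
  paths["mutual_ranks"] <- p
  # config references files relative to its own directory, so a bundle can be
  # relocated and two same-seed bundles are byte-identical
  inputs <- list(genes = basename(paths[["genes"]]),
                 sizes = basename(paths[["sizes"]]),
                 contacts = lapply(contact_paths, function(x)
                   lapply(x, basename)),
                 dialect = "dense",
                 resolution = bundle$cfg$resolution,
                 tf_targets = basename(paths[["tf_targets"]]),
                 mutual_ranks = basename(paths[["mutual_ranks"]]))
  if (!is.null(bundle$go)) {
    p <- file.path(dir, "go.obo")
    write_obo_subset(bundle$go$dag, p)
    paths["obo"] <- p
    inputs$obo <- basename(p)
    p <- file.path(dir, "gene_go.tsv")
    df <- data.frame(gene = rep(names(bundle$go$ann),
                                lengths(bundle$go$ann)),
                     term = unlist(bundle$go$ann, use.names = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths["gene_go"] <- p
    inputs$gene_go <- basename(p)
  }
  config <- list(inputs = inputs, thresholds = list(),
                 seed = bundle$cfg$seed)
  p <- file.path(dir, "analysis_config.json")
  jsonlite::write_json(config, p, auto_unbox = TRUE, pretty = TRUE)
  paths["analysis_config"] <- p
  manifest <- list(config = unclass(bundle$cfg),
                   seed = bundle$cfg$seed,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(paths)),
                     basename(unname(paths)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Minimal OBO writer matching read_obo_subset's dialect.
write_obo_subset <- function(dag, path) {
  by_child <- split(seq_len(nrow(dag$edges)), dag$edges$child)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t0 in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t0),
                 "namespace: biological_process"), con)
    for (i in by_child[[t0]] %||% integer()) {
      if (dag$edges$relation[i] == "is_a")
        writeLines(paste0("is_a: ", dag$edges$parent[i]), con)
      else
        writeLines(paste0("relationship: part_of ", dag$edges$parent[i]), con)
    }
  }
  invisible(path)
}
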