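test_that("simulated genomes are deterministic, non-overlapping, in bounds", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1L, chrom_length = 50e6,
                    n_genes = 200L)
  ann1 <- simulate_genome(cfg)
  ann2 <- simulate_genome(cfg)
  expect_identical(ann1, ann2)
  g <- ann1$genes
  expect_equal(nrow(g), 200L)
  # exhaustive interval sweep: sorted starts never precede previous ends
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  expect_true(all(g$start >= 0 & g$end <= 50e6))
  expect_true(all(g$end - g$start >= 5e3 & g$end - g$start <= 2e5))

  empty <- simulate_genome(sim_config(seed = 9, n_genes = 0L))
  expect_equal(nrow(empty$genes), 0L)

  dense <- sim_config(seed = 9, n_chromosomes = 1L, chrom_length = 1e6,
                      n_genes = 500L)
  expect_error(simulate_genome(dense), class = "chromex_config_error")
})

test_that("contact counts follow decay and the compartment boost", {
  # kappa = 1: within a diagonal counts are iid Poisson -> the dispersion
  # statistic sum((x - xbar)^2 / xbar) is ~ chi^2 with n - 1 df
  cfg <- sim_config(seed = 10, kappa = 1, n_chromosomes = 1L,
                    chrom_length = 100e6, base_contacts = 200)
  m <- simulate_contacts(cfg, simulate_compartments(cfg))[["chr1"]]
  for (d in c(1, 5, 20)) {
    i <- seq_len(m$n_bins - d)
    x <- m$counts[cbind(i, i + d)]
    stat <- sum((x - mean(x))^2 / mean(x))
    expect_gt(pchisq(stat, length(x) - 1, lower.tail = FALSE), 1e-4)
  }

  # alpha large: off-diagonal essentially empty, diagonal dominant
  steep <- sim_config(seed = 10, decay_alpha = 8, kappa = 1)
  ms <- simulate_contacts(steep, simulate_compartments(steep))[["chr1"]]
  off <- ms$counts[abs(row(ms$counts) - col(ms$counts)) >= 2]
  expect_lt(mean(off), 1)
  expect_gt(mean(diag(ms$counts)), 50)

  # same-block vs cross-block mean ratio at equal offset ~ kappa
  cfg3 <- sim_config(seed = 11, kappa = 3, n_chromosomes = 1L,
                     chrom_length = 100e6, n_blocks = 10L,
                     base_contacts = 300)
  blocks <- simulate_compartments(cfg3)
  m3 <- simulate_contacts(cfg3, blocks)[["chr1"]]
  lab <- blocks[["chr1"]]
  same <- outer(lab, lab, "==")
  d <- abs(row(m3$counts) - col(m3$counts))
  decay <- (1 + d)^(-cfg3$decay_alpha)
  norm <- m3$counts / (cfg3$base_contacts * decay)
  ratio <- mean(norm[same & d > 0]) / mean(norm[!same])
  expect_gt(ratio, 3 * 0.85)
  expect_lt(ratio, 3 * 1.15)
})

test_that("expression coupling matches the factor-model expectation", {
  cfg <- sim_config(seed = 12, beta = 0.9, n_genes = 200L,
                    n_conditions = 200L)
  ann <- simulate_genome(cfg)
  blocks <- simulate_compartments(cfg)
  expr <- simulate_expression(cfg, ann, blocks)
  expect_identical(expr, simulate_expression(cfg, ann, blocks))
  keys <- chromex:::gene_block_keys(ann, blocks, cfg$resolution)
  cc <- cor(t(expr))
  same <- outer(keys, keys, "==") & upper.tri(cc)
  diffk <- !outer(keys, keys, "==") & upper.tri(cc)
  expect_equal(mean(cc[same]), 0.9, tolerance = 0.05)
  expect_lt(abs(mean(cc[diffk])), 0.05)

  null_cfg <- sim_config(seed = 12, beta = 0, n_genes = 200L)
  e0 <- simulate_expression(null_cfg, ann, blocks)
  cc0 <- cor(t(e0))
  expect_lt(abs(mean(cc0[upper.tri(cc0)])), 0.02)
  expect_error(simulate_expression(sim_config(beta = 2), ann, blocks),
               class = "chromex_config_error")
})

test_that("mutual ranks reproduce the exhaustive double-ranking oracle", {
  set.seed(13)
  for (n in c(3, 5, 8, 10)) {
    expr <- matrix(rnorm(n * 10), n,
                   dimnames = list(sprintf("g%02d", 1:n), NULL))
    tab <- mutual_ranks_from_expression(expr)
    oracle <- oracle_mutual_ranks(expr)
    expect_setequal(names(tab$mr), names(oracle))
    expect_equal(tab$mr[names(oracle)], oracle, tolerance = 1e-12)
  }

  # mutual best hit has MR 1
  expr <- rbind(g1 = c(1, 2, 3, 4, 5),
                g2 = c(1.1, 2, 3.2, 4, 4.9),
                g3 = c(5, 1, 4, 2, 3))
  tab <- mutual_ranks_from_expression(expr)
  expect_equal(lookup_mutual_rank(tab, "g1", "g2"), 1)

  # constant gene profile -> its pairs are omitted
  expr_const <- rbind(expr, g4 = rep(2, 5))
  tab2 <- mutual_ranks_from_expression(expr_const)
  expect_true(is.na(lookup_mutual_rank(tab2, "g1", "g4")))
  expect_error(mutual_ranks_from_expression(expr[, 1:2]),
               class = "chromex_usage_error")
})

test_that("TF network respects degrees and the cohort boundary", {
  cfg <- sim_config(seed = 14)
  ann <- simulate_genome(cfg)
  net <- simulate_tf_network(cfg, ann)
  expect_true(all(table(net$edges$tf) >= 1))
  expect_true(all(net$edges$target %in% ann$genes$id))
  expect_identical(net$edges, simulate_tf_network(cfg, ann)$edges)
})

test_that("GO coupling gamma raises same-compartment gene similarity", {
  base <- list(seed = 15, n_genes = 120L, n_chromosomes = 1L,
               go_depth = 3L, go_branching = 3L)
  run <- function(gamma) {
    cfg <- do.call(sim_config, c(base, list(gamma = gamma)))
    ann <- simulate_genome(cfg)
    blocks <- simulate_compartments(cfg)
    go <- simulate_go(cfg, ann, blocks)
    keys <- chromex:::gene_block_keys(ann, blocks, cfg$resolution)
    ids <- ann$genes$id
    set.seed(1)
    pairs <- t(replicate(250, sample(ids, 2)))
    sims <- chromex:::pairwise_gene_similarity(go$dag, go$ann,
                                               pairs[, 1], pairs[, 2])
    same <- keys[pairs[, 1]] == keys[pairs[, 2]]
    c(same = mean(sims[same]), diff = mean(sims[!same]))
  }
  coupled <- run(0.95)
  null <- run(0)
  expect_gt(coupled["same"] - coupled["diff"], 0.03)
  expect_lt(abs(null["same"] - null["diff"]),
            coupled["same"] - coupled["diff"])
})

test_that("bundles are reproducible end to end, including on disk", {
  cfg <- sim_config(seed = 16, n_genes = 80L, go_depth = 3L)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  m1 <- write_bundle(simulate_bundle(cfg, with_go = TRUE), d1)
  m2 <- write_bundle(simulate_bundle(cfg, with_go = TRUE), d2)
  expect_identical(m1$files, m2$files)  # md5 of every artifact matches

  # manifest checksums match the files on re-read
  sums <- tools::md5sum(file.path(d1, names(m1$files)))
  expect_identical(unname(sums), unlist(m1$files, use.names = FALSE))

  # the bundle is directly consumable by the full pipeline
  res <- run_full_analysis(file.path(d1, "analysis_config.json"))
  expect_s3_class(res, "AnalysisResults")
  expect_named(res$strata$all$panels,
               c("oh_cellA", "oh_cellB", "pc_cellA", "pc_cellB"))
  expect_false(is.null(res$go_panels))
})
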