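write_lines_tmp <- function(lines) {
  p <- tempfile()
  writeLines(lines, p)
  p
}

sizes_path <- function(...) {
  df <- list(...)
  write_lines_tmp(vapply(names(df), function(ch)
    paste(ch, df[[ch]], sep = "\t"), ""))
}

test_that("BED6 reading maps fields, validates, and sorts", {
  sp <- sizes_path(chr1 = 10000, chr2 = 20000)
  bed <- write_lines_tmp(c("chr1\t5000\t9000\tgeneB\t0\t-",
                           "chr1\t1000\t5000\tgeneA\t0\t+",
                           "chr2\t100\t200\tgeneC\t0\t."))
  ann <- read_gene_annotation(bed, sp)
  expect_s3_class(ann, "GeneAnnotation")
  expect_equal(ann$genes$id, c("geneA", "geneB", "geneC"))
  expect_equal(ann$genes[1, ],
               data.frame(id = "geneA", chrom = "chr1", start = 1000,
                          end = 5000, strand = "+"),
               ignore_attr = TRUE)

  # start == end violates 0 <= start < end
  bad <- write_lines_tmp("chr1\t1000\t1000\tg\t0\t+")
  expect_error(read_gene_annotation(bad, sp), "line 1",
               class = "chromex_validation_error")
  # interval past chromosome end
  bad <- write_lines_tmp("chr1\t1000\t10001\tg\t0\t+")
  expect_error(read_gene_annotation(bad, sp), "exceeds chromosome",
               class = "chromex_validation_error")
  # duplicate id
  bad <- write_lines_tmp(c("chr1\t0\t10\tg\t0\t+", "chr1\t50\t60\tg\t0\t+"))
  expect_error(read_gene_annotation(bad, sp), "duplicate gene id",
               class = "chromex_validation_error")
  # malformed line is reported with its number
  bad <- write_lines_tmp(c("chr1\t0\t10\tg1\t0\t+", "chr1\t0\t10"))
  expect_error(read_gene_annotation(bad, sp), "line 2",
               class = "chromex_parse_error")
})

test_that("contact matrices read from coo and dense dialects", {
  coo <- write_lines_tmp(c("0\t1\t5", "1\t1\t2"))
  m <- read_contact_matrix(coo, "chr1", "cellA", 10, 20, "coo")
  expect_equal(m$counts, matrix(c(0, 5, 5, 2), 2))
  expect_equal(m$n_bins, 2L)

  dense <- tempfile()
  write_contact_matrix(m, dense)
  m2 <- read_contact_matrix(dense, "chr1", "cellA", 10, 20, "dense")
  expect_identical(m2$counts, m$counts)

  neg <- write_lines_tmp("0\t0\t-1")
  expect_error(read_contact_matrix(neg, "chr1", "cellA", 10, 20, "coo"),
               "negative", class = "chromex_validation_error")
  oob <- write_lines_tmp("0\t2\t1")
  expect_error(read_contact_matrix(oob, "chr1", "cellA", 10, 20, "coo"),
               "out of range", class = "chromex_validation_error")
  asym <- write_lines_tmp(c("bin\t0\t10", "0\t1\t2", "10\t3\t4"))
  expect_error(read_contact_matrix(asym, "chr1", "cellA", 10, 20, "dense"),
               "asymmetric", class = "chromex_validation_error")
})

test_that("contact read -> write -> read round trip is exact", {
  counts <- random_symmetric_counts(7, 42)
  m <- make_contact(counts, resolution = 100)
  p <- tempfile()
  write_contact_matrix(m, p)
  m2 <- read_contact_matrix(p, "chr1", "cellA", 100, 700, "dense")
  expect_identical(m2$counts, m$counts)
  expect_true(isSymmetric(m2$counts))
})

test_that("TF network dedups edges with a warning and serves TF sets", {
  p <- write_lines_tmp(c("TF1\tg1", "TF1\tg1", "TF2\tg1"))
  expect_warning(net <- read_tf_targets(p), "duplicate")
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(tf_set(net, "g1"), c("TF1", "TF2"))
  expect_equal(tf_set(net, "absent"), character())
})

test_that("mutual-rank table is symmetric and rejects conflicts", {
  p <- write_lines_tmp(c("g1\tg2\t4.5", "g3\tg1\t7"))
  tab <- read_mutual_ranks(p)
  expect_equal(lookup_mutual_rank(tab, "g2", "g1"), 4.5)
  expect_equal(lookup_mutual_rank(tab, "g1", "g3"), 7)
  expect_true(is.na(lookup_mutual_rank(tab, "g2", "g3")))

  conflict <- write_lines_tmp(c("g1\tg2\t4", "g2\tg1\t7"))
  expect_error(read_mutual_ranks(conflict), "conflicting",
               class = "chromex_validation_error")
  dup_same <- write_lines_tmp(c("g1\tg2\t4", "g2\tg1\t4"))
  expect_equal(length(read_mutual_ranks(dup_same)$mr), 1L)
})

test_that("OBO subset parses chains and rejects cycles and bad namespaces", {
  p <- write_lines_tmp(c("[Term]", "id: A", "is_a: B ! bee",
                         "", "[Term]", "id: B",
                         "relationship: part_of C ! sea",
                         "", "[Term]", "id: C"))
  dag <- read_obo_subset(p)
  expect_equal(nrow(dag$edges), 2L)
  expect_equal(dag$roots, "C")
  expect_equal(dag$edges$relation, c("is_a", "part_of"))

  cyc <- write_lines_tmp(c("[Term]", "id: A", "is_a: B",
                           "", "[Term]", "id: B", "is_a: A"))
  expect_error(read_obo_subset(cyc), "cycle",
               class = "chromex_validation_error")
  badns <- write_lines_tmp(c("[Term]", "id: A",
                             "namespace: molecular_function"))
  expect_error(read_obo_subset(badns), "biological_process",
               class = "chromex_validation_error")
  unk <- write_lines_tmp(c("[Term]", "id: A", "is_a: Z"))
  expect_error(read_obo_subset(unk), "not a declared term",
               class = "chromex_validation_error")
})

test_that("gene-GO annotations must reference known terms", {
  obo <- write_lines_tmp(c("[Term]", "id: A", "", "[Term]", "id: B",
                           "is_a: A"))
  dag <- read_obo_subset(obo)
  p <- write_lines_tmp(c("g1\tA", "g1\tB", "g2\tB"))
  ann <- read_gene_go(p, dag)
  expect_setequal(ann[["g1"]], c("A", "B"))
  bad <- write_lines_tmp("g1\tZZZ")
  expect_error(read_gene_go(bad, dag), "unknown term",
               class = "chromex_validation_error")
})

test_that("GoDAG acyclicity verified on random DAG fixtures", {
  for (seed in 1:20) expect_s3_class(random_dag(12, seed), "GoDAG")
  # adding a back edge to a chain creates a cycle
  expect_error(
    chromex:::new_go_dag(c("A", "B", "C"),
                         data.frame(child = c("A", "B", "C"),
                                    parent = c("B", "C", "A"),
                                    relation = "is_a")),
    "cycle", class = "chromex_validation_error")
})

test_that("pair table writes a headered TSV that round-trips", {
  df <- data.frame(gene_a = "g1", gene_b = "g2", chrom = "chr1",
                   norm_dist = 0.123456789012345, oh_cellA = 3.5,
                   pc_cellA = -0.25, mutual_rank = 12, tcs = 2 / 3,
                   rank_pct_cellA = 0.4, go_sim = NA_real_,
                   stringsAsFactors = FALSE)
  tab <- hand_pair_table(df, cell_types = "cellA")
  p <- tempfile()
  write_pair_table(tab, p)
  lines <- readLines(p)
  expect_length(lines, 2L)
  back <- read_pair_table(p)
  for (col in names(df)) {
    if (is.numeric(df[[col]]))
      expect_equal(back$pairs[[col]], df[[col]], tolerance = 1e-12)
    else expect_identical(back$pairs[[col]], df[[col]])
  }

  empty <- hand_pair_table(df[0, ], cell_types = "cellA")
  p2 <- tempfile()
  write_pair_table(empty, p2)
  expect_length(readLines(p2), 1L)
})

test_that("results JSON contains one object per panel", {
  res <- list(metadata = list(alpha = 0.05),
              strata = list(all = list(panels = list(
                oh_cellA = list(r = -0.5, p = 0.01),
                oh_cellB = list(r = -0.4, p = 0.02),
                pc_cellA = list(r = -0.3, p = 0.03),
                pc_cellB = list(r = -0.2, p = 0.04)))))
  p <- tempfile(fileext = ".json")
  write_results(res, p)
  back <- jsonlite::read_json(p)
  expect_named(back$strata$all$panels,
               c("oh_cellA", "oh_cellB", "pc_cellA", "pc_cellB"))
})
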