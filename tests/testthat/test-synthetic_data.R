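small_cfg <- function(...) {
  sim_config(n_orders = 2L, genomes_per_order = 4L, seed = 11L, ...)
}

test_that("generation is byte-identical for a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(small_cfg(), d1)
  simulate_dataset(small_cfg(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- tempfile()
  simulate_dataset(sim_config(n_orders = 2L, genomes_per_order = 4L,
                              seed = 12L), d3)
  expect_false(identical(readLines(file.path(d1, "genes.tsv")),
                         readLines(file.path(d3, "genes.tsv"))))
})

test_that("emitted files agree with the planted truth tallies", {
  ds <- generate_dataset(small_cfg())
  # planted ATPase proteins exist in the gene table with domain hits
  expect_true(all(ds$truth$atpases$protein_id %in% ds$genes$protein_id))
  expect_true(all(ds$truth$atpases$protein_id %in% ds$hits$protein_id))
  # per-genome planted copy numbers match the truth record
  planted <- table(factor(ds$truth$atpases$genome_id,
                          levels = ds$truth$genomes$genome_id),
                   factor(ds$truth$atpases$variant,
                          levels = c("one_domain", "two_domain")))
  expect_equal(unname(planted[, "one_domain"]),
               ds$truth$genomes$one_domain)
  expect_equal(unname(planted[, "two_domain"]),
               ds$truth$genomes$two_domain)
  # marker labels only occur in genomes flagged cbb3-positive
  has_markers <- vapply(split(ds$genes$labels, ds$genes$genome_id),
                        function(x) any(nzchar(x)), logical(1))
  expect_equal(unname(has_markers[ds$truth$genomes$genome_id]),
               ds$truth$genomes$cbb3_present)
  # orders are monophyletic by construction
  collapsed <- collapse_to_rank(ds$tree, ds$taxonomy)
  expect_setequal(collapsed$tip.label, unique(ds$taxonomy$order))
})

test_that("a noiseless run recovers the truth exactly", {
  ds <- generate_dataset(small_cfg())
  out <- tempfile()
  cfg <- pipeline_config(genes = ds$genes, hits = ds$hits,
                         taxonomy = ds$taxonomy, out_dir = out)
  res <- run_classify(cfg)
  mism <- truth_compare(ds$truth, res$genome_summaries, res$cluster_calls)
  expect_equal(nrow(mism), 0L)
})

test_that("point-mass-at-zero copy numbers yield all-zero genomes", {
  cfg <- sim_config(n_orders = 2L, genomes_per_order = 3L,
                    copy_number_probs = list(one_domain = 1,
                                             two_domain = 1),
                    p_cbb3_cluster = 0, seed = 5L)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$truth$atpases), 0L)
  out <- tempfile()
  res <- run_classify(pipeline_config(genes = ds$genes, hits = ds$hits,
                                      out_dir = out))
  agg <- summarize_order(res$genome_summaries, ds$taxonomy,
                         variants = c("two_domain", "one_domain"))
  expect_true(all(agg$p0 == 1))
  expect_true(all(agg$cbb3_proportion == 0))
})

test_that("infeasible or invalid configurations fail before output", {
  expect_error(sim_config(genes_per_contig = c(2L, 4L)),
               class = "fx_config_error")
  expect_error(sim_config(copy_number_probs = list(one_domain = c(0.5, 0.4),
                                                   two_domain = 1)),
               class = "fx_config_error")
  expect_error(sim_config(p_cbb3_cluster = 1.5), class = "fx_config_error")
  expect_error(sim_config(decoy_domain_pool = c("PF00403")),
               class = "fx_config_error")
})

test_that("truth_compare flags fabricated mismatches and id gaps", {
  ds <- generate_dataset(small_cfg())
  out <- tempfile()
  res <- run_classify(pipeline_config(genes = ds$genes, hits = ds$hits,
                                      out_dir = out))
  gs <- res$genome_summaries
  gs$one_domain[1] <- gs$one_domain[1] + 1L
  mism <- truth_compare(ds$truth, gs, res$cluster_calls)
  expect_gt(nrow(mism), 0L)
  expect_true(any(grepl("copy_number_one_domain", mism$item)))

  gs2 <- res$genome_summaries[-1, ]
  expect_error(truth_compare(ds$truth, gs2, res$cluster_calls),
               class = "fx_validation_error")
})

test_that("scrambled orders break monophyly and trigger suffixing", {
  cfg <- sim_config(n_orders = 3L, genomes_per_order = 6L,
                    scramble_orders = TRUE, seed = 21L)
  ds <- generate_dataset(cfg)
  w <- testthat::capture_warnings(
    collapsed <- collapse_to_rank(ds$tree, ds$taxonomy))
  expect_true(length(w) > 0 && all(grepl("not monophyletic", w)))
  expect_true(any(grepl("_2$", collapsed$tip.label)))
})
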