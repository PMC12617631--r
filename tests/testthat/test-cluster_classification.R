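mk <- marker_set()

cluster_with_labels <- function(labels, strands = rep("+", length(labels)),
                                focal = 1L) {
  g <- make_contig(strands, labels = labels)
  extract_strand_run(g, focal - 1L)
}

test_that("distinct markers are counted once, focal excluded", {
  cl <- cluster_with_labels(c("", "ccoN", "ccoO", "unrelated"))
  expect_equal(count_markers(cl, mk), 2L)

  # focal only
  cl <- extract_strand_run(make_contig(c("-", "+", "-")), 1L)
  expect_equal(count_markers(cl, mk), 0L)

  # duplicated subunit counts once
  cl <- cluster_with_labels(c("", "ccoN", "ccoN"))
  expect_equal(count_markers(cl, mk), 1L)

  # focal gene's own label does not count
  cl <- cluster_with_labels(c("ccoN", "ccoO", ""))
  expect_equal(count_markers(cl, mk), 1L)
})

test_that("markers can be matched through member architectures", {
  mk_acc <- marker_set(labels = character(0) ,
                       accessions = c("PF12345", "PF23456"))
  cl <- cluster_with_labels(c("", "", ""))
  arch <- list(g1_c1_p02 = c("PF12345"), g1_c1_p03 = c("PF23456", "PF99001"))
  expect_equal(count_markers(cl, mk_acc, architectures = arch), 2L)
  expect_equal(count_markers(cl, mk_acc), 0L)
})

test_that("FixI-like requires a 1-domain focal and enough markers", {
  run2 <- cluster_with_labels(c("", "ccoN", "ccoO"))
  expect_equal(classify_cluster(run2, "one_domain", mk)$classification,
               "fixi_like")
  run3 <- cluster_with_labels(c("", "ccoN", "ccoO", "ccoP"))
  expect_equal(classify_cluster(run3, "two_domain", mk)$classification,
               "unclassified")
  run1 <- cluster_with_labels(c("", "ccoN"))
  expect_equal(classify_cluster(run1, "one_domain", mk)$classification,
               "unclassified")
  expect_equal(
    classify_cluster(run1, "one_domain", mk, min_markers = 1L)$classification,
    "fixi_like")
})

test_that("relaxing min_markers only adds FixI-like calls", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    labels <- sample(c("", mk$labels), n, replace = TRUE)
    g <- make_contig(sample(c("+", "-"), n, replace = TRUE), labels = labels)
    focal <- sample(n, 1) - 1L
    cl <- extract_strand_run(g, focal)
    strict <- classify_cluster(cl, "one_domain", mk, 2L)$classification
    loose <- classify_cluster(cl, "one_domain", mk, 1L)$classification
    if (strict == "fixi_like") expect_equal(loose, "fixi_like")
  }
})

test_that("adding a marker inside the run never revokes a FixI-like call", {
  base <- c("", "ccoN", "ccoO")
  cl <- cluster_with_labels(base)
  before <- classify_cluster(cl, "one_domain", mk)$classification
  grown <- cluster_with_labels(c(base, "ccoP"))
  after <- classify_cluster(grown, "one_domain", mk)$classification
  expect_equal(before, "fixi_like")
  expect_equal(after, "fixi_like")
})

test_that("genome-level cbb3 detection needs a co-directional marker run", {
  g <- make_contig(c("+", "+", "-"), labels = c("ccoN", "ccoO", ""))
  expect_true(genome_has_cbb3_cluster(g, mk))

  # adjacent markers on opposite strands do not form a cluster
  g2 <- make_contig(c("+", "-", "+"), labels = c("ccoN", "ccoO", ""))
  expect_false(genome_has_cbb3_cluster(g2, mk))
  expect_true(genome_has_cbb3_cluster(g2, mk, mode = "anywhere"))

  g3 <- make_contig(c("+", "+"), labels = c("", ""))
  expect_false(genome_has_cbb3_cluster(g3, mk))
  expect_false(genome_has_cbb3_cluster(g3, mk, mode = "anywhere"))
})

test_that("cbb3 detection is invariant under contig reversal and order", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    g <- make_contig(sample(c("+", "-"), n, replace = TRUE),
                     labels = sample(c("", "ccoN", "ccoO", "ccoP"), n, TRUE))
    has <- genome_has_cbb3_cluster(g, mk)
    expect_identical(genome_has_cbb3_cluster(reverse_contig(g), mk), has)
    # second contig, permuted order
    g2 <- make_contig(sample(c("+", "-"), 4, replace = TRUE), contig = "c0")
    both <- rbind(g2, g)
    expect_identical(genome_has_cbb3_cluster(both, mk), has)
  }
})
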