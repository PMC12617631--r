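test_that("gene-table TSV parsing assigns ranks in coordinate order", {
  f <- write_tsv_lines(c(
    gene_table_header,
    "g1\tc1\tga\t2001\t2900\t+\tpa\t",
    "g1\tc1\tgb\t1\t900\t-\tpb\tccoN;ccoO",
    "g1\tc1\tgc\t1001\t1900\t+\tpc\t"))
  genes <- read_gene_table(f)
  expect_equal(genes$gene_id, c("gb", "gc", "ga"))
  expect_equal(genes$rank, 0:2)
  expect_equal(genes$strand, c("-", "+", "+"))
  expect_equal(genes$labels[1], "ccoN;ccoO")

  empty <- read_gene_table(write_tsv_lines(gene_table_header))
  expect_equal(nrow(empty), 0L)
})

test_that("gene-table parse errors name the offending line", {
  f <- write_tsv_lines(c(
    gene_table_header,
    "g1\tc1\tga\t1\t900\t+\tpa\t",
    "g1\tc1\tgb\tabc\t1900\t-\tpb\t"))
  expect_error(read_gene_table(f), "line 3", class = "fx_parse_error")

  f2 <- write_tsv_lines(c(
    gene_table_header,
    "g1\tc1\tga\t1\t900\t*\tpa\t"))
  expect_error(read_gene_table(f2), "strand", class = "fx_parse_error")

  f3 <- write_tsv_lines(c(
    gene_table_header,
    "g1\tc1\tga\t1\t900\t+\tpa\t",
    "g1\tc1\tgb\t1001\t1900\t-\tpa\t"))
  expect_error(read_gene_table(f3), "duplicate protein_id",
               class = "fx_validation_error")
})

test_that("GFF3 dialect keeps gene features and rejects bad coordinates", {
  f <- write_tsv_lines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t900\t.\t+\t.\tID=ga;protein_id=pa",
    "c1\tsrc\ttRNA\t950\t980\t.\t+\t.\tID=t1",
    "c1\tsrc\tgene\t1001\t1900\t.\t-\t.\tID=gb;protein_id=pb;marker=ccoN,ccoO"))
  expect_message(genes <- read_gene_table(f, dialect = "gff3",
                                          genome_id = "g1"),
                 "non-gene")
  expect_equal(nrow(genes), 2L)
  expect_equal(genes$labels[2], "ccoN;ccoO")
  expect_equal(genes$rank, 0:1)

  bad <- write_tsv_lines(
    "c1\tsrc\tgene\t900\t100\t.\t+\t.\tID=ga;protein_id=pa")
  expect_error(read_gene_table(bad, dialect = "gff3", genome_id = "g1"),
               class = "fx_parse_error")
})

test_that("gene tables and taxonomy round-trip bit-for-bit", {
  set.seed(11)
  genes <- do.call(rbind, lapply(1:3, function(i) {
    make_contig(sample(c("+", "-"), 8, replace = TRUE),
                labels = sample(c("", "ccoN", "ccoO;ccoP"), 8, TRUE),
                genome = paste0("g", i), contig = "c1")
  }))
  f <- tempfile()
  write_gene_table(genes, f)
  back <- read_gene_table(f)
  rownames(genes) <- NULL
  expect_identical(back, genes[, names(back)])

  tax <- data.frame(
    genome_id = c("g1", "g2"),
    lineage = rep(paste0("d__Bacteria;p__Pseudomonadota;",
                         "c__Alphaproteobacteria;o__Caulobacterales;",
                         "f__Caulobacteraceae;g__Caulobacter;s__"), 2),
    stringsAsFactors = FALSE)
  ft <- tempfile()
  utils::write.table(tax, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_taxonomy(ft)
  expect_equal(parsed$order, rep("Caulobacterales", 2))
  ft2 <- tempfile()
  write_taxonomy(parsed, ft2)
  expect_identical(readLines(ft), readLines(ft2))
})

test_that("per-contig ranks never have gaps on random tables", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    df <- data.frame(
      genome_id = "g", contig_id = sample(c("c1", "c2"), n, TRUE),
      gene_id = sprintf("x%03d", sample(1000, n)),
      start = sample(1e6, n),
      strand = sample(c("+", "-"), n, TRUE),
      labels = "", stringsAsFactors = FALSE)
    df$end <- df$start + 899L
    df$protein_id <- df$gene_id
    f <- tempfile()
    utils::write.table(
      df[, c("genome_id", "contig_id", "gene_id", "start", "end",
             "strand", "protein_id", "labels")],
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    genes <- read_gene_table(f)
    unlink(f)
    for (contig in split(genes, genes$contig_id)) {
      expect_identical(contig$rank, seq_len(nrow(contig)) - 1L)
      expect_false(is.unsorted(contig$start))
    }
  }
})

test_that("domain hits are sorted, version-stripped and validated", {
  f <- write_tsv_lines(c(
    "protein_id\taccession\tali_start\tali_end\tevalue",
    "p1\tPF00122\t120\t300\t1e-40",
    "p1\tPF00403.28\t5\t70\t1e-20"))
  hits <- read_domain_hits(f)
  expect_equal(hits$accession, c("PF00403", "PF00122"))
  expect_equal(hits$ali_start, c(5L, 120L))

  bad <- write_tsv_lines(c(
    "protein_id\taccession\tali_start\tali_end\tevalue",
    "p1\tPB00403\t5\t70\t1e-20"))
  expect_error(read_domain_hits(bad), "accession",
               class = "fx_validation_error")
})

test_that("taxonomy requires an order rank", {
  f <- write_tsv_lines(c("genome_id\tlineage", "g1\td__Bacteria"))
  expect_error(read_taxonomy(f), "g1", class = "fx_validation_error")
})

test_that("iTOL datasets carry the fixed header and re-parse to unit sums", {
  summary <- data.frame(
    order = rep(c("Caulobacterales", "Rhizobiales"), each = 2),
    variant = rep(c("one_domain", "two_domain"), 2),
    n_genomes = 4L, stringsAsFactors = FALSE)
  p <- matrix(0, 4, 8, dimnames = list(NULL, paste0("p", 0:7)))
  p[1, ] <- c(1, 0, 0, 0, 0, 0, 0, 0)
  p[2, ] <- c(0.25, 0.5, 0.25, 0, 0, 0, 0, 0)
  p[3, ] <- c(0.5, 0.25, 0.125, 0.125, 0, 0, 0, 0)
  p[4, ] <- c(0, 0, 0, 0, 0, 0, 0, 1)
  summary <- cbind(summary, as.data.frame(p))
  summary$cbb3_proportion <- rep(c(0.75, 0.5), each = 2)

  out <- tempfile()
  files <- write_itol_datasets(summary, out)
  expect_length(files, 3L)
  multibar <- readLines(files[1])
  expect_equal(multibar[1], "DATASET_MULTIBAR")
  expect_true(any(grepl("^FIELD_LABELS\tcopy_0", multibar)))
  expect_true(any(grepl("\t1\\.000000", multibar)))

  for (f in files[1:2]) {
    dat <- read_itol_data(f)
    expect_equal(nrow(dat), 2L)  # one row per order, input order kept
    sums <- rowSums(dat[, -1, drop = FALSE])
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  bar <- read_itol_data(files[3])
  expect_equal(bar$id, c("Caulobacterales", "Rhizobiales"))
  expect_equal(bar[[2]], c(0.75, 0.5))
})

test_that("newick trees survive write/read and pruning re-serialization", {
  tree <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  f <- tempfile(fileext = ".nwk")
  write_newick(tree, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tree$tip.label)
  pruned <- prune_tree(back, c("A", "B"))
  f2 <- tempfile(fileext = ".nwk")
  write_newick(pruned, f2)
  expect_setequal(read_newick(f2)$tip.label, c("A", "B"))
})
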