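mk_calls <- function(variants, genome = "g1") {
  data.frame(genome_id = rep(genome, length(variants)),
             protein_id = as.character(seq_along(variants)),
             variant = variants, stringsAsFactors = FALSE)
}

mk_taxonomy <- function(genomes, orders) {
  data.frame(genome_id = genomes,
             lineage = sprintf("d__Bacteria;p__P;c__C;o__%s;f__;g__;s__",
                               orders),
             domain = "Bacteria", phylum = "P", class = "C", order = orders,
             family = NA, genus = NA, species = NA, stringsAsFactors = FALSE)
}

test_that("genome summaries count calls per variant, excluding none", {
  s <- summarize_genome(mk_calls(c("one_domain", "one_domain", "two_domain",
                                   "none")), cbb3 = TRUE)
  expect_equal(s$copy_number, c(one_domain = 2L, two_domain = 1L))
  expect_true(s$cbb3_present)
  s0 <- summarize_genome(mk_calls(character()), cbb3 = FALSE)
  expect_equal(unname(s0$copy_number), c(0L, 0L))
  s9 <- summarize_genome(mk_calls(rep("one_domain", 9)), cbb3 = FALSE)
  expect_equal(s9$copy_number[["one_domain"]], 9L)  # binning is later
})

test_that("order summaries bin copy numbers with a 7+ cap", {
  gs <- data.frame(genome_id = paste0("g", 1:4),
                   one_domain = c(0L, 1L, 1L, 2L),
                   two_domain = c(0L, 0L, 0L, 9L),
                   cbb3_present = c(TRUE, TRUE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  tax <- mk_taxonomy(gs$genome_id, rep("Caulobacterales", 4))
  s <- summarize_order(gs, tax)
  one <- s[s$variant == "one_domain", ]
  expect_equal(unlist(one[paste0("p", 0:7)], use.names = FALSE),
               c(0.25, 0.5, 0.25, 0, 0, 0, 0, 0))
  two <- s[s$variant == "two_domain", ]
  expect_equal(two$p7, 0.25)  # copy number 9 lands in the top bin
  expect_equal(s$cbb3_proportion, rep(0.5, 2))
  expect_equal(s$n_genomes, rep(4L, 2))

  # single genome, no ATPases
  s1 <- summarize_order(
    data.frame(genome_id = "g9", one_domain = 0L, two_domain = 0L,
               cbb3_present = FALSE, stringsAsFactors = FALSE),
    mk_taxonomy("g9", "Rhizobiales"))
  expect_equal(s1$p0, rep(1, 2))
  expect_equal(s1$cbb3_proportion, rep(0, 2))

  expect_error(summarize_order(gs, mk_taxonomy("gX", "O")),
               class = "fx_validation_error")
})

test_that("bin proportions always sum to one and ignore genome order", {
  set.seed(8)
  gs <- data.frame(genome_id = sprintf("g%03d", 1:60),
                   one_domain = sample(0:10, 60, TRUE),
                   two_domain = sample(0:3, 60, TRUE),
                   cbb3_present = sample(c(TRUE, FALSE), 60, TRUE),
                   stringsAsFactors = FALSE)
  tax <- mk_taxonomy(gs$genome_id, sample(paste0("O", 1:4), 60, TRUE))
  s <- summarize_order(gs, tax)
  sums <- rowSums(s[, paste0("p", 0:7)])
  expect_true(all(abs(sums - 1) < 1e-9))
  shuffled <- summarize_order(gs[sample(60), ], tax)
  expect_equal(shuffled, s)
})

test_that("pruning keeps requested leaves and sums collapsed branch lengths", {
  tree <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  all4 <- prune_tree(tree, c("A", "B", "C", "D"))
  expect_setequal(all4$tip.label, tree$tip.label)
  expect_equal(ape::Ntip(all4), 4L)

  cherry <- prune_tree(tree, c("A", "B"))
  expect_setequal(cherry$tip.label, c("A", "B"))
  expect_equal(ape::Ntip(cherry), 2L)

  # single-leaf prune: branch length = root-to-leaf path sum
  single <- prune_tree(tree, "C")
  expect_equal(single$tip.label, "C")
  expect_equal(single$edge.length, 4 + 6)

  # idempotence
  keep <- c("A", "C", "D")
  once <- prune_tree(tree, keep)
  twice <- prune_tree(once, keep)
  expect_equal(ape::write.tree(twice), ape::write.tree(once))

  expect_error(prune_tree(tree, c("A", "Z")), "Z",
               class = "fx_validation_error")
})

test_that("collapsing to order yields one leaf per monophyletic taxon", {
  tree <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  tax <- mk_taxonomy(c("A", "B", "C", "D"), c("X", "X", "Y", "Y"))
  collapsed <- collapse_to_rank(tree, tax)
  expect_setequal(collapsed$tip.label, c("X", "Y"))

  # all leaves one order -> single-leaf tree
  tax1 <- mk_taxonomy(c("A", "B", "C", "D"), rep("X", 4))
  one <- collapse_to_rank(tree, tax1)
  expect_equal(one$tip.label, "X")

  # non-monophyletic order gets suffixed extra clades and a warning
  tax2 <- mk_taxonomy(c("A", "B", "C", "D"), c("X", "Y", "X", "Y"))
  w <- testthat::capture_warnings(split2 <- collapse_to_rank(tree, tax2))
  expect_true(all(grepl("not monophyletic", w)) && length(w) == 2L)
  expect_setequal(split2$tip.label, c("X", "X_2", "Y", "Y_2"))
})
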