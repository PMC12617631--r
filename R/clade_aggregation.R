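#' @title Order-level aggregation and tree operations
#' @name clade_aggregation
#' @description Genome-level variant calls are tallied into per-genome
#'   copy numbers, then aggregated per taxonomic order into copy-number
#'   bin proportions (bins 0..6 and 7+, matching a 0-to-7 display
#'   scale) and the proportion of genomes encoding a cbb3-type oxidase
#'   gene cluster. The companion tree operations prune a phylogeny to a
#'   genome subset and collapse it to one leaf per taxon at a chosen
#'   rank.
NULL

#' Summarize the variant calls of one genome
#'
#' @param calls Variant-call `data.frame` rows of one genome (column
#'   `variant`); calls of `"none"` are excluded from copy numbers.
#' @param cbb3 Logical: does the genome encode a cbb3 cluster?
#' @param variants Variant names to tally.
#' @return List with `copy_number` (named integer vector over
#'   `variants`) and `cbb3_present`.
#' @export
summarize_genome <- function(calls, cbb3,
                             variants = c("one_domain", "two_domain")) {
  v <- calls$variant[calls$variant != "none"]
  cn <- vapply(variants, function(x) sum(v == x), integer(1))
  list(copy_number = cn, cbb3_present = isTRUE(cbb3))
}

#' Summarize all genomes into a per-genome table
#'
#' @param genome_ids Character vector of every genome in the dataset
#'   (genomes without any call get copy number 0).
#' @param calls Variant-call `data.frame` with columns `genome_id` and
#'   `variant`.
#' @param cbb3 Named logical vector (or `data.frame` with `genome_id`,
#'   `cbb3_present`) of genome-level cbb3 presence.
#' @inheritParams summarize_genome
#' @return `data.frame` with `genome_id`, one count column per variant,
#'   and `cbb3_present`.
#' @export
summarize_genomes <- function(genome_ids, calls, cbb3,
                              variants = c("one_domain", "two_domain")) {
  if (is.data.frame(cbb3)) {
    cbb3 <- stats::setNames(cbb3$cbb3_present, cbb3$genome_id)
  }
  out <- data.frame(genome_id = genome_ids, stringsAsFactors = FALSE)
  for (v in variants) {
    sub <- calls[calls$variant == v, , drop = FALSE]
    tab <- table(sub$genome_id)
    out[[v]] <- as.integer(tab[out$genome_id])
    out[[v]][is.na(out[[v]])] <- 0L
  }
  out$cbb3_present <- as.logical(cbb3[out$genome_id])
  if (anyNA(out$cbb3_present)) {
    fx_validation_error("cbb3 presence missing for some genomes")
  }
  out
}

#' Aggregate genome summaries per taxonomic order
#'
#' Copy numbers are binned into 0..`max_copy_bin`, with larger values
#' assigned to the top bin (displayed as, e.g., "7+"). Proportions per
#' order and variant sum to 1 by construction.
#'
#' @param genome_summaries Output of [summarize_genomes()].
#' @param taxonomy Taxonomy table from [read_taxonomy()] (needs
#'   `genome_id` and `order`).
#' @param variants Variant count columns to aggregate.
#' @param max_copy_bin Top copy-number bin; default 7.
#' @return `data.frame`, one row per order x variant: `order`,
#'   `variant`, `n_genomes`, `p0` ... `p<max_copy_bin>`,
#'   `cbb3_proportion`. Rows ordered by order name then variant.
#' @export
summarize_order <- function(genome_summaries, taxonomy,
                            variants = c("one_domain", "two_domain"),
                            max_copy_bin = 7L) {
  ord <- taxonomy$order[match(genome_summaries$genome_id,
                              taxonomy$genome_id)]
  if (anyNA(ord)) {
    fx_validation_error(sprintf(
      "genomes missing from taxonomy: %s",
      paste(genome_summaries$genome_id[is.na(ord)], collapse = ", ")))
  }
  bins <- 0:max_copy_bin
  rows <- list()
  for (o in sort(unique(ord))) {
    sub <- genome_summaries[ord == o, , drop = FALSE]
    n <- nrow(sub)
    for (v in variants) {
      capped <- pmin(sub[[v]], max_copy_bin)
      p <- vapply(bins, function(b) sum(capped == b) / n, numeric(1))
      row <- data.frame(order = o, variant = v, n_genomes = n,
                        stringsAsFactors = FALSE)
      row[paste0("p", bins)] <- as.list(p)
      row$cbb3_proportion <- mean(sub$cbb3_present)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Prune a phylogeny to a set of genomes
#'
#' Retains exactly the requested leaves; unary internal nodes created
#' by the pruning are collapsed with their branch lengths summed onto
#' the retained child edge.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain (must all be
#'   present in the tree).
#' @return The pruned `phylo` object. A single-leaf request returns a
#'   one-tip tree whose edge length is the root-to-leaf path sum.
#' @export
prune_tree <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    fx_validation_error(sprintf("leaves not in tree: %s",
                                paste(missing, collapse = ", ")))
  }
  if (length(keep) == 0L) fx_validation_error("keep set is empty")
  if (length(keep) == 1L) {
    # ape trees need >= 2 tips; build the single-tip tree directly with
    # the path-summed branch length
    len <- if (is.null(tree$edge.length)) NULL else {
      depths <- ape::node.depth.edgelength(tree)
      depths[match(keep, tree$tip.label)]
    }
    tr <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = keep,
               Nnode = 1L)
    if (!is.null(len)) tr$edge.length <- len
    class(tr) <- "phylo"
    return(tr)
  }
  ape::keep.tip(tree, keep)
}

#' Collapse a phylogeny to one leaf per taxon at a rank
#'
#' Each maximal monophyletic set of leaves sharing one taxon is
#' replaced by a single leaf named for the taxon. When a taxon is not
#' monophyletic, its largest clade keeps the plain name and the extra
#' clades receive suffixed names (`"X_2"`, `"X_3"`, ...) with a warning.
#'
#' @param tree A `phylo` object with genome-labelled leaves.
#' @param taxonomy Taxonomy table from [read_taxonomy()].
#' @param rank Taxonomic rank column to collapse at; default `"order"`.
#' @return A `phylo` object with one leaf per (clade of a) taxon.
#' @export
collapse_to_rank <- function(tree, taxonomy, rank = "order") {
  taxa <- taxonomy[[rank]][match(tree$tip.label, taxonomy$genome_id)]
  if (anyNA(taxa)) {
    fx_validation_error(sprintf(
      "leaves missing a %s assignment: %s", rank,
      paste(tree$tip.label[is.na(taxa)], collapse = ", ")))
  }
  ntip <- length(tree$tip.label)
  if (ntip == 1L || length(unique(taxa)) == 1L) {
    # whole tree is one taxon: collapse to a single leaf
    tr <- prune_tree(tree, tree$tip.label[1])
    tr$tip.label <- taxa[1]
    return(tr)
  }
  # taxon of each node when all descendant tips agree, else NA
  nnode <- ntip + tree$Nnode
  node_taxon <- c(taxa, rep(NA_character_, tree$Nnode))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  for (nd in rev(sort(unique(tree$edge[, 1])))) {
    ts <- unique(node_taxon[children[[as.character(nd)]]])
    node_taxon[nd] <- if (length(ts) == 1L && !anyNA(ts)) ts else NA_character_
  }
  # group of each tip = its highest same-taxon ("pure") ancestor
  parent_of <- integer(nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  group_node <- integer(ntip)
  for (tip in seq_len(ntip)) {
    nd <- tip
    while (nd != root && !is.na(node_taxon[parent_of[nd]])) {
      nd <- parent_of[nd]
    }
    group_node[tip] <- nd
  }
  groups <- split(seq_len(ntip), group_node)
  gtaxon <- vapply(groups, function(tips) taxa[tips[1]], character(1))
  gsize <- lengths(groups)
  # largest clade of a taxon keeps the plain name; extras get _2, _3, ...
  gname <- character(length(groups))
  for (tx in unique(gtaxon)) {
    idx <- which(gtaxon == tx)
    idx <- idx[order(-gsize[idx])]
    gname[idx[1]] <- tx
    if (length(idx) > 1L) {
      gname[idx[-1]] <- paste0(tx, "_", seq.int(2L, length(idx)))
      warning(sprintf("taxon %s is not monophyletic: split into %d clades",
                      tx, length(idx)))
    }
  }
  reps <- vapply(groups, function(tips) tree$tip.label[tips[1]], character(1))
  out <- prune_tree(tree, reps)
  out$tip.label <- gname[match(out$tip.label, reps)]
  out
}

#' Write an order summary as TSV
#'
#' @param summary Output of [summarize_order()].
#' @param path Output path.
#' @export
write_order_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
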