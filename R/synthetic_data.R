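#' @title Synthetic genome generator with planted ground truth
#' @name synthetic_data
#' @description Generates ordered, stranded gene lists per genome with
#'   planted ATPase architectures (as Pfam domain hits), planted
#'   co-directional cbb3 marker runs, order-level taxonomy and a random
#'   order-monophyletic phylogeny, together with a machine-readable
#'   truth record, so every pipeline stage can be tested for exact
#'   recovery without any database download. Planted blocks are
#'   strand-isolated from their flanking genes by construction, so the
#'   expected classification of every planted ATPase is known exactly.
NULL

#' Simulation configuration
#'
#' Defaults emulate a modest multi-order survey: per-genome ATPase copy
#' numbers concentrated on 0-3 for the 1-domain variant and 0-2 for
#' the 2-domain variant, a majority of genomes encoding a cbb3 cluster,
#' and most 1-domain ATPases co-localizing with one.
#'
#' @param n_orders Number of taxonomic orders.
#' @param genomes_per_order Genomes per order.
#' @param genes_per_contig Integer range (length 2) of genes per contig.
#' @param contigs_per_genome Contigs per genome.
#' @param copy_number_probs Named list (per variant) of probability
#'   vectors over copy numbers 0..k; each must sum to 1.
#' @param p_cbb3_cluster Probability a genome carries a standalone cbb3
#'   marker run.
#' @param p_fixi_colocalization Probability a planted 1-domain ATPase
#'   is embedded inside a planted cbb3 run (on the same strand).
#' @param strand_flip_prob Per-step probability that a background gene
#'   flips strand relative to its predecessor.
#' @param decoy_domain_pool Pfam-like accessions used for decoy hits on
#'   background genes; must not collide with signature accessions.
#' @param decoy_hit_prob Probability a background gene receives decoy
#'   domain hits.
#' @param decoy_partial_prob Probability a background gene receives an
#'   incomplete signature prefix (PF00403-PF00122) as a hard decoy.
#' @param gene_length,intergenic_gap Gene length and intergenic gap in
#'   bp (coordinates only matter for ordering and gap limits).
#' @param scramble_orders Permute tree leaves across orders to produce
#'   non-monophyletic taxa (exercises the collapse suffix rule).
#' @param seed Integer seed; generation is fully deterministic given
#'   the seed (R's Mersenne-Twister, set explicitly).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_orders = 10L,
                       genomes_per_order = 20L,
                       genes_per_contig = c(20L, 40L),
                       contigs_per_genome = 2L,
                       copy_number_probs = list(
                         one_domain = c(0.35, 0.40, 0.20, 0.05),
                         two_domain = c(0.55, 0.30, 0.15)),
                       p_cbb3_cluster = 0.6,
                       p_fixi_colocalization = 0.7,
                       strand_flip_prob = 0.25,
                       decoy_domain_pool = sprintf("PF99%03d", 1:20),
                       decoy_hit_prob = 0.10,
                       decoy_partial_prob = 0.02,
                       gene_length = 900L,
                       intergenic_gap = 100L,
                       scramble_orders = FALSE,
                       seed = 1L) {
  cfg <- list(n_orders = as.integer(n_orders),
              genomes_per_order = as.integer(genomes_per_order),
              genes_per_contig = as.integer(genes_per_contig),
              contigs_per_genome = as.integer(contigs_per_genome),
              copy_number_probs = copy_number_probs,
              p_cbb3_cluster = p_cbb3_cluster,
              p_fixi_colocalization = p_fixi_colocalization,
              strand_flip_prob = strand_flip_prob,
              decoy_domain_pool = decoy_domain_pool,
              decoy_hit_prob = decoy_hit_prob,
              decoy_partial_prob = decoy_partial_prob,
              gene_length = as.integer(gene_length),
              intergenic_gap = as.integer(intergenic_gap),
              scramble_orders = isTRUE(scramble_orders),
              seed = as.integer(seed))
  if (cfg$n_orders < 1L || cfg$genomes_per_order < 1L ||
      cfg$contigs_per_genome < 1L) {
    fx_config_error("counts must be positive")
  }
  if (length(cfg$genes_per_contig) != 2L ||
      any(cfg$genes_per_contig < 1L) ||
      cfg$genes_per_contig[1] > cfg$genes_per_contig[2]) {
    fx_config_error("genes_per_contig must be an increasing range of length 2")
  }
  if (!all(c("one_domain", "two_domain") %in% names(cfg$copy_number_probs))) {
    fx_config_error("copy_number_probs must cover one_domain and two_domain")
  }
  for (v in names(cfg$copy_number_probs)) {
    p <- cfg$copy_number_probs[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      fx_config_error(sprintf("copy_number_probs for %s must sum to 1", v))
    }
  }
  probs <- c(cfg$p_cbb3_cluster, cfg$p_fixi_colocalization,
             cfg$strand_flip_prob, cfg$decoy_hit_prob,
             cfg$decoy_partial_prob)
  if (any(probs < 0 | probs > 1)) {
    fx_config_error("probabilities must lie in [0, 1]")
  }
  sigs <- unique(unlist(default_signatures()))
  if (length(intersect(cfg$decoy_domain_pool, sigs))) {
    fx_config_error("decoy_domain_pool collides with signature accessions")
  }
  # largest planted block: cbb3 run (3 markers) + embedded ATPase, plus
  # one isolating flank gene on each side
  if (cfg$genes_per_contig[2] < 6L) {
    fx_config_error("genes_per_contig too small to host a planted cbb3 run")
  }
  structure(cfg, class = "sim_config")
}

CBB3_MARKERS <- c("ccoN", "ccoO", "ccoP")

# Planted domain hits spelling each signature exactly.
signature_hits <- function(protein_id, variant) {
  if (variant == "one_domain") {
    data.frame(protein_id = protein_id,
               accession = c("PF00403", "PF00122", "PF00702"),
               ali_start = c(10L, 150L, 380L),
               ali_end = c(75L, 350L, 560L),
               evalue = c(1e-40, 1e-60, 1e-50), stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = protein_id,
               accession = c("PF00403", "PF00403", "PF00122", "PF00702"),
               ali_start = c(10L, 95L, 220L, 450L),
               ali_end = c(75L, 160L, 420L, 630L),
               evalue = c(1e-40, 1e-38, 1e-60, 1e-50),
               stringsAsFactors = FALSE)
  }
}

# block size in genes
block_size <- function(kind) {
  switch(kind, atpase_one = 1L, atpase_two = 1L, cbb3 = 3L, fixi = 4L)
}

generate_genome <- function(cfg, genome_id) {
  n1 <- sample.int(length(cfg$copy_number_probs$one_domain), 1L,
                   prob = cfg$copy_number_probs$one_domain) - 1L
  n2 <- sample.int(length(cfg$copy_number_probs$two_domain), 1L,
                   prob = cfg$copy_number_probs$two_domain) - 1L
  embedded <- if (n1 > 0L) stats::runif(n1) < cfg$p_fixi_colocalization
  else logical()
  standalone_cbb3 <- stats::runif(1) < cfg$p_cbb3_cluster
  blocks <- c(rep("fixi", sum(embedded)),
              rep("atpase_one", n1 - sum(embedded)),
              rep("atpase_two", n2),
              rep("cbb3", as.integer(standalone_cbb3)))
  if (length(blocks) > 1L) blocks <- sample(blocks)
  contig_of_block <- if (length(blocks)) {
    sort(sample.int(cfg$contigs_per_genome, length(blocks), replace = TRUE))
  } else integer()

  gene_rows <- list(); hit_rows <- list(); atpase_rows <- list()
  gene_counter <- 0L
  step <- cfg$gene_length + cfg$intergenic_gap

  new_gene <- function(contig_id, pos, strand, labels = "") {
    gene_counter <<- gene_counter + 1L
    gid <- sprintf("%s_g%04d", genome_id, gene_counter)
    start <- (pos - 1L) * step + 1L
    data.frame(genome_id = genome_id, contig_id = contig_id, gene_id = gid,
               start = start, end = start + cfg$gene_length - 1L,
               strand = strand, protein_id = sub("_g", "_p", gid),
               labels = labels, stringsAsFactors = FALSE)
  }

  for (ci in seq_len(cfg$contigs_per_genome)) {
    contig_id <- sprintf("%s_c%d", genome_id, ci)
    my_blocks <- blocks[contig_of_block == ci]
    nb <- length(my_blocks)
    block_strands <- if (nb) sample(c("+", "-"), nb, replace = TRUE)
    else character()
    n_target <- sample.int(cfg$genes_per_contig[2] -
                             cfg$genes_per_contig[1] + 1L, 1L) +
      cfg$genes_per_contig[1] - 1L
    n_block_genes <- sum(vapply(my_blocks, block_size, integer(1)))
    # isolating fillers: >=1 at each edge slot, >=2 between blocks;
    # the contig grows beyond its sampled size if it cannot host the plan
    min_slots <- if (nb) c(1L, rep(2L, max(nb - 1L, 0L)), 1L) else 0L
    n_fill <- max(n_target - n_block_genes, sum(min_slots))
    slots <- min_slots
    extra <- n_fill - sum(slots)
    if (extra > 0L) {
      slots <- slots + stats::rmultinom(1, extra,
                                        rep(1, length(slots)))[, 1]
    }

    pos <- 0L
    strand_state <- sample(c("+", "-"), 1L)
    for (si in seq_along(slots)) {
      left_s <- if (si > 1L) block_strands[si - 1L] else NULL
      right_s <- if (si <= nb) block_strands[si] else NULL
      for (fi in seq_len(slots[si])) {
        if (stats::runif(1) < cfg$strand_flip_prob) {
          strand_state <- setdiff(c("+", "-"), strand_state)
        }
        s <- strand_state
        if (fi == 1L && !is.null(left_s)) s <- setdiff(c("+", "-"), left_s)
        if (fi == slots[si] && !is.null(right_s)) {
          s <- setdiff(c("+", "-"), right_s)
        }
        strand_state <- s
        pos <- pos + 1L
        g <- new_gene(contig_id, pos, s)
        gene_rows[[length(gene_rows) + 1L]] <- g
        u <- stats::runif(1)
        if (u < cfg$decoy_partial_prob) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            protein_id = g$protein_id,
            accession = c("PF00403", "PF00122"),
            ali_start = c(10L, 150L), ali_end = c(75L, 350L),
            evalue = c(1e-20, 1e-25), stringsAsFactors = FALSE)
        } else if (u < cfg$decoy_partial_prob + cfg$decoy_hit_prob) {
          nacc <- sample.int(2L, 1L)
          acc <- sample(cfg$decoy_domain_pool, nacc)
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            protein_id = g$protein_id, accession = acc,
            ali_start = 10L + 200L * (seq_len(nacc) - 1L),
            ali_end = 150L + 200L * (seq_len(nacc) - 1L),
            evalue = 10^-stats::runif(nacc, 10, 40),
            stringsAsFactors = FALSE)
        }
      }
      if (si <= nb) {
        kind <- my_blocks[si]
        s <- block_strands[si]
        if (kind %in% c("atpase_one", "atpase_two")) {
          variant <- if (kind == "atpase_one") "one_domain" else "two_domain"
          pos <- pos + 1L
          g <- new_gene(contig_id, pos, s)
          gene_rows[[length(gene_rows) + 1L]] <- g
          hit_rows[[length(hit_rows) + 1L]] <-
            signature_hits(g$protein_id, variant)
          atpase_rows[[length(atpase_rows) + 1L]] <- data.frame(
            genome_id = genome_id, protein_id = g$protein_id,
            variant = variant, embedded = FALSE,
            expected_classification = "unclassified",
            stringsAsFactors = FALSE)
        } else {
          n_slots <- block_size(kind)
          atp_at <- if (kind == "fixi") sample.int(n_slots, 1L) else 0L
          mi <- 0L
          for (i in seq_len(n_slots)) {
            pos <- pos + 1L
            if (i == atp_at) {
              g <- new_gene(contig_id, pos, s)
              hit_rows[[length(hit_rows) + 1L]] <-
                signature_hits(g$protein_id, "one_domain")
              atpase_rows[[length(atpase_rows) + 1L]] <- data.frame(
                genome_id = genome_id, protein_id = g$protein_id,
                variant = "one_domain", embedded = TRUE,
                expected_classification = "fixi_like",
                stringsAsFactors = FALSE)
            } else {
              mi <- mi + 1L
              g <- new_gene(contig_id, pos, s, labels = CBB3_MARKERS[mi])
            }
            gene_rows[[length(gene_rows) + 1L]] <- g
          }
        }
      }
    }
  }
  list(genes = do.call(rbind, gene_rows),
       hits = if (length(hit_rows)) do.call(rbind, hit_rows) else NULL,
       atpases = if (length(atpase_rows)) do.call(rbind, atpase_rows)
       else NULL,
       truth = data.frame(genome_id = genome_id, one_domain = n1,
                          two_domain = n2,
                          cbb3_present = standalone_cbb3 || any(embedded),
                          stringsAsFactors = FALSE))
}

# random binary joining of newick subtree strings (coalescent-style)
random_join_newick <- function(parts) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 2L)
    bl <- stats::runif(2, 0.01, 1)
    joined <- sprintf("(%s:%.4f,%s:%.4f)", parts[i[1]], bl[1],
                      parts[i[2]], bl[2])
    parts <- c(parts[-i], joined)
  }
  parts
}

#' Generate a synthetic dataset with ground truth
#'
#' Produces gene tables, domain hits, taxonomy, a phylogeny and the
#' planted truth for a [sim_config()]. Byte-identical output for a
#' fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `genes` (gene table), `hits` (domain
#'   hits), `taxonomy`, `tree` (`phylo`) and `truth` (list with
#'   `genomes` and `atpases` data frames).
#' @export
generate_dataset <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  orders <- sprintf("Order%02d", seq_len(cfg$n_orders))
  genes <- list(); hits <- list(); atp <- list(); gtruth <- list()
  tax_rows <- list()
  genome_ids_by_order <- list()
  for (oi in seq_len(cfg$n_orders)) {
    ids <- sprintf("G%02d_%03d", oi, seq_len(cfg$genomes_per_order))
    genome_ids_by_order[[orders[oi]]] <- ids
    for (gid in ids) {
      g <- generate_genome(cfg, gid)
      genes[[length(genes) + 1L]] <- g$genes
      if (!is.null(g$hits)) hits[[length(hits) + 1L]] <- g$hits
      if (!is.null(g$atpases)) atp[[length(atp) + 1L]] <- g$atpases
      gtruth[[length(gtruth) + 1L]] <- cbind(g$truth, order = orders[oi])
      tax_rows[[length(tax_rows) + 1L]] <- data.frame(
        genome_id = gid,
        lineage = sprintf(
          "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__%s;f__Fam%02d;g__Gen%02d;s__",
          orders[oi], oi, oi),
        stringsAsFactors = FALSE)
    }
  }
  genes <- finalize_gene_table(do.call(rbind, genes))
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(), accession = character(),
               ali_start = integer(), ali_end = integer(),
               evalue = numeric(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  atpases <- if (length(atp)) do.call(rbind, atp) else
    data.frame(genome_id = character(), protein_id = character(),
               variant = character(), embedded = logical(),
               expected_classification = character(),
               stringsAsFactors = FALSE)
  rownames(atpases) <- NULL
  taxonomy_raw <- do.call(rbind, tax_rows)
  # parse via the reader so downstream sees the standard rank columns
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf), add = TRUE)
  utils::write.table(taxonomy_raw, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  taxonomy <- read_taxonomy(tf)
  subtrees <- vapply(orders, function(o) {
    random_join_newick(sprintf("%s", genome_ids_by_order[[o]]))
  }, character(1))
  txt <- random_join_newick(subtrees)
  if (!grepl("(", txt, fixed = TRUE)) txt <- sprintf("(%s:1);", txt)
  else txt <- paste0(txt, ";")
  tree <- ape::read.tree(text = txt)
  if (cfg$scramble_orders) {
    tree$tip.label <- sample(tree$tip.label)
  }
  truth_genomes <- do.call(rbind, gtruth)
  rownames(truth_genomes) <- NULL
  list(genes = genes, hits = hits, taxonomy = taxonomy, tree = tree,
       truth = list(genomes = truth_genomes, atpases = atpases),
       config = cfg)
}

#' Generate a synthetic dataset and write it to disk
#'
#' Writes the exact file formats the readers consume: `genes.tsv`,
#' `domain_hits.tsv`, `taxonomy.tsv`, `tree.nwk` and `truth.json`.
#'
#' @inheritParams generate_dataset
#' @param out_dir Output directory (created if absent).
#' @return The [generate_dataset()] list, invisibly, with a `paths`
#'   element added.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  ds <- generate_dataset(cfg)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    fx_io_error(sprintf("cannot create directory %s", out_dir))
  }
  paths <- list(
    genes = file.path(out_dir, "genes.tsv"),
    hits = file.path(out_dir, "domain_hits.tsv"),
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    truth = file.path(out_dir, "truth.json"))
  write_gene_table(ds$genes, paths$genes)
  write_domain_hits(ds$hits, paths$hits)
  write_taxonomy(ds$taxonomy, paths$taxonomy)
  write_newick(ds$tree, paths$tree)
  jsonlite::write_json(ds$truth, paths$truth, dataframe = "columns",
                       digits = NA, pretty = TRUE)
  ds$paths <- paths
  invisible(ds)
}

#' Compare pipeline output against planted truth
#'
#' Exact-match comparison of per-genome copy numbers and cbb3 presence
#' and per-ATPase variant and classification. On a noiseless synthetic
#' dataset the mismatch report is empty.
#'
#' @param truth Truth list from [generate_dataset()] (elements
#'   `genomes`, `atpases`).
#' @param genome_summaries Output of [summarize_genomes()].
#' @param cluster_calls Output of [classify_contexts()].
#' @return `data.frame` of mismatches (zero rows when recovery is
#'   perfect) with columns `genome_id`, `item`, `expected`, `observed`.
#' @export
truth_compare <- function(truth, genome_summaries, cluster_calls) {
  if (!setequal(truth$genomes$genome_id, genome_summaries$genome_id)) {
    fx_validation_error("genome id sets differ between truth and output")
  }
  mism <- list()
  note <- function(genome_id, item, expected, observed) {
    mism[[length(mism) + 1L]] <<- data.frame(
      genome_id = genome_id, item = item,
      expected = as.character(expected), observed = as.character(observed),
      stringsAsFactors = FALSE)
  }
  gs <- genome_summaries[match(truth$genomes$genome_id,
                               genome_summaries$genome_id), ]
  for (v in c("one_domain", "two_domain")) {
    bad <- which(gs[[v]] != truth$genomes[[v]])
    for (i in bad) {
      note(gs$genome_id[i], paste0("copy_number_", v),
           truth$genomes[[v]][i], gs[[v]][i])
    }
  }
  bad <- which(gs$cbb3_present != truth$genomes$cbb3_present)
  for (i in bad) {
    note(gs$genome_id[i], "cbb3_present", truth$genomes$cbb3_present[i],
         gs$cbb3_present[i])
  }
  for (i in seq_len(nrow(truth$atpases))) {
    p <- truth$atpases$protein_id[i]
    j <- match(p, cluster_calls$focal_protein)
    if (is.na(j)) {
      note(truth$atpases$genome_id[i], paste0("missing_call:", p),
           truth$atpases$variant[i], NA)
      next
    }
    if (cluster_calls$variant[j] != truth$atpases$variant[i]) {
      note(truth$atpases$genome_id[i], paste0("variant:", p),
           truth$atpases$variant[i], cluster_calls$variant[j])
    }
    if (cluster_calls$classification[j] !=
        truth$atpases$expected_classification[i]) {
      note(truth$atpases$genome_id[i], paste0("classification:", p),
           truth$atpases$expected_classification[i],
           cluster_calls$classification[j])
    }
  }
  if (length(mism)) do.call(rbind, mism) else
    data.frame(genome_id = character(), item = character(),
               expected = character(), observed = character(),
               stringsAsFactors = FALSE)
}
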