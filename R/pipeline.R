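#' @title End-to-end pipeline orchestration
#' @name cli_pipeline
#' @description Chains the stages — variant classification, context
#'   extraction, FixI-like calling, genome-level cbb3 detection, and
#'   order-level aggregation with tree collapsing and iTOL export —
#'   with validated configuration and a machine-readable run manifest.
#'   A thin command-line wrapper over these functions ships in
#'   `inst/cli/fixiscan`.
NULL

#' Pipeline configuration
#'
#' @param genes,hits,taxonomy,tree Input file paths (or, for `genes`
#'   and `hits`, data frames already in memory).
#' @param out_dir Output directory.
#' @param signatures Named list of accession vectors; default the two
#'   Cu-ATPase variants.
#' @param mode Architecture match mode, `"exact"` or `"subsequence"`.
#' @param markers [marker_set()] identifying cbb3 subunit genes.
#' @param min_markers Distinct markers required for a FixI-like call
#'   (and for genome-level cbb3 presence); default 2.
#' @param cbb3_mode `"run"` (markers must share a co-directional run)
#'   or `"anywhere"`.
#' @param max_gap_bp Optional intergenic-gap limit for context
#'   extraction.
#' @param max_copy_bin Top copy-number bin; default 7.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(genes, hits, taxonomy = NULL, tree = NULL,
                            out_dir, signatures = default_signatures(),
                            mode = c("exact", "subsequence"),
                            markers = marker_set(), min_markers = 2L,
                            cbb3_mode = c("run", "anywhere"),
                            max_gap_bp = NULL, max_copy_bin = 7L) {
  mode <- match.arg(mode)
  cbb3_mode <- match.arg(cbb3_mode)
  for (p in list(genes, hits, taxonomy, tree)) {
    if (is.character(p) && !file.exists(p)) {
      fx_validation_error(sprintf("input file not found: %s", p))
    }
  }
  if (min_markers < 1L) fx_validation_error("min_markers must be >= 1")
  if (max_copy_bin < 1L) fx_validation_error("max_copy_bin must be >= 1")
  if (!is.null(max_gap_bp) && max_gap_bp < 0) {
    fx_validation_error("max_gap_bp must be >= 0")
  }
  structure(list(genes = genes, hits = hits, taxonomy = taxonomy,
                 tree = tree, out_dir = out_dir, signatures = signatures,
                 mode = mode, markers = markers,
                 min_markers = as.integer(min_markers),
                 cbb3_mode = cbb3_mode, max_gap_bp = max_gap_bp,
                 max_copy_bin = as.integer(max_copy_bin)),
            class = "pipeline_config")
}

config_fingerprint <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  public <- cfg[setdiff(names(cfg), c("out_dir"))]
  writeLines(utils::capture.output(utils::str(public)), f)
  unname(tools::md5sum(f))
}

input_checksums <- function(cfg) {
  paths <- Filter(is.character, cfg[c("genes", "hits", "taxonomy", "tree")])
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

write_manifest <- function(path, cfg, counts) {
  manifest <- list(
    config_hash = config_fingerprint(cfg),
    inputs = input_checksums(cfg),
    counts = counts,
    # timestamp isolated in its own field so outputs proper stay
    # byte-comparable across runs
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

resolve_gene_input <- function(x) {
  if (is.character(x)) read_gene_table(x) else x
}

resolve_hits_input <- function(x) {
  if (is.character(x)) read_domain_hits(x) else x
}

#' Run the classification stage
#'
#' Classifies every protein with domain hits, extracts ATPase context
#' clusters, calls FixI-like clusters, decides genome-level cbb3
#' presence and writes `cluster_calls.tsv`, `genome_summary.tsv` and
#' `manifest_classify.json` to the configured output directory.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `calls` (variant calls), `cluster_calls`,
#'   `genome_summaries` and the output `paths`, invisibly.
#' @export
run_classify <- function(cfg) {
  genes <- resolve_gene_input(cfg$genes)
  hits <- resolve_hits_input(cfg$hits)
  if (!dir.exists(cfg$out_dir) &&
      !dir.create(cfg$out_dir, recursive = TRUE)) {
    fx_io_error(sprintf("cannot create directory %s", cfg$out_dir))
  }
  calls <- classify_proteins(hits, cfg$signatures, cfg$mode)
  clusters <- extract_all_contexts(genes, calls, cfg$max_gap_bp)
  architectures <- NULL
  if (length(cfg$markers$accessions)) {
    by_protein <- split(hits, hits$protein_id)
    architectures <- lapply(by_protein, build_architecture)
  }
  cluster_calls <- classify_contexts(clusters, cfg$markers,
                                     cfg$min_markers, architectures)
  genome_ids <- unique(genes$genome_id)
  cbb3 <- vapply(genome_ids, function(g) {
    genome_has_cbb3_cluster(genes[genes$genome_id == g, , drop = FALSE],
                            cfg$markers, cfg$min_markers, cfg$cbb3_mode)
  }, logical(1))
  gs <- summarize_genomes(genome_ids, cluster_calls,
                          stats::setNames(cbb3, genome_ids),
                          variants = names(cfg$signatures))
  paths <- list(
    cluster_calls = file.path(cfg$out_dir, "cluster_calls.tsv"),
    genome_summary = file.path(cfg$out_dir, "genome_summary.tsv"),
    manifest = file.path(cfg$out_dir, "manifest_classify.json"))
  utils::write.table(cluster_calls, paths$cluster_calls, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gs, paths$genome_summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- list(n_genomes = length(genome_ids), n_genes = nrow(genes),
                 n_proteins_with_hits = length(unique(hits$protein_id)),
                 n_atpase_calls = nrow(cluster_calls))
  for (v in names(cfg$signatures)) {
    counts[[paste0("n_", v)]] <- sum(cluster_calls$variant == v)
  }
  counts$n_fixi_like <- sum(cluster_calls$classification == "fixi_like")
  counts$n_cbb3_genomes <- sum(cbb3)
  write_manifest(paths$manifest, cfg, counts)
  invisible(list(calls = calls, cluster_calls = cluster_calls,
                 genome_summaries = gs, paths = paths))
}

#' Run the aggregation stage
#'
#' Consumes the classification outputs plus taxonomy and tree, writes
#' `order_summary.tsv`, the order-collapsed newick, iTOL dataset files
#' and `manifest_aggregate.json`.
#'
#' @param cfg A [pipeline_config()] whose `out_dir` holds the
#'   [run_classify()] outputs and which names `taxonomy` and,
#'   optionally, `tree` inputs.
#' @return List with `order_summary`, `collapsed_tree` (or `NULL`) and
#'   output `paths`, invisibly.
#' @export
run_aggregate <- function(cfg) {
  gs_path <- file.path(cfg$out_dir, "genome_summary.tsv")
  if (!file.exists(gs_path)) {
    fx_validation_error(sprintf("classification output not found: %s (run run_classify first)",
                                gs_path))
  }
  gs <- utils::read.delim(gs_path, stringsAsFactors = FALSE)
  if (is.null(cfg$taxonomy)) fx_validation_error("taxonomy input required")
  taxonomy <- if (is.character(cfg$taxonomy)) read_taxonomy(cfg$taxonomy)
  else cfg$taxonomy
  summary <- summarize_order(gs, taxonomy,
                             variants = names(cfg$signatures),
                             max_copy_bin = cfg$max_copy_bin)
  paths <- list(order_summary = file.path(cfg$out_dir, "order_summary.tsv"),
                manifest = file.path(cfg$out_dir, "manifest_aggregate.json"))
  write_order_summary(summary, paths$order_summary)
  itol <- write_itol_datasets(summary, cfg$out_dir)
  paths$itol <- itol
  collapsed <- NULL
  if (!is.null(cfg$tree)) {
    tree <- if (is.character(cfg$tree)) read_newick(cfg$tree) else cfg$tree
    extra_tree <- setdiff(tree$tip.label, gs$genome_id)
    extra_data <- setdiff(gs$genome_id, tree$tip.label)
    if (length(extra_data)) {
      fx_validation_error(sprintf(
        "tree/summary leaf mismatch; only in data: %s%s",
        paste(extra_data, collapse = ", "),
        if (length(extra_tree)) paste0("; only in tree: ",
                                       paste(extra_tree, collapse = ", "))
        else ""))
    }
    pruned <- if (length(extra_tree)) prune_tree(tree, gs$genome_id)
    else tree
    collapsed <- collapse_to_rank(pruned, taxonomy, rank = "order")
    paths$collapsed_tree <- file.path(cfg$out_dir, "collapsed_order_tree.nwk")
    write_newick(collapsed, paths$collapsed_tree)
  }
  counts <- list(n_orders = length(unique(summary$order)),
                 n_summary_rows = nrow(summary),
                 n_itol_files = length(itol))
  write_manifest(paths$manifest, cfg, counts)
  invisible(list(order_summary = summary, collapsed_tree = collapsed,
                 paths = paths))
}

#' Run classification and aggregation in one call
#'
#' @inheritParams run_classify
#' @return List combining the [run_classify()] and [run_aggregate()]
#'   results, invisibly.
#' @export
run_pipeline <- function(cfg) {
  cls <- run_classify(cfg)
  agg <- run_aggregate(cfg)
  invisible(c(cls, agg))
}
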