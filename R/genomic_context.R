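#' @title Co-directional gene-neighborhood extraction
#' @name genomic_context
#' @description The genomic-context unit is the strand run: starting
#'   from a focal gene, the neighborhood extends gene by gene upstream
#'   and downstream for as long as the neighbor is on the same strand
#'   (and, optionally, within an intergenic-gap limit). Strand is the
#'   sole default criterion; clusters never cross contig boundaries and
#'   contigs are treated as linear.
NULL

#' Bounds of the same-strand run containing a focal gene
#'
#' Low-level primitive on plain vectors. Extends left and right from
#' `focal` while the neighboring gene shares the focal strand and, when
#' `max_gap_bp` is given, the intergenic distance does not exceed it.
#'
#' @param strands Character vector of `"+"`/`"-"` in contig order.
#' @param focal 1-based index of the focal gene.
#' @param starts,ends Optional coordinate vectors, required when
#'   `max_gap_bp` is set.
#' @param max_gap_bp Optional maximum intergenic gap in bp.
#' @return Integer vector `c(lo, hi)` of 1-based run bounds.
#' @export
strand_run_bounds <- function(strands, focal, starts = NULL, ends = NULL,
                              max_gap_bp = NULL) {
  n <- length(strands)
  if (focal < 1L || focal > n) {
    fx_contract_error(sprintf("focal index %d out of range 1..%d", focal, n))
  }
  if (!is.null(max_gap_bp) && (is.null(starts) || is.null(ends))) {
    fx_contract_error("max_gap_bp requires start/end coordinates")
  }
  s <- strands[focal]
  lo <- focal
  while (lo > 1L && strands[lo - 1L] == s &&
         (is.null(max_gap_bp) ||
          starts[lo] - ends[lo - 1L] - 1L <= max_gap_bp)) {
    lo <- lo - 1L
  }
  hi <- focal
  while (hi < n && strands[hi + 1L] == s &&
         (is.null(max_gap_bp) ||
          starts[hi + 1L] - ends[hi] - 1L <= max_gap_bp)) {
    hi <- hi + 1L
  }
  c(lo, hi)
}

#' Extract the co-directional cluster around a focal gene
#'
#' @param contig_genes Gene table rows of a single contig, ordered by
#'   `rank`.
#' @param focal_rank 0-based rank of the focal gene on the contig.
#' @param max_gap_bp Optional maximum intergenic gap in bp; `NULL`
#'   (default) applies no gap limit, matching the strand-only criterion.
#' @return A `context_cluster` object: list with `genome_id`,
#'   `contig_id`, `focal` (one-row `data.frame`), `members` (gene-table
#'   rows of the run, contiguous ranks, all on the focal strand),
#'   `upstream_count` and `downstream_count` (genes left/right of the
#'   focal in genomic coordinates).
#' @export
extract_strand_run <- function(contig_genes, focal_rank, max_gap_bp = NULL) {
  n <- nrow(contig_genes)
  if (n == 0L || length(unique(contig_genes$contig_id)) != 1L) {
    fx_contract_error("contig_genes must be a non-empty single-contig table")
  }
  contig_genes <- contig_genes[order(contig_genes$rank), , drop = FALSE]
  idx <- focal_rank + 1L
  if (focal_rank < 0L || idx > n) {
    fx_contract_error(sprintf("focal_rank %d out of range 0..%d",
                              focal_rank, n - 1L))
  }
  b <- strand_run_bounds(contig_genes$strand, idx,
                         starts = contig_genes$start,
                         ends = contig_genes$end, max_gap_bp = max_gap_bp)
  structure(list(
    genome_id = contig_genes$genome_id[idx],
    contig_id = contig_genes$contig_id[idx],
    focal = contig_genes[idx, , drop = FALSE],
    members = contig_genes[b[1]:b[2], , drop = FALSE],
    upstream_count = idx - b[1],
    downstream_count = b[2] - idx
  ), class = "context_cluster")
}

#' @export
print.context_cluster <- function(x, ...) {
  cat(sprintf("<context_cluster> %s/%s focal %s (%s): %d member(s), %d up / %d down\n",
              x$genome_id, x$contig_id, x$focal$gene_id, x$focal$strand,
              nrow(x$members), x$upstream_count, x$downstream_count))
  invisible(x)
}

#' Extract the context cluster of every classified ATPase
#'
#' One cluster is produced per call whose variant is not `"none"`;
#' overlapping clusters from distinct ATPases are kept separately.
#'
#' @param genes Gene table covering all genomes.
#' @param calls Variant calls as from [classify_proteins()]
#'   (columns `protein_id`, `variant`).
#' @param max_gap_bp Optional intergenic-gap limit in bp.
#' @return List of `context_cluster` objects, each with a `variant`
#'   element attached.
#' @export
extract_all_contexts <- function(genes, calls, max_gap_bp = NULL) {
  calls <- calls[calls$variant != "none", , drop = FALSE]
  if (nrow(calls) == 0L) return(list())
  pos <- match(calls$protein_id, genes$protein_id)
  if (anyNA(pos)) {
    fx_validation_error(sprintf(
      "variant calls reference protein_ids absent from the gene tables: %s",
      paste(calls$protein_id[is.na(pos)], collapse = ", ")))
  }
  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- pos[i]
    contig <- genes[key == key[g], , drop = FALSE]
    cl <- extract_strand_run(contig, genes$rank[g], max_gap_bp = max_gap_bp)
    cl$variant <- calls$variant[i]
    out[[i]] <- cl
  }
  out
}
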