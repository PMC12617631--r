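#' @title FixI-like cluster classification and genome-level cbb3 detection
#' @name cluster_classification
#' @description A context cluster is called FixI-like when its focal
#'   ATPase is the 1-domain variant and the surrounding co-directional
#'   run carries at least `min_markers` distinct cbb3-type oxidase
#'   subunit markers; everything else is left unclassified (such
#'   ATPases may be CopA-like detoxifiers or other metal transporters).
NULL

#' Define a marker set
#'
#' Markers identify cbb3-type cytochrome c oxidase subunit genes.
#' Identity is primarily via gene labels in the input table; an
#' optional set of Pfam accessions can be supplied to match against
#' member architectures when label annotations are unavailable (no
#' default accession list is shipped).
#'
#' @param name Marker-set name.
#' @param labels Character vector of marker gene labels.
#' @param accessions Optional character vector of Pfam accessions.
#' @return A `marker_set` object.
#' @export
marker_set <- function(name = "cbb3_subunits",
                       labels = c("ccoN", "ccoO", "ccoP",
                                  "fixO", "fixP", "fixC"),
                       accessions = character()) {
  if (length(labels) == 0L && length(accessions) == 0L) {
    fx_validation_error("marker set needs labels and/or accessions")
  }
  structure(list(name = name, labels = labels, accessions = accessions),
            class = "marker_set")
}

#' Count distinct markers in a context cluster
#'
#' Counts the number of DISTINCT marker labels (and, when supplied,
#' marker accessions matched against member architectures) found among
#' cluster members, excluding the focal ATPase itself. Duplicated
#' subunit genes count once.
#'
#' @param cluster A `context_cluster` from [extract_strand_run()].
#' @param markers A [marker_set()].
#' @param architectures Optional named list `protein_id -> accession
#'   vector` used for accession-based matching.
#' @return Integer count of distinct markers.
#' @export
count_markers <- function(cluster, markers, architectures = NULL) {
  members <- cluster$members
  members <- members[members$gene_id != cluster$focal$gene_id, , drop = FALSE]
  found <- character()
  for (i in seq_len(nrow(members))) {
    found <- c(found, intersect(split_labels(members$labels[i]),
                                markers$labels))
    if (length(markers$accessions) && !is.null(architectures) &&
        !is.na(members$protein_id[i])) {
      arch <- architectures[[members$protein_id[i]]]
      if (!is.null(arch)) {
        found <- c(found, intersect(arch, markers$accessions))
      }
    }
  }
  length(unique(found))
}

#' Classify one ATPase context cluster
#'
#' @inheritParams count_markers
#' @param variant Variant call of the focal ATPase (`"one_domain"`,
#'   `"two_domain"`, ...).
#' @param min_markers Minimum number of distinct markers required;
#'   default 2 (the minimal reading of "multiple" subunits).
#' @return A list with `cluster`, `variant`, `n_markers` and
#'   `classification` (`"fixi_like"` or `"unclassified"`).
#' @export
classify_cluster <- function(cluster, variant, markers, min_markers = 2L,
                             architectures = NULL) {
  if (min_markers < 1L) fx_validation_error("min_markers must be >= 1")
  n <- count_markers(cluster, markers, architectures)
  list(cluster = cluster, variant = variant, n_markers = n,
       classification = if (identical(variant, "one_domain") &&
                            n >= min_markers) "fixi_like" else "unclassified")
}

#' Classify all context clusters into a report table
#'
#' @param clusters List of `context_cluster` objects with `variant`
#'   attached, as produced by [extract_all_contexts()].
#' @inheritParams classify_cluster
#' @return One row per ATPase: `genome_id`, `contig_id`,
#'   `focal_protein`, `variant`, `n_members`, `upstream_count`,
#'   `downstream_count`, `n_markers`, `classification`,
#'   `member_gene_ids` and `member_labels` (semicolon-joined).
#' @export
classify_contexts <- function(clusters, markers, min_markers = 2L,
                              architectures = NULL) {
  rows <- lapply(clusters, function(cl) {
    cc <- classify_cluster(cl, cl$variant, markers, min_markers,
                           architectures)
    labs <- unlist(lapply(cl$members$labels, split_labels))
    data.frame(
      genome_id = cl$genome_id, contig_id = cl$contig_id,
      focal_protein = cl$focal$protein_id, variant = cl$variant,
      n_members = nrow(cl$members),
      upstream_count = cl$upstream_count,
      downstream_count = cl$downstream_count,
      n_markers = cc$n_markers, classification = cc$classification,
      member_gene_ids = paste(cl$members$gene_id, collapse = ";"),
      member_labels = paste(labs, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(
      genome_id = character(), contig_id = character(),
      focal_protein = character(), variant = character(),
      n_members = integer(), upstream_count = integer(),
      downstream_count = integer(), n_markers = integer(),
      classification = character(), member_gene_ids = character(),
      member_labels = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Does a genome encode a cbb3-type oxidase gene cluster?
#'
#' In `"run"` mode (default) the genome qualifies when some contig
#' contains a contiguous same-strand run holding at least `min_markers`
#' distinct marker labels; runs are computed with the same strand-run
#' semantics as the context extraction, seeded at each marker gene. In
#' `"anywhere"` mode mere presence of `min_markers` distinct marker
#' labels anywhere in the genome qualifies.
#'
#' @param genome_genes Gene table rows of one genome.
#' @param markers A [marker_set()].
#' @param min_markers Minimum distinct markers; default 2.
#' @param mode `"run"` or `"anywhere"`.
#' @return Logical scalar.
#' @export
genome_has_cbb3_cluster <- function(genome_genes, markers, min_markers = 2L,
                                    mode = c("run", "anywhere")) {
  mode <- match.arg(mode)
  if (nrow(genome_genes) == 0L) return(FALSE)
  labs <- lapply(genome_genes$labels, function(x)
    intersect(split_labels(x), markers$labels))
  if (mode == "anywhere") {
    return(length(unique(unlist(labs))) >= min_markers)
  }
  for (contig in split(seq_len(nrow(genome_genes)), genome_genes$contig_id)) {
    contig <- contig[order(genome_genes$rank[contig])]
    strands <- genome_genes$strand[contig]
    seeds <- which(lengths(labs[contig]) > 0L)
    for (s in seeds) {
      b <- strand_run_bounds(strands, s)
      n <- length(unique(unlist(labs[contig][b[1]:b[2]])))
      if (n >= min_markers) return(TRUE)
    }
  }
  FALSE
}
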