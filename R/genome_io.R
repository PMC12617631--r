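#' @title Readers and writers for gene tables, domain hits, taxonomy,
#'   trees and iTOL datasets
#' @name genome_io
#' @description All external formats used by the pipeline are plain
#'   UTF-8, tab-separated text with `#`-prefixed comment lines ignored.
#'   Coordinates are 1-based inclusive in every dialect; the internal
#'   `rank` column (position of a gene along its contig) is 0-based.
NULL

GTDB_RANKS <- c(d = "domain", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")

# Read non-comment, non-empty lines keeping original line numbers.
read_data_lines <- function(path) {
  if (!file.exists(path)) fx_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

parse_int_field <- function(x, what, lineno) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) | v != suppressWarnings(as.numeric(x)))
  if (length(bad)) {
    fx_parse_error(sprintf("malformed %s '%s' at line %d",
                           what, x[bad[1]], lineno[bad[1]]))
  }
  v
}

parse_strand_field <- function(x, lineno) {
  bad <- which(!x %in% c("+", "-"))
  if (length(bad)) {
    fx_parse_error(sprintf("malformed strand '%s' at line %d (expected + or -)",
                           x[bad[1]], lineno[bad[1]]))
  }
  x
}

# Sort by (genome, contig, start) with the deterministic tie-break
# (end, then gene_id), assign 0-based ranks within each contig, and
# check protein_id uniqueness per genome.
finalize_gene_table <- function(df) {
  o <- order(df$genome_id, df$contig_id, df$start, df$end, df$gene_id,
             method = "radix")
  df <- df[o, , drop = FALSE]
  key <- paste(df$genome_id, df$contig_id, sep = "\r")
  df$rank <- stats::ave(seq_len(nrow(df)), key,
                        FUN = function(i) seq_along(i) - 1L)
  has_p <- !is.na(df$protein_id) & nzchar(df$protein_id)
  pk <- paste(df$genome_id[has_p], df$protein_id[has_p], sep = "\r")
  if (anyDuplicated(pk)) {
    dup <- df$protein_id[has_p][duplicated(pk)][1]
    fx_validation_error(sprintf("duplicate protein_id within a genome: %s", dup))
  }
  rownames(df) <- NULL
  df[, c("genome_id", "contig_id", "rank", "gene_id", "start", "end",
         "strand", "protein_id", "labels")]
}

#' Read a gene table
#'
#' Reads per-genome gene coordinates from either the package's tabular
#' dialect or a GFF3-like file, sorts genes by position and assigns the
#' 0-based per-contig `rank` used by all neighborhood operations.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (columns `genome_id`, `contig_id`, `gene_id`,
#'   `start`, `end`, `strand`, `protein_id`, `labels`; labels
#'   semicolon-joined, possibly empty) or `"gff3"` (standard 9 columns;
#'   only `gene` features are kept, `protein_id` and `marker` read from
#'   the attribute column; non-gene features are dropped with a message).
#' @param genome_id Genome identifier used for the GFF3 dialect, which
#'   carries no genome column; defaults to the file basename.
#' @return A `data.frame` with columns `genome_id`, `contig_id`, `rank`,
#'   `gene_id`, `start`, `end`, `strand` (`"+"`/`"-"`), `protein_id`
#'   (`NA` for non-coding) and `labels` (semicolon-joined marker tags,
#'   `""` when none), sorted by genome, contig and start coordinate.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand\tprotein_id\tlabels",
#'              "g1\tc1\tga\t1\t900\t+\tpa\t",
#'              "g1\tc1\tgb\t1001\t1900\t-\tpb\tccoN"), tf)
#' read_gene_table(tf)
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"),
                            genome_id = NULL) {
  dialect <- match.arg(dialect)
  dat <- read_data_lines(path)
  if (dialect == "tsv") {
    if (length(dat$lines) == 0L) {
      fx_parse_error(sprintf("no header line in %s", path))
    }
    header <- strsplit(dat$lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("genome_id", "contig_id", "gene_id", "start", "end",
              "strand", "protein_id", "labels")
    if (!all(need %in% header)) {
      fx_parse_error(sprintf("missing columns in %s: %s", path,
                             paste(setdiff(need, header), collapse = ", ")))
    }
    rows <- dat$lines[-1]
    lineno <- dat$lineno[-1]
    if (length(rows) == 0L) return(empty_gene_table())
    parts <- strsplit(rows, "\t", fixed = TRUE)
    nf <- lengths(parts)
    # trailing empty labels field may be dropped by strsplit
    parts[nf == length(header) - 1L] <-
      lapply(parts[nf == length(header) - 1L], function(p) c(p, ""))
    if (any(lengths(parts) != length(header))) {
      bad <- which(lengths(parts) != length(header))[1]
      fx_parse_error(sprintf("wrong field count at line %d", lineno[bad]))
    }
    m <- do.call(rbind, parts)
    colnames(m) <- header
    df <- data.frame(
      genome_id = m[, "genome_id"], contig_id = m[, "contig_id"],
      gene_id = m[, "gene_id"],
      start = parse_int_field(m[, "start"], "start coordinate", lineno),
      end = parse_int_field(m[, "end"], "end coordinate", lineno),
      strand = parse_strand_field(m[, "strand"], lineno),
      protein_id = ifelse(nzchar(m[, "protein_id"]), m[, "protein_id"], NA),
      labels = m[, "labels"],
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(genome_id)) {
      genome_id <- sub("\\.[^.]*$", "", basename(path))
    }
    rows <- dat$lines
    lineno <- dat$lineno
    if (length(rows) == 0L) return(empty_gene_table())
    parts <- strsplit(rows, "\t", fixed = TRUE)
    if (any(lengths(parts) != 9L)) {
      bad <- which(lengths(parts) != 9L)[1]
      fx_parse_error(sprintf("expected 9 GFF3 columns at line %d", lineno[bad]))
    }
    m <- do.call(rbind, parts)
    is_gene <- m[, 3] == "gene"
    n_drop <- sum(!is_gene)
    if (n_drop > 0) {
      message(sprintf("read_gene_table: dropped %d non-gene feature(s) from %s",
                      n_drop, path))
    }
    m <- m[is_gene, , drop = FALSE]
    lineno <- lineno[is_gene]
    if (nrow(m) == 0L) return(empty_gene_table())
    attr_field <- function(attrs, key) {
      vapply(strsplit(attrs, ";", fixed = TRUE), function(kv) {
        kv <- trimws(kv)
        hit <- grep(paste0("^", key, "="), kv, value = TRUE)
        if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else ""
      }, character(1))
    }
    df <- data.frame(
      genome_id = genome_id, contig_id = m[, 1],
      gene_id = attr_field(m[, 9], "ID"),
      start = parse_int_field(m[, 4], "start coordinate", lineno),
      end = parse_int_field(m[, 5], "end coordinate", lineno),
      strand = parse_strand_field(m[, 7], lineno),
      protein_id = attr_field(m[, 9], "protein_id"),
      labels = gsub(",", ";", attr_field(m[, 9], "marker"), fixed = TRUE),
      stringsAsFactors = FALSE
    )
    df$protein_id[!nzchar(df$protein_id)] <- NA
    df$gene_id[!nzchar(df$gene_id)] <-
      paste0("gene_", seq_len(nrow(df)))[!nzchar(df$gene_id)]
  }
  bad <- which(df$start < 1L | df$end < df$start)
  if (length(bad)) {
    fx_parse_error(sprintf("invalid coordinates (start %d, end %d) at line %d",
                           df$start[bad[1]], df$end[bad[1]], lineno[bad[1]]))
  }
  finalize_gene_table(df)
}

empty_gene_table <- function() {
  data.frame(genome_id = character(), contig_id = character(),
             rank = integer(), gene_id = character(), start = integer(),
             end = integer(), strand = character(), protein_id = character(),
             labels = character(), stringsAsFactors = FALSE)
}

#' Write a gene table in the package TSV dialect
#'
#' @param genes A gene table as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes[, c("genome_id", "contig_id", "gene_id", "start", "end",
                   "strand", "protein_id", "labels")]
  out$protein_id[is.na(out$protein_id)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read Pfam domain hits
#'
#' Reads a table of per-protein Pfam-A hits (as produced by re-serializing
#' `pfam_scan` output). Version-suffixed accessions such as `PF00403.28`
#' are stripped to the unversioned accession; anything not matching
#' `PF` + 5 digits is rejected.
#'
#' @param path TSV with columns `protein_id`, `accession`, `ali_start`,
#'   `ali_end`, `evalue`.
#' @return A `data.frame` with those columns, hits of each protein sorted
#'   by `ali_start` (ties broken by smaller `evalue`).
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) fx_io_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "accession", "ali_start", "ali_end", "evalue")
  if (!all(need %in% names(df))) {
    fx_parse_error(sprintf("missing columns in %s: %s", path,
                           paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df <- df[, need]
  if (nrow(df) == 0L) return(df)
  df$accession <- sub("\\.\\d+$", "", df$accession)
  bad <- which(!grepl("^PF\\d{5}$", df$accession))
  if (length(bad)) {
    fx_validation_error(sprintf("invalid Pfam accession '%s' for protein %s",
                                df$accession[bad[1]], df$protein_id[bad[1]]))
  }
  df$ali_start <- as.integer(df$ali_start)
  df$ali_end <- as.integer(df$ali_end)
  df$evalue <- as.numeric(df$evalue)
  if (any(df$ali_start < 1L | df$ali_end < df$ali_start | df$evalue < 0)) {
    fx_validation_error("invalid alignment coordinates or e-value")
  }
  df <- df[order(df$protein_id, df$ali_start, df$evalue, method = "radix"), ]
  rownames(df) <- NULL
  df
}

#' @rdname read_domain_hits
#' @param hits Domain-hit `data.frame`.
#' @export
write_domain_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GTDB-style taxonomy table
#'
#' Parses lineage strings of the form
#' `d__...;p__...;c__...;o__...;f__...;g__...;s__...` into one column per
#' rank. Trailing ranks may be missing or empty, but the order rank is
#' required for every genome since all aggregation happens at order level.
#'
#' @param path TSV with columns `genome_id` and `lineage`.
#' @return A `data.frame` with columns `genome_id`, `lineage` and the
#'   seven GTDB ranks (`domain` ... `species`, `NA` where absent).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) fx_io_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("genome_id", "lineage") %in% names(df))) {
    fx_parse_error(sprintf("taxonomy %s must have genome_id and lineage columns",
                           path))
  }
  if (anyDuplicated(df$genome_id)) {
    fx_validation_error(sprintf("duplicate genome_id in taxonomy: %s",
                                df$genome_id[duplicated(df$genome_id)][1]))
  }
  ranks <- matrix(NA_character_, nrow(df), length(GTDB_RANKS),
                  dimnames = list(NULL, unname(GTDB_RANKS)))
  if (nrow(df) > 0) {
    fields <- strsplit(df$lineage, ";", fixed = TRUE)
    for (i in seq_len(nrow(df))) {
      f <- trimws(fields[[i]])
      pref <- sub("__.*$", "", f)
      name <- sub("^.__", "", f)
      ok <- pref %in% names(GTDB_RANKS) & grepl("^.__", f)
      for (j in which(ok)) {
        if (nzchar(name[j])) ranks[i, GTDB_RANKS[[pref[j]]]] <- name[j]
      }
    }
    miss <- which(is.na(ranks[, "order"]))
    if (length(miss)) {
      fx_validation_error(sprintf("lineage for genome %s lacks an order (o__) field",
                                  df$genome_id[miss[1]]))
    }
  }
  cbind(df[, c("genome_id", "lineage")], as.data.frame(ranks))
}

#' @rdname read_taxonomy
#' @param taxonomy Taxonomy `data.frame` (only `genome_id` and `lineage`
#'   are written).
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("genome_id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a newick phylogeny
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that
#' validate leaf-label uniqueness.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) fx_io_error(sprintf("file not found: %s", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) fx_parse_error(sprintf("could not parse newick in %s", path))
  if (anyDuplicated(tree$tip.label)) {
    fx_validation_error("duplicate leaf labels in tree")
  }
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write iTOL annotation datasets for an order-level summary
#'
#' Emits one `DATASET_MULTIBAR` file per ATPase variant (one field per
#' copy-number bin) and one `DATASET_SIMPLEBAR` file for the proportion
#' of genomes per order that encode a cbb3-type oxidase gene cluster.
#' Files are plain fixed-header text suitable for drag-and-drop into
#' iTOL; proportions are written with 6 decimal places.
#'
#' @param summary Order summary as returned by [summarize_order()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_itol_datasets <- function(summary, out_dir) {
  if (nrow(summary) == 0L) fx_validation_error("empty order summary")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    fx_io_error(sprintf("cannot create directory %s", out_dir))
  }
  pcols <- grep("^p\\d+$", names(summary), value = TRUE)
  pcols <- pcols[order(as.integer(sub("^p", "", pcols)))]
  bar_colors <- grDevices::hcl.colors(length(pcols), "Viridis")
  files <- character()
  for (v in unique(summary$variant)) {
    sub <- summary[summary$variant == v, , drop = FALSE]
    f <- file.path(out_dir, sprintf("itol_copy_number_%s.txt", v))
    hdr <- c(
      "DATASET_MULTIBAR",
      "SEPARATOR TAB",
      paste0("DATASET_LABEL\tcopy_number_", v),
      "COLOR\t#1f78b4",
      paste(c("FIELD_LABELS",
              paste0("copy_", sub("^p", "", pcols))), collapse = "\t"),
      paste(c("FIELD_COLORS", bar_colors), collapse = "\t"),
      "DATA"
    )
    rows <- vapply(seq_len(nrow(sub)), function(i) {
      paste(c(sub$order[i], sprintf("%.6f", as.numeric(sub[i, pcols]))),
            collapse = "\t")
    }, character(1))
    writeLines(c(hdr, rows), f)
    files <- c(files, f)
  }
  orders <- summary[!duplicated(summary$order),
                    c("order", "cbb3_proportion"), drop = FALSE]
  f <- file.path(out_dir, "itol_cbb3_proportion.txt")
  hdr <- c("DATASET_SIMPLEBAR", "SEPARATOR TAB",
           "DATASET_LABEL\tcbb3_cluster_proportion", "COLOR\t#e31a1c",
           "DATA")
  rows <- sprintf("%s\t%.6f", orders$order, orders$cbb3_proportion)
  writeLines(c(hdr, rows), f)
  files <- c(files, f)
  invisible(files)
}

#' Re-parse the DATA section of an iTOL dataset file
#'
#' @param path An iTOL dataset text file written by [write_itol_datasets()].
#' @return A `data.frame` with column `id` followed by the numeric fields.
#' @export
read_itol_data <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- match("DATA", lines)
  if (is.na(i)) fx_parse_error(sprintf("no DATA section in %s", path))
  rows <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  id <- vapply(parts, `[[`, character(1), 1L)
  vals <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  out <- data.frame(id = id, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(vals))
}

# Split a semicolon-joined labels field into a character vector.
split_labels <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1]]
}
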