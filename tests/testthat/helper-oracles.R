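# Independent brute-force oracles and small fixture builders.

# Brute-force signature matcher: tries signatures longest first; in
# subsequence mode checks every window explicitly.
oracle_classify <- function(arch, signatures, mode) {
  for (k in order(-lengths(signatures))) {
    sig <- signatures[[k]]
    m <- length(sig)
    hit <- if (mode == "exact") {
      length(arch) == m && identical(unname(arch), unname(sig))
    } else {
      found <- FALSE
      if (m <= length(arch)) {
        for (s in seq_len(length(arch) - m + 1L)) {
          if (identical(arch[s:(s + m - 1L)], sig)) { found <- TRUE; break }
        }
      }
      found
    }
    if (hit) return(names(signatures)[k])
  }
  "none"
}

# Exhaustive maximal same-strand window containing the focal gene:
# enumerate every contiguous window, keep uniform ones containing the
# focal index, return the longest.
oracle_strand_run <- function(strands, focal) {
  n <- length(strands)
  best <- c(focal, focal)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i <= focal && focal <= j &&
          all(strands[i:j] == strands[focal]) &&
          (j - i) > (best[2] - best[1])) {
        best <- c(i, j)
      }
    }
  }
  best
}

# Minimal single-contig gene table.
make_contig <- function(strands, labels = rep("", length(strands)),
                        genome = "g1", contig = "c1",
                        gene_len = 900L, gap = 100L) {
  n <- length(strands)
  start <- (seq_len(n) - 1L) * (gene_len + gap) + 1L
  data.frame(genome_id = genome, contig_id = contig,
             rank = seq_len(n) - 1L,
             gene_id = sprintf("%s_%s_g%02d", genome, contig, seq_len(n)),
             start = start, end = start + gene_len - 1L,
             strand = strands,
             protein_id = sprintf("%s_%s_p%02d", genome, contig, seq_len(n)),
             labels = labels, stringsAsFactors = FALSE)
}

# Reverse a contig: reverse gene order, flip strands, rebuild
# coordinates and ranks ascending again.
reverse_contig <- function(genes) {
  flipped <- genes[rev(seq_len(nrow(genes))), ]
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  n <- nrow(flipped)
  step <- genes$start[2] - genes$start[1]
  if (is.na(step) || n < 2) step <- 1000L
  flipped$start <- (seq_len(n) - 1L) * step + 1L
  flipped$end <- flipped$start + (genes$end[1] - genes$start[1])
  flipped$rank <- seq_len(n) - 1L
  rownames(flipped) <- NULL
  flipped
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

gene_table_header <- "genome_id\tcontig_id\tgene_id\tstart\tend\tstrand\tprotein_id\tlabels"
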