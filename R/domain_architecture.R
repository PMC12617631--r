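#' @title Domain architectures and ATPase variant classification
#' @name domain_architecture
#' @description A protein's domain architecture is the N-to-C ordered
#'   sequence of Pfam accessions of its surviving hits after overlap
#'   resolution. Two architectures define the Cu-ATPase variants of
#'   interest: a 1-domain variant (PF00403-PF00122-PF00702) with a single
#'   N-terminal heavy-metal-binding domain, and a 2-domain variant
#'   (PF00403-PF00403-PF00122-PF00702) carrying a duplication of that
#'   domain.
NULL

#' Default variant signatures
#'
#' The two Cu-transporting P1B-ATPase domain architectures, longest
#' first so that the 2-domain variant always takes precedence.
#'
#' @return Named list of accession vectors.
#' @export
default_signatures <- function() {
  list(
    two_domain = c("PF00403", "PF00403", "PF00122", "PF00702"),
    one_domain = c("PF00403", "PF00122", "PF00702")
  )
}

#' Parse a dash-separated signature string
#'
#' @param x e.g. `"PF00403-PF00122-PF00702"`.
#' @return Character vector of accessions.
#' @export
parse_signature <- function(x) {
  acc <- strsplit(x, "-", fixed = TRUE)[[1]]
  if (!all(grepl("^PF\\d{5}$", acc))) {
    fx_validation_error(sprintf("invalid accession in signature '%s'", x))
  }
  acc
}

#' Build the domain architecture of one protein
#'
#' Sorts hits along the protein and resolves overlaps: when two hits
#' overlap by more than `max_overlap_fraction` of the shorter hit, only
#' the better hit survives (lower e-value; ties broken by longer
#' alignment, then lexicographically smaller accession).
#'
#' @param hits `data.frame` of domain hits for a single protein
#'   (columns `protein_id`, `accession`, `ali_start`, `ali_end`,
#'   `evalue`). May have zero rows.
#' @param max_overlap_fraction Overlap tolerance as a fraction of the
#'   shorter hit; default 0.5.
#' @return Character vector of surviving accessions in N-to-C order
#'   (empty for an empty hit list).
#' @examples
#' h <- data.frame(protein_id = "p1",
#'                 accession = c("PF00403", "PF00122", "PF00702"),
#'                 ali_start = c(5, 120, 320), ali_end = c(70, 300, 500),
#'                 evalue = c(1e-20, 1e-40, 1e-35))
#' build_architecture(h)
#' @export
build_architecture <- function(hits, max_overlap_fraction = 0.5) {
  if (nrow(hits) == 0L) return(character())
  if (length(unique(hits$protein_id)) != 1L) {
    fx_contract_error("build_architecture: hits span multiple protein_ids")
  }
  len <- hits$ali_end - hits$ali_start + 1L
  # priority: best e-value, then longer hit, then accession
  pri <- order(hits$evalue, -len, hits$accession, method = "radix")
  kept <- integer()
  for (i in pri) {
    conflict <- FALSE
    for (j in kept) {
      ov <- min(hits$ali_end[i], hits$ali_end[j]) -
        max(hits$ali_start[i], hits$ali_start[j]) + 1L
      if (ov > 0 && ov / min(len[i], len[j]) > max_overlap_fraction) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  kept <- kept[order(hits$ali_start[kept], hits$ali_end[kept],
                     hits$accession[kept], method = "radix")]
  hits$accession[kept]
}

#' Classify an architecture as a 1-domain or 2-domain ATPase variant
#'
#' In `"exact"` mode (the default) an architecture must equal a
#' signature exactly; in `"subsequence"` mode a signature must occur as
#' a contiguous run inside the architecture. Signatures are tested
#' longest first, so an architecture matching the 2-domain signature is
#' never called 1-domain.
#'
#' @param arch Character vector of accessions (N-to-C).
#' @param signatures Named list of accession vectors; see
#'   [default_signatures()] and [parse_signature()].
#' @param mode `"exact"` or `"subsequence"`.
#' @return The matching signature name, or `"none"`.
#' @export
classify_variant <- function(arch, signatures = default_signatures(),
                             mode = c("exact", "subsequence")) {
  mode <- match.arg(mode)
  if (length(signatures) == 0L) fx_validation_error("no signatures supplied")
  ord <- order(-lengths(signatures))
  for (k in ord) {
    sig <- signatures[[k]]
    if (mode == "exact") {
      if (length(arch) == length(sig) && all(arch == sig)) {
        return(names(signatures)[k])
      }
    } else {
      n <- length(arch); m <- length(sig)
      if (m <= n && m > 0L) {
        for (s in seq_len(n - m + 1L)) {
          if (all(arch[s:(s + m - 1L)] == sig)) return(names(signatures)[k])
        }
      }
    }
  }
  "none"
}

#' Classify every protein in a domain-hit table
#'
#' Convenience wrapper: builds one architecture per protein with
#' [build_architecture()] and classifies it with [classify_variant()].
#' The result is independent of input row order.
#'
#' @inheritParams classify_variant
#' @inheritParams build_architecture
#' @param hits Domain-hit `data.frame` for any number of proteins.
#' @return `data.frame` with columns `protein_id`, `variant` and
#'   `architecture` (dash-joined surviving accessions).
#' @export
classify_proteins <- function(hits, signatures = default_signatures(),
                              mode = c("exact", "subsequence"),
                              max_overlap_fraction = 0.5) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0L) {
    return(data.frame(protein_id = character(), variant = character(),
                      architecture = character(), stringsAsFactors = FALSE))
  }
  by_protein <- split(hits, hits$protein_id)
  arch <- lapply(by_protein, build_architecture,
                 max_overlap_fraction = max_overlap_fraction)
  data.frame(
    protein_id = names(by_protein),
    variant = vapply(arch, classify_variant, character(1),
                     signatures = signatures, mode = mode),
    architecture = vapply(arch, paste, character(1), collapse = "-"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
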