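Package: fixiscan
Title: Profiling Copper-Transporting P-type ATPase Architectures and
    cbb3 Oxidase Gene Clusters Across Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics pipeline that classifies
    Cu-transporting P1B-type ATPases by Pfam domain architecture
    (a 1-domain variant PF00403-PF00122-PF00702 and a 2-domain variant
    with a duplicated heavy-metal-binding domain), extracts the
    co-directional (same-strand) gene neighborhood around each ATPase,
    labels neighborhoods containing multiple cbb3-type cytochrome c
    oxidase subunits as FixI-like clusters, and aggregates copy-number
    and cbb3 co-occurrence proportions per taxonomic order on a pruned,
    rank-collapsed phylogeny with iTOL-ready annotation exports.  A
    synthetic-genome generator with machine-readable ground truth makes
    every stage testable without database downloads.  Also provides the
    companion assay computations: metal atoms per cell from atomic
    absorption measurements, TMPD oxidase activity from absorbance
    kinetics, and NADI staining phenotype classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
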