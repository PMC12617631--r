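---
title: "Profiling Cu-ATPase domain architectures and cbb3 oxidase clusters"
author: "fixiscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling Cu-ATPase domain architectures and cbb3 oxidase clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixiscan)
```

## The biological question

Copper-transporting P1B-type ATPases serve two very different masters.
CopA-like pumps export excess Cu(I) from the cytoplasm for
detoxification; FixI/CcoI-like pumps deliver Cu to the assembly line of
the cbb3-type cytochrome c oxidase (cbb3-Cox), the high-oxygen-affinity
terminal oxidase whose CcoN subunit carries a CuB center. The two roles
cannot be told apart from the pump sequence alone at scale, but two
genomic signals separate them well:

1. **Domain architecture.** Among Alphaproteobacterial Cu-ATPases two
   Pfam architectures dominate: a *1-domain variant*
   (PF00403–PF00122–PF00702), with a single N-terminal
   heavy-metal-binding domain (HMBD, PF00403), and a *2-domain variant*
   (PF00403–PF00403–PF00122–PF00702) with a duplicated HMBD. PF00122 is
   the E1-E2 ATPase transmembrane core and PF00702 the haloacid
   dehalogenase-like hydrolase domain that houses the phosphorylation
   site.
2. **Genomic context.** FixI-like pumps sit inside the cbb3-Cox operon.
   A 1-domain ATPase whose co-directional gene neighborhood carries
   multiple distinct cbb3 subunit genes (CcoN/CcoO/CcoP, a.k.a.
   FixN/FixO/FixP) is therefore annotated *FixI-like*; ATPases without
   that co-localization stay unclassified, since they may be CopA-like
   or transport other metals.

The package chains these signals into a per-order profile: for each
taxonomic order, the distribution of per-genome copy numbers of each
variant (bins 0..7, color-codable in iTOL) next to the proportion of
genomes encoding a cbb3-Cox gene cluster. It also implements the
companion bench assays: metal atoms per cell from atomic absorption
spectroscopy (AAS), TMPD oxidase kinetics, and NADI staining phenotype
calls.

## The pipeline, stage by stage

### Architectures from domain hits

Pfam hits per protein (as re-serialized `pfam_scan` output) are sorted
along the protein; when two hits overlap by more than a configurable
fraction of the shorter hit (default 0.5, the standard Pfam
post-processing heuristic), only the lowest-e-value hit survives, with
ties broken by longer alignment and then lexicographic accession so the
result is fully deterministic. Version-suffixed accessions
(`PF00403.28`) are stripped: architectures are defined over unversioned
accessions.

Variant calling defaults to **exact** matching — the architecture must
equal the printed signature — because the signatures are stated as full
architectures. A **subsequence** mode (signature as a contiguous run
inside a longer architecture) is provided because real proteomes carry
incidental extra domains; exact-mode calls are provably a subset of
subsequence-mode calls. Signatures are tested longest first, so a
protein matching the 2-domain signature is never also called 1-domain.
Architectures with three or more HMBD copies match neither signature in
exact mode and are left uncalled.

### Co-directional neighborhoods

The genomic-context unit is the *strand run*: starting at a focal gene,
the neighborhood extends gene by gene upstream and downstream while the
neighbor shares the focal strand. Strand is the sole default criterion;
an optional `max_gap_bp` intergenic-gap limit exists because operon
callers commonly use one, but it is off by default. Runs never cross
contig boundaries (adjacency is undefined there) and contigs are
treated as linear; circular topologies are not modeled. Non-coding
features are dropped at parse time with a logged count, so they do not
break adjacency — whether they should is unknowable from gene tables
alone, and the choice is recorded here rather than hidden.

### FixI-like calls and genome-level cbb3 presence

"Multiple cbb3 subunits in proximity" is operationalized as: at least
`min_markers = 2` **distinct** marker labels among run members other
than the focal gene, within the same co-directional run (no separate
distance threshold). Duplicated subunit genes count once. The default
marker catalog (`ccoN`, `ccoO`, `ccoP`, `fixO`, `fixP`, `fixC`) is a
configurable assumption; marker identity can alternatively run through
Pfam accessions matched against member architectures, but no default
accession list is shipped to avoid inventing one. FixI-like status is
restricted to 1-domain focal ATPases.

Genome-level cbb3 presence defaults to the same run semantics (`"run"`
mode: some co-directional run holds ≥ `min_markers` distinct markers);
an `"anywhere"` mode (markers anywhere in the genome) is exposed
because the aggregation could plausibly be defined either way.

### Order-level aggregation and tree collapsing

Per-genome copy numbers are binned into 0..7 with values above 7
assigned to the top bin, matching the 0-to-7 display scale; the cap is
configurable (`max_copy_bin`). Every emitted distribution sums to 1 to
within 1e-9 by construction, and the aggregation is invariant to
genome input order.

Tree pruning (via `ape::keep.tip`) collapses unary nodes and sums their
branch lengths; a single-leaf request returns a one-tip tree whose edge
length is the root-to-leaf path sum. Collapsing to a rank replaces each
maximal monophyletic same-taxon leaf set with one leaf named for the
taxon; a non-monophyletic taxon keeps its name on its largest clade and
suffixes the others (`X_2`, ...) with a warning — collapse must be
total, and GTDB orders are near-monophyletic so suffixes are rare on
realistic inputs.

## Assay computations

* **Atoms per cell**: `concentration [mg/L] × volume [L] / 1000 /
  molar mass [g/mol] × N_A / cell count`, with the 2019 SI Avogadro
  constant 6.02214076×10²³ (the commonly printed 6.022×10²³ differs far
  below reported precision). The molar mass is taken in g/mol with the
  units documented explicitly. The quantity is homogeneous of degree
  zero in (concentration, cell count) jointly and inversely
  proportional to cell count alone — both properties are tested.
* **TMPD oxidase activity**: ΔA520 over the interval, converted by
  Beer–Lambert with ε = 6.1 mM⁻¹ cm⁻¹ for TMPD; activity in µmol TMPD
  oxidized min⁻¹ per well (2.4×10⁴ cells). ε and the optical path enter
  only as a product, which is asserted as an invariance test. The
  optical path defaults to 0.29 cm — the approximate depth of 100 µl in
  a 96-well plate — because plate-reader assays rarely state it; set it
  explicitly for cuvettes. Negative rates (blank drift) are returned
  with a warning, never clipped, so blank-subtraction errors stay
  visible.
* **NADI phenotypes**: dark staining within 60 s is NADI⁺; any staining
  within 900 s (15 min) that is not NADI⁺ is NADIslow; no staining over
  a window of at least 900 s is NADI⁻. An unstained colony watched for
  less than the slow cutoff is returned as `"indeterminate"` rather
  than called negative. Staining that begins only after the slow cutoff
  is treated as NADI⁻ (no activity within the slow window). The slow
  cutoff follows the 15-minute protocol definition; some observations
  are reported against a 30-minute exposure, so both cutoffs are plain
  arguments.

## The synthetic-data generator

Because the real survey depends on external databases (reference
proteomes crossed with a genome taxonomy), the package ships a
generator that emulates the *statistical structure* of such a dataset
with planted, machine-readable truth:

* genomes are ordered, stranded gene lists (fixed 900 bp genes, 100 bp
  gaps — coordinates only matter for ordering and gap limits);
  background strands follow a Markov flip process (default flip
  probability 0.25, giving mean same-strand runs of ~4 genes, a
  realistic operon scale);
* per-genome variant copy numbers are drawn from configurable
  distributions (defaults: 1-domain over 0..3 with mean ≈ 1, 2-domain
  over 0..2 with mean ≈ 0.6 — modest multi-copy incidence as seen in
  order-level surveys);
* a genome gains a standalone cbb3 marker run with probability 0.6, and
  each planted 1-domain ATPase is embedded inside a cbb3 run with
  probability 0.7 (`p_fixi_colocalization`);
* planted blocks (lone ATPases, 3-marker cbb3 runs, cbb3 runs with an
  embedded ATPase) are strand-isolated from their flanks by
  construction — the immediately adjacent background genes are forced
  to the opposite strand — so the expected classification of every
  planted ATPase is exact, not probabilistic;
* decoy proteins carry domains from a pool disjoint from the
  signatures, plus occasional hard decoys bearing the incomplete prefix
  PF00403–PF00122, which exact matching must reject;
* taxonomy is order-level GTDB-style lineages; the tree is built by
  random binary joining with orders monophyletic by construction, so
  rank collapsing has a known answer; `scramble_orders` deliberately
  breaks monophyly to exercise the suffix rule.

Generation is fully deterministic given `seed` (R's Mersenne–Twister,
set explicitly with fixed normal/sample kinds). When a sampled contig
cannot host its assigned blocks the contig grows to the minimum
feasible size; a configuration whose *maximum* contig size cannot host
even one cbb3 run fails validation before any output.

What the generator does **not** emulate: sequence evolution, HMM score
distributions, annotation noise (missed or spurious domain calls),
pseudogenes, assembly fragmentation inside operons, or horizontal
transfer. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct on cleanly annotated input, not that the
biological classification is robust to annotation error.

## Problem sizes and numerical choices

The test-suite study conditions are 10 orders × 20 genomes for
truth-recovery (with full co-localization, every planted 1-domain
ATPase must be called FixI-like, zero mismatches), 10⁴ random tuples
for the classifier fuzz, 10⁴ random contigs (≤ 30 genes) for the
strand-run oracle equivalence, and 2 orders × 500 genomes for
distribution recovery, where empirical bin proportions must sit within
3·√(p(1−p)/500) of the generative probabilities. Proportion
conservation is asserted at 1e-9; all other comparisons are exact
because every stage is deterministic.

Ties everywhere are broken deterministically (coordinates, then
e-value, then accession or gene id), so identical inputs give
byte-identical outputs; the run manifests isolate their timestamp in a
single field to keep everything else comparable across runs.

## Limitations

* FixI-like assignment is guilt-by-association; an ATPase adjacent to a
  cbb3 operon by chance rearrangement would be mislabeled, and real
  surveys should treat calls near `min_markers` as provisional.
* Exact-mode architecture matching is conservative: any extra domain
  (even a spurious repeat) removes a protein from both variants.
  Subsequence mode trades that for inclusiveness; neither is "the"
  right choice, which is why both ship.
* Order collapsing assigns no meaningful branch length to collapsed
  leaves beyond the retained representative path; downstream displays
  should treat the collapsed tree as a cladogram.
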