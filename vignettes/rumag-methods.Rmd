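---
title: "Methods: locus calling, genome QC and toy classification in rumag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus calling, genome QC and toy classification in rumag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumag)
```

`rumag` covers the downstream, post-annotation analyses of a rumen MAG
study: polysaccharide utilization locus (PUL) prediction, genome quality
control, CAZyme and cellulosome profiling, coverage-based plasmid
detection with Hi-C attribution, and a toy k-mer classifier for
database-augmentation experiments. This vignette records the models
behind each component, the tunable parameters and their defaults, the
design choices made where the methods literature leaves the design open,
and what the synthetic-data generator does and does not emulate.

## PUL calling

### Model

A PUL is modelled as a run of consecutive genes on one contig anchored by
a susC/susD-like tandem pair. Recognition is annotation-driven:

* a protein is *susC-like* if it carries a domain from the susC Pfam set
  (default `PF00593`, `PF07715`: the TonB-dependent receptor plug and
  beta-barrel), and *susD-like* for the susD set (default `PF07980`,
  `PF12741`, `PF12771`, `PF14322`). The defaults follow the PULDB
  convention; both sets are plain character vectors in `pul_config()` and
  can be replaced wholesale. A protein carrying labels from both sets
  takes the role of its higher-bitscore hit, ties resolving to susC
  (susC hits are typically the longer, higher-scoring match, so the tie
  break is rarely exercised).
* a gene is a *CAZy gene* if its protein has at least one CAZy-family
  domain hit (source `"cazy"` in the domain table).

A *seed pair* is two genes adjacent in contig gene order — no intervening
gene call — one susC-like and one susD-like, in either order. Strand is
deliberately ignored: "tandem" is not defined more precisely by the
upstream literature, the two genes of real Sus systems are co-oriented
almost always, and requiring co-orientation would silently drop loci on
mis-stranded gene calls. An optional `max_seed_gap` (bp of intergenic
distance, default unlimited) is available for stricter definitions.
Chains such as susC–susD–susC yield every adjacent pair; downstream
merging (below) keeps them from being counted twice.

### Window extension

From each side of the seed the caller scans a moving window of
`window = 5` gene predictions outward from the current boundary. If any
gene in the window is a CAZy gene, the boundary jumps to the **farthest**
such gene within the window and the scan repeats from the new boundary;
extension ends when a window contains no CAZy gene or the contig does.
Genes between the final boundaries are all members; members that are
neither sus genes nor CAZy genes are labelled `unc` (unclassified).

Two open points were decided here. First, the re-scan jumps to the
farthest in-window CAZy gene rather than the nearest: both converge to
the same final boundary (any nearer CAZy gene is inside the next window
anyway), but farthest-jump reaches the fixpoint in fewer iterations and
makes each step's postcondition easy to state. The test suite checks the
result against an independent re-scanner that iterates to fixpoint, so
the equivalence is verified rather than assumed. Second, extensions from
different seeds whose gene ranges overlap are merged into one locus with
all seeds recorded — otherwise a susC–susD–susC chain would produce two
heavily overlapping loci and inflate per-genome counts.

A locus whose members are exactly one susC and one susD gene is flagged
*simple*; under the five-gene window this is precisely the "bare tandem
pair" configuration with no CAZy homologue within five genes on either
side. A locus never crosses a contig boundary, and per-contig locus
identifiers number merged loci left to right, so output is deterministic.

### Architecture signatures

`architecture_signature()` writes member labels in coordinate order,
joined by `-`; maximal runs of genes on the opposite strand from the
seed susC are split into blocks joined by `" | "`. Genes with both a sus
role and a CAZy label print the sus role. The mapping is invertible
(`parse_signature()`): the block holding the first `susC` anchors the
reference strand and blocks alternate because runs are maximal. The
generator uses the same grammar for planted layouts, which makes
generator and caller mutually inverse on clean data — a property the
suite tests on random signatures.

## Genome quality control

Two thresholds coexist deliberately, with different boundary semantics:

* the **pass filter** is inclusive — completeness ≥ 80% *and*
  contamination ≤ 10% — matching the convention of reporting "≥/≤"
  bounds for draft-genome inclusion;
* the **high-quality draft tier** is strict — completeness > 90% *and*
  contamination < 5% — following the MIMAG draft-quality criteria, which
  are stated with strict inequalities. A genome at exactly 90%
  completeness is therefore `pass_draft`, not high quality.

Genus-level cleaning (`clean_bin()`) removes contigs whose majority-genus
call maps outside Bacteria/Archaea. The genus-to-superkingdom mapping is
an input table, not an embedded taxonomy: the rule is the method, the
database is the user's. Contigs without a call, or with a genus missing
from the lookup, are kept — absence of evidence is not treated as
contamination. Taxonomy-resolution summaries require lineages to fill
top-down (a gap below a filled rank is an input error, not a zero).

## CAZyme profiling

dbCAN's suggested significance cut-offs are encoded as defaults:
alignments longer than 80 aa need E-value < 1e-5, shorter ones < 1e-3,
and every hit needs HMM coverage > 0.3. All four numbers are arguments of
`apply_dbcan_filters()`. One assignment is kept per surviving hit, so
multi-domain proteins contribute to several families and classes — class
counts are therefore domain-weighted, matching how CAZy class totals are
usually reported. Family labels keep subfamily suffixes (`GH13_10`) with
`cazy_base_family()` exposing the base family, and `CBM` families map to
the `CB` class.

Novelty is a single inclusive threshold on the best identity across all
searched databases: `max_identity >= 95` means known, anything else —
including proteins with no hit anywhere — is novel. Per-class identity
distributions count each protein once per class (not once per domain) and
use the median-unbiased quantile estimator (`type = 8`), chosen so that
any reimplementation has an unambiguous target.

## Cellulosome screen

Scaffoldin candidates are proteins with multiple cohesin domains
(default label set `PF00963`). Domain hits frequently overlap, so
counting deduplicates: hits are accepted greedily by descending bitscore
(ties by envelope start, then label), and a hit is kept only if it
overlaps every accepted hit by at most half the shorter envelope. The
overlap rule is an explicit design decision — upstream descriptions do
not say how repeated-domain hits were deduplicated — and the suite
verifies the outcome is order-invariant, pairwise-compatible and maximal
(no rejected hit could be added). "Multiple" means ≥ 2, since two-domain
proteins are reported as biologically meaningful candidates.

## Plasmid detection

Putative multi-copy plasmid contigs are those with depth strictly
greater than `factor = 2` times the mean coverage of their genome. The
mean is the plain arithmetic mean over contigs by default — "mean average
coverage" without qualification — with a length-weighted option. The
selection is invariant under uniform rescaling of depths, so it is a
copy-number statement, not a sequencing-effort one. Note the genome mean
includes the candidate contig itself; with few contigs this pulls the
threshold up slightly, which is the conservative direction.

BLAST HSP filtering removes hits strictly below 500 bp or strictly below
10% of the query length, so boundary values survive. Plasmid annotation
is a case-insensitive substring search for "plasmid" in the subject
title — no regular expression by default, because titles like
"megaplasmid" should (and do) match while the rule stays predictable.
Hi-C links between a contig and a genome cluster sum the read pairs with
one mate on the contig and one on any cluster member; self-links are
excluded and cluster membership must partition the contigs.

## Toy k-mer LCA classifier

The classifier exists to run database-augmentation experiments at desk
scale, not to compete with production tools. The index maps every
canonical k-mer (lexicographic minimum of the k-mer and its reverse
complement) of every reference to the lowest common ancestor of all
genomes containing it; k-mers with ambiguous bases are skipped. Adding a
genome only adds keys or moves values toward the root, and the index is
independent of input order.

Classification scores every node that received at least one k-mer hit by
the summed hit counts along its root-to-node path and returns the deepest
maximal scorer, ties broken by depth and then lexicographic node id — all
fixed so results are bit-reproducible. Candidates are restricted to hit
nodes: extending the candidate set below the deepest hit cannot change
the score and would make "deepest" ill-defined. Reads shorter than k
warn and return unclassified.

The default `k = 21` is shorter than the 31 used by production
classifiers: at reference lengths of a few kilobases it keeps indexes at
a few tens of thousands of keys while preserving the behaviour under
study (exact matching, LCA promotion, monotone gains from database
growth). There is no minimizer or compression machinery — correctness
over speed at toy scale.

## Synthetic data: what it emulates, and what it does not

The generator's defaults are the study conditions of the test suite and
acceptance script:

* **Gene grids** of 40 genes per contig (900 bp genes, 100 bp gaps), one
  planted locus layout per contig, taken from the two architectures most
  relevant to the callers: the bare pair `susC-susD` and the xylan
  pattern `GH43-GH10 | GH67-GH35-susC-susD-unc-GH10`. Layouts are flanked
  by at least `2 * window` spacer genes, and decoy CAZy genes (rate 0.05
  per spacer gene) are excluded from within `window` genes of a planted
  boundary. Under these conditions exact recovery of planted boundaries
  is a provable property of the window search, and the suite demands
  100% of it; decoys placed closer would legitimately extend a locus,
  which is the caller working as specified, not an error — the
  `decoy_near_truth` switch exists for studying exactly that.
* **Coverage**: chromosomal contigs draw depth from
  Normal(20, cv × 20) truncated at zero with cv = 0.1; plasmids at copy
  number 3 draw around 60 with the same cv. Detection power and false
  positives are measured over ≥ 1000 Monte-Carlo draws.
* **Reads**: 150 bp (the common Illumina length in rumen studies),
  uniform start positions, iid substitution errors at 0.005. No indels,
  no quality model, no coverage bias.
* **Identities**: a two-component Normal mixture on the 0–100 scale —
  91% of proteins around 68% identity (sd 6) and 9% around 97% (sd 1.5) —
  emulating a community where the large majority of carbohydrate-active
  proteins lack a close database match.

What passing these tests shows is that the implementations compute their
definitions exactly and behave correctly under controlled noise. What it
does not show: robustness to fragmented assemblies, chimeric bins,
mis-called genes, strand errors, GC-dependent coverage, or real domain
architecture complexity — none of which the generator models.

## Numerical and reproducibility choices

* Coordinates are 1-based inclusive (GFF3) everywhere inside the
  package; `convert_to_half_open()` is the only boundary shim.
* Every generator runs on its own RNG stream (`set.seed` on entry,
  caller's stream restored on exit), so one integer seed fully determines
  any synthetic dataset and generators do not interfere with each other.
* Quantiles are `type = 8`; means are unweighted unless asked; depth
  draws truncate at zero rather than resampling.
* CLI outputs are written to a temporary file and renamed (atomic), carry
  a provenance header (package version + configuration hash) and are
  byte-identical across runs with equal config and seed.
* Problem sizes in the acceptance script — 300 simulated genomes for
  locus recovery, 300 random contigs for the extension oracle, 1000
  Monte-Carlo coverage draws per condition, 2000 community reads, 5000
  proteins for the novelty profile — were chosen to estimate each rate
  comfortably while keeping a full run around two minutes.

## Known limitations

* The PUL caller requires seed pairs on a single contig; loci broken
  across contigs are reported as fragments or missed.
* Substrate prediction from signatures is out of scope; signatures are
  descriptive.
* The cohesin count is a greedy maximal compatible set, not a maximum
  one; in pathological overlap patterns a different ordering could admit
  more domains, but the bitscore ordering is the biologically sensible
  one and is deterministic.
* The classifier holds its index in memory as a named vector; it is not
  meant for references beyond megabase scale.
* `clean_bin()` trusts the provided genus lookup; genera absent from it
  are silently kept.
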