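---
title: "Genome-wide lectin family characterization: models, decisions and limits"
author: "lectinomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide lectin family characterization: models, decisions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectinomics)
```

# Scope

`lectinomics` implements the analysis stages of a genome-wide lectin-family
characterization of the kind performed for rice (*Oryza sativa*), with the
EUL (*Euonymus*-related lectin) family as the motivating case: a domain-based
family census, tandem- and segmental-duplication analysis, SNP consequence
calling and subpopulation clustering, an integrative promoter cis-regulatory
pipeline, stress-expression profiling, and EUL-domain conservation scoring.
Homology search, alignment, tree inference and structural modeling are out of
scope: the package consumes their outputs (domain-annotation tables, MSAs,
collinear-block tables) in standard formats.

Every stage can be driven by the built-in synthetic-data generators, which
plant known ground truth so that each method's recovery behaviour is testable
without any database download.

# The family census

Genes are classified by their protein-domain content: a gene carrying at
least one domain whose Pfam accession maps to one of the twelve plant lectin
families (ABA, amaranthin, CRA, cyanovirin, EUL, GNA, hevein, JRL, legume,
LysM, nictaba, ricin-B) is retained, everything else is dropped.
The published tables never state how a gene carrying domains from two
different lectin families should be counted; we count it once in *each*
family, flag it `multi_family`, and report both the per-family counts and the
number of distinct genes, so the table's arithmetic remains transparent.
Percentages are per-family counts over distinct genes, rounded half-up to one
decimal (the convention that turns 134/329 into 40.7%). A family is
"represented" iff its count is at least 1.

```{r census}
cts <- c(CRA = 2, EUL = 5, GNA = 134, hevein = 10, JRL = 30,
         legume = 104, LysM = 20, nictaba = 20, `ricin-B` = 4)
family_census(cts)
```

# Duplication analysis

**Tandem blocks.** Two genes are tandem-linked iff (1) they belong to the
same lectin family, (2) they lie on the same chromosome, and (3) no more than
ten genes intervene between them. Three decisions deserve note:

* *Intervening genes are counted over all annotated genes*, not only
  lectins — in a genome context "ten intervening genes" conventionally means
  any genes. This is an assumption; the rule's source leaves it open.
* *The ten-gene boundary is inclusive*: exactly ten intervening genes still
  links.
* *Blocks are connected components* of the pairwise link relation: if A–B
  and B–C link, {A, B, C} is one block even when A and C alone exceed the
  gap. Because the rank gap of an outer pair always dominates the gaps of
  inner pairs, components equal maximal runs of sufficiently close family
  members; the test suite nevertheless checks the component semantics
  against an independent all-pairs union-find oracle.

**Segmental blocks.** Collinear gene pairs (produced externally) are
filtered on the synonymous substitution rate: blocks with Ks *strictly
above* 1.0 are omitted as saturated — Ks = 1.0 exactly is retained — and
only blocks with at least one lectin anchor are reported.

# SNP consequences and subpopulation clustering

A variant is located against the gene model (intergenic, UTR, intron or
CDS). For CDS hits the affected codon is rebuilt — alleles on minus-strand
genes are complemented first — and translated with the standard genetic
code; an unchanged amino acid is silent, anything else missense. Coordinates
follow the field's conventions: 1-based genomic positions at the file
boundary (GFF3/VCF style), 1-based codon and residue positions, 0-based
half-open intervals internally for promoter work.

Reference-allele usage per subpopulation is the percentage of non-missing
haploid calls equal to the reference allele; the denominator is kept per
cell, and a cell with no calls is NA rather than 0. Subpopulations are then
clustered by UPGMA on the RMSD distance

$$d(a,b) = \sqrt{\tfrac{1}{L}\sum_{l=1}^{L}(x_{la}-x_{lb})^2},$$

computed on allele *fractions* (0–1) rather than percentages so that merge
heights are scale-free. NA cells are dropped pairwise per distance (the
behaviour of the original heat-map/dendrogram tooling is unspecified; a
pair with zero complete loci is an error rather than a silent zero). The
agglomeration is average linkage via `stats::hclust`; ties in merge order
are resolved by `hclust`'s deterministic internal ordering, and the random
matrices used in validation are continuous, so ties are measure-zero there.
The tree is ultrametric; branch lengths in the exported Newick are half the
merge heights.

# The promoter cis-regulatory pipeline

The pipeline reproduces an integrative analysis with three configurable
tracks — motif mapping, functional-region filtering, and regulon
enrichment — as one parameterised flow.

**Promoters** are the 2,000 bp immediately upstream of the translation
start (the first CDS base) in transcript orientation, clipped at chromosome
ends with the clipping recorded. The anchor is the ATG because that is how
the 2-kb windows were defined in the motivating study's figures; a TSS
anchor (`anchor = "tss"`) is available since "upstream promoter region" is
ambiguous.

**Scanning.** Motif models are probability PWMs (pseudocount-normalised);
a window scores $\sum_j \log_2 p_j(b_j)/q(b_j)$ bits against the background
composition $q$, both strands are scanned, and windows touching an N are
never reported. This plain per-motif log-odds scan deliberately stands in
for Cluster-Buster run with cluster scoring disabled (`-c 0`), whose
operative output is individual motif matches; the HMM cluster model is not
reproduced. The default threshold is 6 bits and is per-call configurable —
sharper synthetic motifs are scanned at 12 bits in the validation suite so
that chance-hit rates on uniform sequence stay near
$2\times10^{-5}$ per window.

**Functional-region filtering** mirrors `intersectBed -f 0.5`: regions are
merged (union of overlapping or book-ended intervals) and a match is kept
iff at least half its length overlaps a *single* merged region — a match
straddling two regions separated by a gap is judged on its best
single-region overlap. Adding regions can only grow the retained set;
raising the fraction can only shrink it; both monotonicities are asserted
in the tests.

**Regulons** are the `top_n = 200` genes most positively Pearson-correlated
with the focal gene across all samples. Signed correlation is used, not
$|r|$: "co-expressed" is read as positive co-variation (configurable).
Members whose identifier has no entry in the supplied id-conversion map are
dropped after selection — mirroring the shrinkage from roughly 200 to
roughly 150 genes seen when converting between rice annotation namespaces —
and the post-mapping size is recorded.

**Enrichment.** Presence/absence (at least one retained match) defines, per
motif, $k$ of $n$ regulon promoters and $K$ of $N$ background promoters;
$p = P(X \ge k)$ under Hypergeometric$(N, K, n)$ and $q$ is the
Benjamini–Hochberg adjustment across the motif library. Presence counts
rather than match counts define $k$ and $K$ because the hypergeometric
sampling frame is over promoters, not matches. The background universe is
all genes with an extracted promoter — the natural sampling frame, since a
gene without a promoter can never contribute a match; the original analysis
does not state its universe. A motif is reported enriched only when
$q < 0.05$ *and* it is present in the focal gene's own promoter.

# Expression profiling

Fold change per transcript and stratum (tissue × timepoint) is
(treated + ε)/(control + ε) with ε = 10⁻⁶; a zero-expression control is
rescued by the pseudocount and flagged rather than producing an infinity.
A gene's profile is the arithmetic mean over its representative
transcripts. Significance stars follow a two-tier scheme: `***` for
q < 0.001, `**` for 0.001 ≤ q < 0.05, empty otherwise. The conventional
one-star tier is deliberately off by default: the usual legend wording
("* below 0.05" alongside "** below 0.05 but at least 0.001") is internally
inconsistent, so the package implements the two unambiguous tiers and
leaves a third tier configurable. External q-values are consumed when
present; for replicate-level synthetic tables, `replicate_significance()`
computes a stand-in q from two-sample t-tests with BH correction.

# EUL-domain conservation

Architecture calls are structural: one EUL-domain hit is an S-type protein,
two non-overlapping hits a D-type whose linker is the inter-domain stretch;
zero hits reject the protein and more than two are flagged unsupported.

Pairwise percent identity excludes dual-gap columns from the denominator
and counts single-gap columns as mismatches. Percent similarity
additionally counts substitutions scoring positively under BLOSUM62 — the
published tables never define "similarity", so the conventional
positive-score groups are used and the matrix is configurable in principle
through the scoring helper. Identity ≤ similarity holds by construction and
is asserted on every matrix.

The conservation profile works in the 151-residue EUL-domain frame.
Per-column information content is $IC = \log_2 20 - H$ with $H$ the Shannon
entropy of the non-gap composition; the small-sample correction applied by
sequence-logo tools is off by default (the logo use here is quantitative
ranking of columns, not publication graphics) and available as a flag. The
landmark report counts, per sequence: Q at 34 and W at 36 (the QxW motif,
any residue between), D116, N143, Q144 (the carbohydrate-binding triad),
W136, and the F/L mix at 118. When an MSA contains insertion columns, a
151-entry column map must be supplied; the generators emit gap-free
domains, so the identity map applies there.

# The synthetic-data generators

One `simulation_config()` drives five generators (genome/gene models,
population SNPs, expression, promoters/motifs/regions, EUL proteins), each
seeded from the configuration so a fixed seed reproduces a study byte for
byte. Planted truth is always returned alongside the data.

The defaults are the validation study's conditions, fixed once:

* **Genome**: 3 chromosomes × 60 genes, LOC-style identifiers, one planted
  EUL tandem array; background family labels are placed at least 12 ranks
  apart so the planted arrays are exactly the tandem blocks present.
* **SNP panel**: six subpopulations in a japonica/indica-like split with
  reference-allele fractions 0.95 vs 0.05, 50 accessions each, 20 loci,
  haploid calls (matching how reference-allele percentages are presented in
  3000-genomes-style summaries).
* **Expression**: one 150-gene module among 2,000 genes; condition fold
  changes drought 4×, osmotic 2×, ABA 1.5×, JA 1× over a control, three
  timepoints × two replicates. Members share a profile up to a per-gene
  scale plus additive Gaussian noise; at noise sd 6 the member–focal
  correlation sits near 0.9, the regime the regulon-recovery claim is made
  for. Non-members are uncorrelated log-normal noise.
* **Promoters**: i.i.d. uniform A/C/G/T sequence, so chance-hit rates are
  analytically checkable; the focal motif's exact consensus (sharp 0.97
  PWMs, width 10) is inserted at a recorded coordinate with probability 0.6
  inside the module and 0.1 outside; functional regions are disjoint 100-bp
  tiles covering 25% of promoter bases, plus a guaranteed cover over
  planted instances. Consensus insertion (rather than PWM sampling)
  guarantees detectability at any sensible threshold.
* **EUL proteins**: 2 S-type and 3 D-type (the rice counts), all domains
  151 aa with the landmark residues fixed, F:L at 118 drawn at 0.63:0.37,
  N-terminal regions 19–117 aa and linkers 18–76 aa, per-site substitution
  probability 0.05 elsewhere.

What the generators *do not* emulate — and what passing tests therefore do
not show — includes realistic base composition and repeat structure,
linkage disequilibrium and shared population history (each accession is an
independent draw), correlated noise or batch structure in expression,
dependent motif occurrences, and insertion/deletion variation in protein
families. Recovery rates measured here are upper bounds relative to real
data with those complications.

# Problem sizes and numerical choices

The validation suite runs, as the package's own choice of study sizes: 500
random gene orders (20–200 genes) against the tandem oracle; full
enumeration of the hypergeometric tail for N ≤ 12; exhaustive PWM-scan
enumeration on promoters ≤ 50 bp; 200 random matrices against a naive
O(n³) UPGMA; all 576 single-base codon substitutions; 100 seeds of
regulon recovery and of planted-motif enrichment (N = 2,000 background
promoters, 500 bp each in the enrichment simulations; promoter length is a
free generator argument and defaults to 2,000 bp for genomic use); 50 null
seeds for empirical FDR control; and 200 seeds of two-cluster SNP panels.
The acceptance script recomputes the same quantities at moderately smaller
seed counts and records the size used next to every value.

Numerical conventions: round-half-up (not banker's rounding) for table
percentages; BH via `stats::p.adjust`; hypergeometric tails via
`stats::phyper`; p-values are validated to lie in (0, 1] before
adjustment; RMSD on fractions; -Inf sentinels make windows that touch
promoter boundaries or Ns unreportable in the scanner regardless of
threshold.

# Known limitations

* The scanner is a per-motif log-odds scanner; motif-cluster (CRM) scoring
  is intentionally not implemented.
* Similarity percentages depend on the chosen substitution groups; other
  matrices will shift values by a few percent.
* The UPGMA tie-break follows `stats::hclust`; data with exactly tied
  distances may merge in a different (but deterministic) order than a
  lowest-index-first rule.
* Multi-allelic sites, indels and diploid genotypes are out of scope for
  the SNP module.
* `fold_change_profile()` consumes externally supplied FDR values when
  present; the built-in replicate t-test is a stand-in for synthetic data,
  not a recommendation for real RNA-seq inference.
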