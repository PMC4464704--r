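---
title: "Methods: island-based differential histone-mark and factorial expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: island-based differential histone-mark and factorial expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimark)
```

# Scope

`epimark` reimplements, as a tested pipeline, the analysis used to
characterize a histone-methyltransferase deletion mutant from ChIP-seq and
expression-array data: island calling of a broad gene-body mark (H3K36me3)
against input chromatin, differential islands between genotypes, scaled
metagene profiling of the mark's 5'/3' positional balance, replicate
quality control and ChIP-qPCR summaries, a per-gene 2x2x2 factorial ANOVA
(genotype x carbon x light), and the hypergeometric set integration that
defines direct targets (bound and hypomethylated) and functional targets
(hypomethylated and down-regulated). A synthetic-data generator with known
per-gene truth emulates the study design at desk scale, so every stage is
validated by recovery rather than by fiat.

# Island calling

Broad marks such as H3K36me3 do not form sharp peaks; the caller therefore
works in SICER's window-cluster manner with the published parameter set:
windows of 200 bp, gaps up to 200 bp, an effective genome factor of 0.9
(the mappable fraction entering the background rate), a redundancy
threshold of 1 for PCR-duplicate removal, island FDR < 0.01 and ChIP/input
enrichment > 2 for retained islands.

Concretely, each chromosome is tiled into non-overlapping 200 bp windows
and ChIP fragment midpoints are counted per window (midpoint assignment is
unambiguous and mass-preserving across windows). Under the background
model, window counts are Poisson with rate
$\lambda_w = L \cdot w / (f \cdot G)$ for library size $L$, window $w$,
effective genome factor $f$ and genome length $G$; a window is *eligible*
when its upper-tail probability falls below 0.05. Maximal runs of eligible
windows, bridging ineligible stretches up to the gap size, form candidate
islands. Each island is then tested against the input library: the island
ChIP count is compared by an upper-tail Poisson test to the larger of the
library-size-scaled input count and the background expectation
$\lambda_w \times$ (windows in the island) — taking the larger of the two
keeps islands over input-depleted regions honest. Benjamini–Hochberg
adjustment runs across all candidate islands. The window eligibility level
(0.05) and the island-level Poisson-versus-input test are this package's
concrete choices; they reproduce the qualitative behavior of the published
caller with a closed form that can be tested exactly. On pure-null
simulations (ChIP and input both uniform, twenty seeds, 10 Mb genome,
200,000 fragments) the retained-island false rate stays well under twice
the nominal FDR, and a single implanted 2 kb region at 10x background is
recovered with reciprocal overlap above 80%.

A pseudocount of 0.5 is added to both counts for enrichment and
fold-change ratios only — never to the test statistics — so ratios are
defined when an input count is zero.

# Differential islands

For a genotype or treatment contrast, islands are first called in each
ChIP library against its own input (or the genomic background when no
input exists). The candidate regions for the differential test are the
*disjoint atoms* of the two island sets: where the islands differ in
extent, the differing stretch is tested on its own rather than averaged
into the full island. This resolution choice matters for a positional
loss: a gene whose 3' mark disappears still retains a strong 5' island in
the mutant, and averaging over the whole wild-type island would dilute the
3' fold change to the point of missing the gene entirely at a 2-fold
cutoff. Counts in each region are compared by the exact conditional test
of two Poisson rates with the library sizes as exposures (the classical
binomial conditioning, via `stats::poisson.test`), which makes
differential calling exactly anti-symmetric: swapping the libraries flips
directions and preserves p-values. Regions with BH FDR < 0.05 and
pseudocounted RPM fold change > 2 are significant (the milder 1.3-fold
cutoff used for transient-treatment contrasts is available through
`fc_cutoff`). Genes are then labeled by overlap (at least 1 bp, the
conventional rule): overlap with regions higher in the first library only
gives `hypomethylated` (for a WT-versus-mutant contrast), the reverse
`hypermethylated`, and a gene overlapped by both directions in one
contrast is labeled `ambiguous` and excluded from downstream sets — the
conservative reading where the source analysis is silent.

Whether treatment contrasts should re-call islands per condition or reuse
the union was left open by the source analysis; the union (atoms) route is
implemented.

# Metagene profiles

Each gene body is scaled into 40 near-equal bins, plus ten 50 bp bins per
500 bp flank, giving a 60-bin profile oriented 5'→3'. Binning uses mean
per-base RPM coverage, so the profile conserves mass exactly:
$\sum_b \bar c_b \cdot w_b$ over body bins equals the summed body
coverage for every gene. When the body length is not divisible by 40, the
remainder bases are assigned one per bin in genomic left-to-right order
and the finished 60-vector is reversed for minus-strand genes. Allocating
genomically rather than transcript-wise makes the minus-strand profile the
*exact* reversal of the plus-strand profile for every gene length — a
symmetry we consider non-negotiable for a positional statistic; an
allocation that walks from the transcript 5' end breaks it whenever the
length is ragged. Genes shorter than 40 bp, or whose flank would leave the
chromosome, are skipped and reported.

Aggregation over a gene set is the per-bin median, and the 5'/3' balance
is summarized by `three_prime_fraction`, the share of body signal in body
bins 21–40 (0.5 for a flat profile). Because attenuation in the generator
is confined to the hypomethylated subset (about a third of marked genes),
the per-bin median over *all* marked genes barely moves — the median gene
is unattenuated — so the package measures the shift on profiles aggregated
over the hypomethylated set, where the affected geometry actually lives.
At an attenuation of 0.2 the wild-type-minus-mutant difference in the
three-prime fraction is about 0.2, comfortably clearing the 0.05
detection requirement in the test suite.

Cross-sample normalization corrects for globally different mark
landscapes: by default each profile is divided by its own sample's mean
RPM coverage over that sample's marked gene bodies, after which each
sample's gene-body mean signal is 1 in expectation. The alternative
reading — dividing by the whole-genome mean coverage — is available via
`mode = "genome_mean"`; since equal-depth RPM tracks have equal genome
means, that mode compares samples on a common per-million scale and is the
mode under which the 5' bins of the two genotypes agree within 10% while
the 3' bins diverge. The exact formula behind the published phrase is not
stated there; both readings are provided and the default follows the more
specific phrasing.

# Replicate QC and ChIP-qPCR

Three concordance criteria are implemented as published: (1) each
replicate's top 40% of islands by ascending FDR (ties by p, then
coordinate) must be shared — at least 1 bp overlap — with the other
replicate's top set at 80% or better, in both directions; (2) Spearman
correlation of per-base coverage over three randomly drawn, non-overlapping
300 kb regions must average above 0.9 (a per-region mode is available);
(3) more than 80% of all retained islands must be shared, again both ways.
Sharing is made directional and required both ways because the published
"share" is directionless; the symmetric requirement is the stricter
reading. Downstream results are reported only when true in both
replicates: the consensus operator intersects (gene, status) pairs.

ChIP-qPCR summaries follow the delta-Ct formulas: percent input is
$2^{Ct_{input} - Ct_{ChIP}} \times$ dilution factor, normalized by the
geometric mean of the reference genes' percent inputs (the standard
multi-reference convention; the source names reference normalization
without a formula), and fold enrichment over the no-antibody control is
$2^{Ct_{noab} - Ct_{ChIP}}$ with a strict > 3 pass rule.

# Factorial expression analysis

Linear-scale expression values are filtered by the published cutoff of 40,
read inclusively (a gene is kept if *any* sample reaches 40; it is removed
only when below the cutoff across all conditions). The 2x2x2 ANOVA is
fitted on log2(x + 1) — the source applies its cutoff on the linear scale
but does not state the analysis transform; log2 is the standard
variance-stabilizing choice for such array summaries, and a raw-scale
mode is available. Under the balanced design the seven one-degree-of-freedom
terms are orthogonal contrasts, so all genes are fitted in a handful of
matrix products; the result is the classical ANOVA table, and the test
suite requires agreement with `stats::aov` to 1e-10 relative. The balanced
design also makes the sums-of-squares type moot. Benjamini–Hochberg is
applied per term across genes (the source names FDR, not a procedure; BH
is the standard reading). Response sets use the published thresholds:
genotype FDR < 0.05 split by the sign of the mutant-minus-WT log2
contrast, carbon/light FDR < 0.05, genotype-by-light FDR < 0.15.

# Set integration

Overlap significance is the exact upper-tail hypergeometric probability.
The background universe defaults to the annotation's gene set shared by
the compared sets and is always reported alongside the p-value, because
published hypergeometric p-values are background-dependent and the source
never states its universe. Direct targets are hypomethylated ∩ bound;
functional targets are hypomethylated ∩ down-regulated. The
responsiveness partition splits a target set into carbon-only, light-only,
both, and neither, reporting the percent responsive rounded half-up — the
rounding that reproduces the published percentages (for example
100 x 728/2267 → 32).

Expression–methylation binning ranks genes by one measure into ten
equal-count bins (remainder to the lowest bins) and summarizes the other
per bin (median methylation over expression bins; mean log2 expression
change over hypomethylation-magnitude bins), with a Spearman trend
statistic over the bin summaries. Chromosomal clustering slides a
20-gene window (step 1) along each chromosome's gene order, scores
member counts by the upper-tail hypergeometric given the genome-wide set
frequency, and merges overlapping windows with raw p < 0.05 into
clusters — raw thresholds as published for this scan; an optional BH mode
is deliberately off by default.

# The synthetic generator

The generator emulates the study design at desk scale with truth labels
for every derived quantity: two genotypes, a 2x2 carbon/light treatment,
two ChIP replicates plus input per genotype/condition, an enzyme-binding
library, and a 3-replicate factorial expression matrix. Defaults mirror
the published proportions — half the genes marked in wild type, 35% of
marked genes hypomethylated in the mutant (4,060 of ~12,000), 18% of
hypomethylated genes bound (728 of 4,060), carbon/light responsiveness at
22%/35% (4,735 and 7,475 of 21,552) — with desk-scale genomes (5 Mb, 500
genes) and libraries (2–5 x 10^5 fragments) sized so the full test suite
and the acceptance script run in minutes on one CPU.

Fragments are fixed-length (200 bp, a median-fragment-size reading) and
strandless, placed by midpoint: input libraries uniformly, mark-ChIP
libraries as uniform background plus `enrichment_fold`-weighted density
over marked gene bodies under a linear 5'-weighted profile (weight 1.5 at
the TSS tapering to 0.75 at the TTS, normalized to mean 1 — the published
shape is shown but not parameterized, and any monotone 5'-biased profile
serves). In the mutant, density over the 3' 60% of hypomethylated bodies
is multiplied by the attenuation factor (0 = complete loss; boundary
configurable). Library sizes are Poisson around the target, and every
dataset is reproducible from its seed. Expression is built on the log2
scale as baseline + assigned effects + Gaussian noise and emitted on the
linear scale so the cutoff-40 filter is genuinely exercised; the baseline
(mean 8, sd 1.6 on log2) puts roughly 5% of genes below 40 everywhere.

What the generator does *not* model: sequencing reads (no FASTQ),
fragment-length variation, mappability or GC bias, spike-ins, exon
structure, and condition-dependent mark changes. Passing recovery tests
therefore demonstrates the pipeline's statistical machinery on data whose
generative assumptions match the model's; they do not certify performance
on real libraries with correlated artifacts.

# Numerical choices and degenerate inputs

Window eligibility uses the smallest count whose Poisson upper tail falls
below the window p; island boundaries are window-aligned by construction.
Ratios use a 0.5 pseudocount; test statistics never do. Equal RPM in a
differential region keeps the `a_up` label by convention but can never be
significant (fold change 1). Empty chip libraries, out-of-bounds
fragments, unbalanced designs, empty gene sets for aggregation, all-zero
gene bodies, and undersized genomes are rejected with explicit errors.
Sharing and consensus operators are symmetric by construction;
deduplication is idempotent and order-independent.

# Known limitations

The caller is a single-library-pair method; replicate structure is handled
by the QC criteria and the both-replicates consensus rule rather than by
joint modeling. The hypergeometric background must be chosen by the user
where universes differ. The metagene module offers scaled-body coordinates
only (no TSS-anchored mode, no exon awareness). Printed significance
bounds from the original study that depend on its unstated background
universe are not reproduced, only the background-free arithmetic is.
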