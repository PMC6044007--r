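---
title: "Quality assessment of MeRIP-seq data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of MeRIP-seq data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(meripqc)
```

This vignette documents the statistical procedures implemented in
`meripqc`, the assumptions behind them, and the design decisions taken
where the methodology left genuine choices open. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## The measurement model

A MeRIP-seq experiment pairs an antibody-enriched IP library with a
non-enriched Input control. If a transcript region carries m6A, IP reads
concentrate there; Input reads follow gene expression alone. All of the
package's metrics therefore live on a transcript coordinate system that
separates signal-bearing exonic space from intronic and non-genic
background.

**Gene models.** Isoforms are not resolved: all exon records of a gene are
merged into a disjoint union, which defines the gene's mRNA coordinates
(position 0 = 5' end; on the minus strand that is the rightmost genomic
base). Counting reads per isoform would double-count shared exons and turn
region tallies non-additive; the union model keeps every accounting exact.
When CDS records exist, the union CDS footprint projected into transcript
coordinates splits the mRNA into 5'UTR / CDS / 3'UTR. Genes without CDS
are kept for exon/intron accounting and binning but excluded from
sub-region percentages and the metagene. Strand "." is treated as "+".
Internally all coordinates are 0-based half-open; GTF input is read as
1-based closed via `rtracklayer`.

**Bins.** Each mRNA is tiled 5'→3' with `bin_width` = 200 nt bins, a
common window size for MeRIP analyses (fragments are ~100–200 nt, so one
bin is roughly one resolvable peak footprint). A trailing partial bin is
kept when it is at least a quarter of the bin width and merged into the
previous bin otherwise — short remainders would otherwise form
high-variance micro-bins, while merging everything would make last bins up
to twice the nominal width.

**Read assignment.** A read (or properly-paired fragment) is located by
the midpoint of its aligned genomic span. The midpoint rule assigns every
read to exactly one bin and one region, keeping tallies additive and
robust to fragment length; whether the original tooling counted by 5' end,
midpoint or overlap is not documented anywhere we know of, so the choice
is stated here explicitly. Duplicates are kept (the coverage-class
histogram is designed to *reveal* PCR artifacts); secondary,
supplementary and unmapped alignments are dropped; no MAPQ cut by default.
Assignment is unstranded, since MeRIP library strandedness varies between
protocols.

## Read-distribution statistics

Exon/intron/non-genic percentages are taken over the sample total; the
5'UTR/CDS/3'UTR percentages over the sum of the three sub-region counts
(reads in non-coding genes carry no sub-region). The coverage-class
histogram classifies every bin into decade classes
0, 1–10, (10,10²], ..., (10⁴,10⁵], >10⁵ — comparable across samples only
at a common depth, which the pipeline enforces by hypergeometric
down-sampling to the smallest library.

The metagene profile excludes genes with fewer than 10 exonic reads (not
reliably detected), divides each remaining gene's per-nt coverage by its
mean over the mRNA so every gene carries equal weight, rescales each of
the three regions to 100 grid points by linear interpolation of bin
midpoints, and reports the 25/50/75% quantiles across genes per position
(type-7 quantiles, R's default — conventions differ, so this is pinned
down here). Genes with an empty UTR cannot be rescaled and are skipped.
Per-gene standardization makes the curves exactly invariant to rescaling
a sample's depth, which the tests assert.

## ESES: exome signal extraction scaling

The immunoprecipitation-efficiency metric adapts signal extraction
scaling (developed for ChIP-seq background estimation) to the exome. With
y_{t,g,i} and y_{c,g,i} the IP and Input counts of bin i in gene g:

1. ȳ_{t,g} = Σ_i y_{t,g,i} / n, and ŷ_{t,g,i} = y_{t,g,i} / ȳ_{t,g}
   (likewise for the Input), which cancels gene expression and library
   depth; the mean normalized signal of every retained gene is exactly 1.
2. Genes with fewer than 10 exonic reads are excluded. The threshold is
   applied on *both* the IP and the merged-Input side: the published
   description states only the IP-side filter, but a zero Input mean
   would make step 1 undefined, so the symmetric filter is forced.
3. All ŷ_t are pooled and sorted increasingly; ties are broken by
   (gene, bin) so results are deterministic, and the sort key is rounded
   to 12 significant digits so values tied in exact arithmetic remain
   tied under floating-point rescaling. The Input signals are reordered
   by the same permutation.
4. Cumulative fractions p_j and q_j are formed, and
   k = argmax_j |q_j − p_j| (the *largest* maximizing index, so the
   degenerate IP ≡ Input case lands at k = N with enriched fraction 0).

Reported metrics: scale factor max |q − p|; enriched region (N − k)/N;
signal read count 1 − p_k. Two conventions deserve a note. First, the
enriched region is (N − k)/N — the bins *after* the background cut — which
matches both the textual definition of the split and the magnitude of
published values (~13% for good samples); the occasionally seen "(k/N)"
print is inconsistent with its own surrounding text. Second, the signal
read count is computed on normalized signal (1 − p_k), not raw reads,
mirroring how the cumulative curves themselves are defined; q is likewise
the expression-normalized Input.

**Identifiability.** The background cut k is only well defined when the
cumulative gap |q − p| has drift throughout the background. Bins of genes
that carry no methylation at all behave identically in IP and Input, so
they contribute a flat, zero-drift stretch in which the argmax wanders
under any sampling noise; in an experiment (or simulation) where many
genes are entirely unmethylated, the enriched-region estimate inflates
toward the middle of that flat stretch. This is a property of signal
extraction scaling itself, not of the implementation — the package's
recovery tests demonstrate exact recovery in the noiseless limit and
±0.05 recovery at 100k reads when every gene carries a peak. It is also
why the metric should be read comparatively (across samples and against
the reference ranges) rather than as an absolute methylation-fraction
estimate.

## C-test

For bins with more than 10 combined reads, enrichment at fold c is tested
by the exact conditional comparison of two Poisson means: given
T = x_IP + x_Input, under H0: λ_IP ≤ c·d·λ_Input the IP count is
Binomial(T, π₀) with π₀ = c·d/(1 + c·d), where d is the IP/Input depth
ratio (computed from total exonic bin counts for internal consistency).
The p-value is the exact upper tail, one-sided toward enrichment; the
test is vectorized through `pbinom` and verified in the suite against
brute-force enumeration of the binomial mass to 1e−12. The profile
reports the fraction of tested bins with p < α over a fold grid
(default 1–4 in steps of 0.5, α = 0.05; the significance level is not
prescribed anywhere, so it is a visible, configurable default). The tail
probability is monotone in π₀, so profiles are non-increasing in c by
construction.

## Multi-sample comparisons

Size factors are s_j = y_j / exp(mean_n log y_n) with y_j the total
exonic bin count of sample j; normalized counts are x_{i,j}/s_j, making
every column sum equal to the geometric mean of the raw totals
(asserted to 1e−6 relative in the tests). Bins with zero counts in every
sample carry no information and destabilize distances, so they are
dropped. Hierarchical clustering uses Euclidean distance with complete
linkage — the default of the standard agglomerative routine, stated
explicitly for reproducibility — with columns pre-sorted by sample id so
tied merges resolve deterministically. PCA is centered and unscaled (the
`prcomp` default); all-identical samples are flagged degenerate rather
than crashing. Normalization makes both analyses invariant to uniform
depth rescaling of any sample, which the tests assert on dendrogram
topology.

Gene-level heterogeneity takes each gene's mean and SD of bin counts
(≥ 2 bins) within one sample; replicate consistency takes each bin's
cross-replicate mean μ_i and SD s_i of normalized counts with the
√(J−1) divisor. Both are smoothed by a tri-cube weighted, degree-1 local
regression with span 0.75 — the classic loess default, since no smoothing
parameters are published — evaluated on a 100-point grid over the
observed range. loess emits numerical warnings on heavily tied
abscissae; these are suppressed as the fit remains well defined.

## Verdicts and the report

The three headline ESES metrics are compared against packaged reference
ranges compiled from a published survey of 61 good-quality m6A-seq IP
samples: enriched region 12–25%, scale factor 0.08–0.3, signal reads
87–95%. Intervals are closed (a boundary value counts as within), and the
ranges are user-overridable — other modifications, notably m1A, have
legitimately different regimes. The pipeline writes a self-contained HTML
report (tables plus base64-embedded figures) and a JSON summary whose
numbers agree with the HTML tables exactly; with a fixed seed and
configuration, reruns are bit-identical. In lenient mode, failed
non-fatal sections are recorded with their reason instead of aborting.

## The synthetic-data generator

`simulate_dataset()` emits a single-chromosome toy transcriptome
(default 50 genes; 5'UTR 100–300 nt, CDS 600–1500 nt, 3'UTR 300–800 nt,
0–3 introns of 0.2–2 kb, 10% non-coding), log-normal gene abundances
(sdlog 1), and single-end 50-nt ungapped MAPQ-60 reads. Input reads are
multinomial over bins proportional to abundance × bin width; IP reads
multiply methylated bins by `peak_fold` (default 8, a strong antibody).
Methylated bins are placed within ±2 bins of the stop codon and assigned
round-robin across genes — every coding gene receives one stop-codon
peak before any gene receives a second — reflecting that m6A methylation
is a gene-level phenomenon rather than i.i.d. over bins. Background rates
(IP: 5% intronic, 46% non-genic; Input: 3%/55%) mirror the region
percentages reported for real mouse m6A-seq libraries. Artifact modes:
`pcr_dup` duplicates 5% of reads with geometric (p = 0.05, jackpot-like)
copy counts; `three_prime_bias` tilts within-gene sampling by
exp(2 · position/length); `swap` exchanges the IP and Input roles.

What the generator does *not* emulate: splice-junction reads, sequencing
errors and quality scores, fragment-length variation, isoform-specific
expression, rRNA contamination, and the scale of a real experiment
(~20k genes, 10⁷ reads). Passing tests therefore validate the
arithmetic, the contracts and the qualitative failure-mode signatures —
not performance on real libraries.

**Problem sizes used in validation.** The test suite runs the generator
at desk scale: the default fixture set is 50 genes × 11 samples × 15k
reads (≤ 200k reads in total); planted-fraction recovery uses 15 coding
genes at 100k reads per sample, 20 seeds per condition, with transcript
lengths set so bins-per-gene ≈ 1/f (see the identifiability note above);
null calibration of the C-test uses 20 seeds of 300 Poisson bins. The
end-to-end pipeline on the default fixtures completes in a few minutes
on one CPU.

## Known limitations

- ESES's enriched fraction is comparative, not an absolute methylation
  estimate (identifiability, above).
- The sub-region split of a bin's reads is resolved read-by-read, but
  normalization treats a bin as a unit; bins straddling the CDS/3'UTR
  boundary blur the metagene by up to half a bin width.
- No variance-stabilizing transform is applied before clustering/PCA
  (none is used in the original methodology), so very deep samples are
  dominated by high-count bins.
- The GTF parser accepts the common gene_id/transcript_id attribute
  dialect; exotic GFF3 variants should be converted first.
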