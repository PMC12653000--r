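---
title: "Methods: transcript-level tissue specificity and promoter profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-level tissue specificity and promoter profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tisspec)
```

## The statistic

For every transcript, `specificity_raw()` standardizes the expression
value of each tissue against the transcript's own cross-tissue
distribution:

$$x_i = \frac{e_i - \bar e}{\sqrt{\tfrac{1}{n-1}\sum_{j=1}^{n}(e_j - \bar e)^2}}$$

where $e_i$ is the expression (FPKM or TPM) of the transcript in tissue
$i$, $\bar e$ its mean over the $n$ tissues of that species' atlas, and
the denominator the sample standard deviation. The statistic is
dimensionless and invariant to the transcript's absolute abundance, so
high expressors and near-silent transcripts are placed on the same scale.
Two analytic facts anchor the test suite:

* a transcript expressed in exactly one tissue attains the maximal value
  $(n-1)/\sqrt{n}$ there, for any expression level — this closed form is
  checked against direct evaluation of the formula;
* a constant row (including all zeros) has an undefined standardization
  (0/0); we define its specificity as 0 in every tissue, because such a
  transcript is maximally non-specific. This is a deliberate convention,
  not a numerical fallback.

`normalize_maxabs()` then rescales to $[-1, 1]$ by dividing each tissue
column by that column's largest absolute raw value (max-abs scaling per
feature, each tissue being a feature). After scaling, 1 marks the most
specific transcript *of that tissue*; values are comparable within a
tissue, and only loosely across tissues. Because the normalizing constant
is an extreme statistic of the column, it is anchored by whichever
transcript is most specific there — in both real atlases and the
synthetic ones below, tissue-restricted transcripts pin it at or near the
$(n-1)/\sqrt{n}$ bound. Whether the source analyses scaled per column or
over the flattened matrix is not documented; both are implemented
(`scope = "column"` is the default, `"global"` the alternative) and the
choice is recorded in every output.

## Categories and thresholds

`assign_categories()` splits the normalized scale into four categories:
underrepresented (strictly below −0.20), generally expressed (−0.20 to
0.00, both ends included), enriched (above 0 up to and including 0.80)
and highly enriched (strictly above 0.80). The boundary inclusivity
mirrors the qualitative wording the cutoffs come from ("below",
"between", "from … to", "exceeding"); exact boundary values are rare in
continuous data, so the choice is about reproducibility rather than
counts. All thresholds are plain parameters (`category_thresholds()`,
`count_enriched(threshold = )`) — in particular there is no fixed cutoff
for "tissue-specific" (values close to 1) as distinct from "highly
enriched"; callers who need one pass their own threshold.

Tie-breaks: the argmax tissue of a transcript
(`summarize_transcripts()`) resolves ties lexicographically by tissue
name, so reruns and platform changes cannot flip the reported top
tissue.

## Cohort statistics

`group_summary()` reports per-category means, medians and 95%
confidence-interval half-widths computed from the t-distribution
($t_{0.975,\,m-1}\, s/\sqrt{m}$ for group size $m$) rather than the
normal approximation, since focal categories can be small. Empty
categories yield absent statistics (not zeros); singletons yield a mean
but no interval. Between-category location tests use Welch's two-tailed
t-test (`welch_t_test()`), which does not assume equal variances; all
pairwise category comparisons are computed and reported uncorrected,
with the usual significance stars (* < 0.05, ** < 0.01, *** < 0.001).
Correlation matrices (`correlation_matrix()`) use pairwise-complete
observations, default to Spearman whenever an expression or specificity
vector is involved (heavy-tailed scales), use average ranks for ties,
and flag — rather than zero — coefficients involving a constant vector.

## Orthology and networks

Ortholog links carry integer database-support scores; `filter_orthologs()`
keeps pairs supported by at least 12 of the 14 reference databases. The
cutoff is inclusive ("at least 12"), and exposed as a parameter. For
cross-species joins a gene is represented by its transcript with maximal
normalized specificity in the focal tissue (`gene_tissue_summary()`);
this preserves the enrichment signal that the comparison tracks, whereas
mean aggregation (available via `aggregate = "mean"`) dilutes it across
variants. Many-to-many ortholog links yield one joined row per pair.
`filter_by_expression()` removes low expressors using the transcript's
*maximum* expression across tissues (floor 5), so tissue-restricted
transcripts are not penalized for being silent elsewhere.

Networks are undirected and unweighted: physical-interaction edges join
same-species nodes drawn from the per-tissue highly-enriched gene sets,
ortholog edges join cross-species nodes. Centralities are computed on
the physical subgraph only — ortholog edges never enter shortest paths —
per connected component: betweenness normalized by $(m-1)(m-2)/2$ for
component size $m$, closeness $(m-1)/\sum d$ with isolated nodes scored
0. The hub filter keeps nodes with physical degree strictly above 20,
where degree is measured on the built (tissue-restricted) graph; whether
the source analyses counted degree before restriction is not documented,
so the restriction-first convention is fixed here and stated in the
exports.

## TSS composition profiles

The TSS of a transcript is the annotation start for `+` strand and
`end − 1` (0-based half-open) for `−` strand. All coordinates are
0-based half-open internally; GTF (1-based closed) and BED are converted
at the I/O boundary only. "Upstream" always means 5′ of the transcript:
minus-strand flanks are reverse-complemented, which is what makes the
downstream T/G skew visible at all — the suite contains an ablation
showing the planted peak disappears under strand-naive extraction.
Flanks are deduplicated as exact uppercase strings (so identical
annotated TSSs of transcript variants collapse), windows run
`U = D = 5000` by default (a 10 kb view), contig-edge positions are
N-padded, and N is excluded from frequency denominators — the grid stays
rectangular without biasing composition. Profile comparisons report MSE
and Euclidean distance over the concatenated per-base frequency vectors,
and per-base Pearson correlations over selectable sub-windows (defaults:
upstream = [−5000, −500), TSS = [−500, 500); the exact sub-windows behind
the published heatmap panels are not documented, so they are parameters
and every output is labelled with the range used). Profiles are
unsmoothed by default (`smooth = 1`). Motif-analysis exports cover the
upstream 300 bp and the ±100 bp core-promoter windows, written as
byte-stable 60-column FASTA with the control set as background; motif
discovery itself is left to external tools.

The control (background) set is defined per species: transcripts whose
maximum normalized specificity stays at or below 0.8 in every tissue.
Non-coding subsets below 50 sequences are refused rather than profiled,
since per-position frequencies from a handful of sequences are noise.

## The synthetic data model

The generators produce every input the pipeline consumes, with ground
truth, so all stages are testable without downloads.

*Expression* (`gen_expression()`): per-transcript baseline abundance is
log-normal (meanlog 2, sdlog 1.5 — medians around 7 FPKM spanning
several orders of magnitude, the right-skew typical of FPKM/TPM data),
modulated by multiplicative tissue noise $\max(0,\,1 + 0.2\,Z)$. A small
fraction (0.4%) of transcripts is *tissue-private* — detected in exactly
one tissue, assigned round-robin so every tissue receives some. This
mirrors real atlases, where rare private isoforms exist in every tissue,
and it is what anchors each column's max-abs constant at the
$(n-1)/\sqrt{n}$ bound; without such transcripts the normalizer is just
the luckiest noise row and the background false-positive rate at the
0.8 threshold rises by an order of magnitude. Under this model a pure
background (fold 1) run leaves about 0.4–0.5% of transcripts above 0.8
at both atlas sizes (17 and 33 tissues), and planted fold-100
transcripts are recovered essentially completely with false positives
well under 1%. Planted enrichment multiplies the target-tissue value by
`fold` (default 100). Transcripts-per-gene means default to 3.4
(human-like) and 2.2 (fly-like).

What the generator does *not* emulate: correlated tissue blocks (e.g.
brain/head/eye redundancy), length or GC bias of FPKM estimation,
isoform-level expression coupling within a gene, and zero inflation
beyond the private fraction. Passing recovery tests therefore shows the
statistic and thresholds behave as designed under clean planted signal,
not that real-atlas counts would be reproduced.

*Genomes* (`gen_genome_annotation()`): i.i.d. background bases at GC
0.41, with three strand-aware promoter signals per signal-bearing
transcript — a GC rise over [−100, 0) (+0.15 GC), an A/T peak at
−25 ± 5 bp (+0.20 A/T, overriding the rise in its window, as a
TATA-like element interrupts a GC-rich core promoter), and a downstream
T/G excess (+0.10 over 100 bp). About half of the transcripts are on the
minus strand, with the signal reverse-complemented into the genome.

*Links* (`gen_links()`): ortholog pairs over a configurable fraction of
the gene universes with uniform integer scores 1–15; sparse background
interaction edges (mean degree 3) plus designated hubs wired to exactly
25 distinct partners (background edges touching hubs are removed first,
so the planted degree is exact); disease terms on 30% of species-A
genes.

All generators take one explicit seed, restore the caller's RNG state,
and are byte-reproducible.

## Problem sizes

The shipped test suite and the acceptance script run the generators at
the study-shaped sizes: 17- and 33-tissue atlases, 2,000 transcripts for
recovery experiments (50 planted at fold 100), 10,000 transcripts for
the null calibration, 500 promoters for peak localization, and 300-gene
universes with 5 planted hubs per species for the network checks. The
end-to-end pipeline demonstration uses 2,000 transcripts per species
with 500 promoters each and 10 kb profile windows.

## Known limitations

* The specificity index is transcript-level throughout; no gene-level
  index (and no tau-style alternative) is provided.
* Max-abs normalization makes cross-tissue comparisons of normalized
  values depend on each tissue's extreme transcript; comparisons across
  tissues should use the raw index or be interpreted accordingly.
* Centralities are only as meaningful as the interaction tables; the
  package consumes, never infers, interactions and orthologs.
* The percentage convention is half-up rounding to one decimal, chosen
  to match conventional reporting; `round()`'s banker's rounding would
  differ on exact halves.
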