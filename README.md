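# tisspec

Transcript-level tissue specificity and comparative promoter analysis.

`tisspec` is for researchers comparing tissue-restricted gene expression
across species — e.g. a 33-tissue human atlas (GTEx-style) against a
17-tissue *Drosophila* atlas (FlyAtlas2-style) — at the resolution of
individual transcripts. It computes a per-transcript, per-tissue
specificity index, categorizes transcripts by enrichment, summarizes
gene/transcript structure per category, integrates the two species
through ortholog tables, disease annotations and physical-interaction
networks, and profiles strand-aware nucleotide composition around
transcription start sites. A seeded synthetic-data suite generates every
input with ground truth, so the entire pipeline runs and is tested
without any download.

## The core statistic

For each transcript with expression values $e_1,\dots,e_n$ across the
$n$ tissues of an atlas,

$$x_i = \frac{e_i - \bar e}{\sqrt{\tfrac{1}{n-1}\sum_j (e_j - \bar e)^2}}$$

is the specificity of the transcript in tissue $i$: its expression
standardized against the transcript's own cross-tissue distribution. A
transcript expressed in a single tissue reaches the maximum
$(n-1)/\sqrt{n}$ there; constant rows are defined as 0 everywhere. The
raw indices are max-abs scaled per tissue column into $[-1, 1]$, where 1
marks the most specific transcript of the tissue. Transcripts are then
categorized as underrepresented (< −0.20), general (−0.20–0.00),
enriched (0–0.80) or highly enriched (> 0.80).

Around that core, the package provides Welch's t-tests and
Pearson/Spearman correlation matrices between categories and features;
DIOPT-style ortholog filtering (support ≥ 12) with cross-species joins
and Venn decompositions of highly-enriched gene sets; disease-association
percentages; igraph-based interaction networks with per-component
betweenness/closeness and a strict degree > 20 hub filter; and 10 kb
strand-aware ATGC profiles around TSSs with MSE/Euclidean/correlation
comparisons and byte-stable FASTA export of core-promoter windows for
external motif tools.

## Worked example

Generate a 17-tissue atlas with 50 transcripts planted at 100-fold
enrichment in one tissue, then recover them:

```r
library(tisspec)
gen <- gen_expression(n_transcripts = 2000, tissues = 17,
                      plan = data.frame(tissue = "tissue05", n = 50,
                                        fold = 100),
                      seed = 7)
sp <- specificity(gen$expr)          # raw index + max-abs normalization
count_enriched(sp, "tissue05", threshold = 0.8)
#> $count
#> [1] 51
#> $fraction
#> [1] 0.0255
```

51 transcripts exceed 0.8: all 50 planted ones plus one background
transcript (a 0.05% false-positive rate). The four-way categorization of
the same tissue:

```r
a <- assign_categories(sp)
table(a[, "tissue05"])
#>         enriched          general  highly_enriched underrepresented
#>             1019              524               51              406
group_summary(a, gen$expr, "tissue05")[, c("category", "n_transcripts",
                                           "mean_expr", "ci_expr")]
#>           category n_transcripts  mean_expr     ci_expr
#> 1 underrepresented           406   19.59285    6.847623
#> 2          general           524   22.96964    4.649045
#> 3         enriched          1019   26.92319    4.280616
#> 4  highly_enriched            51 1929.41305 1354.672551
```

The highly-enriched category has ~100-fold higher mean expression in the
tissue — the planted signal — with a wide t-based 95% CI reflecting the
log-normal abundance spread. `write_fixture()` + `run_pipeline()` run
the same machinery end to end (two species, orthologs, networks, TSS
profiles) from a single config; see the methods vignette in
`vignettes/` for the model, parameter and design details.

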