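---
title: "Methods: chromatin and expression statistics for the embryonic germline"
author: "germchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin and expression statistics for the embryonic germline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germchrom)
```

# Scope

Single-cell multiome profiling of the Drosophila embryonic germline asks
two quantitative questions that standard scATAC/scRNA toolkits do not
answer directly: *how* accessibility is distributed along genes within a
cell cluster (not just how much of it there is), and how the X
chromosome's output compares between XX and XY germ cells at both the
chromatin and the expression level. `germchrom` implements the small
family of statistics built around those questions -- the end-to-start
accessibility (ESA) score, TSS enrichment and FRiP quality scores,
megabase-windowed accessibility indices with female-to-male ratios,
negative-binomial selection of zygotically activated genes, sex
expression ratios by chromosome, germline-to-soma transcription bias
with promoter extraction for motif discovery, motif-site accessibility
indices with PCA, and per-nucleus histone H3 intensity normalization --
together with a fully seeded synthetic-data generator whose planted
ground truth is the package's validation surface.

Upstream processing (alignment, barcode handling, droplet QC,
clustering, peak calling) is out of scope: fragments files, gene
annotations, cluster assignments, count matrices, peak intervals and
per-nucleus intensity tables are inputs.

# Conventions

All interval arithmetic is 0-based half-open internally. Fragment files
and BED are read as-is; GTF (1-based closed) is converted on read. Gene
models carry 1-based TSS and 3' end positions. Fragment coordinates are
assumed already Tn5-shifted by the upstream pipeline, as in standard
fragment files; no re-shifting is applied. When a gene has several
isoforms, the longest transcript provides the single (TSS, 3' end)
anchor pair -- a deterministic convention, overridable by supplying a
pre-reduced table via the `tsv` dialect of `read_gene_models()`.

"Reads" are operationalized as Tn5 cut sites for all density statistics
(ESA, TSS enrichment, windowed indices, chromosome tallies): each
fragment contributes its start and `end - 1`, replicated by its count,
so cut-site mass is exactly twice fragment mass. FRiP alone uses
whole-fragment overlap, matching that score's standard definition.

# The chromatin statistics

## End-to-start accessibility

For gene $g$ and cluster $c$, with $t_g$ and $e_g$ the numbers of the
cluster's cut sites within $\pm 250$ bp (default `flank`) of the TSS
and the transcript 3' end,

$$\mathrm{ESA}_{gc} = \frac{e_g + \alpha}{t_g + \alpha}, \qquad \alpha = 1.$$

ESA near 1 indicates accessibility dispersed over the gene body (both
windows sample the same density); ESA $\ll 1$ indicates TSS-focused
accessibility. The pseudocount $\alpha$ keeps the ratio defined at zero
counts; it is applied symmetrically so the uniform-placement expectation
stays at 1. Genes whose two windows overlap (TSS-to-end distance
$< 2 \times$ flank) are flagged and must be excluded from summaries,
since their windows partly count the same cut sites. Cluster-size
normalization cancels in this within-cluster ratio and is therefore not
applied inside the score; per-cluster totals are available in the
windowed tables where normalization does matter.

A caveat that shapes how the package validates this score: at low
per-window counts the ratio $(e+1)/(t+1)$ of two Poisson variables is
Jensen-biased upward (for $\lambda \approx 3$ the bias reaches tens of
percent). The uniform-placement calibration of ESA is therefore run on
the compact genome preset (`sim_config_compact()`, 1.8 Mb, 180 genes),
where $2\times10^5$ cut sites put roughly 50 cuts in each 501-bp window
and the mean ESA under uniformity is within a few percent of 1. On
sparse data, per-gene ESA values should be aggregated (medians across
genes), exactly as the cluster-level analyses here do.

## TSS enrichment and FRiP

TSS enrichment follows the community recipe with the package's fixed
conventions: cut-site density is aggregated strand-aware over
$\pm 2000$ bp around every TSS, normalized by the mean density in the
two outermost 100-bp segments plus a pseudocount of 0.1, and scored as
the mean normalized density within $\pm 50$ bp. Uniform placement
scores $\approx 1$; promoter-focused chromatin scores well above 1. The
exact span/core/flank values are this package's convention -- published
recipes differ in detail while sharing the "flank-normalized density at
the TSS" structure, and only the relative ordering of clusters is
interpreted. FRiP is the count-weighted fraction of a cell's fragments
overlapping any peak by at least 1 bp; cells with zero fragments are
omitted.

## Windowed accessibility and dosage ratios

Windows of 1 Mb (default) tile each chromosome from coordinate 0; the
final short window is retained and flagged. For cluster $c$ and window
$w$, the accessibility index is cut sites in $w$ per million cluster
cut sites. Female-to-male ratios use a pseudocount of 0.1 on both
indices, and chromosome summaries are plain means over that
chromosome's windows. With two female X copies and one male copy
boosted by a factor $a$, the expected X ratio is $2/a$ (up to the
per-cluster total normalization, which shifts all ratios by the ratio
of total accessible mass -- about 2% here); autosomes sit near 1. The
per-chromosome tallies table divides each chromosome's cut-site total
by the 2L total within each cluster.

# Differential expression and dosage statistics

## The NB Wald engine

The zygotic-activation selection needs a two-group test on counts.
`nb_wald_de()` is intentionally plain: cells are total-count normalized
within the comparison (size factor = cell total / median cell total);
per-gene group means $\hat\mu_A, \hat\mu_B$ of normalized counts
estimate the NB means; a single per-gene dispersion $\hat\phi$ comes
from the method of moments,
$\hat\phi_k = (s_k^2 - \hat\mu_k \overline{1/f_k})/\hat\mu_k^2$
per group (the middle term removes the size-factor-scaled Poisson
component), pooled across groups by residual degrees of freedom and
floored at $10^{-8}$. The Wald statistic is
$z = \mathrm{LFC}/\mathrm{SE}$ with
$\mathrm{LFC} = \log_2(\hat\mu_A/\hat\mu_B)$ and the delta-method
standard error
$$\mathrm{SE}^2 = \frac{1}{\ln^2 2}\left[
  \frac{\hat\mu_A \overline{1/f_A} + \hat\phi\hat\mu_A^2}{n_A \hat\mu_A^2} +
  \frac{\hat\mu_B \overline{1/f_B} + \hat\phi\hat\mu_B^2}{n_B \hat\mu_B^2}
  \right],$$
with a two-sided normal p-value. A continuity term of 0.5 added to each
group's summed normalized count keeps the fold change finite when a
gene is absent from one group; with a couple of hundred cells per group
it is negligible otherwise. There is no shrinkage, no outlier
refitting, and no multiple-testing adjustment -- the downstream
selection applies raw-p cutoffs by design, and an import path
(`read_de_table()`) accepts an externally produced table (for example
a DESeq2 export with columns `gene lfc p`) wherever the engine should
be swapped.

Simulation shows the test is well calibrated in the regime it is used
in (the acceptance suite measures the type-I fraction at $p<0.05$
across a 20-seed null sweep of 2,000 genes at 100 cells per group, and
the power to call a planted 4-fold gene at $p<10^{-10}$ with 200 cells
per group).

## Selection and ratio rules

Zygotically activated genes are those with fold change strictly greater
than 2 **and** $p < 10^{-10}$, computed for the stage-2 germline
(pooled female and male) against the pre-activation cluster, after
excluding genes whose total raw count across the two groups is below
10. Sex expression ratios are
$(\bar{x}_F + 0.01)/(\bar{x}_M + 0.01)$ on normalized group means; the
0.01 floor mirrors the pseudocount convention used for the run-on soma
reference, since no separate value is stated for expression ratios.
Chromosome means are taken over gene-set members with any expression in
either sex. Sex-biased ranking orders non-excluded genes by descending
fold with ties broken by ascending p-value then gene id, so the rank
table is always a permutation of the tested genes.

# Germline-to-soma bias, promoters and motifs

Germline nuclear expression (per-cluster mean normalized snRNA counts)
is compared with a somatic nascent-transcription reference: genes with
germline value below 1 are excluded (an inclusion floor -- the
alternative reading, clamping values up to 1, is available by
pre-transforming the input, but filtering is the default because a
clamped ratio would rank unexpressed genes by soma signal alone); the
soma signal receives +0.01 so the ratio $g/(s+0.01)$ is always defined,
and genes absent from the soma table are treated as $s = 0$. The top
150 genes per cluster (descending ratio; ties by descending germline
value then gene id) feed promoter extraction: 500 bp upstream of the
TSS, strand-aware (`[t-1-500, t-1)` on plus, `[t, t+500)` on minus, 0
based), clipped at chromosome bounds with clipped regions flagged. The
promoter FASTA is ready for an external motif-discovery run; discovery
itself is out of scope.

Motif scanning is a straightforward log-odds scan: each PWM column is a
probability (count matrices get +0.01 per cell and renormalize), scores
are $\sum_j \log(p_{b_j j}/q_{b_j})$ against the background $q$
(uniform unless the file provides one), `N` scores 0, both strands are
scanned, and a window is a hit at $\ge 0.8\times$ the maximum
attainable score. The threshold fraction is a convention -- there is no
canonical value -- and the scanner is validated against exhaustive
window enumeration.

The motif-site accessibility index deliberately replaces chromVAR-style
GC-matched background deviations with a length-normalized enrichment
ratio: for cluster $c$ and motif $m$, the fraction of the cluster's
in-region cut sites falling within 50 bp of hit centers, divided by the
fraction of scanned length those windows occupy (0.5 pseudocount on
both counts; hit windows merged and intersected with the scanned
regions so lengths and counts agree). Uniform placement gives indices
near 1. This preserves the qualitative use of the statistic --
cluster-biased TF-site accessibility -- but is **not** chromVAR: it
does not correct for GC or accessibility-matched backgrounds, so
absolute values should not be compared across motifs with very
different compositions. PCA over the cluster-by-motif matrix centers
and unit-scales columns (zero-variance columns dropped), decomposes by
singular values, and fixes each component's sign so its
largest-magnitude loading is positive, making score plots reproducible.

# Imaging quantitation

Each nucleus's mean H3 intensity is divided by its mean DAPI intensity,
and germ-cell values are then divided by the mean ratio over all SGP
(somatic gonadal precursor) nuclei of the same gonad. Both steps are
ratios within one gonad, so the score is exactly invariant to any
per-gonad staining gain -- the property the per-gonad SGP reference
exists to provide. Sexes are compared within stages by a two-sided
Wilcoxon rank-sum test (the underlying report does not name its test;
rank-sum is chosen because intensity ratios are skewed and
group sizes are small), exact for groups of up to 8 and
normal-approximated with continuity correction above that.

# The synthetic-data generator

The generator emulates the statistical structure the analyses consume,
with planted parameters every downstream stage must recover:

* **Annotation** -- five chromosomes named like the fly arms (default
  8 Mb each plus a 1.6-Mb X), genes in equal slots with seeded jitter,
  2-6 kb long, alternating strands; one TSS +/- 250 bp peak per gene;
  optionally an i.i.d. uniform-base genome (compact preset only -- the
  default genome is never materialized as sequence).
* **Fragments** -- per cell Poisson fragment counts; chromosomes drawn
  proportional to length times diploid copy weight (autosomes 2 in both
  sexes; X: 2 in females, a boosted single copy `x_boost` in males, 1.5
  in unsexed clusters -- so a female X tallies like an autosome of its
  length); centers TSS-concentrated with probability `theta_tss`
  (normal, SD 75 bp) and uniform otherwise; lengths from a
  subnucleosomal/mononucleosomal normal mixture (means 75 and 200 bp,
  clamped to [20, 600] -- clamping, not resampling, so the extreme
  tails pile at the bounds, which no analysis here is sensitive to).
* **Counts** -- NB with lognormal per-copy baseline means and the same
  diploid multipliers; planted activation set (fold 4 in
  post-activation clusters), planted male-biased set with log-spaced
  folds, and the X compensation factor `x_factor` as the expression
  analogue of `x_boost`.
* **Nuclei** -- gonad-grouped intensities with per-gonad lognormal
  gain and planted germ/SGP ratios per sex and stage.

Defaults encode the study conditions the analyses target: 200 cells and
500 fragments per cell per cluster; female clusters TSS-focused
(`theta_tss` 0.6) with the first male post-activation stage
decondensed (0.1); partial dosage compensation `x_boost = x_factor =
1.6` (the value at which the expected X expression ratio, 2/1.6 =
1.25, sits inside the 1.12-1.31 range the real analyses report);
male H3 deficit at the early stage (germ/SGP ratio 0.7 versus 1.0)
reversing at later stages. One master seed derives fixed sub-seeds per
stream (annotation, fragments, counts, imaging), so streams regenerate
independently and byte-identically.

What the generator does **not** emulate -- and what passing tests
therefore do not show about real data: realistic sequence composition
(motif hits on the uniform genome are background hits), linked
chromatin and expression for the same cell (ATAC and RNA streams are
independent), doublets and ambient contamination, batch effects,
cluster-assignment error, and overdispersion beyond a single NB
dispersion parameter. The recovery suite demonstrates that the
estimators measure what they claim under a known model; it cannot
certify upstream processing of real libraries.

# Numerical choices and problem sizes

Pseudocounts: ESA $\alpha=1$; windowed-ratio 0.1; TSS-enrichment flank
0.1; expression-ratio floor 0.01; soma +0.01; motif-index 0.5; PWM
+0.01 per count cell. DE: dispersion floor $10^{-8}$, continuity 0.5
per group sum. Ties: documented lexicographic-last tie-breaks in both
ranking operations, so outputs are deterministic. Degenerate inputs:
zero-cut clusters give missing TSS scores and missing motif-index
entries rather than errors; empty barcode intersections, missing SGP
references and unknown cluster labels are hard errors naming the
offender.

The validation suite runs at deliberately modest sizes chosen so every
statistic is in its stable regime: 1.8-Mb genome with $10^5$ fragments
per cluster for ESA/TSS calibration (about 50 cuts per window, see the
Jensen-bias note above), the 35-Mb default genome with 200-300 cells
per cluster for dosage recovery, 2,000 genes at 100-200 cells per
group for DE calibration and planted-design recovery, and 30 gonads
per group for imaging recovery. All of it, plus the end-to-end
pipeline, completes in a few minutes on one CPU.

# Known limitations

* The ESA score is a ratio of small counts on sparse data; use medians
  over genes, never per-gene values at low depth.
* The TSS-enrichment recipe is one of several in circulation; compare
  scores only within one recipe.
* The motif-accessibility index is not a chromVAR deviation; absolute
  cross-motif comparisons are confounded by composition.
* The NB engine estimates one pooled dispersion per gene by moments;
  for designs with strong mean-variance structure or few cells, import
  an external DE table instead.
* The generator's independence assumptions (above) bound what the
  green suite can claim about real multiome libraries.
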