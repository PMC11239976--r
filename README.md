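# germchrom

Chromatin accessibility and expression statistics for single-cell
multiome studies of the *Drosophila* embryonic germline.

Right after zygotic genome activation, the early male germline passes
through a brief phase in which chromatin accessibility is spread along
gene bodies instead of being concentrated at promoters, and the
germline X chromosome is only partially dosage-compensated between XX
and XY cells. Quantifying those two phenomena takes a handful of
purpose-built statistics that general scATAC/scRNA toolkits do not
provide. `germchrom` implements them over standard file formats
(fragments TSV, GTF/BED, MTX, BED peaks, JASPAR/MEME PFMs, FASTA,
per-nucleus intensity tables):

* **ESA (end-to-start accessibility)** per cluster and gene: with
  $t_g$ and $e_g$ the Tn5 cut sites within ±250 bp of the TSS and the
  transcript 3′ end, $\mathrm{ESA}_{g} = (e_g + 1)/(t_g + 1)$ — near 1
  for dispersed chromatin, ≪ 1 for TSS-focused chromatin.
* **TSS enrichment** (flank-normalized cut density at the TSS) and
  **FRiP** (count-weighted fraction of fragments in peaks) per cell
  and cluster, plus fragment-size distributions.
* **Windowed accessibility indices** (cut sites per 1-Mb window per
  million cluster cut sites), female/male ratios per window and
  chromosome — expected 2 on the X without dosage compensation, 1 with
  full compensation — and per-chromosome tallies normalized to 2L.
* **Zygotic-activation gene selection**: an in-house negative-binomial
  Wald test (total-count size factors, moment dispersion, delta-method
  SE) with the fold > 2, *P* < 10⁻¹⁰ and total-count ≥ 10 rules, plus
  an import path for externally computed DE tables; sex expression
  ratios `(mean_F + 0.01)/(mean_M + 0.01)` by chromosome and stage;
  sex-biased gene ranking with deterministic tie-breaks.
* **Germline-to-soma transcription bias** (nuclear expression over
  run-on soma signal with the cutoff-1 and +0.01 pseudocount rules),
  top-150 gene selection, strand-aware 500-bp promoter FASTA export,
  log-odds PWM scanning, a length-normalized motif-site accessibility
  index, and PCA over the cluster × motif matrix.
* **Histone H3 imaging quantitation**: per-nucleus H3/DAPI ratios
  normalized to each gonad's SGP mean (exactly invariant to per-gonad
  staining gain), with Wilcoxon rank-sum comparisons between sexes.
* A fully seeded **synthetic-data generator** producing every input
  above with planted ground truth (TSS concentration, male-X boost,
  activation folds, X compensation factor, germ/SGP intensity ratios).

See `vignettes/germchrom-methods.Rmd` for the models, parameter
defaults and numerical conventions.

## Worked example

Simulate a compact multiome data set (five germline clusters: GC
before activation, then female/male stages 1-2, with the planted male
stage-1 decondensation and a male-X boost of 1.6), and compute the
core statistics:

```r
library(germchrom)

cfg <- sim_config_compact(seed = 7)
ann <- make_toy_annotation(cfg)
sim <- simulate_fragments(cfg, ann)
cuts <- build_cut_sites(sim$fragments, sim$clusters)

esa <- compute_esa(cuts, ann$genes)
ok <- !esa$windows_overlap
round(tapply(esa$esa[ok], esa$cluster[ok], median), 4)
#>   FGC1   FGC2     GC   MGC1   MGC2
#> 0.0346 0.0343 0.1096 0.3257 0.1086

tss_enrichment(cuts, ann$genes)$scores
#>   cluster score
#> 1    FGC1 51.03
#> 2    FGC2 54.41
#> 3      GC 15.72
#> 4    MGC1  4.81
#> 5    MGC2 16.09

wa <- windowed_accessibility(cuts, window = 2e5)
sex_ratio_windows(wa, "FGC1", "MGC1")$chromosomes
#>   chrom mean_ratio n_windows
#> 1    2L      0.965         2
#> 2    2R      0.984         2
#> 3    3L      0.984         2
#> 4    3R      0.972         2
#> 5     X      1.241         1
```

The numbers tell the planted story: the male stage-1 cluster (MGC1,
TSS concentration 0.1) has the highest median ESA (0.33 — reads spread
along gene bodies) and by far the lowest TSS enrichment, while the
female clusters (TSS concentration 0.6) are strongly
promoter-focused; autosomal female/male accessibility ratios sit near
1 while the X ratio (1.24) lies between the no-compensation
expectation of 2 and full compensation at 1, matching the planted
male-X boost of 1.6 (2/1.6 = 1.25).

The full pipeline — fragments, counts, bias ranking, promoters, motif
indices, imaging — runs end to end with
`run_pipeline("out/", config = sim_config_compact(seed = 7))`, writing
one TSV per table plus a `summary.json` that echoes every parameter.

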