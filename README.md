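# coexgalaxy

Differential gene co-expression analysis between two sample groups via a
disease-specific cutoff point.

## The problem

Differential *expression* analysis finds genes whose level changes between
conditions, but says nothing about the functional linkages among genes.
Differential *co-expression* analysis asks instead whether the correlation
structure of a gene panel — for example, the predicted targets of an
oncogenic miRNA cluster in leukemia patients versus healthy controls —
changes as a whole between two states. `coexgalaxy` implements a
distribution-based version of that comparison for anyone with a normalized
genes × samples matrix and a two-level group factor (microarray or
otherwise): rather than testing each gene pair separately, it compares the
two full distributions of pairwise co-expression levels and derives a single
data-driven cutoff that splits pairs into strong and weak co-expression
classes.

## The method

For genes *i*, *j* and group *g* ∈ {normal, disease}, the co-expression
level is the absolute Pearson correlation of the two expression profiles
within that group:

> C_g(i,j) = | cor(x_gi, x_gj) | ∈ [0, 1]

All g(g−1)/2 unordered pairs give two samples of co-expression levels, one
per group, summarized by their exceedance (survival) distributions
F_g(C) = Prob(C_g ≥ C).  The **maximum deviation**

> D = max over C of | F_d(C) − F_n(C) |

is the two-sample Kolmogorov–Smirnov statistic; the threshold where it is
attained is the **disease-specific cutoff point** C.  D is compared against
the asymptotic Smirnov critical value c(α)·√((n₁+n₂)/(n₁·n₂)) (c(0.05) =
1.36) to decide whether the two co-expression patterns differ structurally.
The cutoff then partitions every pair by (strong in normal?, strong in
disease?) into the four regions of the **co-expression galaxy**:
normal-specific strong, disease-specific strong, common strong, common weak
— where "strong" means C_g(i,j) ≥ C.

Companion stages cover the full workflow around that core:

* **Target consensus** — candidate miRNA target genes selected by
  "predicted in ≥ k of the databases covering the miRNA" voting (default
  k = 4) and unioned over the cluster members, then restricted to measured
  genes.
* **Enrichment** — DAVID-style EASE scores (one-tailed hypergeometric with
  the overlap jackknifed by one) with Benjamini–Hochberg FDR, dual
  threshold EASE < 0.05 and FDR < 0.05.
* **Pair mapping** — for each significant term, all annotated gene pairs
  are mapped onto the galaxy; the 2×2 table of specific categories
  (a = normal-specific strong, b = normal-specific weak, c =
  disease-specific strong, d = disease-specific weak; a = d and b = c by
  construction) is tested one-sided for an excess of normal-specific strong
  pairs (Fisher exact, Bonferroni-corrected over the tested terms).
* **Synthetic data** — a single-factor block model plants within-block
  correlation per group (`x = √ρ·z + √(1−ρ)·e`) with known ground truth, so
  every stage is testable end to end without external data.

## Worked example

Two planted 10-gene blocks — one that loses its co-expression in disease
(ρ 0.9 → 0.05), one stable (ρ 0.85) — plus 20 unstructured genes, 50
samples per group:

```r
library(coexgalaxy)
cfg <- synthetic_config(
  blocks = list(list(n_genes = 10, rho_normal = 0.9,  rho_disease = 0.05),
                list(n_genes = 10, rho_normal = 0.85, rho_disease = 0.85)),
  n_noise_genes = 20, n_normal_samples = 50, n_disease_samples = 50,
  seed = 17)
ds  <- generate_dataset(cfg)
tab <- pairwise_coexpression(ds$expression)
(cut <- detect_cutoff(tab))
#> Disease-specific cutoff detection
#>   maximum deviation D : 0.0962
#>   cutoff point C      : 0.8560
#>   critical D (alpha=0.05): 0.0689
#>   pairs (normal/disease): 780 / 780
#>   distributions differ : yes (D > D_critical)

cls <- classify_pairs(tab, cut$C)
galaxy_summary(cls)
#> Co-expression galaxy over 780 gene pairs
#>   normal_specific_strong         76  ( 9.744%)
#>   disease_specific_strong         1  ( 0.128%)
#>   common_strong                   9  ( 1.154%)
#>   common_weak                   694  (88.974%)
#>   strong/weak in normal : 85 / 695
#>   strong/weak in disease: 10 / 770
```

The deviation D = 0.096 exceeds the critical value 0.069, so the two
co-expression patterns differ structurally, and the galaxy is dominated by
normal-specific strong pairs — the planted decoupled block.  Mapping that
block's gene set onto the classification gives the 2×2 table and one-sided
Fisher test:

```r
ct <- contingency(annotated_pairs(ds$truth$gene_id[ds$truth$block_id %in% "B1"],
                                  rownames(ds$expression$values)), cls)
ct
#>  a  b  c  d
#> 43  0  0 43
fisher_one_sided(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]])
#> 1.51e-25
```

43 of the block's 45 pairs land in the normal-specific strong region and
none in the disease-specific one: the lost co-expression is recovered.

`run_pipeline()` chains all stages (reading TSV/GMT inputs, optional probe
collapsing and target-consensus restriction, cutoff detection,
classification, enrichment, mapping) and writes TSV/JSON/PNG artifacts plus
a run log; `inst/scripts/coexgalaxy.R` is a thin command-line wrapper with
`run`, `simulate` and `fisher` subcommands.

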