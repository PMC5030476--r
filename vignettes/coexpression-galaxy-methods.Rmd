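---
title: "Methods: differential co-expression via a disease-specific cutoff"
author: "coexgalaxy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression via a disease-specific cutoff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexgalaxy)
```

## The model

`coexgalaxy` compares the co-expression structure of a gene panel between
two groups of samples, labelled *normal* and *disease*.  The primitive is
the co-expression level of an unordered gene pair within one group: the
absolute Pearson correlation of the two expression profiles,
$C_g(i,j) = |\mathrm{cor}(x_{gi}, x_{gj})| \in [0,1]$.  Taking the absolute
value deliberately discards the sign — a strong negative linear
relationship is as much a functional linkage as a strong positive one —
and makes a scalar similarity out of the correlation.  Correlations are
always computed within one group, never pooled: pooling would confound
between-group mean shifts with co-expression.  (Whether variances are
normalized by $n$ or $n-1$ is irrelevant; the factor cancels in $r$.)

For $g$ analyzed genes, each group yields $g(g-1)/2$ co-expression levels.
The two collections are summarized by their *exceedance* (survival)
distributions $F_g(C) = \mathrm{Prob}(C_g \ge C)$, and compared through the
maximum deviation

$$D = \max_C\ |F_d(C) - F_n(C)|,$$

which is identical to the classical two-sample Kolmogorov–Smirnov
statistic (the supremum of a difference of survival curves equals the
supremum of the difference of the corresponding CDFs).  The threshold at
which $D$ is attained is the *disease-specific cutoff point* $C$: the
co-expression level at which the two patterns are most different.
Significance is judged against the asymptotic Smirnov critical value
$D_{crit} = c(\alpha)\sqrt{(n_1+n_2)/(n_1 n_2)}$ with the standard
coefficient table ($c(0.05) = 1.36$), with strict inequality
$D > D_{crit}$.

The cutoff then classifies every pair in each group as strongly
($C_g(i,j) \ge C$, boundary inclusive) or weakly co-expressed, and the two
indicators partition pairs into the four regions of the *co-expression
galaxy*: normal-specific strong, disease-specific strong, common strong,
common weak.  A pair strong only in the normal group is identically a pair
weak only in the disease group; the implementation derives all "specific"
categories from the joint truth table so these equivalences hold by
construction rather than by separate computation.

## Assumptions and their limits

* **Linear association.**  Pearson correlation only captures linear
  relationships; monotone nonlinear coupling is attenuated.  Alternative
  measures (Spearman, mutual information) are out of scope.
* **Independence of pairs.**  The Smirnov critical value treats the
  $g(g-1)/2$ pairs per group as independent observations, but pairs
  sharing a gene — and all pairs, through the shared samples — are
  dependent.  The decision is therefore approximate, and the approximation
  degrades as the number of pairs grows relative to the number of samples:
  with few samples per group, a single extreme sample shifts thousands of
  correlations coherently, inflating $D$ under the null far beyond what
  the independent-pairs critical value allows for.  The run log states
  this caveat explicitly.  A permutation null that respects the dependence
  (shuffling group labels) would be the principled alternative and is a
  documented non-goal.
* **At least 3 samples per group**, and nonzero within-group variance per
  gene; `drop_degenerate_genes()` removes (and logs) genes that are
  constant within either group or carry missing values, keeping the
  correlation formulas unambiguous.

## Numerical choices

* **Candidate grid.**  Both exceedance curves are step functions with
  jumps only at observed co-expression values, so the supremum over
  $[0,1]$ is attained on the sorted union of all observed values.  The
  search over that grid is exact — not a discretization — and the grid
  size is recorded in the run log.
* **Tie-break.**  When several thresholds attain $D$, the smallest is
  reported.  Any choice on the attaining set is defensible; smallest is
  deterministic and reproducible.
* **Boundary conventions.**  "Strong" is $\ge C$; the KS decision and both
  enrichment thresholds and the mapping decision are strict ($<$).
* **Exceedance counting** uses `findInterval()` on sorted values (count of
  strictly smaller elements), which is $O((n+m)\log(n+m))$ overall and
  exact for the tied values that absolute correlations never produce in
  practice but the code tolerates.
* **Full precision internally.**  All display rounding (3 decimals for
  p-values and percentages) happens at serialization only.  Corrected
  p-values are computed from full-precision p-values, then rounded for
  display — multiplying *rounded* p-values by the term count can differ in
  the last digit, a discrepancy we accept and document rather than
  imitate.

## Target consensus

Candidate miRNA targets are taken as genes predicted by at least
`min_databases` (default 4) of the prediction databases *covering that
miRNA*, then unioned over the cluster's members with per-gene provenance
retained.  Each database votes once per gene regardless of transcript
multiplicity.  Prediction tables are consumed as frozen local TSV files,
never fetched live: database contents drift, so reproducibility requires a
snapshot.  When a database lacks a miRNA entirely it simply does not vote
on it; requiring "4 of the 5 global databases" instead would silently
disenfranchise miRNAs with partial coverage.  Genes absent from the
expression matrix are dropped (with a logged count) before co-expression.

## Enrichment: EASE and FDR

Term enrichment of the candidate list uses the EASE score: the one-tailed
hypergeometric tail recomputed after removing one gene from the list–term
overlap, $P(X \ge k-1)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$.  It is
always $\ge$ the plain Fisher tail and equals 1 when the overlap is a
single gene, damping spurious enrichment of tiny overlaps.  Multiplicity is
controlled by Benjamini–Hochberg FDR (the conventional reading of an
enrichment tool's "FDR" column), and selection requires both EASE $< 0.05$
and FDR $< 0.05$.

The background universe defaults to the measured genes that appear in at
least one gene set (overridable to all measured genes or an explicit
list).  Web annotation services carry their own versioned internal
backgrounds, so locally recomputed EASE/FDR values are comparable in
method but not numerically interchangeable with a service's output — which
is why enrichment results depend on the supplied GMT and background, and
only the statistic itself is fixed.

## Pair mapping

For each significant term, the annotated genes among the analyzed panel are
paired in all combinations, mapped onto the galaxy, and counted into a 2×2
table over the *specific* categories only: $a$ = normal-specific strong,
$b$ = normal-specific weak, $c$ = disease-specific strong, $d$ =
disease-specific weak.  Because the specific categories are two views of
the same pairs, $a = d$ and $b = c$ on every input (asserted in tests, not
assumed), and common-strong/common-weak pairs contribute to no cell.  The
one-sided Fisher exact test asks whether normal-specific strong pairs are
over-represented (upper tail of the hypergeometric with fixed margins); the
direction is fixed rather than configurable to avoid silent sign errors,
and both cell counts and p-values are emitted so the opposite tail is
recomputable.  Correction is Bonferroni — multiplication by the number of
terms that actually produced a testable table, not the ontology size — with
significance at corrected $p < 0.05$.  Terms whose annotated pairs are all
common yield no table; they are reported with `NA` and excluded from the
multiplier.

## The synthetic-data generator

`generate_dataset()` plants a single-factor block model: within each group
independently, gene $x$ of block $b$ is $\sqrt{\rho_{bg}}\, z +
\sqrt{1-\rho_{bg}}\, e$ with a per-sample latent factor $z$ and independent
Gaussian noise $e$, so two same-block genes have population correlation
exactly $\rho_{bg}$; noise genes are pure $e$.  This guarantees the target
correlation with $O(\text{genes})$ sampling and models disease-lost
co-expression simply as $\rho_d = 0$.  Defaults mirror a small
case-control microarray design (8 normal, 9 disease samples).  All
randomness flows from one mandatory seed; identical configurations are
bit-identical.

What the generator does *not* emulate: probe-level effects,
heteroscedastic or non-Gaussian noise, correlated blocks, negative planted
correlations (the absolute value makes them equivalent to positive ones),
and realistic gene-set overlap structure.  Passing tests on this generator
therefore demonstrate the statistical machinery — not robustness to
microarray artifacts.

## Problem sizes used by the test suite

Sample-correlation noise dominates at small $n$: $|r|$ at 8 samples has
enormous variance, so per-pair category recovery at the default sample
sizes is intrinsically noisy, and tests at that scale assert only the
*direction* of the deviation (normal-enriched structure implies
$F_n \ge F_d$ at the cutoff).  Quantitative recovery is checked at 50
samples per group — two planted decoupled blocks (ρ 0.9 → 0.0) among 40
genes, 20 replicates, requiring a significant $D$ every time and ≥ 90 % of
planted within-block categories recovered at the detected cutoff — and
null calibration at the same panel and sample sizes with all ρ = 0 over
100 replicates, requiring the deviation to stay below the critical value
in ≥ 90 % of them (the pair-dependence caveat above is why this bound is
not the nominal 95 %).  The acceptance script scales the full pipeline to
a 488-gene panel with 288 consensus candidates — hence 41,328 gene pairs —
at the default 8 + 9 samples, which exercises every stage at a realistic
study scale in seconds.

## Known limitations

* The KS-style decision ignores pair dependence (see above); at many
  pairs and few samples it is anticonservative.
* A single global cutoff summarizes the whole deviation curve; localized
  differences away from the maximum are not captured.
* Identifier matching is exact string equality; harmonizing probe, target
  and annotation namespaces is the caller's responsibility.
* Enrichment values depend on the supplied annotation snapshot and
  background; they are not interchangeable with any web service's output.
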