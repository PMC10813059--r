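---
title: "Models and methods behind proteosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proteosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteosig)
```

# The study design and what the pipeline estimates

`proteosig` analyzes label-free proteomic and phosphoproteomic data from a
genotype (WT/TG) × treatment (CTRL/OE) factorial profiled in female and
male animals. Two contrasts carry the science, each computed *within* a
sex by subsetting samples (the design is stratified, not modelled jointly;
no sex×genotype interaction terms are fitted):

* the disease contrast `5xFADvsWT` (TG-CTRL vs WT-CTRL), and
* the treatment contrast `5xFAD-DUSP4vs5xFAD` (TG-OE vs TG-CTRL).

The central phenomenon of interest is **reversal**: features pushed up (or
down) by the disease genotype and pushed back in the opposite direction by
the treatment. Everything downstream — signed signature overlaps,
reversal fractions, cell-type and module projections, site-set scores,
and the target-centric network — interrogates that structure.

# Quality control and preprocessing

**Protein tables.** Contaminant, reverse-decoy and only-identified-by-site
rows are removed, then proteins observed in more than half of the samples
are retained. "More than half" is read strictly (`observed > N/2`): a
protein observed in exactly half of 46 samples is dropped. The coverage
filter is applied once, globally, across all samples — not per sex or per
group — so all contrasts share one feature universe, which is also the
background used by every enrichment test (overlap universes must match the
tested feature space).

**Phosphosite tables.** Flagged rows and rows lacking a gene name or an
integer position are removed; remaining rows are keyed as
`GENE;<S|T|Y><position>` (uppercase gene, 1-based position, e.g.
`APP;S441`) and rows sharing a key — including MaxQuant multiplicity
rows — are collapsed by **summing** raw intensities, the additive-abundance
convention (a median collapse is available via
`qc_filter_sites(summarize = "median")`). Sites never observed in any
sample are also dropped: they carry no quantitative information and cannot
be imputed.

**Proteome preprocessing** is log2 → kNN imputation → median centering.
The kNN imputer follows the classic microarray algorithm and its defaults
(k = 10, rowmax = 0.5, colmax = 0.8): a missing cell is filled with the
mean of the k nearest rows (Euclidean distance over co-observed columns,
normalized by their number) that are observed at that column; rows missing
beyond `rowmax` fall back to column means. Observed values are never
modified — a property the test suite asserts for both imputers.

**Phosphoproteome preprocessing** is quantile normalization of raw
intensities (delegated to `limma::normalizeQuantiles`, ties averaged,
missing entries ignored and preserved) followed by low-rank truncated-SVD
completion, analyzed on the log2 scale. One numerical choice deserves
emphasis: the SVD completion itself runs on log2-transformed values. Raw
LFQ intensities span several orders of magnitude, and the alternating
truncated-SVD iteration on the raw scale converges extremely slowly and
can produce negative imputations; on the log2 scale it converges in tens
of iterations. Because log2 is monotone and observed entries are
untouched, this changes only the geometry of the completion, not the data.
Defaults: rank `min(5, samples − 1)`, tolerance 1e-4 on the relative
Frobenius change of the imputed entries, 200 iterations; non-convergence
returns the best iterate with a warning. An alternative `log_first` order
(quantile-normalize the log2 values) is available.

# The moderated t-statistic

For a two-group contrast with `nA`, `nB` samples, each feature has
`log2FC = mean(A) − mean(B)` and pooled within-group variance `s²` on
`d = nA + nB − 2` degrees of freedom. The empirical-Bayes hierarchical
model places a scaled inverse-χ² prior `(s₀², d₀)` on the true variances;
the closed-form moment estimator matches the mean and variance of
`log s²` to the implied scaled-F marginal, inverting the trigamma function
by Newton iteration. The posterior variance is the convex combination

```
s̃²  =  (d₀·s₀² + d·s²) / (d₀ + d)
```

and `t = log2FC / sqrt(s̃²·(1/nA + 1/nB))` is referred to a t distribution
on `d + d₀` degrees of freedom (capped at the pooled residual df of the
matrix). Degenerate inputs follow the reference implementation's
conventions: zero sample variances are offset to `1e-5 ×` the median
variance for prior estimation, and when the between-feature spread of
`log s²` does not exceed its sampling component the prior df is infinite
and every posterior variance equals the mean sample variance — in which
case the moderated t coincides with the ordinary pooled t feature by
feature. The test suite verifies the whole closed form against both an
independently coded oracle (root-bracketing instead of Newton) and
`limma::eBayes`, to 1e-8 and 1e-10 respectively.

Signatures are called at strict thresholds: `p < α` (nominal by default,
BH-adjusted on request) and a non-zero fold change; `p = α` exactly, or a
significant feature with `log2FC = 0`, is not called.

# Signed overlaps and the reversal fraction

For two signed signatures on a common background of `N` features, each of
the four signed pairs (up·up, up·down, down·up, down·down) is scored by
`FE = k·N/(m·n)` and the upper-tail hypergeometric `P(X ≥ k)`, BH-adjusted
across the four tests. Empty sets yield `k = 0` with undefined FE (`NA`).
The reversal fraction is pure set arithmetic:
`|(fad_up ∩ oe_down) ∪ (fad_down ∩ oe_up)| / (|fad_up| + |fad_down|)`.
Both statistics are exact — the suite checks the hypergeometric p against
exhaustive enumeration of all draws for backgrounds up to 20.

# Site-set enrichment scores

Sample-wise scoring follows the kernel-ECDF random-walk construction.
Each feature is transformed to `z_ij = mean_k Φ((x_ij − x_ik)/h_i)` with
Gaussian bandwidth `h_i = sd_i/4`, making scores exactly invariant to
per-feature positive affine transforms. Per sample, features are ranked
by `z` descending and weighted by the symmetric rank statistic
`|P/2 − rank|` (tau = 1); the walk adds normalized in-set increments and
subtracts `1/(P − m)` out of set; the enrichment score is the sum of the
largest positive and largest negative deviations ("maxdiff"), bounded in
[−1, 1]. These are the defaults of the cited algorithm family; the
variant is pinned here because the upstream description names only the
algorithm, not its options. Signed site collections (suffixes `;u`/`;d`
in GMT) reflect negatively-annotated sites (`z → 1 − z`) before ranking;
with all-positive annotations this reduces exactly to direction-naive
scoring. Constant features are excluded with a warning; sets matching
fewer than `min_overlap = 5` sites are dropped; a set covering every
feature is an error (the out-of-set step is undefined). Differential
analysis of the score matrix reuses the moderated t.

# Ranked enrichment and module projection

Ranked (GSEA-style) enrichment uses hit weights `|score|^tau` (or, in the
documented `rank` mode, symmetric rank weights, which makes the statistic
invariant to monotone score transforms) and an extreme-deviation ES. The
null re-draws set positions: exhaustively over all `choose(P, m)`
placements when that is at most 20,000, otherwise with 1,999 seeded random
draws; NES divides ES by the mean |null ES| of matching sign. Module
projection maps mouse symbols to human by uppercasing (an explicit
two-column mapping overrides this — the default is deliberately simple and
covers the large majority of one-to-one orthologs), runs
overrepresentation per signature × module, and reports `−log10(q)` with
Top10/Top20/Top30 rank classes.

# Consensus network and signaling map

Per dataset, every gene is correlated with the target (Pearson by default
on log-scale expression; Spearman by flag), `p` from the t transform,
BH within dataset — matching a per-dataset discovery rule. Directional
voting counts datasets with `q < 0.05` split by correlation sign; a gene
significant in both directions across datasets votes both ways, and a tie
(`n_pos = n_neg`) gives net sign 0 and exclusion — the conflict rule is a
package decision since the source procedure does not state one. The
network at frequency threshold `n` keeps genes whose dominant count
reaches `n` with a non-tied sign, so network size is non-increasing in
`n` (asserted across n = 1..k); nodes are annotated
female_specific/male_specific/shared/unaffected by the sex-specific
treatment-contrast signatures. All thresholds are emitted; reports
default to n = 4, the midpoint of an 8-dataset panel.

The signaling map tests the positive and negative neighbourhoods
separately against each curated disease set with a one-sided Fisher exact
test, BH pooled across the full (set × sign) family by default (per-sign
families by flag), keeps FDR < 0.05 and scores `−log10(FDR)` — so score
> 1.301 and retention are the same statement. Sets kept for both signs
are classed `both`.

# The synthetic generator: what it emulates, and what it does not

The generator reproduces the statistical skeleton the analysis assumes:

* the 46-sample two-sex factorial (7/7/5/5 female and 4/5/7/6 male per
  group) as the default design;
* log2 baselines ~ Normal(25, 2), mimicking LFQ intensity ranges;
* genotype effects in a `de_frac` of features (default 0.2) with log2
  magnitudes ~ |Normal(1, 0.3)| and random signs; a `reversal_frac`
  (default 0.25) of those receive the exactly opposing effect in treated
  TG samples;
* a designated `TARGET` feature overexpressed `22.8`-fold in treated
  samples of both genotypes;
* intensity-dependent missingness `P(missing) = logistic(−steepness·(x −
  q20))` against the per-sample 20th percentile, plus uniform MCAR
  (defaults 0.8 and 0.02 — the source reports no missingness rates, so
  these are tunable, documented choices that put post-QC retention near
  80%, matching the reported 3578/4459);
* MaxQuant-dialect decoy rows ("+" flags) so ingest filters are exercised
  end to end;
* ~3 phosphosites per parent protein (`1 + Poisson(mean − 1)`, default
  mean 3.2 giving ≈ 7100 sites over 2222 parents), S:T:Y residues at
  86:12:2, positions uniform in 1..2000, effects inheriting the parent
  direction with positive multiplicative jitter;
* optional cell-type labels on directional features so marker-enrichment
  recovery can be scored;
* multi-cohort panels in which designated correlates track the target at
  ±rho in exactly `support` of k datasets.

It does **not** emulate peptide-level quantification, shared-peptide
protein inference, retention-time or batch structure, correlated
co-regulation between features, or heavy-tailed noise. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under the generative model the analysis itself assumes — not
that the pipeline is robust to every pathology of real LC-MS/MS data.

# Problem sizes and expectations in the verification suite

The shipped checks run at desk scale, chosen to make Monte-Carlo
tolerances meaningful: calibration uses 20 null simulations of 2,000
features at 6 vs 6 (pooled type-I error 0.05 ± 0.01); recovery uses
planted effects of 1.0 log2 at noise sd 0.5 (sensitivity ≥ 0.9, reversal
0.25 recovered within ±0.05; these recovery checks run without
missingness so the stated power target refers to the statistical test
itself rather than to imputation); network recovery uses 100 seeded
8-dataset panels (rho 0.8, support 6, 50 samples, threshold 5). The
planted-shift check for differential site-set scores uses a +0.4 ES shift
against noise sd 0.15, a typical spread for sample-wise enrichment scores
on [−1, 1]. `scripts/acceptance.R` recomputes all of these from scratch
under a caller-supplied seed.

# Known limitations

* Two-group moderated t only; no covariates, trends, robust fits or
  interaction models.
* GO semantics are whatever flat GMT collections the user supplies; no
  DAG traversal or redundancy trimming.
* Module *detection* is out of scope; module membership is consumed as
  input.
* Exact multi-set (> 2) intersection distributions are not computed; the
  four signed pairwise tests carry the overlap analysis.
* The default mouse→human mapping is case-based; paralog-ambiguous
  families need an explicit mapping table.
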