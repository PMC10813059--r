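# proteosig

Sex-stratified differential proteomics and phosphoproteomics for factorial
mouse designs, with signature-reversal statistics, phosphosite-set
enrichment, and target-centric consensus co-expression networks.

## What this package is for

Label-free (LFQ) proteomic and phosphoproteomic studies of disease models
frequently use a genotype × treatment factorial — e.g. an amyloidopathy
transgene (TG vs WT) crossed with a candidate-gene overexpression arm
(OE vs CTRL) — profiled separately in female and male animals. The
scientific questions are then:

1. Which proteins/phosphosites respond to the disease genotype, per sex?
2. Which of those changes does the treatment *reverse*?
3. Which cell types, kinase site-sets and co-expression modules carry the
   signal?
4. Which genes track the target across independent human cohorts, and which
   disease pathways do those genes implicate?

`proteosig` implements this analysis end to end, plus a synthetic-data
generator with planted ground truth so every stage is verifiable without
access to deposited animal data.

## Methods at a glance

* **Ingest/QC** — MaxQuant-dialect `proteinGroups` and `Phospho(STY)Sites`
  tables; removes contaminant/reverse/site-only rows; keeps proteins
  observed in more than half of samples; summarizes phosphosite rows by
  canonical `GENE;S|T|Y<pos>` key.
* **Preprocessing** — proteome: log2 → kNN imputation → median centering;
  phosphoproteome: quantile normalization → low-rank (truncated-SVD)
  completion → log2 scale.
* **Differential analysis** — empirical-Bayes moderated t per pairwise
  contrast within each sex. With pooled per-feature variance s² on d
  degrees of freedom and a scaled inverse-χ² prior (s₀², d₀) estimated by
  closed-form moment matching (trigamma inversion),

      s̃² = (d₀·s₀² + d·s²)/(d₀ + d),   t = Δmean / √(s̃²(1/n_A + 1/n_B)),

  with p-values on d + d₀ degrees of freedom and BH q-values. Signatures
  are called at nominal p < 0.05 by default.
* **Reversal statistics** — signed overlaps of up/down signature pairs with
  hypergeometric tests and fold enrichment FE = k·N/(m·n); the reversal
  fraction is |(disease-up ∩ treatment-down) ∪ (disease-down ∩
  treatment-up)| / |disease signature|.
* **Site-set enrichment** — sample-wise kernel-ECDF random-walk enrichment
  scores (GSVA-style) over signed phosphosite signature collections,
  followed by moderated-t differential scoring.
* **Gene-set analysis** — hypergeometric overrepresentation, ranked
  (GSEA-style) enrichment with a permutation/exhaustive null, and
  projection onto ranked co-expression modules across species.
* **Consensus network** — per-dataset correlations with a target gene
  (FDR < 0.05), directional voting across k cohorts, frequency-thresholded
  target-centric networks with sex-specific signature annotation.
* **Signaling map** — one-sided Fisher-exact enrichment of the positive and
  negative network neighbourhoods against a curated disease gene-set
  collection, scored as −log10(FDR) and filtered at FDR < 0.05.

## Worked example

```r
library(proteosig)

design <- make_design()                      # 46-sample two-sex factorial
sim <- simulate_proteome(design, n_features = 2000,
                         de_frac = 0.2, reversal_frac = 0.25, seed = 1)
qc  <- qc_filter_proteins(sim$table)
mat <- preprocess_proteome(qc)               # log2 -> kNN -> median center

res <- run_contrasts(mat, design)            # both contrasts x both sexes
fad <- res$female[["5xFADvsWT"]]$signature
oe  <- res$female[["5xFAD-DUSP4vs5xFAD"]]$signature
reversal_fraction(fad$up, fad$down, oe$up, oe$down)$fraction
#> [1] 0.1980198
signed_overlap(fad$up, fad$down, oe$up, oe$down, nrow(mat))[, 1:5]
#>        pair  k        FE            p            q
#> 1     up_up  5 0.7975944 7.683693e-01 9.726747e-01
#> 2   up_down 29 4.5599611 7.631238e-14 1.526248e-13
#> 3   down_up 31 4.6597919 3.329664e-15 1.331866e-14
#> 4 down_down  3 0.4445055 9.726747e-01 9.726747e-01
```

The disease signature overlaps the treatment signature almost exclusively
in the *opposite* direction (FE ≈ 4.6, q < 1e-13): the planted treatment
effects reverse a quarter of the genotype effects, and the pipeline
recovers that structure through the full QC/imputation path (the estimate
0.198 sits below the planted 0.25 because power at these sample sizes is
below 1). On the planted `TARGET` feature the treatment contrast here
recovers a 12.6-fold change — attenuated from the simulated 22.8-fold by
intensity-dependent missingness and imputation; without missingness the
recovery is essentially exact (see the acceptance output below).

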