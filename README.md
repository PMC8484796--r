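# m6ascape

Molecular-subtype discovery and prognostic scoring for tumor transcriptome
cohorts based on N6-methyladenosine (m6A) regulator expression.

m6A is the most abundant reversible mRNA methylation mark; it is deposited by
writer methyltransferases (METTL3, METTL14, WTAP, KIAA1429, RBM15/15B,
ZC3H13, CBLL1), removed by erasers (FTO, ALKBH5) and interpreted by reader
proteins (YTHDC1/2, YTHDF1-3, HNRNPC, HNRNPA2B1, IGF2BP1, FMR1, LRPPRC,
ELAVL1). `m6ascape` takes gene x sample expression matrices plus clinical
survival tables and, over this 21-gene regulator panel:

1. **merges cohorts** with empirical-Bayes location/scale batch adjustment
   (ComBat-style parametric shrinkage);
2. discovers **m6A modification patterns** by resampling consensus
   clustering (Ward/Euclidean base clusterer, consensus matrix
   `M_ij = co-cluster / co-sample`, PAC-based choice of k);
3. scores **immune-cell and pathway activity** per sample (ssGSEA
   running-ECDF enrichment, a GSVA-style kernel-CDF variant, hypergeometric
   over-representation);
4. derives the **m6A score**: moderated-t differential expression between
   patterns (empirical-Bayes variance shrinkage), random-forest redundancy
   removal (out-of-bag mean decrease in accuracy), a univariate Cox survival
   filter, a partition of the surviving genes by coefficient sign into sets
   X (risk) and Y (protective), and

   ```
   m6Ascore_j = scale( Σ_{g∈X} e_gj − Σ_{g∈Y} e_gj )
   ```

   followed by a median split into high/low score groups;
5. runs the **downstream statistics**: Cox proportional hazards (Efron
   ties), Kaplan-Meier/log-rank, Wilcoxon rank-sum, Fisher exact,
   Benjamini-Hochberg FDR, correlation and ROC/AUC, plus regulator-level
   mutation/CNV frequency summaries and a prognosis-annotated correlation
   network.

A fully deterministic synthetic-cohort generator (`sim_config()` /
`simulate_cohort()`) plants known clusters, batch effects, proportional-
hazards survival and mutation frequencies, so the entire pipeline is
testable without any external download.

## Worked example

The bundled demo configuration simulates a two-cohort study (200 samples,
two planted modification patterns at 2 SD separation on the regulator
panel, batch effects, cluster hazard ratio 2, 30% censoring) and runs the
full pipeline:

```r
library(m6ascape)
cfg <- read_pipeline_config(
  system.file("extdata", "demo_config.yaml", package = "m6ascape"),
  out_dir = "demo_out")
res <- run_pipeline(cfg)
read.delim(file.path("demo_out", "summary_stats.tsv"))
#>                  quantity        value
#> 1      logrank_p_clusters 5.341343e-05
#> 2 logrank_p_score_groups  6.688612e-05
#> 3      cox_hr_high_vs_low 1.969885e+00
#> 4              selected_k 2.000000e+00
```

The run recovers the two planted patterns (`selected_k` = 2, PAC = 0 at
k = 2), the clusters differ in overall survival (log-rank p ≈ 5e-5), and
the derived m6A score's high/low groups reproduce the planted hazard ratio
of 2 (Cox HR ≈ 1.97, log-rank p ≈ 7e-5). `demo_out/` also contains the
corrected expression matrix, cluster labels, PCA coordinates, the DE table,
random-forest importances, the signature model (X/Y gene sets, scale
parameters, median) and per-sample scores.

Worked single-step examples:

```r
# published univariate Cox table for the 21 regulators
cox <- read_cox_table()
summarize_cox_table(cox, alpha = 0.05)$significant$gene_id
#> [1] "ALKBH5"   "KIAA1429" "ELAVL1"

# ssGSEA scores for an immune signature collection (GMT)
scores <- score_gene_sets(expr, read_gmt("immune24.gmt"), method = "ssgsea")
```

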