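# mirvuln

Network-vulnerability discovery of chemoresistance miRNA biomarkers.

Platinum-based chemotherapy is the backbone of treatment for high-grade
serous ovarian cancer, and identifying which tumours will resist it is a
central clinical problem.  `mirvuln` implements, for computational
biologists working with paired miRNA/mRNA expression cohorts, a
knowledge-guided network pipeline built on the *single-line regulation*
idea: in a bipartite miRNA→mRNA regulatory network, an mRNA controlled by
exactly one miRNA is a structurally vulnerable point, and a miRNA that
monopolises many such exclusive targets — a high **NSR** (number of
single-line regulations) — has strong independent regulatory power.
Combining that structural signal with differential expression and a
resistance-gene knowledge filter yields candidate biomarkers of the
resistant phenotype.

## The method in brief

Given log2 expression matrices for miRNAs and mRNAs across
platinum-sensitive and platinum-resistant samples, a reference miRNA→mRNA
edge list, and a list of resistance-associated genes:

1. **Differential expression** — per-feature moderated t with
   empirical-Bayes variance shrinkage
   ($\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, prior estimated by
   closed-form moment matching of $\log s^2$), BH-FDR adjustment, and the
   filter FC > 1.5 or < 0.67 with adjusted p < 0.05.
2. **Condition-specific subnetwork** — reference edges whose both endpoints
   are differentially expressed; topology (degree, betweenness, closeness,
   top-10% hub/bottleneck sets) and a log–log power-law fit of the degree
   distribution.
3. **NSR statistics** — per-miRNA single-line counts; significance from a
   degree-preserving edge-rewiring permutation null
   ($p = (1+\#\{NSR^\ast \ge NSR\})/(1+n_{perm})$, exact enumeration for
   tiny networks); NPRG = number of resistance-annotated targets.
4. **Selection** — biomarkers are miRNAs with $p_{NSR} < 0.01$ **and**
   NPRG ≥ 1.
5. **Evaluation** — ROC/AUC (resistant = positive class, Mann–Whitney
   convention) and Kaplan–Meier + log-rank survival comparison after
   upper-quartile expression stratification, for PFS and OS.

A seeded synthetic-study generator (`simulate_study()`) emulates the
cohort structure (31 sensitive vs 37 resistant samples, scale-free
bipartite network, planted differential features, planted biomarkers with
excess exclusive targets, biomarker-dependent exponential survival) and
records the ground truth, so the whole pipeline can be exercised and
calibrated without the controlled-access patient data.  See the methods
vignette (`vignettes/network-vulnerability-methods.Rmd`) for the models,
parameter rationale, and limitations.

## Worked example

```r
library(mirvuln)

report <- run_biomarker_pipeline(seed = 3)
report
#> Biomarker discovery report
#>   DE: 20/50 miRNAs, 93/189 mRNAs
#>   Subnetwork: 165 edges, 20 miRNAs, 80 mRNAs
#>   Degree distribution R^2 = 0.725
#>   Selected biomarkers (4): miR-037, miR-048, miR-010, miR-029
#>   Planted recovery: recall = 1.00, false selections = 0

dplyr::filter(report$nsr, selected)
#> # A tibble: 4 × 7
#>   mirna   degree   nsr    p_nsr method  nprg selected
#>   <chr>    <int> <int>    <dbl> <chr>  <int> <lgl>
#> 1 miR-037     17    12 0.00300  rewire     2 TRUE
#> 2 miR-048     15    11 0.000999 rewire     1 TRUE
#> 3 miR-010     12    10 0.000999 rewire     1 TRUE
#> 4 miR-029     11    10 0.000999 rewire     1 TRUE

report$evaluation
#> # A tibble: 4 × 5
#>   mirna     auc split_threshold logrank_p_pfs logrank_p_os
#>   <chr>   <dbl>           <dbl>         <dbl>        <dbl>
#> 1 miR-037 0.928            8.70      2.66e- 8     2.18e- 9
#> 2 miR-048 0.871            9.61      6.26e- 9     2.09e- 9
#> 3 miR-010 0.907           10.2       1.36e- 5     2.05e- 5
#> 4 miR-029 0.938           10.8       1.35e-13     2.87e-12
```

Reading the output: 20 of 50 miRNAs and 93 of 189 mRNAs pass the
differential-expression filter; their 165 connecting reference edges form
the condition-specific subnetwork, whose degree distribution is
heavy-tailed (log–log $R^2 = 0.73$).  Four miRNAs combine a significantly
high single-line count (`p_nsr < 0.01` under the degree-preserving null —
e.g. miR-037 holds 12 exclusive targets among its 17) with at least one
resistance-annotated target (`nprg ≥ 1`), and exactly these four were the
planted ground-truth biomarkers (recall 1.00, no false selections).  Each
selected biomarker separates resistant from sensitive samples (AUC
0.87–0.94) and stratifies both progression-free and overall survival at
its upper-quartile expression threshold (log-rank p ≪ 0.05).  The group
comparison `report$nsr_comparison` confirms the selected miRNAs' NSR
values are high relative to the subnetwork (rank-sum p = 0.0059) and the
full reference network (p = 0.00023).

Every stage is also available piecemeal (`moderated_t()`,
`extract_subnetwork()`, `network_topology()`, `compute_nsr()`,
`nsr_significance()`, `roc_auc()`, `km_logrank()`, `ora()`, …), takes
tibbles, and returns tibbles or tidy-able objects with `tidy()`,
`glance()` and `autoplot()` methods.  File-based workflows use the
`read_*`/`write_*` functions (TSV expression/edge lists/clinical tables,
GMT gene sets, YAML config, JSON reports), and
`run_biomarker_pipeline(output_dir = …)` persists every intermediate.

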