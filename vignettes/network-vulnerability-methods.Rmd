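---
title: "Network-vulnerability discovery of chemoresistance miRNA biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-vulnerability discovery of chemoresistance miRNA biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvuln)
```

## The scientific problem

High-grade serous ovarian cancer is typically treated with platinum-based
chemotherapy, and a substantial fraction of patients relapse with
platinum-resistant disease.  miRNAs are attractive resistance biomarkers:
they are stable, measurable, and sit upstream of large regulatory programs.
`mirvuln` implements a network-vulnerability strategy for finding them.  The
premise is structural: in a bipartite miRNA→mRNA regulatory network, an mRNA
regulated by exactly one miRNA (*single-line regulation*) is a vulnerable
point — losing that one regulator deregulates the target completely.  A
miRNA that monopolises many single-line targets therefore has strong
independent regulatory ability, and if it is also differentially expressed
between platinum-sensitive and platinum-resistant tumours and regulates
known resistance genes, it is a credible driver and biomarker of the
resistant phenotype.

## The pipeline

The stages, each an exported function, are composed by
`run_biomarker_pipeline()`:

1. **Differential expression** (`moderated_t()`, `filter_de()`): two-group
   empirical-Bayes moderated t per feature, BH adjustment, and the
   fold-change/FDR filter.
2. **Subnetwork extraction** (`extract_subnetwork()`): edges of a reference
   miRNA→mRNA network whose *both* endpoints are differentially expressed.
3. **Topology** (`network_topology()`, `fit_degree_powerlaw()`): degree,
   betweenness, closeness; hub and bottleneck sets; scale-freeness
   diagnostic.
4. **Vulnerability statistics** (`compute_nsr()`, `nsr_significance()`,
   `count_nprg()`, `select_biomarkers()`): per-miRNA single-line counts, a
   degree-preserving permutation null, the resistance-gene knowledge
   filter, and the two-criterion selection.
5. **Evaluation** (`roc_auc()`, `km_logrank()`, `evaluate_biomarkers()`):
   discrimination of resistant vs sensitive samples and upper-quartile
   survival stratification.
6. **Enrichment** (`ora()`): generic hypergeometric over-representation of
   biomarker targets in user-supplied gene sets.

## Models and estimators

### Moderated differential expression

For feature $g$ with group means $\bar x_{R,g}, \bar x_{S,g}$ (log2 scale)
and pooled residual variance $s_g^2$ on $d = n_S + n_R - 2$ degrees of
freedom, the moderated statistic is

$$t_g = \frac{\bar x_{R,g} - \bar x_{S,g}}{\tilde s_g\sqrt{1/n_S + 1/n_R}},
\qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d\,s_g^2}{d_0 + d},$$

with p-values from a t distribution on $d_0 + d$ df.  The prior
$(d_0, s_0^2)$ is estimated by the closed-form moment match of
$\log s_g^2$ to a scaled-F model: with
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$,
$d_0$ solves $\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)$ (trigamma
inverse by Newton iteration) and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$.  When the excess
variance is non-positive the prior df is infinite and every variance
shrinks fully to $s_0^2$; `d0 = 0` can be forced to recover the ordinary
pooled t.  The test suite cross-checks the whole fit — prior, statistics
and p-values — against `limma::eBayes` on a heterogeneous-variance
fixture.

Fold change is $2^{\bar x_R - \bar x_S}$ (resistant in the numerator).  A
feature is differentially expressed when $\mathrm{FC} > 1.5$ or
$\mathrm{FC} < 0.67$ *and* BH-adjusted $p < 0.05$; all threshold
comparisons in the package are strict, matching the convention that a value
exactly at a published cutoff does not pass it.

The package takes log2-scale matrices as given and performs no
normalisation: how raw counts or intensities were normalised upstream is
outside its scope and must be handled before import.

### The NSR statistic and its null

On the extracted subnetwork, the NSR of miRNA $m$ is the number of its
targets with in-degree exactly 1.  Significance is assessed against a
*degree-preserving rewiring null*: double-edge swaps
$(m_1g_1, m_2g_2) \to (m_1g_2, m_2g_1)$ that reject duplicate edges, so
every permuted network is simple, bipartite, and has both degree sequences
identical to the observed network.  Each of the `n_perm = 1000`
permutations applies 10 accepted swaps per edge (stationarity of the swap
chain is the uniform distribution over simple bipartite graphs with the
fixed degree sequences; empirically the p-values are stable from ~10
swaps/edge upward).  The one-sided p-value uses add-one smoothing,
$p = (1 + \#\{\mathrm{NSR}^\ast \ge \mathrm{NSR}\})/(1 + n_{perm})$, so it
is never 0 and a miRNA with NSR 0 gets $p = 1$.  For networks with at most
10 edges the permutation is replaced by exact enumeration of all gene-stub
assignments forming simple graphs; every such graph is realized by the same
number of assignments, so the enumeration is uniform over the same null and
the test verifies the swap chain against it.

Because both degree sequences are preserved, the *set* of single-line mRNAs
is invariant under the null; what varies is which miRNA captures them.  The
null for a given miRNA is thus close to (but, due to the simplicity
constraint on high-degree nodes, noticeably wider than) a hypergeometric
draw of its targets from the stub pool.  This is why the permutation route
was chosen over any closed form.

The original method description names a Wilcoxon signed-rank test for this
step without stating what is paired; since that is not recoverable, the
package documents two well-defined alternatives: the rewiring null
(default, recommended) and a rank-based variant (`method = "rank"`)
comparing a miRNA's per-target single-line indicators against the
network-wide single-line rate.  Neither claims to replicate the closed
tool's exact p-values; distribution-level comparisons
(`compare_nsr_groups()`) use the standard one-sided Mann–Whitney rank-sum
test (exact when tie-free and $n_a n_b \le 10^4$).

### Selection and evaluation

A miRNA is selected as a biomarker iff (1) its NSR is significantly high
($p < 0.01$, strict) and (2) it regulates at least one gene from the
user-supplied resistance-gene list within the subnetwork (NPRG $\ge 1$).
Selection is monotone in the gene list: adding a gene can never deselect a
miRNA.

Evaluation treats *resistant* as the positive class with higher expression
as the positive direction (the selected biomarkers are up-regulated): AUC
is the Mann–Whitney probability with the half-tie convention, and the ROC
curve sweeps all distinct thresholds so its trapezoidal area equals that
AUC exactly.  For survival, samples are split at the upper quartile of the
biomarker's expression (type-7 empirical quantile; *high* means strictly
above), Kaplan–Meier curves are fitted per group and compared by the
two-group log-rank test (`survival::survfit`/`survdiff`; $\chi^2$ with
1 df).

### Topology conventions

The bipartite graph is treated as undirected for centralities (the standard
network-biology convention; directedness is immaterial for degree and would
make most betweenness values trivially zero).  Betweenness is normalized by
$(N-1)(N-2)/2$.  Closeness on disconnected graphs uses Wasserman–Faust
component scaling: within a component of size $n_c$,
$(n_c-1)/\sum_j d(i,j)$ scaled by $(n_c-1)/(N-1)$, which keeps values in
$[0,1]$ and comparable across components.  Hubs (degree) and bottlenecks
(betweenness) are the top 10% of nodes: rank descending, take the
$\lceil 0.1N \rceil$-th value as cutoff, include ties — the deterministic,
conservative reading of a "top 10%" rule.  By default the ranking pool is
all nodes, with `rank_within = "mirna"` to restrict it to miRNAs.  The
power-law diagnostic fits OLS to $(\log_{10} k, \log_{10} f(k))$ over
distinct degrees with raw frequencies — the convention of classic
network-analyzer tools — and reports $R^2$ as the squared Pearson
correlation of those points.

## The synthetic study generator

Real cohorts of this design (tens of patients, controlled-access
sequencing) cannot ship with a package, so `simulate_study()` generates
studies with the statistical structure the analysis assumes, plus the
ground truth needed for recovery experiments.  Defaults, chosen once as a
realistic desk-scale emulation:

| parameter | default | rationale |
|---|---|---|
| `n_sensitive` / `n_resistant` | 31 / 37 | the cohort design being emulated |
| `n_mirna` / `n_mrna` | 50 / 200 | desk-scale feature counts with a workable subnetwork |
| `mean_targets` | 20 | miRNAs regulate many genes; keeps the DE subnetwork dense enough that single-line regulation is informative rather than ubiquitous |
| `n_planted` / `planted_excess_singles` | 4 / 10 | four true biomarkers, each with ten dedicated exclusive targets |
| `de_fraction` | 0.35 | a minority of features truly differential |
| `effect_log2fc` | 1 | planted shifts of one log2 unit (FC 2) |
| `sigma` | 0.5 | within-group SD on the log2 scale |
| `hazard_coefficient` | 1.0 | log-hazard per SD of biomarker expression |
| `baseline_hazard` | 0.05 /month | median survival ≈ 14 months at baseline |
| `censor_rate` | 0.3 | ~30% censoring under the null hazard |

The network generator lays background edges by preferential attachment on
mRNA in-degree (weight = in-degree + 1), giving a heavy-tailed, power-law
like degree distribution.  Planted biomarkers then receive their dedicated
single-line targets *in place of* that many background targets: a planted
miRNA keeps a typical total degree, but its regulatory program is dominated
by exclusive targets — the empirical signature of network-vulnerable
biomarker miRNAs, whose NSR is close to their degree.  (Planting the
singles *on top of* a full background target set was tried first and makes
the planted miRNA an oversized hub whose NSR fraction is only marginally
significant under the degree-preserving null; that variant defeats the
generator's purpose of emulating a recoverable signal.)  Each planted
biomarker's first dedicated target is annotated as a resistance gene, with
five random background decoy genes added so the NPRG filter is non-trivial
under the null.

Expression is Gaussian on the log2 scale (baseline means
$\mathcal N(8, 2^2)$, noise SD `sigma`), with the resistant-group mean
shifted by each feature's true log2FC — no count model, since the pipeline
consumes log-scale matrices.  Survival is exponential with log-linear
hazard in the standardized planted-biomarker expressions; progression
times are overall-survival times scaled by $\sqrt{U}$ so PFS ≤ OS; a
shared exponential censoring time is calibrated to the target null
censoring fraction.

**What the generator does not emulate** — and what passing recovery tests
therefore cannot show about real data: sequencing-depth and count noise,
normalisation artefacts, batch effects, miRNA family structure and
correlated targets, measurement error in the reference network (false and
missing edges), and non-proportional or non-exponential hazards.  Recovery
results certify the pipeline's statistical machinery, not its field
performance.

## Numerical choices and degenerate inputs

* All randomness flows from a single seeded RNG stream (the permutation
  kernel uses R's own RNG), so identical seeds give identical results
  end-to-end; seeds are recorded in the simulation truth and the run report.
* Strict inequalities at every published cutoff; output orderings are
  deterministic (NSR descending, ties lexicographic by ID).
* A feature with zero variance and zero mean difference gets $t = 0$,
  $p = 1$; a matrix whose every feature has zero residual variance is a
  degenerate-input error (the variance prior is inestimable).  Non-finite
  moment matching falls back to $d_0 = \infty$ with a warning.
* Fewer than 3 distinct degrees make the power-law fit an error rather than
  a meaningless line; an upper-quartile split that leaves a group with
  fewer than 2 samples is an error naming the threshold.
* The trigamma inverse uses Newton iteration with asymptotic starts
  ($1/\sqrt x$ for large $x$, $1/x$ for small), relative tolerance
  $10^{-10}$.

## Problem sizes used by the shipped experiments

The packaged tests and the acceptance script run the recovery experiment at
50 seeded replicates and the zero-planting calibration at 100 replicates of
the default study size (250 features × 68 samples, ~1000 reference edges,
1000 permutations per NSR test); these sizes give stable medians and rates
while keeping a full run in the order of a minute.  The same code scales to
larger networks — the permutation kernel is compiled and linear in edges ×
permutations.

## Known limitations

* The NSR significance test is a package-defined null, not a replication of
  the original closed-source tool; per-miRNA p-values are not comparable to
  that tool's printed values.
* The DE stage handles only the two-group design (no covariates, no
  multi-factor models).
* Enrichment is a plain hypergeometric over-representation test against
  user-supplied sets: no ontology structure, no term clustering, and its
  universe default (all network mRNAs) matters and should be stated with
  results.
* The published supplementary network file is not distributed; the
  re-derivation of the printed network statistics
  (`validate_published_network()`) runs only when the user supplies that
  file.
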