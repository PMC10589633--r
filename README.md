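# rarecascade

Multi-omics outlier detection and rare-variant prioritization across the
regulatory cascade.

Every genome carries thousands of rare variants (allele frequency < 1%),
and deciding which of them matter is one of the central problems of
human genetics. Impactful rare variants tend to push their carrier's
molecular measurements — gene expression, DNA methylation, splicing,
protein abundance — far outside the population distribution.
`rarecascade` is for analysts of longitudinal multi-omics cohorts who
want to turn that observation into calibrated variant-level
probabilities:

* **Outlier calling**: residualize molecular matrices on covariates and
  hidden factors, scale to Z-scores per exam, and call *joint outliers*
  — (gene, individual) pairs with |Z| > 3 in both of two exams —
  plus replication and cross-omics sharing statistics.
* **SPOT splicing outliers**: per junction cluster, a
  Dirichlet-Multinomial fit, Mahalanobis distances of each individual's
  junction-usage proportions, empirical p-values against draws at the
  individual's own depth, and gene-level aggregation
  `P_gene = 1 − (1 − p_m)^c`.
* **Enrichment statistics**: relative risk of rare-variant carriage in
  outliers vs controls, `RR = [a/(a+b)] / [c/(c+d)]`, with Wald
  confidence intervals, one-sided tests against RR = 1, enrichment
  comparison tests, and ancestry-matched control selection.
* **The Watershed model** (the centrepiece): a latent-variable model
  with annotation inputs G, a fully connected pairwise CRF over latent
  per-signal regulatory states Z, and categorical emissions E,

      P(z | G) ∝ exp( Σ_k z_k (β_k0 + β_k·G) + Σ_{k<l} θ_kl z_k z_l ),
      P(E | z) = Π_k φ_k(E_k | z_k),

  trained by EM with *exact* inference over the 2^K latent
  configurations (K = 4 signals → 16 states), and evaluated on N2
  pairs — individuals sharing an identical rare-variant set near a
  gene — by area under the precision-recall curve against the
  annotation-only logistic baseline (GAM) and the single-signal special
  case (RIVER).
* **Trait scoring**: percentile-normalized GWAS effect-size comparisons
  for posterior-thresholded variant sets and a gene-level rank-sum test
  of carriers' posteriors in trait-outlier vs control individuals.
* **A cohort simulator** that generates all of the above from known
  parameters, so every component is testable without restricted data.

## Worked example

Simulate a cohort with known generating parameters, fit the Watershed
model, and score instances:

```r
library(rarecascade)

cfg <- cohort_config(n_individuals = 60, n_genes = 40, n_annotations = 6,
                     n2_fraction = 0.05, seed = 42)
coh <- simulate_watershed_instances(cfg)
coh
#> Simulated multi-omics cohort
#>   individuals: 60  genes: 40  instances: 2400
#>   signals: expression, methylation, splicing, protein
#>   N2 pairs: 120  variants: 2291

fit <- watershed(coh$G, coh$E, lambda = 1, max_iter = 50)
fit
#> Multi-omics Watershed model
#>   signals:     expression, methylation, splicing, protein
#>   instances:   2400   annotations:  6
#>   lambda:      1
#>   EM:          33 iterations, converged
#>   objective:   -4744.7276
```

The fitted pairwise weights recover the simulated coupling structure
(strong expression–methylation and expression–splicing edges, weak
protein edges; magnitudes shrink toward zero under the penalty at this
cohort size):

```r
round(fit$params$theta, 2)
#>             expression methylation splicing protein
#> expression        0.00        0.59     0.50    0.03
#> methylation       0.59        0.00     0.46    0.44
#> splicing          0.50        0.46     0.00    0.25
#> protein           0.03        0.44     0.25    0.00
```

Posterior probabilities that each signal is functionally perturbed,
given annotations and the observed outlier statuses — computed for all
four signals even where a measurement is missing:

```r
round(predict(fit, coh$G[1:3, ], coh$E[1:3, ]), 3)
#>      expression methylation splicing protein
#> [1,]      0.580       0.525    0.995   0.987
#> [2,]      0.872       0.076    0.922   0.034
#> [3,]      0.022       0.004    0.005   0.001
```

Row 3 is an instance with no outlier evidence and uninformative
annotations: all four posteriors are near zero. Row 1 carries splicing
and protein outlier calls, and the coupled CRF pulls the unobserved
signals up with them.

Enrichment statistics work on plain 2×2 counts — 30 of 100 outlier
instances vs 100 of 1000 control instances carrying a nearby rare
variant:

```r
relative_risk(30, 70, 100, 900)
#> Relative risk: 3  95% CI [2.109, 4.268]  one-sided p = 6.92e-10
#>   outlier instances: 100 (with variant: 30); control instances: 1000 (with variant: 100)
```

See the methods vignette (`vignettes/multiomics-watershed.Rmd`) for the
model, its assumptions, and every numerical choice.

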