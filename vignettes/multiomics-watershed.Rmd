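---
title: "Multi-omics outliers and rare-variant prioritization with rarecascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics outliers and rare-variant prioritization with rarecascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecascade)
```

## The problem

Every genome carries thousands of rare variants (allele frequency below
1%), and almost all of them do nothing. The ones that matter tend to
leave molecular fingerprints: a gene whose expression, methylation,
splicing, or protein abundance in the carrier sits far outside the
population distribution. `rarecascade` implements a full desk-scale
pipeline for exploiting that idea in a longitudinal multi-omics cohort:

1. **Outlier calling** — turn raw molecular matrices from two exams
   (roughly a decade apart) into residual Z-scores and call *joint
   outliers*: (gene, individual) pairs extreme in *both* exams, which
   enriches for genetically driven rather than transient effects.
2. **Splicing outliers (SPOT)** — junction-usage proportions are
   compositional, so splicing gets its own statistic: a
   Dirichlet-Multinomial fit per junction cluster, Mahalanobis
   distances, and sampling-based empirical p-values.
3. **Enrichment statistics** — quantify how much more often outliers
   carry nearby rare variants than controls (relative risk with
   confidence intervals and comparison tests).
4. **The Watershed model** — a latent-variable model that combines
   genomic annotations with the observed outlier statuses of all omic
   signals to compute, per rare variant and signal, the posterior
   probability of a real regulatory effect.
5. **Trait scoring** — connect variant posteriors to complex traits via
   percentile-normalized effect-size comparisons and a gene-level
   rank-sum association test.

Because real cohorts of this design are access-restricted, the package
ships a simulator that generates cohorts with the same statistical
structure from known parameters; every claim the test suite makes is a
claim about recovery of known truth.

## The Watershed model

For each (gene, individual) instance we observe a vector $G \in
\mathbb{R}^P$ of genomic annotations aggregated over the rare variants
the individual carries within 10 kb of the gene, and a vector $E$ of
categorical outlier statuses for $K$ omic signals (expression,
methylation, splicing, protein; any subset may be missing). Between the
two sits a layer of latent binary variables $Z_k$ — "this individual's
rare variants functionally perturb signal $k$ at this gene":

$$P(z \mid G) \propto \exp\Big(\sum_k z_k(\beta_{k0} + \beta_k^\top G)
  + \sum_{k<l} \theta_{kl} z_k z_l\Big), \qquad
  P(E \mid z) = \prod_{k\ \text{observed}} \phi_k(E_k \mid z_k).$$

The latent layer is a fully connected pairwise binary CRF conditioned on
the annotations; $\theta$ captures how regulatory effects propagate
between signals (expression effects dragging protein levels along, and
so on). Direction lives only in the emissions: $Z_k$ is binary, while
directional signals emit three categories (*under*, *none*, *over*) and
splicing — which has no natural direction — emits two (*none*,
*outlier*). With $K = 4$ there are only $2^K = 16$ latent
configurations, so **every** inference in the package (prior, posterior,
marginal likelihood, training gradients) is computed by exact
enumeration; there is no approximate inference anywhere.

`RIVER` is the $K = 1$ special case (`fit_river()`), and the `GAM`
(genomic annotation model, `fit_gam()`) is the annotation-only baseline:
an L2-penalized logistic regression per signal.

### Training

`watershed()` maximizes the penalized marginal likelihood of the
observed statuses by EM:

* **E-step** — exact posteriors $q(z) = P(z \mid G, E)$ over the 16
  configurations, vectorized across instances.
* **M-step, emissions** — $\phi$ is updated in closed form from
  posterior-weighted category counts with a Dirichlet pseudocount of 1.
  The pseudocount corresponds to a Dirichlet(2, ..., 2) prior, so the
  objective the trainer reports (and requires to be non-decreasing, with
  a hard error on any decrease beyond numerical tolerance) is the
  penalized marginal log-likelihood *plus* that emission log-prior — the
  quantity the pseudocounted update actually ascends.
  `marginal_log_likelihood()` exposes the plain penalized likelihood for
  users.
* **M-step, CRF weights** — the expected CRF log-likelihood is concave
  in $(\beta, \theta)$; it is ascended with a bounded quasi-Newton step
  (BFGS with exact analytic gradients, model expectations again by
  enumeration). A bounded inner step makes this a generalized EM, which
  preserves monotonicity while costing far less than running the inner
  optimizer to convergence at every outer iteration.
* **Initialization** is deterministic: per-signal GAM coefficients for
  $\beta$, $\theta = 0$, and $\phi$ from GAM-probability-weighted
  category frequencies (pseudocount 1). No restarts are needed in
  practice; the warm start lands in the basin where latent state 1
  means "outlier-prone", which also fixes the label-switching ambiguity.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 1 | L2 penalty on $\beta$ and $\theta$ (annotations are standardized, so 1 is a mild shrinkage; the penalty covers the intercepts too, matching the objective as stated) |
| `threshold_p` | 0.05 | two-sided p-value threshold turning median Z-scores into outlier categories (roughly $|Z| > 2$) |
| `tol` | 1e-6 | relative objective change stopping EM |
| `max_iter` | 300 | EM iteration cap |

### Scoring and evaluation

Posteriors $P(Z_k = 1 \mid G, E)$ are computed for all four signals even
when only one signal was measured — missing emissions are simply
marginalized. Variant-level scores take the maximum posterior across
carriers (`score_all_variants()`).

Evaluation uses **N2 pairs**: two individuals carrying the *identical*
set of rare variants near the same gene. The model scores the held-out
individual from the shared annotations plus the held-in individual's
outlier statuses; labels are the held-out individual's own binarized
statuses. Performance is the area under the precision-recall curve
(average-precision estimator), with uncertainty from 100 half-subsample
bootstraps. When more than two individuals share a variant set, the two
lexicographically smallest IDs form the pair and the second is held
out — an arbitrary but deterministic rule. Random continuous scores sit
at the label prevalence by construction; note that using tie-heavy
scores (e.g. the labels themselves permuted) biases the
average-precision estimator and is not a valid null baseline.

## Outlier calling choices

* **Hidden factors.** Technical covariates are estimated as the leading
  right singular vectors of the feature-centered matrix
  (`estimate_hidden_factors()`, default $k = 30$) — a deterministic,
  dependency-free latent-factor estimator filling the role a
  probabilistic factor model plays in large cohort pipelines.
* **Residualization** is single-pass per-feature OLS on the shared
  covariates (plus an optional per-feature top-QTL genotype column),
  with residuals centered and scaled to unit variance within each exam.
  Missing values are excluded pairwise; a feature needs 30 non-missing
  individuals (configurable) to be scored. Collinear designs are a hard
  error naming the offending columns; zero-residual-variance features
  are excluded with a warning.
* **Joint outliers** need $|Z| > 3$ (default) in both exams with
  consistent sign; controls need $|Z| < 1$ in both.
* **Global outliers** — individuals with more outlier calls than
  Q3 + 1.5 IQR across individuals — are removed per signal. Quartiles
  use the linear-interpolation (type-7) convention; this is a choice, and
  it is fixed and documented here because different quartile rules move
  the fence.
* **Methylation** is transformed from beta to m-values
  ($m = \log_2 \beta/(1-\beta)$) before residualization, and CpG-level
  Z-scores aggregate to genes as the median over CpGs within 1.5 kb
  upstream of the TSS, strand-aware, boundary inclusive.
* Coordinates are 0-based half-open internally (BED-native); window
  checks use `start - flank <= pos < end + flank`.

## SPOT choices

* The DM concentration is fit by the digamma fixed-point iteration from
  a moment-matched start, stopping at relative log-likelihood change
  below 1e-8 (cap 500 iterations).
* Mahalanobis distances use the DM covariance of proportions **at the
  individual's own depth**, dropping the last junction coordinate to
  avoid the simplex singularity. The null MD distribution depends on
  depth, so empirical p-values compare against draws at the same depth;
  draws are shared within a depth class and redrawn across classes.
* Empirical p-values carry the add-one correction
  $(1 + \#\{MD_{null} \ge MD_{obs}\})/(n_{samples}+1)$, bounding them
  away from zero.
* Cluster p-values aggregate to genes as
  $P_{gene} = 1 - (1 - p_m)^c$ with $p_m$ the minimum over the gene's
  $c$ clusters.
* The Z conversion is the one-sided upper-tail normal quantile floored
  at zero: splicing outliers are directionless, so a signed Z would be
  arbitrary.

## Enrichment choices

Relative risk uses the standard Wald log-RR interval; zero cells return
an explicitly flagged undefined CI rather than a silent continuity
correction. The one-sided test against RR = 1 uses a t reference with
$df = n_{outlier} + n_{control} - 2$, the same df convention as the
two-enrichment comparison test. Ancestry matching pairs each outlier
with the Euclidean-nearest control in genotype-PC space, reusing
controls and breaking exact ties by ID order.

## What the simulator emulates — and what it does not

`simulate_watershed_instances()` generates instances in the model's own
generative direction: annotations (a configurable mix of Bernoulli(0.3)
flags and standard-normal scores, a leading subset truly informative
with weight 1.5 on the standardized scale), latent states from the
exact CRF, emissions from known tables, and Z-scores drawn from the
matching tails so that re-binarizing reproduces the emitted categories.
Default couplings make expression–methylation and expression–splicing
edges strong (1.0, 0.9) and protein edges weak — the ordering the
model class is meant to detect. Cross-exam matrices share a latent
component giving per-feature correlation `exam_correlation` (default
0.67, the level a stable plasma-proteome signal shows across a decade);
injected outliers appear in both exams. N2 pairs are created by letting
a second individual share an instance's variant, annotations *and
latent state*, with fresh emission draws — the "same causal variant,
same regulatory effect, independent measurement" idealization.
Missingness is independent per signal (default 10%).

The simulator does **not** emulate linkage disequilibrium, realistic
allele-frequency spectra, sequence-level genotypes, array probe
chemistry, or correlated missingness. Passing tests therefore show that
the estimators recover the structure they assume, at the noise levels
configured — not that real data satisfy those assumptions. One
consequence worth knowing: with the default emission tables, even the
true latent state predicts a held-out individual's binarized status
imperfectly (the emission noise caps attainable precision-recall), so
absolute AUC-PR values from simulations are not comparable to any real
cohort's.

## Problem sizes and numerical tolerances

The test and acceptance workloads use sizes chosen to make sampling
error negligible relative to the tolerances they assert: exact-inference
checks on 1,000 random draws at 1e-10 against an independent loop-based
enumerator; EM parameter recovery on 10,000 simulated instances (mean
absolute emission error below 0.05; signs of all pairwise weights above
0.5 recovered); DM recovery at 2,000 individuals of depth 200 (15% per
component); SPOT calibration on 2,000 null individuals against 2,000
null draws per depth class; enrichment calibration on 2,000 null tables
and 200 planted-effect replicates; N2 evaluation on a 9,000-instance
cohort with ~700 pairs and 100 bootstrap halves. EM declares an
inference bug (hard error) if the objective ever falls by more than
1e-8 relative; the inner optimizer stops at gradient-scale relative
change 1e-10.

## Known limitations

* Exact enumeration is exponential in the number of signals; the
  implementation is meant for the $K \le 6$ regime (16 states at
  $K = 4$).
* The L2 penalty default (`lambda = 1`) is a mild fixed choice on
  standardized annotations, not a tuned value; a held-out grid search
  is possible via the exported likelihood but is not automated.
* `theta` attenuates toward zero at small sample sizes (the penalty
  plus limited information); sign recovery is reliable long before
  magnitude recovery.
* The trait association test treats variants within an individual as
  exchangeable draws; it does not model relatedness or LD between
  carriers.
* Probe masking for methylation and the cluster-to-gene map for
  splicing are consumed as inputs, not recomputed.
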