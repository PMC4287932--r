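---
title: "EMT scoring and signature derivation: models, parameters, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMT scoring and signature derivation: models, parameters, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtscore)
```

## Overview

`emtscore` quantifies where a transcriptomic sample sits on the
epithelial–mesenchymal continuum. The core statistic is a signed
two-sample Kolmogorov–Smirnov (2KS) score comparing the within-sample
rank distributions of an epithelial (Epi) and a mesenchymal (Mes) gene
set; around it the package implements the pipeline that produces such
gene sets from expression cohorts and merges disease-specific versions
into a generic signature. This vignette records the model choices, the
tunable parameters with their defaults and rationale, the numerical
conventions, and — importantly — what the synthetic benchmarks do and do
not demonstrate.

## The 2KS EMT score

For a sample `s`, all genes observed in `s` are ranked by ascending
expression with mid-ranks for ties; genes missing in `s` are excluded
from `s`'s ranking only, so other samples are unaffected. With
`F_Epi` and `F_Mes` the ECDFs of the signature genes' rank positions,
the score is

* `D+ = sup (F_Epi − F_Mes)`, `D− = sup (F_Mes − F_Epi)`,
* `score = D+` if `D+ > D−`, `−D−` if `D− > D+`, and `0` on an exact tie.

Because the rank axis ascends in expression, Mes genes sitting at high
expression delay `F_Mes`, so `F_Epi` leads and the score is positive:
**positive = mesenchymal-like**, with `+1` attained exactly when every
Mes signature gene outranks every Epi signature gene, and `−1` in the
mirror case. `|score|` equals the classical KS statistic `D` except in
the measure-zero tie case, which we map to 0 (and hence to an
intermediate call); the tie rule matters only for tiny, symmetric
configurations and is asserted explicitly in the tests.

Only membership of the gene sets enters the score — signature weights
produced by the combination step are carried as provenance and ignored
here, since the ECDFs are unweighted. The score is therefore invariant
under any strictly increasing transform of one sample's expression
values, which is what makes it comparable across platforms.

### Significance and classification

The p-value for `D` uses the asymptotic Kolmogorov distribution at
`sqrt(n_eff) * D`, `n_eff = n_epi * n_mes / (n_epi + n_mes)` — the same
approximation `stats::ks.test()` applies to large two-sample problems,
against which it is tested. For small signatures
(`n_epi + n_mes <= 20`) an exact mode enumerates all label assignments
of the (assumed untied) rank positions and returns `P(D* >= D)`.

Samples are segregated four ways: `Mes` (`score > 0`, `p < threshold`),
`intermediate-Mes` (`score > 0`, `p >= threshold`), and symmetrically
for the Epi side; a score of exactly 0 is `intermediate-Epi` by
convention. The default threshold is 0.05; 0.001 is a common stricter
choice for calling only extreme phenotypes, and any value in (0, 1) is
accepted.

Coverage: scoring requires at least `min_genes = 3` genes of each set
in the matrix (one or two genes give degenerate ECDFs), and warns when
less than half of a set is found. In `score_matrix()` a sample failing
coverage yields a flagged `NA` record rather than aborting the cohort.

## ssGSEA pre-ranking

The derivation pipeline needs a rough per-sample EMT ordering before
any signature exists. We use a single-sample GSEA enrichment score:
walking the genes in descending expression, an in-set mass `P_in`
(each in-set gene weighted by its ascending rank to the power `alpha`,
normalized to 1) and a uniform out-of-set mass `P_out` are accumulated,
and `ES = sum_i (P_in(i) − P_out(i))`. With `alpha = 0` all in-set genes
weigh equally and the score is a pure rank-concentration measure;
`alpha = 0.25` (the default) mildly up-weights highly expressed genes,
in the spirit of the widely used ssGSEA variant. Because the weights are
the ranks themselves, the ES is invariant under strictly increasing
transforms at every `alpha`. No cross-sample normalization is applied:
ES values are compared within a cohort, and cross-cohort use is the
caller's responsibility. Ties in expression are broken by current gene
order (stable), which only matters when tied genes straddle the set
boundary.

## The six-step derivation

`derive_cancer_signature()` reproduces the derivation scheme on one
cohort:

1. ssGSEA scores for each published EMT gene set;
2. Spearman correlation of each set's ES with canonical marker genes
   (defaults: Mes — TWIST1, SNAI1, SNAI2, VIM, CDH2, ZEB1; Epi — CDH1,
   DDR1, ERBB2, ERBB3, KRT19); each set gets an agreement score,
   `mean(rho over Mes markers) − mean(rho over Epi markers)`, and the
   set with the largest absolute agreement wins. A negative agreement
   means the set is epithelial-oriented, so the ranking is flipped —
   this makes the pipeline indifferent to the polarity of published
   sets;
3. the `n_seed` most Mes and most Epi samples by that ranking (default
   15 per end, clamped to 10–20) train the metagene probit;
4. the probit assigns every sample a Mes probability. Steps 1–3 may be
   repeated (`max_iter > 1`), re-seeding from the probabilities, until
   the seed membership stabilizes; the default is a single pass, which
   sufficed in every synthetic experiment;
5. the extreme samples by probability — fraction `frac = 0.25` per end
   for cell-line panels, fixed `n_each = 100` per end for tumour
   cohorts, always capped at half the cohort so the groups stay
   disjoint — enter SAM and per-gene ROC; genes with `q% <= 0`,
   `ROC > 0.8` and positive SAM `d` become Mes, genes with `q% <= 0`,
   `ROC < 0.2` and negative `d` become Epi. Genes whose `d` and ROC
   disagree are excluded with a warning. Both ROC endpoints are
   exposed (`roc_hi`, `roc_lo`) since 0.8–0.85 / 0.15–0.2 are all
   defensible;
6. the selected genes' statistics (log2 fold-change, q%, ROC, cohort
   size) are attached for the cross-disease combination.

### The metagene probit stand-in

The original pipeline this emulates used an external Bayesian binary
regression program (probit on SVD metagenes, fitted by MCMC). We
implement the same model family with a deterministic fit: training
genes are standardized, the top `k = 2` left singular vectors define
the metagenes (each sign-fixed so its loading on the Mes-group mean is
positive, making the fit reproducible), and a probit of phenotype on
the metagene coordinates is fitted by IRLS with a small ridge penalty
(`ridge = 1e-3`) on the slopes. The ridge keeps the optimum finite on
linearly separable training groups — the typical case for extreme
phenotype panels — at the cost of mild shrinkage; the IRLS solution is
verified in the tests against a direct optimizer of the penalized
likelihood. This is an approximation by design: it makes no claim of
numerical equivalence to the Bayesian fit, only of the same
discriminant geometry. Prediction projects new samples onto the stored
basis after standardization with the training centers and scales;
missing predictor genes are imputed at the training mean (warned), and
more than 50% missing is an error.

## SAM and the q-value rule

The SAM statistic is `d_g = (mean_Mes − mean_Epi) / (s_g + s0)` with the
pooled standard error `s_g` and a fudge factor `s0`, by default the 5th
percentile of the `s_g` distribution; the classical
coefficient-of-variation minimization over percentile candidates
(`s0 = "tusher"`) is available. Fold-changes are recorded as
`mean_Mes − mean_Epi` on the log2 input scale, i.e. log2 fold-changes.

q-values come from label permutations with group sizes fixed —
exhaustive enumeration whenever the number of distinct assignments is
within the permutation budget (the observed labeling and its mirror are
excluded), otherwise `n_perm = 1000` seeded random assignments. The
permutation universe is built over a canonical (sorted) sample order,
so swapping the two group arguments provably yields identical q-values
with every `d` negated. At the cut `|d| >= |d_g|`, the q-value is
`100 * F / C` with `C` the observed call count and `F` the expected
false-call count across permutations.

Two estimators of `F` are offered. The default, `fdr = "mean"`, uses
the mean per-permutation count, equivalently the pooled exceedance
count divided by the number of permutations. Its key property is null
calibration at `q = 0`: a gene reaches `q = 0` only when *no*
permutation places *any* gene beyond it, so on pure-null data the
`q = 0` stratum is empty with high probability, while strongly
separated genes still reach 0 because their statistics dwarf the whole
permutation distribution. The Tusher-style `fdr = "median"` (median
per-permutation count) is also provided and oracle-tested; with few
genes its median is frequently zero at the top cut — the observed
maximum exceeds the median permutation maximum about half the time
under the null — so it assigns spurious `q = 0` calls to null data and
is not suitable as a `q = 0` selection rule at small gene counts, which
is exactly how the selection step uses q-values. That calibration
argument, confirmed by simulation, is why `mean` is the default.
q-values are capped at 100 and forced monotone non-increasing in `|d|`.

Per-gene ROC values are the normalized Mann–Whitney `U`:
`AUC = P(Mes > Epi) + 0.5 P(tie)` via mid-ranks, verified against
exhaustive pair counting.

## The generic signature combination

Genes recurring across disease-specific signatures are weighted

`w_g = sum_d |fc_gd| * (1 − q_gd/100) * 2|ROC_gd − 0.5| * sqrt(n_d)`

over the diseases whose signature contains the gene. The multiplicative
form with these four factors is our concrete reconstruction of a
combination rule specified only qualitatively (monotone in fold-change,
in `1 − q`, in distance of ROC from chance, and in cohort size): each
factor is normalized to a comparable scale, a chance-level ROC or a
100% q-value annihilates a disease's contribution, and the `sqrt(n_d)`
damping stops one very large cohort from dominating. Swapping in a
different algebraic form only requires changing `gene_weight()`.

Weights are z-transformed over the population of all genes appearing in
at least one disease signature — a deliberately broad population,
because the selection cut `z > 3.09` is the upper 0.001 normal quantile
and only makes sense against a background of mostly unremarkable genes.
Selection requires (strictly) `z > 3.09`, membership in all `D`
signatures by default (`at_least_k` is available when the all-of-D rule
is too harsh), and a consistent Epi/Mes direction; direction conflicts
are excluded with a warning since a generic signature needs one
direction per gene.

## The synthetic benchmark

`generate_cohort()` draws `x_gs = mu_g + beta_g * phi_s + eps_gs` with
`mu_g ~ N(7, 1)` (a log2-like baseline), `beta_g = +b` for Mes-block
genes, `−b` for Epi-block, `0` for background, `eps ~ N(0, sigma^2)`,
and a latent EMT position `phi_s` either uniform on `[−1, 1]` or in two
clusters at `±0.8` (sd 0.1, clamped) — the clustered mode emulates
cohorts with distinct Epi and Mes groups, the regime the SAM/ROC
selection expects. The defaults — 200 samples, 500 background genes,
50 + 50 block genes, `b = 2`, `sigma = 0.5` — are the study conditions
for all recovery experiments: under them the EMT score tracks the
planted axis with Spearman rho above 0.9, the six-step derivation
recovers over 90% of planted block genes with at most 1% background
false positives, and the D = 6 multi-disease collection (10 + 10
consensus genes shared by all diseases, 40 private genes per disease,
per-disease seeds `seed + d`) yields a combined signature containing
the consensus genes and no private ones under the all-of-D rule.

One subtlety: at `sigma = 0` a `phi = ±1` sample is *not* guaranteed a
score of exactly `±1` at `b = 2`, because the baseline spread `mu_g`
can by itself invert an (Epi, Mes) gene pair; exact extremity holds
once the effect dominates the baseline spread, and the tests assert it
in that regime (`b = 8`) while checking near-extremity at `b = 2`.

What passing these benchmarks does **not** show: the generator has no
probe effects, no batch structure, no stromal or immune admixture, no
correlated gene modules beyond the single planted axis, and Gaussian
noise throughout. Real cohorts violate all of these; the benchmarks
validate the algebra and the selection logic, not robustness to real
microarray artefacts, which is why inputs are assumed already
normalized and batch-corrected upstream.

## Numerical conventions and edge cases

* Gene identifiers match by exact string comparison after whitespace
  trimming; no alias resolution. Duplicate gene rows collapse by
  arithmetic mean on the log2 scale (warned); duplicate sample ids are
  an error. Sample order is never changed on load; gene order follows
  the file.
* Ties in expression: mid-ranks everywhere in scoring and ROC; stable
  order in the ssGSEA walk.
* Probit IRLS: linear predictors clamped to `±8`, probabilities to
  `[1e-10, 1 − 1e-10]`; non-convergence after `max_iter = 100`
  iterations is an error reporting the last coefficient change rather
  than a silent bad fit.
* Permutation draws take an explicit integer seed, recorded in the
  result object; generators save and restore the caller's RNG state.
* Problem sizes in the shipped tests are chosen for a laptop-scale run:
  cohorts of 40–200 samples, 150–600 genes, 200–1000 permutations,
  exhaustive enumeration wherever the assignment count is below the
  permutation budget. They exercise every code path; larger inputs
  scale linearly in genes and permutations.

## Known limitations

* The 2KS p-value treats the two gene sets as independent samples of
  rank positions, ignoring gene–gene correlation; classification
  thresholds should be read as conventional cutoffs, not calibrated
  error rates on real data.
* The metagene probit is a deterministic surrogate for a Bayesian fit;
  posterior uncertainty of the phenotype probabilities is not
  available.
* The cross-disease weight formula is a documented reconstruction, not
  a transcription of the original (unpublished) expression.
* `fdr = "median"` reproduces the classical SAM false-call estimator
  but should not be combined with a `q = 0` selection cut on small
  gene universes (see above).
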