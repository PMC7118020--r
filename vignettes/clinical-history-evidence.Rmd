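---
title: "Clinical-history evidence for BRCA1/BRCA2 variant classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical-history evidence for BRCA1/BRCA2 variant classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vuslr` turns the personal and family cancer histories of probands tested
by multigene hereditary-cancer panels into per-variant likelihood ratios
(LRs) of pathogenicity, per-class estimates of the proportion of
pathogenic variants, and posterior probabilities of pathogenicity. This
vignette is the package's account of the statistical machinery: the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data tests do and do not establish.

## The carrier-prediction model

Within one gene (BRCA1 or BRCA2) and one of four race/ethnicity strata
(European plus mixed/unknown, African American, Asian, Hispanic), carrier
status is modelled by logistic regression,

$$\operatorname{logit} P(\text{carrier} \mid x) = \beta_0 + x'\beta,$$

where $x$ is a vector of 29 binary clinical-history indicators: 14
personal (DCIS; invasive breast cancer in six cells of triple-negative
status $\times$ diagnosis age $<50/\ge 50$; bilateral breast cancer;
ovarian cancer $<60/\ge 60$; pancreatic cancer; male breast cancer;
prostate cancer $<60/\ge 60$) and 15 family (counts of affected first- and
second-degree relatives, maternal and paternal combined, capped at
$0/1/2/3{+}$ for breast cancer and $0/1/2{+}$ for ovarian, pancreatic and
prostate cancer, plus a male-breast-cancer flag). Cases are probands with
a known pathogenic variant; controls are probands with no reportable
variant in the gene. Carriers of VUS or likely pathogenic (VLP) variants
are never used for fitting — they are precisely the probands whose
variants are to be scored, so no leave-one-out correction is needed when
their predicted probabilities are later computed.

Before fitting, three exclusions are applied in fixed order: probands with
insufficient personal/family history information; carriers of a
pathogenic/likely pathogenic variant in another susceptibility gene; and
carriers of any reportable variant (pathogenic, VLP or VUS) in the
*opposite* BRCA gene. The order is a package convention so exclusion
reports are deterministic; each proband is counted under the first rule
that removes it. Probands carrying both a pathogenic variant and a VUS in
the *same* gene are treated by their most severe status (they enter as
cases and are not scored), the only reading under which cases and scored
probands stay disjoint.

Three design points were genuinely open and are resolved as follows:

* **Male breast cancer** sets the `male_bc` indicator *and* the
  appropriate TN-by-age cell. The two predictors are parallel, not
  exclusive; the alternative (exclusive coding) is available via
  `cohort_config(male_bc_fills_tn_cell = FALSE)`.
* **DCIS** is an indicator on its own; concurrent invasive breast cancer
  additionally fills its TN-by-age cell. **Bilateral disease** likewise
  stacks on top of the TN-by-age cell.
* **Unknown TN status** is its own pair of cells (`tn_unk_*`); a breast
  cancer with partially known receptor status is treated as unknown
  unless the triple-negative determination is complete.

Indicators with no exposed probands, or exposed only among cases or only
among controls, are non-estimable (infinite MLE); they are dropped from
the fit and flagged in the output rather than penalised, mirroring how
sparse strata are reported with "–" cells in published model tables.
Remaining quasi-separation (a finite but absurd coefficient, $|\beta| >
15$) raises an error naming the indicator. Fitting is iteratively
reweighted least squares (`stats::glm.fit`) to relative tolerance
$10^{-8}$, at most 100 iterations.

The null carrier probability of a stratum is the case fraction
$r_0 = n_\text{cases}/(n_\text{cases}+n_\text{controls})$, and model
discrimination is summarised by the rank-based (Mann–Whitney) AUC with a
Hanley–McNeil closed-form variance — chosen over resampling intervals
because it is deterministic and cheap at cohort scale.

## From predicted probabilities to evidence

For proband $k$ with predicted carrier probability $r_k$, the likelihood
ratio of the observed clinical history under pathogenicity versus
benignity is the odds ratio

$$LR_k = \frac{r_k (1 - r_0)}{(1 - r_k)\, r_0},$$

computed in log space from the difference of logits. Per-variant evidence
multiplies $LR_k$ over all probands carrying the variant; probands in
different race/ethnicity strata contribute with their own stratum's model
and $r_0$. All accumulation is in $\log_{10}$ (the scale used in the
package's output headers); the linear-scale product is materialised only
on output and clamped at $10^{\pm 300}$ with the log-scale sum always
reported exactly. A proband carrying two distinct VUS in the same gene
contributes its LR to both variants and is flagged
(`multi_vus_proband`), since the evidence cannot be attributed between
them without external information.

## The admixture (heterogeneity) model

For a class $C$ of $N_C$ variants with combined ratios $LR_i$, the
likelihood of the pathogenic proportion $\alpha$ is

$$L(\alpha) = \prod_{i=1}^{N_C} \left[ \alpha\, LR_i + (1 - \alpha) \right],$$

a two-component mixture in which each variant is pathogenic (contributing
$LR_i$) with probability $\alpha$ or benign (contributing 1) otherwise.
$\hat\alpha$ maximises the log-likelihood on $[0,1]$ by Brent's method
(tolerance $10^{-8}$) with explicit endpoint comparison, since the
maximum frequently sits on a boundary. Approximate 95% confidence
intervals are profile-likelihood intervals: the $\alpha$ values at which
$2[\ell(\hat\alpha) - \ell(\alpha)] = 3.84$, found by bisection on each
side and truncated at $[0,1]$. At a boundary estimate the interval is
one-sided but still defined by the same drop; no mixture-boundary
$\chi^2(0{:}1)$ correction is applied to the interval. Partitions of the
variant space are compared by the likelihood-ratio test
$\chi^2 = 2[\sum_\text{parts} \ell_\text{max} - \ell_\text{max}^\text{pooled}]$
on (number of classes − 1) degrees of freedom; when a boundary estimate is
involved the $\chi^2$ reference is conservative, which the output notes.

Two behaviours of this model are worth knowing. A fully flat likelihood
(every $LR_i = 1$) leaves $\alpha$ unidentifiable; the package returns
$\hat\alpha = 0$ with CI $[0,1]$ and a warning. And when the true
$\alpha$ is exactly 0, the score at the boundary, $\sum_i (LR_i - 1)$,
has mean zero for any properly calibrated LR (because
$E[LR \mid \text{benign}] = 1$), so $\hat\alpha$ sits exactly at 0 in
only roughly half of replicates — the rest land at small positive values
whose CIs still touch 0. Boundary estimates are therefore common and are
flagged, not exceptional.

Heterogeneity analyses take one term per *variant* (the combined LR), not
per proband; the per-proband table is kept as an attribute of the
evidence for auditing.

## Posterior classification

Posterior odds are prior odds times the combined LR,
$P(\text{pathogenic} \mid \text{data}) = \pi\,LR / (\pi\,LR + 1 - \pi)$,
computed as `plogis(qlogis(prior) + ln LR)` for numerical stability, with
exact 0/1 priors mapped to exact 0/1 posteriors. Default qualitative
labels use the 10:1 odds convention: `supports_pathogenic` for $LR > 10$,
`supports_benign` for $LR < 0.1$, otherwise `indeterminate`; thresholds
are arguments, not constants. The strength-of-evidence flag
`meets_family_count_rule` marks variants observed in at least five
probands — "informative families" is operationalised as scored probands,
counting those whose LR is near 1 as well, since informativeness is a
property of the history, not of the conclusion it happens to support.
Packaged default priors per bioinformatic class (`default_priors()`) are
external calibration values from earlier multifactorial studies
(0.02 outside key domains; 0.03/0.29/0.66/0.81 for Align-GVGD C0 through
C65 within key domains; 0.97/0.34 for high/moderate splice damage;
0.64/0.30 for de novo donor predictions); they are inputs to
classification, never estimated by the package.

## The synthetic-cohort generator

The study data such pipelines run on are proprietary, so the generator
produces cohorts with exactly the statistical structure the inference
assumes — and no more:

* **Phenotypes** are drawn from baseline category frequencies
  (`default_phenotype_freqs()`), chosen to resemble a hereditary-cancer
  *testing* population (42% of female probands with invasive breast
  cancer, 12%/55%/33% TN-positive/negative/unknown, 5% ovarian cancer,
  modest Poisson family-history counts), not the general population.
  Blocks are drawn independently; real clinical histories are correlated
  (a proband's breast cancer co-occurs with familial clustering), so the
  generator reproduces the marginal, not joint, structure.
* **Carrier status** is drawn from the logistic model itself, with
  per-stratum log-odds seeded from published odds-ratio tables
  (`default_true_log_odds()`; non-estimable cells set to a null effect)
  and the intercept calibrated by bisection so the expected prevalence is
  1.5% per gene per stratum.
* **VUS observations**: each simulated variant draws a bioinformatic
  class (abundances proportional to the published class sizes), a latent
  pathogenic status with the class's mixture proportion
  (`default_alpha_by_class()`, mirroring the magnitudes reported for
  those classes), and a geometric number of carrier probands with
  success probability 0.65 — which reproduces the ~65% singleton share
  observed in real VUS collections (and implies a mean of about 1.5
  probands per variant). Carriers of pathogenic-latent variants are
  sampled from the MGPT-negative pool with weights proportional to their
  generative carrier *odds* (rejection from the logistic model), benign
  ones uniformly; this makes the carrier- and non-carrier-conditional
  history distributions differ exactly as the admixture model assumes,
  without simulating pedigrees, segregation or allele frequencies.
* A latent **truth table** is emitted separately and is used only for
  evaluating recovery, never by inference.

Because phenotype blocks are independent and LRs are, by construction,
correctly specified, passing tests establish internal consistency —
the pipeline recovers what the generative model put in — not that real
family histories carry this much information. Model misspecification,
correlated phenotypes, ascertainment shifts over time, and errors in
reported histories are all outside what the synthetic tests can detect.

## Determinism and problem sizes

Every stochastic function is driven by a single integer seed carried in
`sim_config()`; identical seeds give identical output, and the pipeline's
file outputs are byte-identical across reruns. The test suite exercises
the statistical guarantees at sizes chosen to make Monte-Carlo error
small relative to the assertion: single-replicate model recovery at
n = 50,000–100,000 probands; coefficient CI coverage over 100 replicates
of n = 200,000; admixture CI coverage over 100 replicates of 500
variants; partition-test type-I error over 400 replicates of two
300-variant classes. The replicated admixture studies draw per-variant
log-LRs directly from the calibrated pair
$\ln LR \sim N(\mp\sigma^2/2, \sigma^2)$ (benign/pathogenic, $\sigma = 2$),
which satisfies the defining density-ratio property of a likelihood ratio
exactly and so keeps the admixture model correctly specified at a tiny
fraction of the cost of rerunning the full cohort pipeline per replicate;
full-pipeline recovery is checked separately in single-replicate tests.

## Known limitations

* Bioinformatic classes and their priors are *inputs*; the package does
  not compute conservation or splice-prediction scores.
* No co-segregation, tumour-pathology (beyond TN status), functional
  assay or population-frequency evidence is integrated; the output LRs
  are one evidence stream for a multifactorial model, not a final
  classification.
* Family-history counts are proband-reported totals over first/second-
  degree relatives; pedigree structure, genotypes of relatives and family
  size are not modelled, so two families of very different sizes with the
  same counts are treated identically.
* Per-variant results based on one or two probands are dominated by
  individual-level noise; the per-class admixture estimates are the
  stable quantity at realistic cohort sizes, which is why the
  five-proband strength rule is carried on every classification record.
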