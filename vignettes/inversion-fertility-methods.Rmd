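---
title: "Methods: inversion diplotype calling and zero-inflated models of family size"
author: "invfert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion diplotype calling and zero-inflated models of family size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invfert)
```

## The scientific setting

The chromosome 17q21.31 inversion spans roughly 900 kb and suppresses
recombination between its two orientations, H1 (common) and H2 (minor in
European populations, frequency around 0.16). Because the region does not
recombine, the two lineages behave as the two alleles of a single
super-locus, and dozens of SNPs inside it are in near-perfect linkage
disequilibrium with the orientation. The analysis this package implements
asks whether the inversion diplotype (H1_H1, H1_H2, H2_H2) is associated
with the number of children a person reports, in a cross-sectional cohort
genotyped on an exome array and restricted to completed fertility.

Three methodological ingredients are non-standard and deserve a full
account: the diplotype caller, the non-event recoding inside a
zero-inflated negative-binomial (ZINB) model, and the age-bin weights.

## Inversion diplotype calling

### Model and assumptions

Within the inversion, an "indicator" SNP has one allele fixed on the H1
background and the other on H2. Consequently every subject is homozygous
for one allele (H1_H1), heterozygous (H1_H2), or homozygous for the other
allele (H2_H2), and *all* indicator SNPs sort subjects into the *same*
three groups. The caller exploits this redundancy:

1. **Seeding** (`seed_partition()`). Among SNPs with no missing calls, the
   three genotype classes of each SNP induce a candidate partition.
   Candidate partitions (grouped up to allele relabelling) are scored by
   how many SNPs in the whole matrix are concordant with them within the
   discordance tolerance; the partition with the most support wins. This
   directly operationalises "groups separated by many SNPs": a single
   unlinked SNP can never out-score the inversion block. Ties go to the
   larger seed set, then to the lowest genomic position, so the result is
   deterministic.
2. **Indicator admission** (`find_indicators()`). A SNP is an indicator
   when, ignoring missing calls, group 1 is homozygous, group 2
   heterozygous, and group 3 counter-homozygous, allowing at most `tol`
   discordant subjects per SNP (default 10). The tolerance absorbs rare
   genotyping errors and mutations that occurred after the H1/H2
   divergence; the group-3 homozygote allele is recorded as the H2-tagging
   allele.
3. **Assignment** (`assign_subjects()`). Each subject is scored against
   the three group-consensus genotype vectors over the indicator SNPs
   (matches divided by non-missing comparisons) and assigned to the
   argmax. A tie, or a subject with no non-missing indicator call, is
   reported `UNASSIGNED` rather than guessed — unassigned subjects are
   excluded from regression and logged. The larger homozygous group is
   labelled H1_H1, reflecting that H1 is the common lineage; at H2
   frequency 0.5 exactly the labelling is inherently ambiguous.

Consensus vectors come from the seed partition and assignment is a single
pass — no iterative refinement — so repeated runs are identical.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `tol` | 10 subjects | per-SNP discordance allowed for indicator admission |
| `min_coverage` | 1.0 | call-rate floor for seed SNPs; relax below 1 when no complete SNP exists (the best-covered SNP then seeds, and its missing subjects fall through to maximum-similarity assignment) |
| `min_group_frac` | 0.01 | genotype classes smaller than this fraction are not required when matching candidate partitions |

`pick_representative()` returns the indicator SNP with the highest call
rate (ties to the lowest position): since the indicators are almost
perfectly linked, one SNP suffices to represent the inversion in
regression, and maximal data wins.

## The zero-inflated negative-binomial model

### Why recode 0–3 children as non-events

Most families stop at two or three children under strong social norms, so
ordinary count regression of family size mostly measures conformity to the
norm. The scientifically interesting signal is *escape* from the norm —
having more children than average. The response is therefore recoded:
counts 0–3 become 0 ("non-events"), counts above 3 are kept unchanged
(`recode_nonevents()`, threshold = 3, the upper integer bound of the
cohort mean; no shift is applied, so the modelled support is {0} ∪ {4, 5,
…}). The ZINB mixture then reads naturally: the zero component absorbs the
probability of being a non-event; the count component describes the size
of large families.

The estimator fits the standard ZINB likelihood to the recoded response.
The likelihood places mass on counts 1–3 that the recoded data never
shows; the maximum-likelihood compromise inflates the count-component mean
and attenuates covariate effects relative to a hypothetical fully
specified model. This is a property of the published estimator itself, not
an implementation artefact; the package's recovery studies therefore
simulate from the *model family being fitted* (`simulate_zinb_process()`)
when the estimand is the coefficient vector, and from the questionnaire
emulator (`simulate_cohort()`) when the object of study is the end-to-end
pipeline.

### Likelihood, optimisation, numerics

For subject $i$ with weight $w_i$:

$$\ell = \sum_i w_i \log\left[ 1\{y_i = 0\}\left(\pi_i + (1-\pi_i)
f_{NB}(0;\mu_i,\theta)\right) + 1\{y_i > 0\}(1-\pi_i)
f_{NB}(y_i;\mu_i,\theta) \right]$$

with $\mu_i = \exp(x_i'\beta)$, $\pi_i = \mathrm{logit}^{-1}(z_i'\gamma)$
and $f_{NB}(k;\mu,\theta) = \frac{\Gamma(k+\theta)}{\Gamma(\theta)k!}
\left(\frac{\theta}{\theta+\mu}\right)^{\theta}
\left(\frac{\mu}{\theta+\mu}\right)^k$. Everything is computed in log
space. Two details matter numerically:

* the $\Gamma$ ratio is expanded as the exact finite sum
  $\sum_{j=0}^{k-1}\log(\theta+j)$, which stays accurate when $\theta$ is
  enormous (a `lgamma` difference loses all precision there), and
  $\log(\theta/(\theta+\mu))$ is computed as `-log1p(mu/theta)`;
* optimisation is quasi-Newton (BFGS) on $(\beta,\gamma,\log\theta)$ with
  the analytic gradient, relative-change tolerance $10^{-10}$, at most 500
  iterations. $|\log\theta|$ is capped at 20 ($\theta \approx 4.9\times
  10^8$): family-size data that is conditionally Poisson pushes
  $\hat\theta$ up an almost flat likelihood ridge, and a fit reaching the
  cap is re-profiled with $\log\theta$ fixed there and flagged
  `theta_at_cap`.

Starting values are deterministic: a weighted Poisson regression for
$\beta$, a weighted logistic regression of $1\{y=0\}$ for $\gamma$, and
$\log\theta = 0$. Standard errors come from the inverse observed
information (numerically differentiated analytic gradient).
Identifiability is judged on the $(\beta,\gamma)$ block of the information
matrix only — the flat $\log\theta$ direction of near-Poisson fits
legitimately yields a huge dispersion standard error (the published
pattern: a log-dispersion in the tens with a standard error several times
larger) and must not be mistaken for a singular design. A genuinely
singular coefficient block (e.g. separation in a tiny genotype class)
marks the fit non-identified; `prune_interactions()` treats a
non-identified full interaction model as "not formed" and falls back to
main effects with a warning, and `fit_snp_model()` reports `"model not
formed"` for SNPs with fewer than two genotype classes carrying events.

A zero-part formula of `~ 0` (e.g. `y ~ x | 0`) removes the zero component
entirely ($\pi \equiv 0$), giving plain weighted negative-binomial
regression; this is used as an internal consistency check against
`MASS::glm.nb`.

### Weights

Enrolment declines with age, so subjects are weighted by the inverse size
of their integer-year age bin, rescaled to sum to the cohort size
(`age_bin_weights()`): $w_i = N/(B\,n_{b(i)})$ with $B$ bins. Weights are
pooled across sexes (computing them within sex strata would be a
defensible alternative; pooled bins are the simpler reading and the
package implements that). Weights multiply log-likelihood contributions,
so rescaling all weights by a constant rescales the log-likelihood and
leaves estimates unchanged — a property the test suite asserts.

### Inference conventions

* **Term tests** (`wald_terms()`): Wald chi-square $W = b'V_b^{-1}b$ on
  the count-component coefficient block of each term, df = block size.
  For a single-df term this is exactly $z^2$ with the identical p-value,
  matching the convention in which the genotype association is a 2-df
  count-part test. (A likelihood-ratio variant was considered and not
  adopted: the printed single-df reference values equal the count-part
  $z^2$ exactly, pinning down the Wald-on-count-block convention.)
* **Interaction pruning** (`prune_interactions()`): fit
  `y ~ snp * age * sex`; if every interaction coefficient in both
  components has Wald $p \ge 0.05$, refit main effects only (mains are
  kept regardless of significance); otherwise keep the full model.
* **Overdispersion** (`overdispersion_check()`): the Wald p-value of
  $\log\theta$. A non-significant value indicates no overdispersion. When
  $\hat\theta$ sits at the optimiser cap the test is meaningless and p is
  reported as 1 with a boundary note. Note the convention tests
  $\log\theta = 0$ ($\theta = 1$): a moderate, precisely estimated
  dispersion is flagged even when it is *less* dispersed than $\theta=1$;
  this mirrors the printed-output convention rather than a boundary LR
  test.
* **Bonferroni** (`bonferroni()`): significance at $p < \alpha/m$ with
  default $m = 7$ — one representative inversion SNP plus six surrogate
  SNPs; negative controls are excluded from the family.

## Linkage disequilibrium and surrogate selection

Two-locus haplotype frequencies from unphased genotypes are estimated by
EM over the nine genotype classes under random union of gametes; only the
double heterozygote is phase-ambiguous and is split between cis and trans
in proportion to the current frequency products. Initialisation is at
linkage equilibrium (product of observed allele frequencies);
convergence when the largest frequency change drops below $10^{-8}$ (at
most 1000 iterations); boundary zero cells stay at the boundary — no
pseudocounts, which would bias small-sample LOD scores. The EM ascent is
monotone and the per-iteration log-likelihood trace is returned so tests
can assert it.

From frequencies: $D = p_{AB} - p_A p_B$; $D' = D/D_{max}$ with $D_{max}$
the usual sign-dependent bound; $r^2 = D^2/(p_A p_a p_B p_b)$; LOD is the
base-10 log ratio of the multinomial genotype-class likelihood at the EM
optimum versus linkage equilibrium with allele frequencies fixed at the
observed margins. Monomorphic loci raise an error naming the locus ($D'$
and $r^2$ are undefined there); the Hardy–Weinberg check is a closed-form
1-df chi-square with p = 1 for monomorphic input.

`select_surrogates()` implements the published rule: candidates within a
*closed* ±50 000 bp window of the target, Hardy–Weinberg consistent
(default $\alpha = 0.05$), LOD ≥ 3.0, ranked by LOD with ties broken by
absolute distance, top two selected — both may fall on the same side of
the target. Distances are signed, negative meaning upstream (lower
coordinate).

## The synthetic-data generator

`sim_config()` defaults are the study conditions: H2 haplotype frequency
0.159 under Hardy–Weinberg; 22 indicator SNPs plus unlinked noise SNPs at
uniform positions in 17:43793582–44776837 (GRCh37); mean per-call
missingness 0.02 — drawn per SNP (exponential, capped at five times the
mean) with a 10 % fraction of SNPs complete, since call failure is a SNP
property on arrays and the seeding step needs occasional full-coverage
SNPs; genotype error 0.001 per call (the true call replaced by a uniformly
chosen different call); ages uniform on 45–90 integer years; equal sexes
with no sex effect on fertility. Children counts follow a mixture that
mirrors the fitted model plus a realistic non-event composition:
structural non-events occur with probability
$\mathrm{logit}^{-1}(3.906649 - 0.027448\,\mathrm{age})$ and draw 0–3
children with probabilities proportional to 1713 : 1051 : 1641 : 747;
otherwise the count is negative binomial with log-mean 1.98656 for the
H2-homozygote reference class, −0.508373 for heterozygotes and −0.557395
for H1 homozygotes, dispersion $\theta = 10^6$ (effectively Poisson), and
a cap of 20 children (the phenotype-table sanity bound). All randomness
flows from the single seed in the configuration.

What the generator does **not** emulate: duplication substructure of the
inversion (H1D/H2D subtypes), recombination or coalescent realism,
population stratification, family relatedness, county-level geography,
age–cohort interactions in fertility, and sex-specific fertility
reporting. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not robustness to
everything real cohorts contain.

## Validation design and problem sizes

The test suite pairs every estimator with an independent route:

* ZINB log-likelihood against direct `dnbinom`/`plogis` mixture
  arithmetic at fixed parameters (the implementation itself uses the
  log-space finite-sum form — a distinct code path), and fitted
  coefficients against `glmmTMB` (`ziformula`, `nbinom2`, weights) on a
  200-subject dataset with moderate dispersion ($\theta = 1.5$) and H2
  frequency 0.3, chosen so all coefficients are well identified at that
  size.
* Parameter recovery: 100 cohorts of n = 5 000 with a planted
  H1-homozygote effect of −0.5; mean bias and Wald 95 % coverage are
  asserted. Null calibration: 1 000 cohorts of n = 1 500 with no genotype
  effect — the smallest size at which the ~38-subject H2-homozygote class
  supports Wald asymptotics — checking the 2-df genotype test rejects at
  3–7 % at $\alpha = 0.05$.
* EM haplotype frequencies against a brute-force coarse-to-fine grid
  search of the same multinomial likelihood on random small tables, plus
  closed-form cases (perfect coupling, exact equilibrium) and the
  allele-swap symmetry.
* The inversion caller against planted truth: exact on noise-free
  cohorts across H2 frequencies 0.05–0.5, and ≥ 99 % accurate at
  genotyping-error rate 0.002 with 2 % missingness.
* Descriptive arithmetic against the packaged published
  genotype-by-children-count table for rs12373123 (group means, allele
  totals 640/3390, 15.9 % H2 prevalence, recessive contrast 0.118 and
  dominant contrast 0.038 under the 3-decimal display rule — contrasts of
  rounded means, reported alongside full-precision variants because
  printed tables round first).

`scripts/acceptance.R` re-runs the main computations at these sizes and
writes the resulting numbers as JSON.

## Known limitations

* The caller reports its own indicator list; with real array data the
  exact membership depends on the SNP panel, and flanking-region SNPs in
  strong but imperfect linkage may be admitted within the tolerance.
* Subjects lost to the `UNASSIGNED` label (ties, all-missing indicator
  calls) are excluded from regression rather than imputed.
* The ZINB support-gap attenuation described above means count-part
  coefficients from recoded questionnaire data are conservative relative
  to the generative effects; cross-study comparisons should compare like
  with like.
* The log(theta) overdispersion convention can flag finite moderate
  dispersion as "overdispersed" even when a boundary likelihood-ratio
  test would not; both the p-value and the boundary note are reported so
  users can judge.
* Two-part formulas share the observation filter across components;
  subjects with missing covariates in either part are dropped from both.
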