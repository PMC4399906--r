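---
title: "Generalized weighted-sum association tests: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized weighted-sum association tests: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(gwss)
```

## The testing problem

Individually, rare variants (minor-allele frequency below roughly 0.01)
carry too few minor alleles for single-marker association tests to detect
anything at realistic sample sizes, so region-based tests collapse the
minor-allele counts of a gene or window into one per-subject burden score
and compare that score between cases and controls. Classical burden tests
make two restrictive choices: they weight variants only by rarity, which
ignores the *direction* of association (a mixture of harmful and
protective variants partially cancels), and they fix an a-priori MAF
cutoff that discards common variants entirely, although common and rare
signals frequently co-occur in the same gene.

The statistics implemented here generalize the weighted-sum idea along
three axes: the weight scheme, the group-comparison summary, and the MAF
threshold.

## The statistic

For subject $i$ and variant $j$, let $G_{ij} \in \{0,1,2\}$ count minor
alleles and $D_i \in \{0,1\}$ be disease status ($n_1$ cases, $n_0$
controls). Two label-dependent per-variant quantities drive everything:

* the **adjusted control MAF** $q_j = (m_j + 1) / (2 n_0 + 2)$, where
  $m_j$ is the minor-allele count among controls (the pseudo-count keeps
  $0 < q_j < 1$ even for monomorphic variants), and
* the **continuity-corrected odds ratio** $\widehat{OR}_j$, the
  cross-product ratio of the case/control × minor/major allele-count
  table with $0.5$ added to every cell, hence always finite and positive.

Given a threshold $\theta$, the burden score is
$$G_i(\theta) = \sum_{j=1}^{k} \{ w_j \, I(q_j \le \theta) \} \, G_{ij},$$
with one of four weights:

| scheme | $w_j$ | carries |
|--------|-------|---------|
| MAF | $1/\sqrt{n_0 q_j (1-q_j)}$ | rarity (always $>0$) |
| OR  | $\log \widehat{OR}_j$ | direction + estimated strength |
| D   | $I(\widehat{OR}_j>1) - I(\widehat{OR}_j<1)$ | direction only |
| DW  | $w^D_j \times w^{MAF}_j$ | direction + rarity as a strength proxy |

The DW scheme is the workhorse: with sparse allele counts the estimated
odds ratio is numerically unstable, but under a rare-disease carrier
penetrance model the magnitude of the log odds ratio decreases as the
control MAF grows (a property the test suite checks numerically on a
penetrance grid), so rarity is a usable surrogate for strength while the
odds-ratio *sign* is retained.

Scores are summarised either by the **rank-sum**
$\sum_{i: D_i = 1} \mathrm{rank}\{G_i(\theta)\}$ (midranks for ties,
which are heavy because most subjects carry zero minor alleles) or by
the **t-sum**, the absolute Welch statistic
$$\frac{|\bar G_{case}(\theta) - \bar G_{ctrl}(\theta)|}
       {\sqrt{V_{case}/n_1 + V_{ctrl}/n_0}}.$$

Finally, the threshold is either fixed or maximised out:
$S = \sup_{\theta \in \Theta} S_\theta$ with $\Theta$ the sorted unique
observed $q_j$ — the finest data-driven candidate set, in the spirit of
variable-threshold tests. Ten named combinations form the standard
family (`gwss_methods()`); "V" marks sup-mode methods, "t" the t-sum.

### Permutation p-values

No distributional result is available for data-driven weights, so
significance is empirical: the case/control labels are permuted $B$
times (case count preserved), the **entire** pipeline — $q_j$,
$\widehat{OR}_j$, weights, thresholds, statistic — is recomputed per
permutation, and
$$p = \frac{1 + \#\{S_{perm} \ge S_{obs}\}}{B + 1}.$$
Recomputing everything per permutation is essential: freezing weights at
their observed-label values would break exchangeability and inflate
type-I error. Both summaries reject for large values, so the comparison
is one-sided upper-tail. The add-one estimator never returns zero and is
slightly conservative; with $B = 200$, the smallest attainable p-value
is $1/201 \approx 0.005$.

Design choices worth stating explicitly:

* **Tie-break in sup mode**: the smallest $\theta$ achieving the
  maximum is reported, for determinism.
* **Fixed-mode default** is $\theta = \infty$ (no filter): every variant
  contributes, matching the family's aim of handling mixed rare/common
  regions; a finite $\theta$ is available for classical behaviour.
* **Degenerate t-sum** (both group variances zero): $0$ if the means
  agree, $+\infty$ otherwise; $\infty \ge \infty$ counts as an
  exceedance, so the convention permutes coherently.
* **Minor-allele orientation** is decided once from the pooled sample
  before testing (ties at frequency exactly $0.5$ keep input
  orientation), so the coding cannot drift across permutations.
* **Missing genotypes** are imputed to 0 copies (conservative toward the
  null) with per-variant missingness logged and a warning above 20%.
* **Label swap is not a symmetry** of the full statistic: the adjusted
  MAF is computed from whichever group is labelled control and the OR
  direction flips, so exchanging labels rebuilds different weights. Only
  the t-sum summary itself, at fixed scores, is swap-invariant.

### Numerical notes

The permutation engine evaluates all requested methods on shared
permutations. Subjects carrying no minor allele have score exactly zero
at every threshold and are dropped from the score algebra (their
contribution enters through the group counts only), which matters
because with MAFs near 0.005 the large majority of subjects are
all-zero. Per-threshold statistics come from cumulative weighted-column
sums over variants ordered by $q_j$; fixed-threshold methods are
evaluated through the same cumulative path, so the sup-mode statistic
dominates every fixed-threshold statistic *exactly*, not merely up to
rounding. Group variances are computed from sums of squares with a
clamp at zero against cancellation error.

## What the simulator emulates

The generator reproduces the simulation design under which the family's
operating characteristics were established:

* **MAF spectra**: rare-variant MAFs from Uniform(0.001, 0.01)
  ("identical" mode; in "different" mode signal rare variants are drawn
  rarer, Uniform(0.001, 0.005)); common variants from Uniform(0.01, 0.1).
* **LD**: each subject carries two independent haplotypes; haplotype
  $l$ has a latent standard-normal vector with
  $\mathrm{Cov}(Z_u, Z_v) = \rho^{|u-v|}$, and carries the minor allele
  at variant $j$ iff $Z_j \le \Phi^{-1}(MAF_j)$. Marginally
  $G_{ij} \sim \mathrm{Binomial}(2, MAF_j)$; $\rho = 0.7$ induces strong
  local LD. The AR(1) draw uses the exact scalar recursion
  $Z_u = \rho Z_{u-1} + \sqrt{1 - \rho^2}\,\epsilon_u$, $O(k)$ per
  haplotype, no Cholesky factor.
* **Disease model**: with baseline prevalence 0.05,
  $$\mathrm{logit} \Pr(D_i = 1 \mid G) = \mathrm{logit}(0.05)
    + \sum_{j \in \mathrm{add}} \log(OR_j) G_{ij}
    + \log(3) \, I\Big(\textstyle\sum_{j \in \mathrm{carrier}} G_{ij} > 0\Big).$$
  The first (up to) four signal variants act additively (per-allele OR 2
  harmful or 1/2 protective; a signal common variant occupies one of
  these slots with OR 1.5 or 1/1.5); the remaining four form an
  any-carrier block whose joint effect (OR 3) fires if *any* of them
  carries a mutation. In the protective scenarios only the additive
  odds ratios are flipped; the carrier block keeps its odds ratio 3, so
  those scenarios mix harmful and protective signals in one region —
  that mixture, with its partial cancellation inside direction-blind
  weighted sums, is precisely what they are designed to probe (the
  carrier effect remains configurable via `or_carrier`).
* **Ascertainment**: subjects are drawn from the population model and
  assigned to strata until exactly $n_1$ cases and $n_0$ controls are
  collected (rejection sampling; at 5% prevalence, 500 cases cost about
  $10^4$ population draws, which is cheap). Variant positions are
  re-randomised per replicate.
* The signal-common-variant scenarios place the CV in an *additive*
  slot: its odds ratio is listed alongside the additive ones, and a
  common variant inside the any-carrier block would saturate the block's
  indicator.

What it does **not** emulate: realistic site-frequency spectra (MAFs are
uniform, not skewed), recombination or haplotype-block structure beyond
AR(1) decay, genotyping/calling error, missingness, covariates or
population stratification. Passing operating-characteristic tests on
these simulations therefore demonstrates correctness of the machinery
and calibration under exchangeability, not robustness to confounding in
real cohorts.

## Operating characteristics at desk scale

The reference design — 1000 simulated datasets per scenario, 500
permutations per test, 500 cases / 500 controls — estimates power with a
binomial SE of about 0.005 at $\hat p \approx 0.97$. The package's test
suite and the bundled acceptance script use a desk-scale preset of
**300 replicates × 200 permutations** (250 × 150 for the ten-method null
sweep), for which the corresponding tolerance around a published
two-decimal power value is about $\pm 0.05$; a full-scale run of one
scenario is a few minutes of CPU with the vectorized engine and remains
available through `estimate_power()`'s arguments. Within a scenario all
methods are compared on the same datasets and the same permutations
(common random numbers), mirroring how method comparisons are designed
and shrinking between-method variance; the master seed spawns a child
seed per replicate so any single dataset can be regenerated in
isolation.

```{r, eval = FALSE}
# power of the direction-and-rarity weighted variable-threshold test
# under 8 harmful signal rare variants, no LD:
sp <- scenario_spec(n_signal_rv = 8)
estimate_power(sp, "VDWSS-t", n_replicates = 300, B = 200, seed = 1)

# type-I error of the whole family under the null:
null_calibration(n_replicates = 300, B = 200, seed = 1)
```

## Known limitations

* No covariate adjustment: the statistic is fully nonparametric;
  stratified application (testing within strata) is the caller's
  responsibility.
* No asymptotic p-values; everything is permutation-based, so very
  small p-values need a correspondingly large $B$.
* Multiple-testing correction across regions is left to the caller
  (`p.adjust` on the results table).
* The rank-sum summary detects case-enriched burden (upper tail); an
  all-protective region with a direction-blind weight will not be
  flagged by it — that is exactly the failure mode the direction-aware
  weights (D, DW, OR) exist to fix.
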