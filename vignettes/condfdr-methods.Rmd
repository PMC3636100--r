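---
title: "Conditional and conjunction FDR for cross-trait GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional and conjunction FDR for cross-trait GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condfdr)
```

## The problem

Highly polygenic traits hide most of their associated variants below
genome-wide significance: thousands of SNPs carry real but individually tiny
effects. When two disorders share genetic architecture — schizophrenia and
bipolar disorder are the motivating pair — a SNP's association with one trait
is evidence about its association with the other. `condfdr` leverages this
*pleiotropy* to re-rank SNPs for a primary trait using the p-values of an
auxiliary trait, within an Empirical Bayes false-discovery-rate framework
that needs only summary statistics.

## The estimators

For p-values of one trait, the Bayes FDR at threshold $p$ is
$\mathrm{FDR}(p) = \pi_0 F_0(p) / F(p)$, where $F_0$ is the null cdf
(uniform, so $F_0(p) = p$) and $F$ the cdf of all SNPs. Replacing $F$ with
the empirical cdf $q = N_p/N$ and $\pi_0$ with 1 gives the conservative
estimate

$$\widehat{\mathrm{FDR}}(p) = \min(p/q,\ 1),$$

which is biased upward; its complement $1 - p/q$ is a downward-biased
(conservative) true discovery rate. On the $-\log_{10}$ scale the estimate is
exactly the horizontal shift of a Q-Q curve from the identity line, which is
why the conditional Q-Q plot is the natural diagnostic.

The **conditional FDR** replaces the marginal cdf with the cdf of the primary
trait's p-values restricted to SNPs whose secondary p-value is at or below a
threshold: $\widehat{\mathrm{FDR}}(p_1 \mid p_2) = p_1 / \hat F(p_1 \mid
p_2)$, again with $\pi_0(p_2) = 1$. Cumulative (nested) conditioning subsets
are used rather than disjoint strata because the stratified empirical cdfs
are far noisier. The **conjunction FDR** — the posterior probability that a
SNP is null for *at least one* trait — is conservatively estimated as the
maximum of the two conditional FDRs; the max rule guards against one strong
trait carrying the pair.

## The look-up table and its numerical choices

`build_lookup()` evaluates the conditional estimate on a grid in
$(-\log_{10} p_1, -\log_{10} p_2)$ and `lookup_fdr()` assigns each SNP a
value by bilinear interpolation. Choices that were genuinely open, and what
this package does:

* **Grid**: $0$ to $10$ in steps of $0.1$ on both axes. Finer than the four
  diagnostic Q-Q thresholds, coarse enough that cells remain stably
  populated.
* **Interpolation in log space**: FDR spans orders of magnitude, so
  interpolation acts on $\log_{10}$ FDR; node queries return node values
  exactly (coordinates within $10^{-9}$ of a node are snapped, so
  $p = 10^{-g}$ round-trips bit-exactly). Queries outside the grid clamp to
  the boundary.
* **Sparse cells**: a conditioning column with fewer than `min_subset_size`
  (default 100) SNPs inherits the nearest looser column and is flagged;
  cells where the evaluation p-value lies below the subset's smallest
  p-value ($q = 0$) conservatively return FDR 1.
* **No monotonisation** of FDR along $p_1$ is applied by default.
* **Ties**: conditioning thresholds are inclusive ($-\log_{10} p_2 \ge t$).

Per-SNP assignment, LD pruning (greedy, keep a SNP iff $r^2 \le 0.2$ with
every better-ranked kept SNP), and single-linkage grouping of significant
SNPs into loci then produce the reported locus tables. Ranking ties are
broken by smaller nominal p, then chromosome and position, so outputs are
deterministic. How published analyses merged pruned SNPs into multi-SNP
"complex" loci is not fully specified anywhere we know of; single linkage
over $r^2$ above the pruning threshold among significant SNPs is this
package's declared rule.

## Genomic control

$\lambda_{GC}$ is the median squared z-score over the $\chi^2_1$ median
($\approx 0.4549$), estimated from **intergenic** SNPs, which are relatively
depleted of true associations; using all SNPs in a polygenic trait
over-corrects. "Dividing the test statistics by $\lambda$" is ambiguous
between $z^2/\lambda$ and $z/\lambda$; the package defaults to the
chi-square convention $z^2/\lambda$ (equivalently $z/\sqrt{\lambda}$),
which is the standard genomic-control reading and makes the correction
idempotent — re-estimating $\lambda$ on corrected data returns 1. The
alternative is available via `apply_gc(..., statistic = "z")`. No lower
bound at 1 is imposed: deflation is allowed.

## Mixture models

The univariate **two-groups model** is
$f(z) = \pi_0 N(0, \sigma_0^2) + (1-\pi_0) N(0, \sigma_0^2 + \sigma_1^2)$,
fitted by EM with random restarts; the **local fdr** is $\pi_0 f_0(z)/f(z)$.
(Some prose definitions call this the posterior probability of being
*non-null*; the formula is the probability of being *null*, and that is what
the package computes.) The non-null variance component scales linearly with
effective sample size, so `scale_effective_n(fit, 2)` emulates a doubling of
effective n.

The bivariate **four-groups model** has components null/null, non-null trait
1 only, non-null trait 2 only, and non-null both. The covariance structure is
a declared parameterisation: components 0–2 are diagonal (each trait
contributes its null variance, plus its extra variance where non-null); the
pleiotropic component allows a free correlation $\rho_3$ between the two
non-null effect parts. Because the null variances are shared across
components, the M-step has no closed form; the package uses generalised EM —
exact mixing-proportion updates plus a BFGS maximisation of the expected
complete-data log-likelihood on per-component sufficient statistics, accepted
only when it improves — so the observed log-likelihood is non-decreasing,
which the tests assert. Fits are by maximum likelihood rather than posterior
sampling: point estimates are what the power analyses consume.

Numerical notes:

* Convergence: relative log-likelihood change below $10^{-8}$ (default) or
  the iteration cap. Near-boundary mixtures ($\pi_1 \sigma_1^2$ nearly
  unidentified) traverse a flat ridge where log-likelihood-based stopping
  halts before the parameters settle; recovery experiments therefore use a
  tighter tolerance ($10^{-10}$–$10^{-12}$). Signs carry no information in a
  zero-mean symmetric model, so fitting uses the z-scores as given.
* Degenerate fits ($\sigma_1^2 \to 0$, or a vanishing proportion) are
  flagged `boundary`, not raised as errors; component identity is fixed by
  the structured parameterisation (the null group is the smaller-variance
  group in the univariate model).
* When a non-null component's extra variance is too small for the data to
  distinguish it from the null, its mixing proportion sits on a
  non-identified ridge (on pure-null data the raw MLE can smear several
  percent of mass into near-duplicate components for a log-likelihood gain
  well under one unit). The four-groups fit resolves this with a parsimony
  rule: any subset of non-null components whose removal costs at most 2
  log-likelihood units per component (an AIC-style threshold) is folded into
  the null and the fit is flagged `boundary`. Real signal components cost
  orders of magnitude more and are never collapsed.
* Power curves integrate the non-null density over the rejection region on a
  fixed grid spanning $[-15, 15]$ (step 0.02 univariate, 0.06 bivariate);
  the grid normalisation error is below $10^{-6}$.

## What the simulator emulates — and what it does not

`simulate_pair()` draws component labels from the four-groups proportions,
z-scores from the component Gaussians, applies optional inflation
$z\sqrt{\lambda}$, and emits two-sided p-values with genic/intergenic labels.
The default scenario — $\pi = (0.97, 0.009, 0.009, 0.012)$, $\sigma_0^2 = 1$,
$\sigma_1^2 = 2$ per trait, $\rho_3 = 0$ — describes two highly polygenic
traits with ~1.2% of SNPs non-null in both. $\sigma_1^2 = 2$ was chosen
analytically so that roughly 1 in $10^4$ SNPs passes local fdr $\le 0.05$
unconditionally (the closed-form cut-point under the marginal two-groups
model puts the rate at $\approx 1.4\times10^{-4}$), mirroring a polygenic
architecture where nearly all signal sits below significance thresholds.
$\rho_3 = 0$ makes the point that conditional enrichment arises from shared
non-*nullness*, not correlated effect sizes.

LD is emulated at the level needed to exercise pruning: consecutive SNPs
form blocks that share a component label and have equicorrelated z-scores at
the stated within-block $r^2$ (each SNP is the scaled shared block signal
plus idiosyncratic noise from the same component distribution, preserving
marginal variances and giving every within-block pair correlation $r^2$).
The simulator does **not** model realistic human LD maps, allele
frequencies, case/control liability scales, genic enrichment of true
signal, or between-cohort heterogeneity — so passing tests demonstrate the
estimators' statistical properties under the stated generative model, not
performance on any particular real cohort.

## Problem sizes used by the test suite

The property suites run at the sizes the claims are stated for: conservativeness
of condFDR/conjFDR calls on $10^5$ SNPs under the default scenario;
two-groups recovery at $10^5$ (1% non-null, extra variance 4); four-groups
recovery of $\pi_3 = 0.012$ at $2\times10^5$; pruning equivalence against an
exhaustive greedy oracle on 1000 random instances of up to 20 SNPs; genomic
control calibration and recovery of an injected $\lambda = 1.24$ at $10^5$.
At these sizes the two-groups $\hat\sigma_1^2$ has a sampling spread of
roughly 10–20% across seeds — the $\pi_1\sigma_1^2$ product is what the data
pin down — which is why the recovery tolerance on variances is loose
relative to the one on $\pi_0$.

## Known limitations

* $\pi_0$ is fixed at 1 in the FDR estimates (by design, conservative); no
  $\pi_0$ estimation option is offered.
* Conditional FDR look-ups assume the two GWAS are independent (no shared
  samples); overlapping controls must be split upstream.
* Allele harmonisation between traits is limited to an id join with a
  discordance warning; strand flips are out of scope.
* The locus count depends on the LD reference supplied; with a different
  reference panel the same assignments can merge or split loci.
* MCMC-based posterior inference for the mixture models is out of scope;
  uncertainty in the fitted parameters is not propagated into the power
  curves.

## A worked example

```{r, eval = FALSE}
prm <- simulation_params(n_snps = 5e4, ld_block_size = 5, seed = 42)
sim <- simulate_pair(prm)
ld <- simulate_ld(prm)

gc1 <- lambda_gc_sumstats(sim$trait1)
t1 <- apply_gc(sim$trait1, gc1)
t2 <- apply_gc(sim$trait2, lambda_gc_sumstats(sim$trait2))

joined <- join_sumstats(t1, t2)
res <- condfdr_assign(joined)
loci <- significant_loci(res$snps, ld)
conj <- conjunction_loci(res$snps, ld)

qq <- conditional_qq(joined)
plot_qq(qq)
```
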