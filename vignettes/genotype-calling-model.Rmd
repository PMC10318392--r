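---
title: "Genotyping from RNA-seq allele counts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping from RNA-seq allele counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnagt)
```

## The problem

RNA-seq reads overlapping a known biallelic SNP carry either the reference
or the alternative allele, so the alternative-allele read count at a site is
informative about the genotype of the individual. Callers built for DNA
sequencing implicitly assume a binomial read model: a heterozygote should
show about half its reads on each allele. In RNA-seq two phenomena break
this assumption. Allele-specific expression (ASE) lets one chromosome's
allele be transcribed more than the other's, inflating the variance of the
heterozygote count far beyond binomial. Reference mapping bias makes reads
carrying the reference allele slightly easier to align, shifting the
heterozygote mean below one half. Both push heterozygous sites toward the
homozygous extremes and cause miscalls — which is particularly damaging when
the calls are then used for ASE analysis itself, because a homozygote
miscalled as heterozygous fabricates a strong allelic-imbalance signal.

`rnagt` addresses this by *learning* the read-count distribution of each
genotype from the data before calling anything.

## The model

For site $l$ with total depth $n_l$ and alternative count $x_l$, the
likelihood is a three-component mixture of beta-binomials, one component per
genotype $g \in \{0, 1, 2\}$ (number of alternative alleles):

$$ L = \prod_l \sum_{g=0}^{2} \theta_g \,
   \mathrm{BB}(x_l \mid n_l, \mu_g, \kappa_g), $$

where $\mathrm{BB}$ is parameterized by its mean $\mu_g = \alpha_g /
(\alpha_g + \beta_g)$ and concentration $\kappa_g = \alpha_g + \beta_g$:

$$ \mathrm{BB}(x \mid n, \mu, \kappa) = \binom{n}{x}
   \frac{B(x + \mu\kappa,\; n - x + (1-\mu)\kappa)}{B(\mu\kappa,
   (1-\mu)\kappa)}. $$

The overdispersion can equivalently be expressed as the intraclass
correlation $\lambda = 1/(1 + \kappa) \in (0,1)$; $\lambda \to 0$ recovers
the binomial. Internally the sampled scale parameter is the concentration
$\kappa$, because the Gamma prior below is coherent on that scale;
$\lambda$ is reported as a derived quantity by `mcmc_diagnostics()` and
`coef()`.

The latent genotype labels are marginalized analytically inside the
likelihood — no per-site label is ever sampled — and all probability
arithmetic is done in log space with log-sum-exp, so depths in the
thousands cause no overflow. A site with zero depth contributes a factor of
1 (log 0) to the likelihood: no data, no influence.

### Priors

$$ \theta \sim \mathrm{Dirichlet}(1,1,1), \qquad
   \mu_g \sim \mathrm{Beta}(\alpha_g, \beta_g), \qquad
   \kappa_g \sim \Gamma(\alpha_g + \beta_g,\, 1), $$

with hyperparameters $(\alpha, \beta)$ of $(1, 499)$, $(10, 10)$ and
$(499, 1)$ for the three components. These centre the component means near
$0.002$, $0.5$ and $0.998$: homozygotes produce almost pure reads of one
allele (up to sequencing/alignment error at the few-per-mille level), while
the heterozygote prior is deliberately diffuse (a Beta(10,10) on the mean,
concentration prior centred at only 20) so that ASE-driven overdispersion
and mapping-bias shifts can be absorbed. Component identity is fixed by the
ascending-mean constraint $\mu_0 < \mu_1 < \mu_2$, which both matches the
prior centres and removes label switching.

## Inference

### Training-site selection

The component parameters are shared across sites, so a modest random subset
suffices to learn them; fitting on every site would only slow the MCMC. By
default `select_training()` draws 1000 SNPs uniformly without replacement
among sites with at least 10 supporting reads (`min_depth = 10`,
inclusive). The depth filter applies to *training only*: once parameters
are learned, genotypes are called at every depth, and benchmarking applies
its own depth stratification. Whether allele-frequency or exclusion-region
filters (`filter_sites()`) are applied before training is left to the
caller; neither is hard-wired into selection.

### Sampler

`bb_fit()` samples the posterior with an adaptive Metropolis-within-Gibbs
random walk on transformed coordinates: stick-breaking logits for $\theta$
(two coordinates), $\mathrm{logit}\,\mu_g$ and $\log \kappa_g$. Each of
the eight coordinates is updated in turn with a Gaussian proposal whose
step size adapts toward a 44% acceptance rate (the scalar random-walk
optimum) during warmup via Robbins–Monro with gain $t^{-0.6}$, and is
frozen afterwards, so the kept draws come from a fixed, valid Markov
kernel. Proposals violating the $\mu$-ordering are rejected, which is
equivalent to truncating the prior to the ordered region; with the
well-separated component priors the truncated mass is negligible.

Two implementation details matter for speed. The component log-pmf matrix
is cached and only the changed column is recomputed per update, and sites
are deduplicated by their $(x, n)$ pair — the likelihood depends on a site
only through that pair, and RNA-seq counts repeat heavily (most homozygous-
reference sites are $x = 0$ at moderate depth). The kernels are in C++ but
draw random numbers from R's generator, so a fit is bitwise reproducible
from its seed: chains run sequentially from a single stream.

Defaults reproduce a standard budget: 4 chains, 1000 warmup iterations
discarded per chain, 1000 kept, i.e. 4000 posterior draws. A default fit
on 1000 training sites takes on the order of a second.

### Convergence diagnostics

`mcmc_diagnostics()` reports per-parameter posterior means, central 95%
credible intervals, split-chain $\widehat{R}$ and an effective sample size
(chain-averaged autocorrelations combined with Geyer's initial positive
sequence truncation). The fit is flagged converged when every sampled
parameter has $\widehat{R} < 1.05$. The command-line `fit` treats
non-convergence as a warning by default and as a failure under `--strict`.
Two further validations are run in the test suite: with an empty training
set the sampler must reproduce the analytic prior moments, and posterior
draws on a disputed dataset were cross-checked against an independent
plain-R Metropolis implementation built only from the (separately
oracle-verified) likelihood and prior functions.

## Calling

For a site with counts $(x, n)$, the genotype posterior is

$$ P(g \mid x, n) \propto \pi_g \cdot \frac{1}{S} \sum_{s=1}^{S}
   \mathrm{BB}(x \mid n, \mu_g^{(s)}, \kappa_g^{(s)}), $$

a Monte-Carlo average of the component likelihood over the $S$ posterior
draws. Averaging propagates parameter uncertainty into the call and
reduces overconfidence at low depth; a plug-in mode
(`method = "plugin"`, posterior means instead of draws) is provided for
speed, and the two agree closely whenever the posterior is concentrated.
This averaged-likelihood rule is a design choice of this package — it is
the standard Bayesian treatment, adopted here because the per-site rule is
the one genuinely open design point in this workflow.

The prior weights $\pi$ are the posterior-mean mixture proportions
(`prior_mode = "theta"`, default) — the only site prior the training data
themselves define — or per-site Hardy–Weinberg probabilities
$((1-f)^2, 2f(1-f), f^2)$ from a supplied effect allele frequency
(`prior_mode = "hwe"`). A zero-depth site returns $\pi$ unchanged and is
never hard-called.

From the posterior simplex come the **dosage** $P(g{=}1) + 2P(g{=}2)$
(always populated) and the **hard call**: the argmax genotype, reported
only when its probability reaches the threshold, `NA` otherwise. The
boundary is inclusive and argmax ties break toward the smaller genotype
index, for determinism. The default threshold 0.99 favours accuracy over
call volume; thresholds 0.90/0.95 trade a small accuracy loss for more
calls, and the number of non-missing calls is non-increasing in the
threshold by construction.

Because the learned parameters are decoupled from the sample they were
learned on, one fit can call genotypes in any number of samples from the
same process (`predict(fit, newdata)`, or the `call` subcommand with a
serialized model file). The test suite checks this exchangeability on
synthetic cohorts: calls made with an external sample's fit agree with
same-sample-fit calls on over 99% of hard calls.

## Baseline and benchmarking

`count_threshold_call()` is the naive comparator: with allele ratio
$r = x/n$, call 0 when $r < t$, 2 when $r > 1-t$, heterozygous in between.
The band boundaries belong to the heterozygote (an inclusive band makes the
rule total and is the convention here; at $t = 0.5$ the band degenerates to
the single point $r = 0.5$, which is why $t$ is restricted to $(0, 0.5)$).
Raising $t$ narrows the heterozygote band, so the heterozygous-call count
is monotonically non-increasing in $t$.

`concordance_by_genotype()` compares hard calls with a gold standard over
sites present in the truth set with at least `min_depth` (default 10)
supporting reads, stratified by the *truth* genotype. Missing calls are
tallied but excluded from the accuracy denominator; truth-absent sites are
never compared (so truth sets lacking homozygous-reference entries are
handled naturally). The two clinically distinct error directions are
counted separately: truth-heterozygous called homozygous (het→hom) and
truth-homozygous called heterozygous (hom→het). `accuracy_vs_depth()`
sweeps the depth filter; `dosage_concordance()` compares dosages rounded to
the nearest integer (halves away from zero — the rounding rule must be
fixed somewhere, and this choice keeps 0.5/1.5 deterministic) with integer
truth.

## The synthetic-data generator

`simulate_counts()` draws data from exactly the generative process the
model assumes: genotype from $\theta$ (or Hardy–Weinberg frequencies from
an allele frequency), depth from a fixed, Poisson (default, mean 30 —
typical exonic coverage) or negative-binomial model (adding the
between-gene coverage dispersion real RNA-seq shows), and the alternative
count from the genotype's beta-binomial. The reference defaults
$\mu = (0.002, 0.48, 0.998)$ and $\kappa = (500, 20, 500)$ encode mild
reference mapping bias (heterozygote mean below 0.5) and strong
heterozygote overdispersion from ASE, with genotype proportions
$(0.6, 0.25, 0.15)$ reflecting the homozygous-reference-dominated site
lists typical of exonic SNP panels.

What the generator deliberately does *not* emulate: alignment artifacts,
splice-junction mapping failures, position-correlated errors, sample
contamination, or multi-allelic sites. Tests passing on synthetic data
therefore demonstrate that the estimator, caller and benchmark logic are
correct *under the model's assumptions*; they cannot certify performance
on real alignments, where upstream read processing dominates data quality.

## Numerical choices and test design

* All pmf and likelihood evaluation in log space via `lgamma`; mixtures via
  log-sum-exp; no factorial overflow to depths beyond $10^6$.
* Zero-depth sites: likelihood factor 1, posterior = prior, hard call
  missing.
* GP fields in the output VCF are printed to 4 decimals and renormalized
  (residual pushed onto the largest entry) so they sum to exactly 1 after
  rounding.
* Model serialization (`write_fit()`) prints doubles with `%.17g`, making
  the text round trip exact and same-seed runs byte-identical.
* The test suite fits at reduced budgets (2 chains × a few hundred
  iterations) where only a usable posterior is needed, and at the full
  default budget for the calibration and exchangeability experiments; the
  replicate experiments use 1000-site training sets, 15 replicates for
  interval calibration and 60 for the supporting calibration study run
  during development.

One calibration subtlety is worth recording. The parameter-recovery
experiment checks that true parameters fall inside 95% credible intervals
across replicates. For a near-boundary proportion such as the
homozygous-reference mean (truth 0.002), the equal-tailed interval
evaluated on a downward-fluctuating dataset is also *narrower* (the
inferred binomial-scale variance shrinks with the estimate), so
fixed-truth coverage sits a few points below the nominal 95% even for a
perfectly correct sampler. The sampler used here was verified three ways —
large-replicate coverage near nominal, agreement with an independent
Metropolis implementation, and analytic prior recovery — so occasional
sub-13/15 coverage of that one parameter in a 15-replicate experiment
reflects this boundary effect plus Monte-Carlo noise, not an inference
defect.

## Limitations

* Biallelic SNPs only; multi-allelic and indel sites must be removed
  upstream, and the count extraction itself (mapping/base-quality filters,
  duplicate handling) is out of scope — the package starts from a counts
  table.
* One individual at a time; no joint calling, no phasing, no discovery of
  sites not in the input list.
* The three-component mixture is fixed; there is no model selection over
  component number.
* Fixed genome-wide component parameters: gene-level variation in ASE
  strength is absorbed into the single heterozygote overdispersion rather
  than modelled per gene.
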