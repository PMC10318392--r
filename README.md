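# rnagt — Bayesian genotype calling from RNA-seq allele counts

Genotyping known biallelic SNPs from RNA-seq reads is harder than from DNA:
allele-specific expression (ASE) inflates the variance of heterozygote read
counts, and reference mapping bias shifts their mean below one half, so a
binomial caller miscalls heterozygotes — and those miscalls matter most in
the very analyses (ASE, eQTL) the RNA-seq genotypes feed. `rnagt` is for
anyone with a per-site table of allele counts (from a pileup over a known
SNP list) who wants genotype posteriors that account for these RNA-seq
specific distortions.

## Model

The alternative-allele count at site *l* is modelled as a mixture of three
beta-binomial distributions, one per genotype *g* ∈ {0, 1, 2}:

L = ∏ₗ Σ_g θ_g · BB(x_l | n_l, μ_g, κ_g),

with BB parameterized by mean μ_g and concentration κ_g (equivalently
overdispersion λ_g = 1/(1+κ_g)). Priors: θ ~ Dirichlet(1,1,1),
μ_g ~ Beta(α_g, β_g), κ_g ~ Gamma(α_g+β_g, 1) with (α, β) pairs (1,499),
(10,10), (499,1) — homozygotes nearly pure, heterozygote diffuse enough to
absorb ASE and mapping bias. The mixture is learned by MCMC (adaptive
Metropolis-within-Gibbs, 4 chains × 1000 kept draws after 1000 warmup) on a
random subset of ~1000 sites with ≥ 10 reads; the learned parameters then
call genotypes at *all* sites: posterior simplex, dosage
P(g=1) + 2·P(g=2), and a hard call reported only when the top posterior
reaches a threshold (default 0.99). One fit can be reused to call many
samples from the same process. A naive allele-ratio caller
(`count_threshold_call()`) and genotype-stratified concordance
benchmarking are included.

## Worked example

```r
library(rnagt)

# synthetic sample under the model's generative process, known truth
sim <- simulate_counts(5000, theta = c(0.6, 0.25, 0.15), seed = 42)

# learn the mixture on 1000 random sites with >= 10 reads
fit <- bb_fit(select_training(sim$counts, size = 1000, min_depth = 10,
                              seed = 42), seed = 42)
fit
#> Beta-binomial genotype mixture fit
#>   1000 training sites; 4 chains x (1000 warmup + 1000 kept)
#>   posterior means:
#>     theta  = (0.597, 0.260, 0.143)
#>     mu     = (0.0023, 0.4799, 0.9987)
#>     kappa  = (498.9, 19.2, 499.7)
```

The heterozygote mean is recovered at 0.48 (the simulated reference
mapping bias), its concentration near 20 (strong ASE overdispersion), and
the genotype proportions match the simulated (0.6, 0.25, 0.15).
`summary(fit)` adds credible intervals, split-chain Rhat and effective
sample sizes per parameter.

```r
calls <- predict(fit, sim$counts, threshold = 0.99)
calls
#> Genotype calls: 5000 sites; hard-call threshold 0.99
#>   called: 4965  missing: 35
#>     site_id n_alt n_total      p_g0      p_g1      p_g2    dosage hard_call
#>  chrS:1:A:G    33      33 6.366e-52 9.971e-06 1.000e+00 2.000e+00         2
#>  chrS:2:A:G    28      29 5.344e-43 4.650e-03 9.954e-01 1.995e+00         2
#>  ...

truth <- data.frame(site_id = sim$counts$site_id, genotype = sim$genotypes)
concordance_by_genotype(calls, truth, min_depth = 10)
#> Genotype concordance (depth >= 10 )
#>  truth_genotype concordant discordant missing accuracy
#>               0       2951          0      20        1
#>               1       1263          0      10        1
#>               2        751          0       5        1
#> aggregate accuracy 1.0000 over 4965 calls (35 missing)
#> errors: het->hom 0 ; hom->het 0
```

At the 0.99 threshold every hard call made here is correct; the price is
35 sites (0.7%) left missing, mostly low-depth heterozygotes. Calls are
written with `write_calls_vcf()` (FORMAT `GT:GP:DS:DP`) or as TSV.

The same workflow runs from the shell:

```sh
exec/rnagt simulate --n-sites 5000 --seed 42 --out-dir sim
exec/rnagt fit      --counts sim/counts.tsv --train-size 1000 --seed 42 --out-dir fit
exec/rnagt call     --counts sim/counts.tsv --model fit/model.txt --out-dir calls
exec/rnagt benchmark --calls calls/calls.tsv --truth sim/truth.tsv --out-dir bench
```

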