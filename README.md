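# bdnn

Bayesian birth-death neural networks for fossil diversification analysis.

## The problem

Speciation and extinction rates vary through time and among lineages, and
that variation is usually driven by several interacting factors at once —
traits, paleoenvironment, biogeography, clade membership. Classical
birth-death models for fossil occurrence data allow one predictor at a
time, with a monotonic (typically linear or exponential) link. `bdnn`
implements a birth-death process whose lineage- and time-specific rates
are emitted by small unsupervised neural networks over an arbitrary mix
of predictors, so nonlinear responses and interactions are estimated
rather than assumed. It is aimed at paleobiologists with a richly sampled
fossil clade (tens to hundreds of species with dated occurrences) who
want to rank candidate drivers of diversification, not just test one.

## The model

For species *i* in time bin *t*, a predictor row
*x*⁽ⁱ'ᵗ⁾ = {*t*, *c*₁⁽ⁱ⁾, *c*₂⁽ⁱ⁾, …} (time, traits, phylogenetic
eigenvectors, environmental series) is mapped through two independent
networks (two tanh hidden layers, softplus output) to a speciation rate
λ⁽ⁱ'ᵗ⁾ and an extinction rate μ⁽ⁱ'ᵗ⁾. A mean-preserving output layer
φ(x, t_reg) = x^t_reg · E(x)/E(x^t_reg) shrinks rates toward their grand
mean: t_reg = 0 is the constant-rate model, t_reg = 1 no shrinkage. The
weights (standard-normal priors), t_reg (truncated Exp(1) favoring the
constant null), origination/extinction times, and the preservation
parameters of a time-variable Poisson fossilization process with
gamma-distributed among-lineage rate multipliers are all sampled by
Metropolis-Hastings against the sampled-birth-death likelihood

  P(s, e) ∝ λ(s) · μ(e) · exp(−∫ₑˢ λ + μ dt)

(the μ factor dropped for extant lineages). Post-hoc, partial-dependence
curves, permutation importance, kappa-additive SHAP values, and their
Kemeny consensus ranking identify which predictors drive the rates.
A nine-scenario forward-time simulator (constant rates, rate shifts,
temperature- and trait-dependent rates, interactions, hidden predictors)
provides the benchmark suite, with MARE / CI-coverage / calibrated-CV
metrics to score recovery.

## Worked example

```r
library(bdnn)

# simulate one benchmark dataset: a categorical trait with 5-fold rates
sim <- simulate_dataset(5, seed = 21, richness = c(100, 200))
sim$dataset
#> Occurrence dataset: 88 taxa, 761 occurrences ( 25 extant )
#> Age range: 34.614 - 0.008 Ma

# fit: joint MCMC over times, preservation, weights, and t_reg
cfg <- mcmc_config(n_iterations = 100000, sampling_freq = 500,
                   burnin = 0.25, seed = 5)
tr <- run_mcmc(sim$dataset, sim$tensor, cfg)
tr
#> BDNN posterior trace: 150 samples, 88 species, 35 time bins
#> Acceptance rates: times 1.00, weights 0.44, preservation 0.38, treg 0.40

# accuracy against the simulated truth
evaluate_fit(tr, sim$truth)$mare
#>    lambda        mu
#> 0.6096619 0.6417783

# marginal effect of the trait on extinction
pd <- partial_dependence(tr, "mu", "cat_trait")
max(pd$mean) / min(pd$mean)      # recovered fold-change (truth: 5)
#> [1] 2.839039
pd_posterior_difference(pd)      # consistency of the effect direction
#> [1] 0.9933333
```

The MARE of 0.61 means the inferred species-specific speciation rates of
this 88-species replicate deviate from the truth by 61% at the median —
per-species accuracy at this clade size and chain length is modest, and
sharpens with more occurrences and longer chains. The effect detection
is already solid: the partial-dependence fold-change of 2.8 recovers the
direction and much of the magnitude of the simulated 5-fold extinction
difference between the trait states, and the posterior puts 99%
probability on the effect's direction.

A command-line front-end wraps the same functions:

```sh
Rscript inst/cli/bdnn.R simulate --scenario 5 --replicates 1 --seed 7 --out sims
Rscript inst/cli/bdnn.R run --occurrences sims/replicate_01/occurrences.tsv \
    --traits sims/replicate_01/traits.tsv --tree sims/replicate_01/tree.nwk \
    --iterations 100000 --sample-freq 500 --seed 5 --out fit
Rscript inst/cli/bdnn.R explain --trace fit --what rank --target mu --out rank.tsv
Rscript inst/cli/bdnn.R evaluate --truth sims/replicate_01 --trace fit --out eval.tsv
```

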