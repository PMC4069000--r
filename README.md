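# abcpower

How much data does Approximate Bayesian Computation (ABC) need before it
can tell a population bottleneck from plain constant population size?
`abcpower` answers that question by simulation for the scientist designing
a population-genetic study — typically of a non-model organism — who must
decide how many individuals to sample and how many loci to sequence before
any inference about demographic history is worth attempting.

The package contains the whole pipeline:

* a compiled **Hudson coalescent-with-recombination simulator** (ancestral
  recombination graph, infinite-sites mutation, instantaneous-bottleneck
  demography) generating multi-locus haplotype datasets;
* the classic **summary statistics**: Watterson's θ, nucleotide diversity
  π, Fay & Wu's θ_H and H, Tajima's D, haplotype diversity, and the folded
  site frequency spectrum in 3 or 5 bins, aggregated across loci
  (mean, sd, 5%/95% quantiles) into named statistic sets
  (TPH, SFS3, T+SFS3, SFS5, TPH+DH);
* the **rejection-ABC engine**: standardized Euclidean distance, tolerance
  quantile acceptance, posterior model probabilities and Bayes factors,
  and Beaumont-style local-linear regression adjustment with Epanechnikov
  weights for parameter estimation;
* **experiment drivers** for power and false-positive-rate studies,
  bottleneck-severity curves, tolerance sweeps, (n × loci) design grids and
  estimation-accuracy studies, plus correlation/PCA diagnostics of the
  summary statistics.

## The models and the statistic

Two coalescent models are compared.  Under the standard neutral model
(SNM) the population size is constant; under the bottleneck model (BNM)
the relative size drops to `botNe` ∈ (0, 1] at time `botEnd = 0.2`
(coalescent units of 4N generations, looking backwards), stays there for a
fixed duration 0.1, and returns to 1.  Datasets are n haploid sequences at
unlinked 750-bp loci with per-bp θ ∈ {0.0015, 0.005} and ρ = 0.01.

A reference table is built by simulating datasets under each model with
parameters drawn from uniform priors (θ ~ U(0, 0.01), ρ ~ U(0, 0.02) per
bp; botEnd ~ U(0, 1.5), botNe ~ U(0, 1)).  For an observed dataset, the
rejection step keeps the fraction `tolerance = 0.001` of reference rows
closest in summary-statistic space; the posterior probability of each
model is its share of the accepted rows, the Bayes factor is

    BF = P(BNM | data) / P(SNM | data),

and the SNM is rejected when BF ≥ 3.  **Power** is the proportion of
BNM-true pseudo-observed replicates with BF ≥ 3; the **false-positive
rate** is the same proportion under SNM truth.

## Worked example

A small-scale power analysis (a desk-sized reference table; the study-scale
defaults are 10^6 draws and 1000 replicates):

```r
library(abcpower)

tab <- build_reference_table(n = 10, loci = 15, draws_per_model = 5000,
                             seed = 42)
sc  <- scenario(n = 10, loci = 15, theta_bp = 0.005, bot_ne = 0.1,
                stat_sets = c("TPH+DH", "SFS5"), tolerance = 0.005,
                replicates = 100, seed = 1)
run_power_scenario(sc, tab)
#> ABC model-choice power study
#>  stat_set power power_lo power_hi  fpr fpr_lo fpr_hi replicates
#>    TPH+DH  0.57   0.4722    0.663 0.02 0.0055  0.070        100
#>      SFS5  0.13   0.0776    0.210 0.00 0.0000  0.037        100
```

With 10 sequences and 15 loci of high diversity, the TPH+DH statistic set
rejects constant size for a 90% bottleneck in 57% of replicates while the
false-positive rate stays below 5% — the SFS5 set is far weaker on the
same data (at this small table and loose tolerance; power grows with both).
Estimating the bottleneck parameters for one such dataset:

```r
set.seed(7)
obs <- simulate_dataset(10, 15, 750, theta_bp = 0.005, rho_bp = 0.01,
                        dem = demography("BNM", bot_end = 0.2, bot_ne = 0.1))
fit <- abc_fit(build_stat_vector(obs, "TPH+DH"), tab, tolerance = 0.005)
coef(fit)
#>       theta         rho     bot_end      bot_ne 
#> 0.004955175 0.007741253 0.363410589 0.097127857
```

The posterior means sit near the true θ = 0.005 and botNe = 0.1, while the
weakly identified bottleneck end time is pulled toward its prior — exactly
the behavior the estimation study quantifies.

A command-line wrapper over the same functions ships in
`inst/exec/abcpower` (`simulate`, `sumstats`, `choose`, `power`,
`sweep-tolerance`, `grid`, `estimate-study`, `explore`), reading YAML
configurations and writing TSV results plus JSON run manifests.

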