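# dpmmcat

Bayesian nonparametric clustering of multivariate categorical survey
responses, for researchers who want robust subgroups *and* a measure of
how much to trust each one. The motivating application is panel-survey
data: a block of 3-point "concern" items answered by thousands of
respondents, clustered into groups of similar concern profiles that are
then profiled against a categorical outcome such as long-term party
identification.

## The method

Respondent $i$'s answers $o_i = (o_{i,1}, \dots, o_{i,D})$ follow a
Dirichlet process mixture of independent categorical distributions. The
partition prior is the Chinese restaurant process: the next respondent
joins cluster $k$ with probability $n_k/(N+\alpha)$ and opens a new
cluster with probability $\alpha/(N+\alpha)$. Cluster parameters are
integrated out, leaving the Dirichlet-categorical posterior predictive

$$F_k(o) = \prod_{d=1}^{D} \frac{n_{k,d,o_d}+\beta}{n_k+V_d\beta},$$

so a collapsed Gibbs sampler can resample the partition directly
(seating probability ∝ $n_k F_k(o)$, new cluster ∝
$\alpha \prod_d 1/V_d$). The number of clusters is inferred, not fixed.

From the retained posterior draws the package computes:

* the **median partition** — the consensus clustering minimising the mean
  *transfer distance* (minimal single-item moves between partitions, up
  to relabelling, solved via a Hungarian linear-sum-assignment reduction
  of the cluster-overlap matrix) to all draws, by greedy local search;
* **cluster stability** — per consensus cluster, the mean transfer
  similarity $TS = 1 - TD/(N-1)$ and Mirkin similarity
  $MS = 1 - 2(c+d)/N^2$ between the intact cluster and the
  sub-partitions its members form across the draws;
* **run disagreement** — the transfer distance between the median
  partitions of independently seeded chains, the practical convergence
  diagnostic;
* **cluster profiles and enrichment** — per-cluster response frequencies
  for every item and outcome-category proportions relative to the whole
  sample.

A synthetic-data generator emulates the survey structure (eleven 3-point
concern items, an employment item with a "not applicable" level, a
binary other-concerns indicator, and a party-identification outcome
dominated by "none") with known latent clusters, so every stage is
testable end to end. See `vignettes/dpmm-clustering.Rmd` for the model,
design decisions and limitations.

## Worked example

```r
library(dpmmcat)

# CRP prior: cluster sizes (5, 2, 1), concentration alpha = 2
prior_seating_probs(c(5, 2, 1), alpha = 2)
#> [1] 0.5 0.2 0.1 0.2

# transfer distance: {{1,2},{3,4}} vs {{1},{2,3,4}} — move participant 2
transfer_distance(c(1, 1, 2, 2), c(1, 2, 2, 2))
#> [1] 1

# simulate a 3-cluster survey and run the full pipeline
gen <- generator_config(n = 300, scheme = "weights", weights = c(1, 1, 1),
                        separation = 0.05, seed = 101)
survey <- generate_survey(gen)
cfg <- sampler_config(alpha = 1, beta = 1, burn_in = 50, thinning = 5,
                      n_samples = 200, n_chains = 2, seed = 202)
report <- run_analysis(survey$dataset, cfg)
print(report)
#> Consensus clustering of 300 respondents
#> Median partition: 3 clusters, mean transfer distance to draws: 0
#> Cluster sizes: 104 104 92
#> Chain medians disagree in 0 of 300 positions ( 0.00% )
#> Stability (mean TS): 1.00 1.00 1.00
truth_recovery_score(survey$truth, report$median)
#> [1] 1
```

The report says: the pooled posterior concentrates on a 3-cluster
partition (sizes 104/104/92, matching the simulation truth exactly),
both independent chains agree on every assignment, and each consensus
cluster stays intact in essentially every posterior draw (mean transfer
similarity 1.00). `report$enrichment` then gives, per cluster, how
over-represented each outcome category is relative to the whole sample
(ratio 1 = no enrichment).

## The analysis workflow

`analysis/` contains the study as numbered scripts over the package
(run from the repository root, outputs under `results/`):

1. `01_simulate.R` — synthetic survey, CRP-drawn cluster sizes
2. `02_fit.R` — two collapsed-Gibbs chains
3. `03_consensus.R` — per-chain medians, run disagreement, pooled median,
   stability
4. `04_profile.R` — cluster profiles, outcome enrichment, size-decay and
   outcome charts

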