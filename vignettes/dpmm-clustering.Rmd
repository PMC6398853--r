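---
title: "Dirichlet process clustering of categorical survey responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dirichlet process clustering of categorical survey responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpmmcat)
```

## The model

`dpmmcat` clusters N respondents described by D categorical items, where
item d has $V_d$ response options, using a Dirichlet process mixture of
independent categorical distributions. Each latent cluster k carries one
probability vector $\theta_{k,d}$ per item, and a respondent's answers
are conditionally independent given the cluster:

$$o_{i,d} \mid t_i = k \;\sim\; \mathrm{Categorical}(\theta_{k,d}),
\qquad \theta_{k,d} \sim \mathrm{Dirichlet}(\beta, \dots, \beta).$$

The partition $t_{1:N}$ follows a Chinese restaurant process (CRP) with
concentration $\alpha$: the next respondent joins an existing cluster of
size $n_k$ with probability $n_k/(N+\alpha)$ and founds a new cluster
with probability $\alpha/(N+\alpha)$. This rich-gets-richer prior is a
deliberate modelling choice for social groupings — larger groups are more
"available" — and it makes the number of clusters an inference output
rather than an input. With cluster sizes (5, 2, 1) and $\alpha = 2$:

```{r crp}
prior_seating_probs(c(5, 2, 1), alpha = 2)
```

### Collapsed sampling

The cluster parameters are integrated out analytically, so the Gibbs
sampler operates directly on partitions with only count statistics as
state. The posterior seating probability multiplies the CRP prior weight
by the Dirichlet-categorical posterior predictive

$$F_k(o) = \prod_{d=1}^{D} \frac{n_{k,d,o_d} + \beta}{n_k + V_d\,\beta},$$

where $n_{k,d,v}$ counts cluster-k members who chose option $v$ on item
$d$; an empty cluster uses the prior predictive $\prod_d 1/V_d$ (which is
independent of $\beta$). One sweep removes each respondent in ascending
index order, deletes any cluster it leaves empty (compacting ids), and
reseats it from its full conditional. Seating probabilities are computed
in log space and normalised by max-subtraction: with D = 13 items the raw
products underflow once clusters hold more than a few hundred members.

### Consensus by median partition

The sampler's output is a posterior *distribution* over partitions. The
reported solution is the median partition: the partition minimising the
mean transfer distance (TD) to the retained draws, where TD is the
minimal number of single-item moves turning one partition into the other,
up to relabelling. TD is computed by an assignment reduction: build the
cluster-overlap matrix, zero-pad it to square, and maximise the total
matched overlap with a Hungarian linear-sum-assignment solver; TD is N
minus that maximum. The greedy search cycles over items, tentatively
placing each into every existing cluster and one new cluster, and keeps a
move only if the mean distance strictly decreases; it stops after a full
cycle without improvement.

Two standardised similarities accompany the distance: the transfer
similarity $TS = 1 - TD/(N-1)$ and the Mirkin similarity
$MS = 1 - 2(c+d)/N^2$, with $c$ and $d$ the discordantly paired item
counts. Cluster stability restricts every draw to the members of one
consensus cluster and averages the similarity between that intact block
and the induced sub-partitions; by construction it measures how often a
consensus cluster is *split* across the posterior, with TS undefined for
singleton clusters (the formula divides by $|C| - 1$).

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 1 | CRP concentration; larger favours more clusters a priori |
| `beta` | 1 | Dirichlet base-measure concentration per response option |
| `burn_in` | 500 | discarded initial sweeps |
| `thinning` | 160 | keep every 160th sweep after burn-in |
| `n_samples` | 2048 | retained draws per chain (S) |
| `n_chains` | 2 | independent chains, pooled for the consensus |

The sampling defaults are the full-survey protocol (two independent runs
at $\alpha = 1$, burn-in 500, thinning 160, S = 2048). They are
hours-scale at N in the thousands; the examples, tests and analysis
scripts in this package use a reduced protocol (burn-in 50, thinning 5,
S = 200, two chains) which changes nothing structurally. The tests run
the recovery study at n = 300 with three equally weighted clusters and
profile separation $\gamma = 0.05$; the analysis scripts use n = 1000
with CRP-drawn cluster sizes.

The base-measure concentration $\beta$ is not pinned down by the
protocol this package re-implements; $\beta = 1$ (uniform base measure)
is the conventional uninformative choice and yields the
$\prod_d 1/V_d$ prior predictive. It is exposed in `sampler_config()`.

## Initialisation: a design note

Two sequential initial placements are plausible: prior-only (CRP weights
alone) and posterior (likelihood-weighted) seating. The package defaults
to the **prior-only** start (`init_with_likelihood = FALSE`) and this is
a considered choice. Likelihood-weighted sequential seating makes early
decisions with tiny counts, where the smoothed predictive cannot
distinguish profiles sharply; with realistic item blocks it fuses two
well-separated clusters in a substantial fraction of runs. That fused
table is then effectively absorbing for a one-item-at-a-time Gibbs
sampler: moving the first member out to a new table costs a factor of
roughly $\prod_d V_d^{-1}$ against staying, about $e^{-14}$ for the
13-item block, so the chain never splits it within any practical run
length. The prior-only start instead begins from an overdispersed state
with roughly $\alpha \log N$ tables that *differentiate* — items migrate
between existing tables, which requires no improbable new-table moves —
and recovers planted structure reliably. Overdispersed initialisation is
standard MCMC practice for exactly this reason.

The same mechanism is the model's main known failure mode at small N:
with only a handful of items' worth of evidence per table, chains can
still collapse clusters together during the first sweeps (single-site
samplers cannot split; the package deliberately ships no split-merge
moves). Running multiple chains and inspecting `run_disagreement` is the
intended diagnostic: disagreeing medians flag exactly this.

## The synthetic generator

`generate_survey()` emulates the shape of a panel survey's concern block:
eleven 3-point concern items, one employment-safety item with a fourth
"not applicable" category (keeping non-employed respondents without
missing data, as the model requires complete codes), and a binary
other-concerns indicator. Cluster labels come either from a CRP
($\alpha_{gen}$, giving the steeply decaying size sequence the prior
implies) or from explicit weights; per-cluster response profiles are
drawn from symmetric Dirichlet($\gamma$) per dimension, with small
$\gamma$ (default 0.05) giving near-one-hot, well-separated profiles. At
$\gamma = 0.01$–$0.05$ most profiles are one-hot but a minority of
cluster–item combinations still draw genuinely mixed profiles; tests
therefore bound the *bulk* of within-cluster agreement, not every item.
The categorical outcome (eight party-identification categories) puts
roughly 50% mass on "none" in every cluster with one over-represented
party per cluster, mimicking the reported pattern shape — a large
no-identification group with selected clusters tilted towards single
parties — without copying any data-bound numbers.

Because items are conditionally independent given the cluster — exactly
the mixture's own likelihood assumption — recovery tests on this
generator check the inference machinery, not robustness: they say nothing
about real survey data, where items correlate within clusters, responses
are ordinal rather than unordered, and no finite set of "true" clusters
exists. Passing them means the sampler, consensus search and stability
measures do what they claim under the model's own assumptions.

## Numerical and procedural choices

* **Canonical labelling.** Clusters are numbered by decreasing size, ties
  broken by the smallest member index, so "cluster 1" is always the
  largest and reports are deterministic.
* **Strict-decrease acceptance** in the median search (ties rejected)
  prevents cycling; the summed distance over draws is integer-valued, so
  the comparison is exact. Within an item's scan the best improving
  target is taken, lowest cluster id on ties, items in ascending order —
  deterministic, with the same fixed points as first-improvement
  scanning.
* **Initial candidate** for the median search: the retained draw with the
  smallest mean distance to all draws (deterministic, already near the
  optimum); a random-draw start is available.
* **Assignment ties.** Equally optimal cluster matchings can exist in the
  LSAP; TD is matching-invariant, so results do not depend on the
  tie-break.
* **Seeds.** A master seed spawns per-chain child seeds; identical seeds
  give bitwise-identical chains, medians and reports.
* **Degenerate inputs.** N = 1 partitions are valid (TS needs N ≥ 2);
  singleton consensus clusters report Mirkin stability only; empty
  sample lists and mismatched lengths are rejected with explicit errors.

## Limitations

* Single-site collapsed Gibbs cannot split fused clusters; see the
  initialisation note. Chain disagreement is the diagnostic.
* The greedy median search is a local optimiser. On small instances the
  test suite compares it against exhaustive search over all set
  partitions (it attains the optimum on majority-structure sample sets
  and is never worse than its starting candidate), but no global
  optimality guarantee exists at scale.
* No hyperparameter inference: $\alpha$ and $\beta$ are fixed inputs.
* Ordinal structure of 3-point items is ignored (categories are
  unordered), and enrichment ratios are descriptive — no testing is done
  on them.
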