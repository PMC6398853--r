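#' Sampler configuration
#'
#' Settings of the collapsed Gibbs sampler. The defaults mirror the
#' sampling protocol used for the full survey analysis: concentration
#' `alpha = 1`, burn-in of 500 sweeps, thinning factor 160, `S = 2048`
#' retained draws per chain and two independent chains. `beta` is the
#' per-option concentration of the symmetric Dirichlet base measure over
#' each dimension's response probabilities; `beta = 1` (uniform) gives the
#' prior predictive `prod_d 1/V_d` for an empty cluster.
#'
#' @param alpha CRP concentration parameter, > 0. Larger values favour
#'   more clusters a priori.
#' @param beta Dirichlet base-measure concentration per response option, > 0.
#' @param burn_in number of initial sweeps discarded, >= 0.
#' @param thinning keep every `thinning`-th sweep after burn-in, >= 1.
#' @param n_samples number of retained draws per chain (S), >= 1.
#' @param n_chains number of independent chains, >= 1.
#' @param seed master seed; per-chain child seeds are derived from it.
#' @param prior_only if `TRUE`, the likelihood is dropped and the sampler
#'   targets the bare Chinese restaurant process (used for calibration).
#' @param init_with_likelihood if `FALSE` (default) the sequential initial
#'   placement uses the CRP prior alone, which starts the chain from an
#'   overdispersed state with more tables than clusters; if `TRUE` it
#'   weights tables by likelihood times size (the posterior seating rule).
#'   Likelihood-weighted placement can fuse two well-separated clusters
#'   while tables are still small, and the one-item-at-a-time Gibbs moves
#'   essentially never split such a fused table afterwards, so the
#'   prior-only start is the safer default.
#' @param random_scan if `TRUE`, each sweep visits items in a fresh random
#'   order; default is fixed ascending order for reproducibility.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(alpha = 1, beta = 1, burn_in = 500, thinning = 160,
                           n_samples = 2048, n_chains = 2, seed = 1L,
                           prior_only = FALSE, init_with_likelihood = FALSE,
                           random_scan = FALSE) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (beta <= 0) stop("`beta` must be positive")
  if (burn_in < 0) stop("`burn_in` must be non-negative")
  if (thinning < 1) stop("`thinning` must be a positive integer")
  if (n_samples < 1) stop("`n_samples` must be a positive integer")
  if (n_chains < 1) stop("`n_chains` must be a positive integer")
  structure(
    list(alpha = alpha, beta = beta, burn_in = as.integer(burn_in),
         thinning = as.integer(thinning), n_samples = as.integer(n_samples),
         n_chains = as.integer(n_chains), seed = as.integer(seed),
         prior_only = isTRUE(prior_only),
         init_with_likelihood = isTRUE(init_with_likelihood),
         random_scan = isTRUE(random_scan)),
    class = "sampler_config"
  )
}

#' CRP prior seating probabilities
#'
#' Probability that the next person joins each existing table or founds a
#' new one under the Chinese restaurant process: table `k` with `n_k`
#' guests is chosen with probability `n_k / (N + alpha)` and a new table
#' with probability `alpha / (N + alpha)`, where `N = sum(sizes)`.
#'
#' @param sizes vector of current cluster sizes (all >= 1); may be empty,
#'   in which case a new table is chosen with probability 1.
#' @param alpha CRP concentration parameter, > 0.
#' @return probability vector of length `length(sizes) + 1`; the last
#'   entry is the new-table probability. Sums to 1.
#' @examples
#' prior_seating_probs(c(5, 2, 1), alpha = 2)  # 0.50 0.20 0.10 0.20
#' @export
prior_seating_probs <- function(sizes, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a positive scalar")
  }
  if (length(sizes) > 0L && any(sizes <= 0)) {
    stop("all cluster sizes must be positive")
  }
  c(sizes, alpha) / (sum(sizes) + alpha)
}

#' Sufficient statistics of a clustered dataset
#'
#' Per-cluster response tallies used by the collapsed sampler: for cluster
#' `k`, dimension `d` and option `v`, `counts[[k]][[d]][v]` is the number
#' of cluster members who chose option `v` on item `d`. Tallies in every
#' dimension sum to the cluster size.
#'
#' @param data a [categorical_dataset()].
#' @param partition partition of the dataset's rows.
#' @return an object of class `cluster_state` with elements `sizes`,
#'   `counts` and `assignments`.
#' @export
cluster_state <- function(data, partition) {
  stopifnot(inherits(data, "categorical_dataset"))
  p <- as_partition(partition)
  if (length(p) != data$n) stop("partition length must equal the number of rows")
  K <- max(p)
  counts <- lapply(seq_len(K), function(k) {
    rows <- data$responses[p == k, , drop = FALSE]
    lapply(seq_len(data$d), function(d) {
      tabulate(rows[, d], nbins = data$category_counts[d])
    })
  })
  structure(
    list(sizes = tabulate(p, K), counts = counts, assignments = p),
    class = "cluster_state"
  )
}

#' Posterior-predictive likelihood of one response vector
#'
#' Closed form of the Dirichlet-categorical predictive obtained by
#' integrating the per-cluster response probabilities out against a
#' symmetric Dirichlet with per-option concentration `beta`: for an
#' occupied cluster the per-dimension factor is
#' `(n_{k,d,o_d} + beta) / (n_k + V_d beta)`; for an empty cluster it is
#' the prior predictive `1 / V_d` (independent of `beta`).
#'
#' @param obs length-D vector of response codes (1-based).
#' @param category_counts length-D vector of options per dimension.
#' @param counts per-dimension tally vectors of the target cluster, as one
#'   element of `cluster_state()$counts`; `NULL` means an empty cluster.
#' @param beta base-measure concentration, > 0.
#' @return likelihood in (0, 1\].
#' @export
predictive_likelihood <- function(obs, category_counts, counts = NULL, beta = 1) {
  if (beta <= 0) stop("`beta` must be positive")
  d <- length(category_counts)
  if (length(obs) != d) stop("`obs` must have one code per dimension")
  if (any(obs < 1L) || any(obs > category_counts)) {
    stop("response codes must lie in 1..V_d")
  }
  if (is.null(counts)) return(prod(1 / category_counts))
  nk <- sum(counts[[1L]])
  f <- vapply(seq_len(d), function(j) {
    (counts[[j]][obs[j]] + beta) / (nk + category_counts[j] * beta)
  }, numeric(1))
  prod(f)
}

#' Posterior seating probabilities for one unseated item
#'
#' Combines the CRP prior with the Dirichlet-categorical predictive: table
#' `k` is chosen with probability proportional to
#' `F_k(obs) * n_k` and a new table with probability proportional to
#' `F_new(obs) * alpha`. This is the full conditional the Gibbs sampler
#' draws from when reseating an item; it is exposed for inspection and
#' testing of the seating rule.
#'
#' @param obs length-D response vector of the item to seat.
#' @param state a [cluster_state()] whose tallies exclude the item.
#' @param category_counts options per dimension.
#' @param alpha CRP concentration, > 0.
#' @param beta base-measure concentration, > 0.
#' @return normalized probability vector of length K + 1 (last entry =
#'   new cluster).
#' @export
seating_probs <- function(obs, state, category_counts, alpha = 1, beta = 1) {
  prior <- prior_seating_probs(state$sizes, alpha)
  K <- length(state$sizes)
  lik <- c(
    vapply(seq_len(K), function(k) {
      predictive_likelihood(obs, category_counts, state$counts[[k]], beta)
    }, numeric(1)),
    predictive_likelihood(obs, category_counts, NULL, beta)
  )
  w <- prior * lik
  w / sum(w)
}

#' Run the collapsed Gibbs sampler
#'
#' Draws partitions from the posterior of the Dirichlet process mixture of
#' independent categorical distributions. Each chain seats the items
#' sequentially into an initially empty state using the posterior seating
#' rule, performs `burn_in` discarded sweeps, then retains every
#' `thinning`-th of the following sweeps until `n_samples` draws are kept.
#' A sweep removes each item in turn from its cluster (deleting emptied
#' clusters) and reseats it from its full conditional. Chains are
#' independent, with child seeds derived deterministically from
#' `config$seed`; results are fully reproducible.
#'
#' @param data a [categorical_dataset()].
#' @param config a [sampler_config()].
#' @return an object of class `sample_chain`: list with `partitions` (an
#'   `n_chains * n_samples` x N integer matrix, one retained draw per
#'   row), `chain` (chain index per row), `k_trace` (cluster count per
#'   retained draw), `config` and `child_seeds`.
#' @export
run_chain <- function(data, config) {
  stopifnot(inherits(data, "categorical_dataset"),
            inherits(config, "sampler_config"))
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  parts <- vector("list", config$n_chains)
  ktr <- vector("list", config$n_chains)
  for (j in seq_len(config$n_chains)) {
    set.seed(child_seeds[j])
    res <- run_chain_cpp(
      data$responses - 1L, data$category_counts,
      config$alpha, config$beta, config$burn_in, config$thinning,
      config$n_samples, config$prior_only, config$init_with_likelihood,
      config$random_scan
    )
    parts[[j]] <- res$partitions
    ktr[[j]] <- res$k_trace
  }
  structure(
    list(partitions = do.call(rbind, parts),
         chain = rep(seq_len(config$n_chains), each = config$n_samples),
         k_trace = unlist(ktr),
         config = config,
         child_seeds = child_seeds),
    class = "sample_chain"
  )
}

#' @export
print.sample_chain <- function(x, ...) {
  cat("Posterior partition sample:", nrow(x$partitions), "draws (",
      x$config$n_chains, "chain(s) x", x$config$n_samples, ") over",
      ncol(x$partitions), "items\n")
  cat("Cluster counts: ", paste(range(x$k_trace), collapse = "-"),
      " (median ", stats::median(x$k_trace), ")\n", sep = "")
  invisible(x)
}
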