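# Synthetic survey generator: panel-style categorical concern items with a
# latent cluster structure and a cluster-conditional party-identification
# outcome, so the whole pipeline is testable without restricted survey data.

#' Default item specification
#'
#' Thirteen categorical dimensions shaped like a panel survey's block of
#' concern items: eleven 3-point concern areas, one employment-safety item
#' with a fourth "not applicable" level (respondents without current
#' employment), and one binary indicator for freely reported other
#' concerns.
#'
#' @return data frame with columns `label` and `levels`.
#' @export
default_item_spec <- function() {
  concerns <- c("economy_general", "economy_own", "finance_markets",
                "own_health", "environment", "climate_change",
                "peacekeeping", "terrorism", "crime",
                "immigration", "xenophobia")
  data.frame(
    label = c(concerns, "employment_safety", "other_concerns"),
    levels = c(rep(3L, length(concerns)), 4L, 2L)
  )
}

# Default cluster-conditional outcome: eight party-identification
# categories with "none" at ~50% everywhere and each cluster tilted
# towards one party (cycling through the parties by cluster index).
default_outcome_spec <- function(n_clusters) {
  categories <- c("none", "cdu_csu", "spd", "greens", "left", "fdp",
                  "afd", "other")
  parties <- categories[-1L]
  probs <- matrix(0, n_clusters, length(categories),
                  dimnames = list(NULL, categories))
  for (k in seq_len(n_clusters)) {
    fav <- parties[(k - 1L) %% length(parties) + 1L]
    p <- stats::setNames(rep(0.25 / (length(parties) - 1L), length(parties)),
                         parties)
    p[fav] <- 0.25
    probs[k, ] <- c(none = 0.5, p)
  }
  list(categories = categories, probs = probs)
}

#' Generator configuration
#'
#' Describes a synthetic survey: sample size, how latent cluster sizes
#' arise, the item block, how well separated the per-cluster response
#' profiles are, and the cluster-conditional outcome.
#'
#' @param n number of respondents, >= 1.
#' @param scheme `"crp"` draws cluster labels from a Chinese restaurant
#'   process with concentration `alpha_gen` (rich-gets-richer sizes that
#'   decay steeply); `"weights"` draws them i.i.d. from explicit cluster
#'   `weights`.
#' @param alpha_gen CRP concentration for the `"crp"` scheme, > 0.
#' @param weights vector of positive cluster weights for the `"weights"`
#'   scheme (normalized internally); its length sets the number of
#'   clusters.
#' @param item_spec data frame with columns `label` and `levels`
#'   (`levels >= 2`); defaults to [default_item_spec()].
#' @param separation concentration `gamma > 0` of the symmetric Dirichlet
#'   from which each cluster's per-dimension response profile is drawn.
#'   Small values (default 0.05) give near-deterministic, well-separated
#'   profiles; large values make clusters overlap.
#' @param outcome_spec `NULL` for no outcome, `"default"` for the built-in
#'   party-identification pattern (eight categories dominated by "none",
#'   one over-represented party per cluster), or a list with `categories`
#'   and a per-cluster `probs` matrix whose rows sum to 1.
#' @param seed integer seed; the draw is fully reproducible.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n, scheme = c("crp", "weights"), alpha_gen = 1,
                             weights = NULL, item_spec = default_item_spec(),
                             separation = 0.05, outcome_spec = "default",
                             seed = 1L) {
  scheme <- match.arg(scheme)
  if (n < 1) stop("`n` must be at least 1")
  if (separation <= 0) stop("`separation` must be positive")
  if (scheme == "crp" && alpha_gen <= 0) stop("`alpha_gen` must be positive")
  if (scheme == "weights") {
    if (is.null(weights) || any(weights <= 0)) {
      stop("`weights` must be a vector of positive cluster weights")
    }
    weights <- weights / sum(weights)
  }
  if (!is.data.frame(item_spec) ||
      !all(c("label", "levels") %in% names(item_spec))) {
    stop("`item_spec` must be a data frame with columns `label` and `levels`")
  }
  if (any(item_spec$levels < 2L)) stop("every item needs at least 2 levels")
  if (is.list(outcome_spec)) {
    if (!all(c("categories", "probs") %in% names(outcome_spec))) {
      stop("`outcome_spec` needs elements `categories` and `probs`")
    }
    if (any(abs(rowSums(outcome_spec$probs) - 1) > 1e-8)) {
      stop("each row of `outcome_spec$probs` must sum to 1")
    }
  }
  structure(
    list(n = as.integer(n), scheme = scheme, alpha_gen = alpha_gen,
         weights = weights, item_spec = item_spec, separation = separation,
         outcome_spec = outcome_spec, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# One draw from a symmetric Dirichlet(gamma) of dimension v via normalized
# gammas; for very small gamma the draws can underflow to all zeros, in
# which case the limiting one-hot profile is returned.
rdirichlet_sym <- function(v, gamma) {
  g <- stats::rgamma(v, shape = gamma, rate = 1)
  if (sum(g) == 0) {
    p <- rep(0, v)
    p[sample.int(v, 1L)] <- 1
    return(p)
  }
  g / sum(g)
}

# Sequential CRP draw of n cluster labels with concentration alpha.
crp_labels <- function(n, alpha) {
  labels <- integer(n)
  sizes <- integer(0)
  for (i in seq_len(n)) {
    k <- sample.int(length(sizes) + 1L, 1L,
                    prob = prior_seating_probs(sizes, alpha))
    if (k > length(sizes)) sizes <- c(sizes, 0L)
    sizes[k] <- sizes[k] + 1L
    labels[i] <- k
  }
  labels
}

#' Generate a synthetic survey with known cluster structure
#'
#' Draws latent cluster labels per the configured scheme, one response
#' profile per cluster and dimension from a symmetric
#' Dirichlet(`separation`), then responses independently per dimension
#' given the cluster, and finally the outcome from the cluster's outcome
#' distribution. Items are conditionally independent given the cluster —
#' exactly the mixture model's own likelihood assumption. Clusters that
#' receive no members are dropped and the truth relabelled; the returned
#' truth partition is canonical (clusters ordered by size).
#'
#' @param cfg a [generator_config()].
#' @return list with `dataset` (a [categorical_dataset()], outcome
#'   attached when configured) and `truth` (list with the canonical true
#'   `partition`, per-cluster `profiles` — one per-dimension probability
#'   vector list per cluster — and `outcome_probs`).
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  labels <- switch(cfg$scheme,
    crp = crp_labels(cfg$n, cfg$alpha_gen),
    weights = sample.int(length(cfg$weights), cfg$n, replace = TRUE,
                         prob = cfg$weights)
  )
  labels <- canonicalize_partition(labels)  # drops empty, orders by size
  K <- max(labels)
  V <- cfg$item_spec$levels
  D <- length(V)
  profiles <- lapply(seq_len(K), function(k) {
    lapply(seq_len(D), function(d) rdirichlet_sym(V[d], cfg$separation))
  })
  responses <- matrix(0L, cfg$n, D,
                      dimnames = list(NULL, cfg$item_spec$label))
  for (k in seq_len(K)) {
    rows <- which(labels == k)
    for (d in seq_len(D)) {
      responses[rows, d] <- sample.int(V[d], length(rows), replace = TRUE,
                                       prob = profiles[[k]][[d]])
    }
  }
  outcome <- NULL
  outcome_probs <- NULL
  spec <- cfg$outcome_spec
  if (identical(spec, "default")) spec <- default_outcome_spec(K)
  if (is.list(spec)) {
    if (nrow(spec$probs) < K) {
      stop("`outcome_spec$probs` needs one row per realized cluster (", K, ")")
    }
    outcome_probs <- spec$probs[seq_len(K), , drop = FALSE]
    outcome <- character(cfg$n)
    for (k in seq_len(K)) {
      rows <- which(labels == k)
      outcome[rows] <- sample(spec$categories, length(rows), replace = TRUE,
                              prob = outcome_probs[k, ])
    }
    outcome <- factor(outcome, levels = spec$categories)
  }
  dataset <- categorical_dataset(responses, category_counts = V,
                                 item_labels = cfg$item_spec$label,
                                 outcome = outcome)
  list(dataset = dataset,
       truth = list(partition = labels, profiles = profiles,
                    outcome_probs = outcome_probs))
}

#' Transfer-similarity recovery score against the generating truth
#'
#' @param truth the `truth` element of [generate_survey()] (or any
#'   partition).
#' @param estimate estimated partition of the same items.
#' @return [transfer_similarity()] between the true and estimated
#'   partitions, in \[0, 1\] (1 = perfect recovery up to relabelling).
#' @export
truth_recovery_score <- function(truth, estimate) {
  p <- if (is.list(truth)) truth$partition else truth
  transfer_similarity(p, estimate)
}
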