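# Consensus (median) partition over posterior draws and per-cluster
# stability under the transfer and Mirkin similarities.

# Accepts a sample_chain, a draws x N matrix, or a list of partitions and
# returns a draws x N integer matrix of 0-based labels for the C++ core.
sample_matrix <- function(samples) {
  if (inherits(samples, "sample_chain")) samples <- samples$partitions
  if (is.list(samples)) {
    if (length(samples) == 0L) stop("`samples` must contain at least one partition")
    samples <- do.call(rbind, lapply(samples, as_partition))
  }
  if (!is.matrix(samples)) stop("`samples` must be a matrix, list or sample_chain")
  if (nrow(samples) == 0L) stop("`samples` must contain at least one partition")
  storage.mode(samples) <- "integer"
  samples
}

#' Mean transfer distance from a candidate to a set of partitions
#'
#' @param candidate partition of N items.
#' @param samples a [run_chain()] result, a draws x N matrix with one
#'   partition per row, or a list of partitions.
#' @return arithmetic mean of `transfer_distance(candidate, s)` over the
#'   sampled partitions `s`.
#' @export
mean_distance <- function(candidate, samples) {
  candidate <- as_partition(candidate)
  samples <- sample_matrix(samples)
  if (ncol(samples) != length(candidate)) {
    stop("candidate and samples must cover the same items")
  }
  mean_distance_cpp(candidate - 1L, samples - 1L)
}

#' Median partition of a set of sampled partitions
#'
#' Greedy local search for the consensus partition minimising the mean
#' transfer distance to the sampled partitions. Starting from an initial
#' candidate, the search cycles over items in ascending order; each item
#' is tentatively placed into every existing cluster and one new cluster,
#' and the move is kept only if the mean distance strictly decreases (the
#' best such move is taken, lowest cluster id on ties). The search stops
#' when a full cycle over all items accepts no move.
#'
#' By default the initial candidate is the sampled partition with the
#' smallest mean distance to all draws, which is deterministic and already
#' close to the optimum; `init = "random"` picks a random draw instead
#' (set a seed for reproducibility), and an explicit partition may also be
#' supplied.
#'
#' @param samples a [run_chain()] result, matrix of draws, or list of
#'   partitions (pooled across chains).
#' @param init `"best"`, `"random"`, or an explicit initial partition.
#' @return the canonical median partition, with attributes
#'   `mean_distance` (its mean transfer distance to the draws) and
#'   `trace` (mean distance after each accepted move; non-increasing).
#' @export
median_partition <- function(samples, init = c("best", "random")) {
  samples <- sample_matrix(samples)
  if (is.character(init)) {
    init <- match.arg(init)
    idx <- switch(init,
      best = best_sample_cpp(samples - 1L),
      random = sample.int(nrow(samples), 1L)
    )
    cand <- samples[idx, ]
  } else {
    cand <- as_partition(init)
    if (length(cand) != ncol(samples)) {
      stop("initial candidate must cover the same items as the samples")
    }
  }
  res <- median_partition_cpp(samples - 1L, as_partition(cand) - 1L)
  out <- canonicalize_partition(res$assignments)
  attr(out, "mean_distance") <- res$mean_distance
  attr(out, "trace") <- res$trace
  out
}

#' Per-cluster stability of a consensus partition
#'
#' For each cluster C of the median partition, every sampled partition is
#' restricted to C's members, inducing a sub-partition; the stability of C
#' is the mean similarity between the single block C and these induced
#' sub-partitions, under the transfer similarity (with N replaced by |C|)
#' and the Mirkin similarity. Singleton clusters have no defined transfer
#' similarity (the formula divides by |C| - 1) and are reported with
#' `mean_ts = NA` and Mirkin similarity only.
#'
#' @param median consensus partition (canonicalized internally).
#' @param samples a [run_chain()] result, matrix of draws, or list of
#'   partitions.
#' @return data frame with one row per median cluster: `cluster`, `size`,
#'   `mean_ts`, `mean_ms`; similarities lie in \[0, 1\].
#' @export
cluster_stability <- function(median, samples) {
  med <- canonicalize_partition(median)
  samples <- sample_matrix(samples)
  if (ncol(samples) != length(med)) {
    stop("median and samples must cover the same items")
  }
  K <- max(med)
  rows <- lapply(seq_len(K), function(k) {
    members <- which(med == k)
    csize <- length(members)
    sub <- samples[, members, drop = FALSE]
    # block vs induced sub-partition: TD = |C| - largest sub-cluster;
    # Mirkin: 1 - (|C|^2 - sum tab^2)/|C|^2 = sum(tab^2)/|C|^2
    stats <- apply(sub, 1L, function(s) {
      tab <- tabulate(match(s, unique(s)))
      c(max(tab), sum(tab^2))
    })
    ts <- if (csize > 1L) mean(1 - (csize - stats[1L, ]) / (csize - 1)) else NA_real_
    ms <- mean(stats[2L, ] / csize^2)
    data.frame(cluster = k, size = csize, mean_ts = ts, mean_ms = ms)
  })
  do.call(rbind, rows)
}

#' Disagreement between two consensus partitions
#'
#' The minimal number of items whose cluster assignment must change to
#' turn one median partition into the other (their transfer distance),
#' reported as an absolute count and as a fraction of N. Used to compare
#' the medians of independently run chains.
#'
#' @param median_a,median_b partitions of the same items.
#' @return list with `count` (integer) and `fraction` (`count / N`).
#' @export
run_disagreement <- function(median_a, median_b) {
  a <- as_partition(median_a)
  b <- as_partition(median_b)
  if (length(a) != length(b)) stop("partitions must have the same length")
  td <- transfer_distance(a, b)
  list(count = td, fraction = td / length(a))
}
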