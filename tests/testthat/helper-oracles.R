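# Brute-force oracles, independent of the package's LSAP / transfer-distance
# code paths: exhaustive permutation search, restricted-growth enumeration of
# set partitions, direct pair counting, and the exact CRP partition law.

# All permutations of 1..n as a matrix (one per row); n <= 7.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Exhaustive LSAP: minimal assignment cost over all permutations.
brute_lsap <- function(cost) {
  n <- nrow(cost)
  perms <- all_perms(n)
  costs <- numeric(nrow(perms))
  for (i in seq_len(n)) costs <- costs + cost[i, ][perms[, i]]
  list(cost = min(costs), perm = perms[which.min(costs), ])
}

# Exhaustive transfer distance: N minus the maximal total overlap over all
# one-to-one matchings of (zero-padded) clusters.
brute_transfer_distance <- function(p1, p2) {
  p1 <- match(p1, unique(p1))
  p2 <- match(p2, unique(p2))
  k1 <- max(p1)
  k2 <- max(p2)
  m <- max(k1, k2)
  ov <- matrix(0L, m, m)
  for (i in seq_along(p1)) ov[p1[i], p2[i]] <- ov[p1[i], p2[i]] + 1L
  perms <- all_perms(m)
  overlaps <- numeric(nrow(perms))
  for (i in seq_len(m)) overlaps <- overlaps + ov[i, ][perms[, i]]
  as.integer(length(p1) - max(overlaps))
}

# Direct O(N^2) pair-counting Mirkin similarity.
brute_mirkin <- function(p1, p2) {
  n <- length(p1)
  cd <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same1 <- p1[i] == p1[j]
      same2 <- p2[i] == p2[j]
      if (xor(same1, same2)) cd <- cd + 1L
    }
  }
  1 - 2 * cd / n^2
}

# All set partitions of n items as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    k <- if (length(labels)) max(labels) else 0L
    for (j in seq_len(k + 1L)) grow(c(labels, j))
  }
  grow(integer(0))
  out
}

# Exact CRP partition probability: alpha^K prod_k (n_k - 1)! / prod_i (alpha + i).
crp_eppf <- function(p, alpha) {
  sizes <- tabulate(match(p, unique(p)))
  n <- length(p)
  exp(length(sizes) * log(alpha) + sum(lfactorial(sizes - 1)) -
        sum(log(alpha + 0:(n - 1))))
}

# Random partition with labels drawn uniformly (then compacted).
random_partition <- function(n, max_k = n) {
  x <- sample.int(max_k, n, replace = TRUE)
  match(x, unique(x))
}

# Tiny well-separated two-cluster dataset used in several sampler tests.
make_two_cluster_data <- function(n_per = 30L, seed = 42L) {
  cfg <- generator_config(n = 2L * n_per, scheme = "weights", weights = c(1, 1),
                          separation = 0.01, seed = seed)
  generate_survey(cfg)
}
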