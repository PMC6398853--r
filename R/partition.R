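#' Coerce a vector of cluster labels to a partition
#'
#' A partition of `n` items is represented as an integer vector of cluster
#' ids. Arbitrary labels (integers, characters, factors) are accepted and
#' relabelled to consecutive ids `1..K`: numeric labels keep their relative
#' order (so a vector that is already labelled `1..K` passes through
#' unchanged), other labels are numbered by first appearance. Use
#' [canonicalize_partition()] for the size-ordered canonical labelling.
#'
#' @param x vector of cluster labels, one per item; no missing values.
#' @return integer vector of cluster ids in `1..K`.
#' @examples
#' as_partition(c("a", "a", "b", "a"))
#' @export
as_partition <- function(x) {
  if (length(x) < 1L) stop("a partition needs at least one item")
  if (anyNA(x)) stop("cluster labels must not contain missing values")
  if (is.numeric(x)) {
    if (any(x != round(x))) stop("numeric cluster labels must be whole numbers")
    xi <- as.integer(x)
    u <- sort(unique(xi))
    if (u[1L] == 1L && u[length(u)] == length(u)) return(xi)
    return(match(xi, u))
  }
  as.integer(match(x, unique(x)))
}

#' Cluster sizes of a partition
#'
#' @param p partition (see [as_partition()]).
#' @return integer vector, entry `k` = number of items with id `k`.
#' @export
cluster_sizes <- function(p) {
  p <- as_partition(p)
  tabulate(p, nbins = max(p))
}

#' Canonical size-ordered labelling of a partition
#'
#' Relabels clusters so that sizes are non-increasing in the cluster id,
#' with ties broken by the smallest member index. Cluster 1 is always the
#' largest cluster; assignments are otherwise unchanged. Idempotent.
#'
#' @param p partition.
#' @return canonically labelled partition.
#' @examples
#' canonicalize_partition(c(3L, 3L, 1L))  # -> 1 1 2
#' @export
canonicalize_partition <- function(p) {
  p <- as_partition(p)
  sizes <- tabulate(p)
  first <- match(seq_along(sizes), p)
  ord <- order(-sizes, first)
  as.integer(match(p, ord))
}

#' Solve a linear sum assignment problem
#'
#' Finds the permutation minimising the total cost of assigning each row of
#' a square cost matrix to a distinct column (Hungarian method, O(n^3)).
#' Negative and non-integer costs are supported.
#'
#' @param cost square numeric matrix with finite entries.
#' @return integer permutation `a`, where row `i` is assigned to column
#'   `a[i]`; the attribute `"cost"` holds the minimal total cost.
#' @examples
#' solve_lsap(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
solve_lsap <- function(cost) {
  if (!is.matrix(cost) || !is.numeric(cost)) {
    stop("`cost` must be a numeric matrix")
  }
  if (nrow(cost) != ncol(cost)) stop("`cost` must be square")
  if (any(!is.finite(cost))) stop("`cost` must have finite entries")
  perm <- solve_lsap_cpp(cost)
  structure(perm, cost = sum(cost[cbind(seq_len(nrow(cost)), perm)]))
}

#' Cluster overlap matrix of two partitions
#'
#' Entry (i, j) counts the items in cluster i of `p1` and cluster j of
#' `p2`; row sums are the cluster sizes of `p1`, column sums those of `p2`.
#'
#' @param p1,p2 partitions of the same items.
#' @return K1 x K2 integer matrix.
#' @export
partition_overlap <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  if (length(p1) != length(p2)) stop("partitions must have the same length")
  k1 <- max(p1)
  k2 <- max(p2)
  m <- matrix(0L, k1, k2)
  tab <- table(factor(p1, levels = seq_len(k1)), factor(p2, levels = seq_len(k2)))
  m[] <- as.integer(tab)
  m
}

#' Transfer distance between two partitions
#'
#' The minimum number of single-item moves needed to turn one partition
#' into the other, up to relabelling of clusters. Computed as N minus the
#' maximal total cluster overlap under an optimal one-to-one matching of
#' clusters: the overlap matrix is zero-padded to square and the matching
#' solved as a linear sum assignment on the negated overlaps.
#'
#' @param p1,p2 partitions of the same items.
#' @return non-negative integer; 0 iff the partitions are identical up to
#'   relabelling. Symmetric in its arguments and at most `N - 1`.
#' @examples
#' transfer_distance(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 1: move item 2
#' @export
transfer_distance <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  if (length(p1) != length(p2)) stop("partitions must have the same length")
  transfer_distance_cpp(p1 - 1L, p2 - 1L)
}

#' Transfer similarity between two partitions
#'
#' The transfer distance standardised to \[0, 1\]:
#' `TS = 1 - TD / (N - 1)`. 1 means identical up to relabelling, 0 maximal
#' dissimilarity (e.g. all singletons versus one block).
#'
#' @param p1,p2 partitions of the same `N >= 2` items.
#' @return real in \[0, 1\].
#' @export
transfer_similarity <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  if (length(p1) != length(p2)) stop("partitions must have the same length")
  n <- length(p1)
  if (n < 2L) stop("transfer similarity requires at least 2 items")
  1 - transfer_distance(p1, p2) / (n - 1)
}

#' Mirkin similarity between two partitions
#'
#' Pair-counting similarity `MS = 1 - 2 (c + d) / N^2`, where `c` counts
#' item pairs together in `p1` but separated in `p2` and `d` vice versa
#' (the Mirkin metric is `2 (c + d)`). Computed from the overlap matrix:
#' with row sums `a`, column sums `b`, `2 (c + d) = sum(a^2) + sum(b^2) -
#' 2 sum(n_ij^2)`.
#'
#' @param p1,p2 partitions of the same items.
#' @return real in \[0, 1\]; 1 iff identical up to relabelling.
#' @export
mirkin_similarity <- function(p1, p2) {
  ov <- partition_overlap(p1, p2)
  n <- sum(ov)
  m <- sum(rowSums(ov)^2) + sum(colSums(ov)^2) - 2 * sum(ov^2)
  1 - m / n^2
}

#' Read or write a partition
#'
#' Partitions are serialised either as a single-column CSV of integer
#' cluster ids (header `cluster`, row order = item order) or as a JSON
#' array. `read_partition()` accepts either format (chosen by extension)
#' and canonicalizes on load.
#'
#' @param p partition to write.
#' @param path file path ending in `.csv` or `.json`.
#' @return `read_partition()` returns a canonical partition;
#'   `write_partition()` returns `path` invisibly.
#' @export
write_partition <- function(p, path) {
  p <- as_partition(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(p, path)
  } else {
    utils::write.csv(data.frame(cluster = p), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path)[[1L]]
  }
  canonicalize_partition(as_partition(x))
}
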