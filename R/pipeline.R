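# End-to-end analysis: sample -> consensus -> stability -> profiles.

#' Per-cluster response and outcome profiles
#'
#' For each cluster of a partition, the proportion of members choosing
#' each response option of each item, and (when the dataset carries an
#' outcome) the proportion in each outcome category. Clusters follow the
#' canonical size ordering.
#'
#' @param data a [categorical_dataset()].
#' @param partition partition of the dataset's rows (canonicalized
#'   internally).
#' @return an object of class `cluster_profiles`: a list with one entry
#'   per cluster, each a list with `cluster`, `size`, `item_freq` (named
#'   list of per-option proportion vectors, each summing to 1) and
#'   `outcome_freq` (named proportion vector, or `NULL` without outcome).
#' @export
profile_clusters <- function(data, partition) {
  stopifnot(inherits(data, "categorical_dataset"))
  p <- canonicalize_partition(partition)
  if (length(p) != data$n) stop("partition length must equal the number of rows")
  out <- lapply(seq_len(max(p)), function(k) {
    rows <- which(p == k)
    item_freq <- lapply(seq_len(data$d), function(d) {
      tab <- tabulate(data$responses[rows, d], nbins = data$category_counts[d])
      stats::setNames(tab / length(rows),
                      paste0("option_", seq_len(data$category_counts[d])))
    })
    names(item_freq) <- data$item_labels
    outcome_freq <- NULL
    if (!is.null(data$outcome)) {
      tab <- table(data$outcome[rows])
      outcome_freq <- as.vector(tab) / length(rows)
      names(outcome_freq) <- names(tab)
    }
    list(cluster = k, size = length(rows), item_freq = item_freq,
         outcome_freq = outcome_freq)
  })
  structure(out, class = "cluster_profiles")
}

#' Outcome enrichment of a cluster relative to the whole sample
#'
#' Ratio of the cluster's outcome proportions to the whole-sample
#' proportions: 1 means no enrichment, > 1 an over-represented category
#' (e.g. a party chosen far more often inside the cluster than overall).
#' Categories with zero overall proportion are undefined and returned as
#' `NA`.
#'
#' @param profile one cluster's entry of [profile_clusters()].
#' @param overall the whole-sample profile (a single-block partition's
#'   only entry).
#' @return named numeric vector of per-category ratios.
#' @export
outcome_enrichment <- function(profile, overall) {
  pf <- profile$outcome_freq
  ov <- overall$outcome_freq
  if (is.null(pf) || is.null(ov)) stop("both profiles need outcome frequencies")
  if (!identical(names(pf), names(ov))) stop("outcome categories must match")
  ratio <- ifelse(ov > 0, pf / ov, NA_real_)
  stats::setNames(ratio, names(pf))
}

#' Run the full clustering analysis
#'
#' Orchestrates the pipeline on one dataset: runs the configured chains,
#' computes per-chain median partitions and their pairwise disagreement
#' (when more than one chain is run), the pooled-sample median partition,
#' per-cluster stability on the pooled median, cluster profiles, outcome
#' enrichment against the whole sample, and the cluster-size sequence.
#' Fully reproducible given `config$seed`.
#'
#' @param data a [categorical_dataset()].
#' @param config a [sampler_config()].
#' @param median_init initial candidate rule for [median_partition()].
#' @return an object of class `analysis_report`; see Details.
#' @details The report is a list with elements `median` (pooled canonical
#'   median partition), `mean_distance`, `cluster_sizes`, `stability`
#'   (data frame from [cluster_stability()]), `profiles`,
#'   `overall_profile`, `enrichment` (clusters x outcome-category matrix,
#'   or `NULL` without outcome), `chain_medians`, `run_disagreement`
#'   (data frame of pairwise chain disagreements, `NULL` for a single
#'   chain), `k_trace`, `config` and `child_seeds`.
#' @export
run_analysis <- function(data, config, median_init = "best") {
  chain <- run_chain(data, config)
  chain_medians <- lapply(seq_len(config$n_chains), function(j) {
    median_partition(chain$partitions[chain$chain == j, , drop = FALSE],
                     init = median_init)
  })
  disagreement <- NULL
  if (config$n_chains > 1L) {
    pairs <- utils::combn(config$n_chains, 2L)
    disagreement <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(m) {
      d <- run_disagreement(chain_medians[[pairs[1L, m]]],
                            chain_medians[[pairs[2L, m]]])
      data.frame(chain_a = pairs[1L, m], chain_b = pairs[2L, m],
                 count = d$count, fraction = d$fraction)
    }))
  }
  med <- median_partition(chain, init = median_init)
  stability <- cluster_stability(med, chain)
  profiles <- profile_clusters(data, med)
  overall <- profile_clusters(data, rep(1L, data$n))[[1L]]
  enrichment <- NULL
  if (!is.null(data$outcome)) {
    enrichment <- do.call(rbind, lapply(profiles, outcome_enrichment,
                                        overall = overall))
    rownames(enrichment) <- paste0("cluster_", seq_len(nrow(enrichment)))
  }
  structure(
    list(median = med,
         mean_distance = attr(med, "mean_distance"),
         cluster_sizes = cluster_sizes(med),
         stability = stability,
         profiles = profiles,
         overall_profile = overall,
         enrichment = enrichment,
         chain_medians = chain_medians,
         run_disagreement = disagreement,
         k_trace = chain$k_trace,
         config = config,
         child_seeds = chain$child_seeds),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  k <- length(x$cluster_sizes)
  cat("Consensus clustering of", length(x$median), "respondents\n")
  cat("Median partition:", k, "clusters, mean transfer distance to draws:",
      round(x$mean_distance, 2), "\n")
  cat("Cluster sizes:", paste(x$cluster_sizes, collapse = " "), "\n")
  if (!is.null(x$run_disagreement)) {
    cat("Chain medians disagree in", x$run_disagreement$count[1L], "of",
        length(x$median), "positions (",
        sprintf("%.2f%%", 100 * x$run_disagreement$fraction[1L]), ")\n")
  }
  st <- x$stability
  cat("Stability (mean TS):",
      paste(sprintf("%.2f", st$mean_ts), collapse = " "), "\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serialises the report as machine-readable JSON (full precision) plus
#' flat CSV tables: the median partition, the stability table, and one
#' long table of per-cluster item/outcome frequencies rounded for human
#' reading.
#'
#' @param report an [run_analysis()] result.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_partition(report$median, file.path(dir, "median_partition.csv"))
  utils::write.csv(report$stability, file.path(dir, "stability.csv"),
                   row.names = FALSE)
  freq <- do.call(rbind, lapply(report$profiles, function(pr) {
    item_rows <- do.call(rbind, lapply(names(pr$item_freq), function(lbl) {
      f <- pr$item_freq[[lbl]]
      data.frame(cluster = pr$cluster, size = pr$size, variable = lbl,
                 category = names(f), proportion = round(unname(f), 4))
    }))
    if (!is.null(pr$outcome_freq)) {
      item_rows <- rbind(item_rows, data.frame(
        cluster = pr$cluster, size = pr$size, variable = "outcome",
        category = names(pr$outcome_freq),
        proportion = round(unname(pr$outcome_freq), 4)))
    }
    item_rows
  }))
  utils::write.csv(freq, file.path(dir, "cluster_frequencies.csv"),
                   row.names = FALSE)
  json <- list(
    config = unclass(report$config),
    child_seeds = report$child_seeds,
    median = as.integer(report$median),
    mean_distance = report$mean_distance,
    cluster_sizes = report$cluster_sizes,
    stability = report$stability,
    run_disagreement = report$run_disagreement,
    enrichment = report$enrichment
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
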