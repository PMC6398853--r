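#!/usr/bin/env Rscript
# Step 4: profile the consensus clusters. Per-cluster response
# distributions for every concern item, outcome (party-identification)
# distributions, and enrichment ratios against the whole sample; plus a
# bar chart of the cluster-size decay and the largest clusters' outcome
# mix.
#
# Reads:  results/survey.csv, results/median_partition.csv
# Writes: results/cluster_frequencies.csv, results/enrichment.csv,
#         results/cluster_sizes.png, results/outcome_profiles.png

suppressPackageStartupMessages(library(dpmmcat))

data <- read_dataset("results/survey.csv")
med <- read_partition("results/median_partition.csv")

profiles <- profile_clusters(data, med)
overall <- profile_clusters(data, rep(1L, data$n))[[1]]

enrich <- do.call(rbind, lapply(profiles, outcome_enrichment, overall = overall))
rownames(enrich) <- paste0("cluster_", seq_len(nrow(enrich)))
utils::write.csv(enrich, "results/enrichment.csv")

freq <- do.call(rbind, lapply(profiles, function(pr) {
  rows <- do.call(rbind, lapply(names(pr$item_freq), function(lbl) {
    f <- pr$item_freq[[lbl]]
    data.frame(cluster = pr$cluster, size = pr$size, variable = lbl,
               category = names(f), proportion = unname(f))
  }))
  rbind(rows, data.frame(cluster = pr$cluster, size = pr$size,
                         variable = "party_identification",
                         category = names(pr$outcome_freq),
                         proportion = unname(pr$outcome_freq)))
}))
utils::write.csv(freq, "results/cluster_frequencies.csv", row.names = FALSE)

sizes <- vapply(profiles, `[[`, integer(1), "size")
grDevices::png("results/cluster_sizes.png", 700, 450)
graphics::barplot(sizes, names.arg = seq_along(sizes),
                  xlab = "Cluster (ordered by size)", ylab = "Members",
                  main = "Cluster-size decay of the consensus partition")
grDevices::dev.off()

top <- utils::head(profiles, 4L)
grDevices::png("results/outcome_profiles.png", 900, 600)
graphics::par(mfrow = c(2, 2), mar = c(7, 4, 3, 1))
for (pr in top) {
  graphics::barplot(pr$outcome_freq, las = 2,
                    ylab = "Proportion", ylim = c(0, 1),
                    main = sprintf("Cluster %d (n = %d)", pr$cluster, pr$size))
}
grDevices::dev.off()

cat("Whole-sample outcome distribution:\n")
print(round(overall$outcome_freq, 3))
for (pr in utils::head(profiles, 4L)) {
  e <- enrich[pr$cluster, ]
  topcat <- names(sort(e[names(e) != "none"], decreasing = TRUE))[1]
  cat(sprintf(
    "Cluster %d (n = %d): '%s' at %.1f%% vs %.1f%% overall (enrichment %.2f)\n",
    pr$cluster, pr$size, topcat, 100 * pr$outcome_freq[topcat],
    100 * overall$outcome_freq[topcat], e[topcat]))
}
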