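#!/usr/bin/env Rscript
# Step 1: simulate a panel-style concern survey with a latent cluster
# structure. Cluster sizes follow a Chinese restaurant process (alpha = 1),
# so they decay steeply from the largest cluster; response profiles are
# well separated (gamma = 0.05); the party-identification outcome is
# dominated by "none" with one over-represented party per cluster.
#
# Writes: results/survey.csv (+ .schema.json), results/truth.json

suppressPackageStartupMessages(library(dpmmcat))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- generator_config(n = 1000L, scheme = "crp", alpha_gen = 1,
                        separation = 0.05, seed = 20260901L)
survey <- generate_survey(cfg)

write_dataset(survey$dataset, file.path(out_dir, "survey.csv"))
jsonlite::write_json(
  list(partition = survey$truth$partition,
       cluster_sizes = cluster_sizes(survey$truth$partition),
       outcome_probs = survey$truth$outcome_probs),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

sizes <- cluster_sizes(survey$truth$partition)
cat("Simulated", survey$dataset$n, "respondents x", survey$dataset$d, "items\n")
cat("True clusters:", length(sizes), "with sizes", paste(sizes, collapse = " "), "\n")
cat("Rich-gets-richer decay: largest cluster holds",
    sprintf("%.1f%%", 100 * sizes[1] / sum(sizes)), "of the sample\n")
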