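#!/usr/bin/env Rscript
# Step 2: draw posterior partitions with the collapsed Gibbs sampler.
# Two independent chains, concentration alpha = 1, uniform base measure
# (beta = 1). Desk-scale protocol: burn-in 50 sweeps, thinning 5, S = 200
# retained draws per chain (the full-survey protocol of burn-in 500 /
# thinning 160 / S = 2048 is hours-scale and changes nothing structurally).
#
# Reads:  results/survey.csv (+ schema)
# Writes: results/chains.jsonl (one retained partition per line, as a
#         JSON array), results/chain_meta.json

suppressPackageStartupMessages(library(dpmmcat))

data <- read_dataset("results/survey.csv")
cfg <- sampler_config(alpha = 1, beta = 1, burn_in = 50L, thinning = 5L,
                      n_samples = 200L, n_chains = 2L, seed = 20260902L)

t0 <- Sys.time()
chain <- run_chain(data, cfg)
elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

writeLines(apply(chain$partitions, 1L, function(p) {
  as.character(jsonlite::toJSON(as.integer(p)))
}), "results/chains.jsonl")
jsonlite::write_json(
  list(config = unclass(cfg), child_seeds = chain$child_seeds,
       chain = chain$chain, k_trace = chain$k_trace),
  "results/chain_meta.json", auto_unbox = TRUE, digits = NA)

print(chain)
cat(sprintf("Sampling took %.1f s\n", elapsed))
cat("Cluster-count trace by chain:\n")
print(tapply(chain$k_trace, chain$chain, function(k) {
  c(min = min(k), median = stats::median(k), max = max(k))
}))
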