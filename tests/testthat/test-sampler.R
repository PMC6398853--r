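test_that("CRP seating probabilities match the worked example and sum to 1", {
  expect_equal(prior_seating_probs(c(5, 2, 1), alpha = 2),
               c(0.50, 0.20, 0.10, 0.20))
  expect_equal(prior_seating_probs(numeric(0), alpha = 3), 1)
  expect_equal(prior_seating_probs(c(1, 1), alpha = 1), rep(1 / 3, 3))
  set.seed(23)
  for (rep in 1:50) {
    sizes <- sample(1:20, sample(1:8, 1L), replace = TRUE)
    alpha <- runif(1, 0.01, 10)
    pr <- prior_seating_probs(sizes, alpha)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_equal(pr[length(pr)], alpha / (sum(sizes) + alpha))
  }
  expect_error(prior_seating_probs(c(2, 0), 1), "positive")
  expect_error(prior_seating_probs(c(2, 1), -1), "positive")
})

test_that("predictive likelihood has the stated closed form", {
  # empty cluster: prior predictive prod 1/V_d, independent of beta
  expect_equal(predictive_likelihood(c(1, 2), c(3, 3)), 1 / 9)
  expect_equal(predictive_likelihood(c(1, 2), c(3, 3), beta = 0.3), 1 / 9)
  # occupied cluster of 2 with unanimous first-option responses
  resp <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  data <- categorical_dataset(resp, category_counts = c(3L, 3L))
  st <- cluster_state(data, c(1L, 1L))
  f <- predictive_likelihood(c(1L, 1L), c(3L, 3L), st$counts[[1]], beta = 1)
  expect_equal(f, (2 + 1) / (2 + 3) * (1 + 1) / (2 + 3))
  expect_error(predictive_likelihood(c(4, 1), c(3, 3)), "1..V_d")
})

test_that("predictive likelihood sums to 1 over all response vectors", {
  specs <- list(c(2L, 3L), c(3L, 3L, 3L), c(4L, 2L, 3L))
  set.seed(29)
  for (V in specs) {
    grid <- as.matrix(expand.grid(lapply(V, seq_len)))
    # empty cluster
    tot <- sum(apply(grid, 1L, predictive_likelihood, category_counts = V))
    expect_equal(tot, 1, tolerance = 1e-10)
    # occupied cluster with random tallies
    n <- 7L
    resp <- sapply(V, function(v) sample.int(v, n, replace = TRUE))
    data <- categorical_dataset(resp, category_counts = V)
    st <- cluster_state(data, rep(1L, n))
    for (beta in c(0.5, 1, 2)) {
      tot <- sum(apply(grid, 1L, predictive_likelihood, category_counts = V,
                       counts = st$counts[[1]], beta = beta))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("predictive likelihood agrees with Monte-Carlo Dirichlet integration", {
  set.seed(31)
  V <- c(3L, 4L)
  n <- 6L
  resp <- sapply(V, function(v) sample.int(v, n, replace = TRUE))
  data <- categorical_dataset(resp, category_counts = V)
  st <- cluster_state(data, rep(1L, n))
  beta <- 0.7
  obs <- c(2L, 3L)
  closed <- predictive_likelihood(obs, V, st$counts[[1]], beta)
  # draw theta from the posterior Dirichlet per dimension, average the
  # likelihood of obs under theta
  M <- 20000L
  draws <- sapply(seq_along(V), function(d) {
    a <- st$counts[[1]][[d]] + beta
    g <- matrix(rgamma(M * V[d], shape = rep(a, each = M)), M, V[d])
    th <- g / rowSums(g)
    th[, obs[d]]
  })
  vals <- draws[, 1] * draws[, 2]
  mc <- mean(vals)
  se <- sd(vals) / sqrt(M)
  expect_lt(abs(closed - mc), 3 * se + 1e-12)
})

test_that("posterior seating rule is symmetric for exchangeable clusters", {
  # two clusters with identical sizes and tallies must get equal probability
  resp <- rbind(matrix(1L, 4, 3), matrix(2L, 4, 3))
  data <- categorical_dataset(resp, category_counts = c(3L, 3L, 3L))
  st <- cluster_state(data, rep(c(1L, 2L), each = 4L))
  pr <- seating_probs(c(3L, 3L, 3L), st, data$category_counts,
                      alpha = 1, beta = 1)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(pr[1], pr[2])
  # alpha -> 0: the new-cluster option vanishes
  pr0 <- seating_probs(c(1L, 1L, 1L), st, data$category_counts,
                       alpha = 1e-12, beta = 1)
  expect_lt(pr0[3], 1e-10)
})

test_that("chains are reproducible and produce valid compact partitions", {
  fix <- make_two_cluster_data(10L)
  cfg <- sampler_config(burn_in = 10L, thinning = 2L, n_samples = 25L,
                        n_chains = 2L, seed = 99L)
  a <- run_chain(fix$dataset, cfg)
  b <- run_chain(fix$dataset, cfg)
  expect_identical(a, b)
  expect_identical(dim(a$partitions), c(50L, 20L))
  for (s in seq_len(nrow(a$partitions))) {
    p <- a$partitions[s, ]
    expect_identical(sort(unique(p)), seq_len(max(p)))  # compact labels
  }
  expect_identical(a$k_trace, apply(a$partitions, 1L, max))
  # on overlapping data, independent chains produce genuinely different draws
  noisy <- generate_survey(generator_config(n = 20L, scheme = "weights",
                                            weights = c(1, 1), separation = 5,
                                            seed = 17L))
  nz <- run_chain(noisy$dataset, cfg)
  expect_false(identical(nz$partitions[1:25, ], nz$partitions[26:50, ]))
})

test_that("a single respondent always sits alone", {
  data <- categorical_dataset(matrix(c(1L, 2L), 1, 2),
                              category_counts = c(3L, 3L))
  cfg <- sampler_config(burn_in = 5L, thinning = 1L, n_samples = 10L,
                        n_chains = 1L, seed = 1L)
  res <- run_chain(data, cfg)
  expect_true(all(res$partitions == 1L))
})

test_that("prior-only sampler matches the CRP expected cluster count", {
  # E[K] for the CRP with alpha = 1 over N = 100 items
  n <- 100L
  expected_k <- sum(1 / (1 + 0:(n - 1)))
  data <- categorical_dataset(matrix(sample.int(3L, n * 2L, replace = TRUE), n, 2L),
                              category_counts = c(3L, 3L))
  cfg <- sampler_config(alpha = 1, burn_in = 50L, thinning = 10L,
                        n_samples = 500L, n_chains = 1L, seed = 7L,
                        prior_only = TRUE)
  res <- run_chain(data, cfg)
  k <- res$k_trace
  se <- sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - expected_k), 3 * se)
})

test_that("prior-only draws follow the exact CRP partition law", {
  # N = 4, alpha = 1: compare retained-draw frequencies over all 15
  # partitions with the exchangeable partition probability function
  n <- 4L
  alpha <- 1
  data <- categorical_dataset(matrix(1:2, n, 2L), category_counts = c(2L, 2L))
  cfg <- sampler_config(alpha = alpha, burn_in = 20L, thinning = 2L,
                        n_samples = 4000L, n_chains = 1L, seed = 5L,
                        prior_only = TRUE)
  res <- run_chain(data, cfg)
  parts <- all_partitions(n)
  keys <- vapply(parts, paste, character(1), collapse = "")
  drawn <- apply(res$partitions, 1L, function(p) {
    paste(match(p, unique(p)), collapse = "")
  })
  counts <- table(factor(drawn, levels = keys))
  probs <- vapply(parts, crp_eppf, numeric(1), alpha = alpha)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  gof <- suppressWarnings(chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 1e-3)
})

test_that("the sampler recovers two well-separated clusters", {
  fix <- make_two_cluster_data(30L)
  cfg <- sampler_config(burn_in = 25L, thinning = 2L, n_samples = 100L,
                        n_chains = 1L, seed = 12L)
  res <- run_chain(fix$dataset, cfg)
  ts <- apply(res$partitions, 1L, function(p) {
    transfer_similarity(fix$truth$partition, p)
  })
  expect_gte(mean(ts >= 0.9), 0.95)
})

test_that("configuration constraints are enforced", {
  expect_error(sampler_config(alpha = 0), "alpha")
  expect_error(sampler_config(beta = -1), "beta")
  expect_error(sampler_config(thinning = 0), "thinning")
  expect_error(sampler_config(n_samples = 0), "n_samples")
  expect_error(sampler_config(burn_in = -1), "burn_in")
})
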