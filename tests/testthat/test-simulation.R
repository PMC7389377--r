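test_that("trajectory simulation honours deterministic and absorbing cases", {
  P <- rbind(a = c(0, 1, 0), b = c(0, 0, 1), d = c(0, 0, 1))
  colnames(P) <- rownames(P)
  ch <- markov_chain(P, "d")
  tr <- simulate_trajectories(ch, "a", 5, seed = 1)
  expect_equal(unname(tr$states), matrix(rep(c(1L, 2L, 3L), each = 5), 5))
  expect_false(tr$truncated)

  # starting in the absorbing state: constant trajectory
  tr2 <- simulate_trajectories(ch, "d", 3, horizon = 4, seed = 1)
  expect_true(all(tr2$states == 3L))
  expect_equal(ncol(tr2$states), 5L)

  expect_error(simulate_trajectories(ch, "zzz", 5), "unknown start state")
})

test_that("one-step frequencies reproduce the transition row", {
  ch <- illness_death_chain()
  tr <- simulate_trajectories(ch, "H", 30000, horizon = 1, seed = 2)
  freq <- tabulate(tr$states[, 2], 3) / 30000
  p <- ch$P["H", ]
  se <- sqrt(p * (1 - p) / 30000)
  expect_true(all(abs(freq - p) < 4 * se))
})

test_that("empirical episode statistics match hand counts", {
  sts <- hid_states()
  X <- matrix(c("H", "I", "I", "H", "I", "D"), nrow = 1)
  em <- empirical_episode_stats(X, "I", states = sts)
  expect_equal(unname(em$episodes["mean"]), 2)
  expect_equal(unname(em$occupancy["mean"]), 3)
  expect_equal(unname(em$avg_length["mean"]), 1.5)
  expect_equal(unname(em$exits_all["mean"]), 2)       # I->H and I->D
  expect_equal(unname(em$exits_recovery["mean"]), 1)  # only I->H

  # a run already in progress at t = 0 is not an entry by default
  X2 <- matrix(c("I", "I", "D"), nrow = 1)
  em2 <- empirical_episode_stats(X2, "I", states = sts)
  expect_equal(unname(em2$episodes["mean"]), 0)
  expect_equal(unname(em2$occupancy["mean"]), 2)
  em3 <- empirical_episode_stats(X2, "I", states = sts,
                                 count_initial_episode = TRUE)
  expect_equal(unname(em3$episodes["mean"]), 1)
})

test_that("analytic episode quantities agree with the Monte-Carlo oracle", {
  set.seed(2024)
  for (rep in 1:3) {
    chain <- random_absorbing_chain(sample(2:3, 1), 1, min_absorbing = 0.08)
    tgt <- "T2"
    tr <- simulate_trajectories(chain, "T1", 30000)
    em <- empirical_episode_stats(tr, tgt)
    s <- suppressWarnings(episode_summary(chain, tgt))
    row <- which(s$start == "T1")
    for (q in c("episodes", "occupancy", "exits_all", "exits_recovery")) {
      z <- (em[[q]]["mean"] - s[[q]][row]) / max(em[[q]]["se"], 1e-12)
      expect_lt(abs(z), 4)
    }
  }
})

test_that("generated panels recover the generating chain", {
  ch <- illness_death_chain()
  pan <- generate_panel(ch, 2000, 30, seed = 61)
  ch_hat <- mle_probabilities(count_transitions(pan))
  expect_lt(max(abs(ch_hat$P - ch$P)), 0.03)

  # deterministic generator: one known block
  P <- rbind(a = c(0, 1, 0), b = c(0, 0, 1), d = c(0, 0, 1))
  colnames(P) <- rownames(P)
  det <- generate_panel(markov_chain(P, "d"), 1, 5, seed = 1)
  expect_equal(det$state_seqs[[1]], c(1L, 2L, 3L))  # truncated at absorption

  # seed determinism
  pan2 <- generate_panel(ch, 2000, 30, seed = 61)
  expect_identical(pan$state_seqs, pan2$state_seqs)

  expect_error(generate_panel(ch, 10, 5, initial_distribution = c(H = 0.5)),
               "probability vector")
})

test_that("heterogeneous panels mix private chains per individual", {
  ch <- illness_death_chain()
  # single component degenerates to the homogeneous generator's law
  cfg1 <- heterogeneous_config(1500, 6, components = list(ch), seed = 3)
  p1 <- mle_probabilities(count_transitions(generate_heterogeneous_panel(cfg1)))
  expect_lt(max(abs(p1$P - ch$P)), 0.05)

  # two components with distinct illness incidence: pooled estimate falls
  # strictly between the component rows
  mk <- function(p_hi) {
    P <- rbind(H = c(0.97 - p_hi, p_hi, 0.03), I = c(0.2, 0.7, 0.1),
               D = c(0, 0, 1))
    colnames(P) <- rownames(P)
    markov_chain(P, "D")
  }
  cfg2 <- heterogeneous_config(3000, 3, components = list(mk(0.05), mk(0.25)),
                               weights = c(0.5, 0.5), seed = 9)
  pooled <- mle_probabilities(count_transitions(generate_heterogeneous_panel(cfg2)))
  expect_gt(pooled$P["H", "I"], 0.05)
  expect_lt(pooled$P["H", "I"], 0.25)
  expect_lt(abs(pooled$P["H", "I"] - 0.15), 0.03)

  # logit-normal scheme with sigma = 0 leaves the base chain untouched
  cfg3 <- heterogeneous_config(1200, 6, base_chain = ch, sigma = 0,
                               scheme = "logit_normal", seed = 4)
  p3 <- mle_probabilities(count_transitions(generate_heterogeneous_panel(cfg3)))
  expect_lt(max(abs(p3$P - ch$P)), 0.05)

  # sigma > 0 produces valid panels
  cfg4 <- heterogeneous_config(50, 5, base_chain = ch, sigma = 0.5,
                               scheme = "logit_normal", seed = 5)
  expect_s3_class(generate_heterogeneous_panel(cfg4), "panel_data")

  expect_error(heterogeneous_config(10, 5, components = list()), "non-empty")
})

test_that("the bias harness reports both methods and flags tiny samples", {
  sc <- default_bias_scenarios(n_individuals = 20, n_steps = 30)
  res <- variance_bias_harness(sc["homogeneous"], n_datasets = 5,
                               n_replicates = 50, seed = 17)
  expect_equal(nrow(res), 2)
  expect_setequal(res$method, c("block", "model_based"))
  expect_true(all(is.finite(res$rel_bias)))
  expect_true(all(res$small_sample))  # 20 blocks: flagged unreliable
  expect_true(all(res$coverage >= 0 & res$coverage <= 1))

  res2 <- variance_bias_harness(sc$heterogeneous, n_datasets = 4,
                                n_replicates = 40, seed = 18)
  expect_match(res2$truth_source[1], "pseudo-truth")
  expect_error(variance_bias_harness(list()), "must not be empty")
})

test_that("random absorbing chains are valid and keep absorption moderate", {
  set.seed(12)
  for (rep in 1:10) {
    ch <- random_absorbing_chain(sample(2:4, 1), sample(1:2, 1))
    expect_s3_class(ch, "markov_chain")
    absorbing_mass <- rowSums(ch$P[seq_len(ch$states$n),
                                   ch$states$is_absorbing, drop = FALSE])
    expect_true(all(absorbing_mass >= 0.05 - 1e-12))
    expect_true(all(absorbing_mass <= 0.10 + 1e-12))
  }
})
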