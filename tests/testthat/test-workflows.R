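test_that("the estimation workflow produces both estimation routes", {
  est <- estimate_transitions(panel_data(toy_panel_df(), hid_states()),
                              step_length = 1, units = "day")
  expect_equal(est$chain_mle$P["H", "I"], 2 / 3)
  expect_equal(est$rates$Q["H", "I"], 2 / 3, tolerance = 1e-12)
  expect_equal(rowSums(est$chain$P), setNames(rep(1, 3), c("H", "I", "D")),
               tolerance = 1e-10)

  # on a slow chain (small per-step rates) the two routes nearly coincide
  Q <- rbind(H = c(0, 0.03, 0.01), I = c(0.05, 0, 0.02), D = c(0, 0, 0))
  colnames(Q) <- rownames(Q)
  slow <- rates_to_probabilities(rate_matrix(Q, "D"))
  est2 <- estimate_transitions(generate_panel(slow, 400, 40, seed = 13))
  expect_lt(max(abs(est2$chain$P - est2$chain_mle$P)), 0.02)
})

test_that("episode reports bound occupancy by the horizon and refuse
           absorbing targets", {
  chain <- rates_to_probabilities(synthetic_frailty_rates())
  rep60 <- episode_report(chain, c("mild", "severe"), horizon = 60,
                          step_length = 1, units = "months")
  expect_true(all(rep60$expectancies$total <= 60 + 1e-9))
  expect_true(all(as.matrix(rep60$expectancies[, c("none", "mild", "severe")]) <= 60))
  expect_equal(rep60$episodes$occupancy,
               rep60$episodes$episodes * rep60$episodes$avg_length,
               tolerance = 1e-10)

  expect_error(episode_report(chain, c("mild", "dead"), horizon = 60),
               "refusing absorbing")
})

test_that("interval records yield occurrence-exposure rates under the
           row-per-transition convention", {
  sts <- state_space(c("Normal", "Low", "Death"), absorbing = "Death")
  # two patients in transition-structured layout: each at-risk interval
  # appears once per competing transition out of its origin state
  rec <- rbind(
    data.frame(id = 1, from = 2, to = 1, Tstart = 0, Tstop = 10, status = 1),
    data.frame(id = 1, from = 2, to = 3, Tstart = 0, Tstop = 10, status = 0),
    data.frame(id = 1, from = 1, to = 2, Tstart = 10, Tstop = 30, status = 0),
    data.frame(id = 1, from = 1, to = 3, Tstart = 10, Tstop = 30, status = 1),
    data.frame(id = 2, from = 2, to = 1, Tstart = 0, Tstop = 40, status = 0),
    data.frame(id = 2, from = 2, to = 3, Tstart = 0, Tstop = 40, status = 1))
  fit <- interval_transition_rates(rec, sts, units = "day")
  # exposure(Low) = 10 + 10 + 40 + 40 = 100; events Low->Normal = 1
  expect_equal(unname(fit$exposure["Low"]), 100)
  expect_equal(fit$rates$Q["Low", "Normal"], 1 / 100)
  expect_equal(fit$rates$Q["Low", "Death"], 1 / 100)
  # exposure(Normal) = 20 + 20 = 40; events Normal->Death = 1
  expect_equal(fit$rates$Q["Normal", "Death"], 1 / 40)
  expect_equal(fit$events["Low", "Normal"], 1)

  expect_error(interval_transition_rates(rec[, -6], sts), "missing column")
})

test_that("the cirrhosis recipe runs end-to-end on synthetic records", {
  # synthetic stand-in records (NOT the trial data): 40 patients with
  # plausible interval structure, just to exercise the pipeline
  set.seed(100)
  mkpat <- function(id) {
    t1 <- round(runif(1, 50, 400)); t2 <- t1 + round(runif(1, 50, 400))
    died <- runif(1) < 0.5
    rbind(
      data.frame(id = id, from = 2, to = 1, Tstart = 0, Tstop = t1,
                 status = 1),
      data.frame(id = id, from = 2, to = 3, Tstart = 0, Tstop = t1, status = 0),
      data.frame(id = id, from = 1, to = 2, Tstart = t1, Tstop = t2, status = 0),
      data.frame(id = id, from = 1, to = 3, Tstart = t1, Tstop = t2,
                 status = as.integer(died)))
  }
  rec <- do.call(rbind, lapply(1:40, mkpat))
  tab <- case_study_cirrhosis(rec, n_replicates = 200, seed = 42)
  expect_equal(tab$quantity,
               c("life_expectancy", "time_low", "time_normal",
                 "episodes_normal", "episode_length_normal"))
  # time split adds up to the partial life expectancy
  expect_equal(tab$estimate[1], tab$estimate[2] + tab$estimate[3],
               tolerance = 1e-10)
  expect_true(all(tab$estimate > 0))
  expect_true(all(tab$ci_lower <= tab$ci_upper))
  expect_lte(tab$estimate[1], 10)

  # deterministic given the seed
  tab2 <- case_study_cirrhosis(rec, n_replicates = 200, seed = 42)
  expect_identical(tab, tab2)
})

test_that("the frailty recipe reports times, episodes and lengths per group", {
  rates <- synthetic_frailty_rates()
  res <- case_study_frailty(list(groupA = rates), horizon = 60)
  expect_equal(res$group, "groupA")
  expect_equal(res$start, "none")
  months <- unlist(res[, c("months_none", "months_mild", "months_severe")])
  expect_true(all(months >= 0))
  expect_lte(sum(months), 60 + 1e-9)
  # consistency: episode length x episode count = total disabled time
  expect_equal(res$episodes * res$episode_length,
               res$months_mild + res$months_severe, tolerance = 1e-8)
})

test_that("the command-line wrapper parses", {
  cli <- system.file("cli", "mcepisodes.R", package = "mcepisodes")
  if (!nzchar(cli)) cli <- file.path("..", "..", "inst", "cli", "mcepisodes.R")
  expect_true(file.exists(cli))
  expect_silent(parse(cli))
})
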