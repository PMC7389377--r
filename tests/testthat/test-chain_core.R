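test_that("chains are validated and put into canonical order", {
  ch <- illness_death_chain()
  expect_s3_class(ch, "markov_chain")
  expect_equal(ch$states$n, 2L)
  expect_equal(ch$states$q, 1L)

  # absorbing state listed first gets reordered, labels follow their rows
  P <- rbind(D = c(1, 0, 0), H = c(0.1, 0.6, 0.3), I = c(0.3, 0.2, 0.5))
  colnames(P) <- rownames(P)
  ch2 <- markov_chain(P, absorbing = "D")
  expect_equal(ch2$states$labels, c("H", "I", "D"))
  expect_equal(ch2$P, illness_death_chain()$P)
})

test_that("constructor errors name the offending state", {
  P <- rbind(H = c(0.6, 0.3, 0.2), I = c(0.2, 0.5, 0.3), D = c(0, 0, 1))
  colnames(P) <- rownames(P)
  expect_error(markov_chain(P, "D"), "does not sum to 1.*H")

  P <- rbind(H = c(0.6, 0.3, 0.1), I = c(0.2, 0.5, 0.3), D = c(0, 0.5, 0.5))
  colnames(P) <- rownames(P)
  expect_error(markov_chain(P, "D"), "absorbing state 'D'")

  # periodic closed transient class: absorbing state unreachable
  P <- rbind(a = c(0, 1, 0), b = c(1, 0, 0), x = c(0, 0, 1))
  colnames(P) <- rownames(P)
  expect_error(markov_chain(P, "x"), "no absorbing state is reachable.*a.*b")

  expect_error(markov_chain(matrix(0.5, 2, 2), absorbing = "b",
                            labels = c("a", "b", "c")),
               "dimension mismatch")
  expect_error(state_space(c("a", "a", "b"), "b"), "duplicate")
})

test_that("fundamental matrix matches hand inversion and the geometric series", {
  # single transient state with self-loop 0.5: geometric series 1/(1-0.5)
  P <- rbind(s = c(0.5, 0.5), d = c(0, 1))
  colnames(P) <- rownames(P)
  expect_equal(fundamental_matrix(markov_chain(P, "d"))$N[1, 1], 2.0)

  # independent 2x2 inversion: (I-U)^{-1} = adj/det, det = 0.14
  ch <- illness_death_chain()
  N <- fundamental_matrix(ch)$N
  oracle <- matrix(c(0.5, 0.3, 0.2, 0.4), 2, 2, byrow = TRUE) / 0.14
  expect_equal(unname(N), oracle, tolerance = 1e-10)
  expect_lt(max(abs(N - rbind(c(3.5714, 2.1429), c(1.4286, 2.8571)))), 1e-3)

  # defining identity N (I - U) = I
  U <- ch$P[1:2, 1:2]
  expect_lt(max(abs(N %*% (diag(2) - U) - diag(2))), 1e-8)
})

test_that("finite horizons count the starting step and converge monotonically", {
  ch <- illness_death_chain()
  expect_equal(unname(fundamental_matrix(ch, 1)$N), diag(2))
  expect_equal(unname(fundamental_matrix(ch, 2)$N),
               unname(diag(2) + ch$P[1:2, 1:2]))

  set.seed(42)
  for (rep in 1:5) {
    chain <- random_absorbing_chain(sample(2:4, 1), sample(1:2, 1))
    prev <- fundamental_matrix(chain, 1)$N
    for (h in c(5, 20, 100)) {
      cur <- fundamental_matrix(chain, h)$N
      expect_true(all(cur >= prev - 1e-12))
      expect_true(all(cur <= h))
      prev <- cur
    }
    expect_lt(max(abs(fundamental_matrix(chain, 2000)$N -
                        fundamental_matrix(chain)$N)), 1e-6)
  }
})

test_that("state expectancies scale occupancy into declared time units", {
  ch <- illness_death_chain()
  fm <- fundamental_matrix(ch)
  ex <- state_expectancies(fm, step_length = 1)
  expect_equal(ex$total, c(40 / 7, 30 / 7), tolerance = 1e-10)
  expect_equal(ex$H[1], 3.5714, tolerance = 1e-3)
  expect_equal(ex$I[1], 2.1429, tolerance = 1e-3)

  P <- rbind(s = c(0.5, 0.5), d = c(0, 1))
  colnames(P) <- rownames(P)
  daily <- state_expectancies(fundamental_matrix(markov_chain(P, "d")),
                              step_length = 1 / 365, units = "years")
  expect_equal(daily$total, 0.00548, tolerance = 1e-5 / 0.00548)
  expect_equal(daily$units, "years")
})

test_that("rate matrices follow the generator convention", {
  Q <- rbind(a = c(0, 0.2, 0.1), b = c(0.05, 0, 0.3), d = c(0, 0, 0))
  colnames(Q) <- rownames(Q)
  rm <- rate_matrix(Q, absorbing = "d")
  expect_equal(unname(rowSums(rm$Q)), c(0, 0, 0))
  expect_equal(rm$Q["a", "a"], -0.3)

  Qbad <- Q; Qbad["a", "b"] <- -0.1
  expect_error(rate_matrix(Qbad, "d"), "negative off-diagonal")
  Qbad <- Q; Qbad["d", "a"] <- 0.1
  expect_error(rate_matrix(Qbad, "d"), "all-zero rate row")
})

test_that("rate-to-probability transform matches closed forms", {
  # zero rates: identity (with a warning, since such a chain never absorbs)
  Q0 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "d"), c("a", "b", "d")))
  expect_warning(P0 <- rates_to_probabilities(rate_matrix(Q0, "d"))$P,
                 "degenerate rates")
  expect_equal(unname(P0), diag(3))

  # single rate mu = 0.5: p11 = (1 - 0.25)/(1 + 0.25) = 0.6
  Q <- rbind(alive = c(0, 0.5), dead = c(0, 0))
  colnames(Q) <- rownames(Q)
  P <- rates_to_probabilities(rate_matrix(Q, "dead"))$P
  expect_equal(P["alive", "alive"], 0.6, tolerance = 1e-12)
  expect_equal(P["alive", "dead"], 0.4, tolerance = 1e-12)

  # rates too large for the step
  Qbig <- rbind(alive = c(0, 5), dead = c(0, 0))
  colnames(Qbig) <- rownames(Qbig)
  expect_error(rates_to_probabilities(rate_matrix(Qbig, "dead")),
               "smaller time step")
})

test_that("transform agrees with the matrix exponential at small rates", {
  skip_if_not_installed("Matrix")
  set.seed(7)
  for (rep in 1:5) {
    Q <- matrix(0, 3, 3, dimnames = list(c("a", "b", "d"), c("a", "b", "d")))
    Q["a", c("b", "d")] <- runif(2, 0, 0.01)
    Q["b", c("a", "d")] <- runif(2, 0, 0.01)
    rm <- rate_matrix(Q, "d")
    P <- rates_to_probabilities(rm)$P
    Pexp <- as.matrix(Matrix::expm(Matrix::Matrix(rm$Q)))
    expect_lt(max(abs(P - Pexp)), 1e-4)
  }
})

test_that("discrete expectancies track continuous time for slow chains", {
  # movement rates up to 0.05/step, absorption slow, so the half-step
  # offset of start-counting is negligible relative to the expectancy
  set.seed(11)
  for (rep in 1:5) {
    Q <- matrix(0, 3, 3, dimnames = list(c("a", "b", "d"), c("a", "b", "d")))
    Q["a", "b"] <- runif(1, 0.01, 0.05); Q["a", "d"] <- runif(1, 0.002, 0.01)
    Q["b", "a"] <- runif(1, 0.01, 0.05); Q["b", "d"] <- runif(1, 0.002, 0.01)
    rm <- rate_matrix(Q, "d")
    N_disc <- fundamental_matrix(rates_to_probabilities(rm))$N
    N_cont <- solve(-rm$Q[1:2, 1:2])
    expect_lt(max(abs(rowSums(N_disc) / rowSums(N_cont) - 1)), 0.01)
  }
})

test_that("labelled-matrix CSVs round-trip with the absorbing header", {
  ch <- illness_death_chain()
  f <- tempfile(fileext = ".csv")
  write_chain_csv(ch, f)
  back <- read_chain_csv(f)
  expect_equal(back$P, ch$P)
  expect_equal(back$states$labels, ch$states$labels)

  rm <- synthetic_frailty_rates()
  f2 <- tempfile(fileext = ".csv")
  write_chain_csv(rm, f2)
  back2 <- read_rates_csv(f2, units = "month")
  expect_equal(back2$Q, rm$Q)
  unlink(c(f, f2))
})
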