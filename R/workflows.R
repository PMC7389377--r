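# End-to-end recipes: panel -> rates -> probabilities -> episode report,
# bootstrap wiring, and the two published-data case studies (liver
# cirrhosis / prednisone with patient-level interval records; frailty /
# disability from an aggregated monthly rate table).

#' Estimate a transition matrix from a panel, two ways
#'
#' Runs [count_transitions()], then both estimation routes: the two-step
#' occurrence-exposure route (rates, then the rate-to-probability
#' transform) and the direct maximum-likelihood estimate, for comparison.
#'
#' @param panel a [panel_data()].
#' @param step_length length of one panel step in `units`.
#' @param units time unit of the exposure.
#' @return List of class `"transition_estimate"`: `counts`, `rates`,
#'   `chain` (occurrence-exposure route) and `chain_mle`.
#' @export
estimate_transitions <- function(panel, step_length = 1, units = "step") {
  stopifnot(inherits(panel, "panel_data"))
  counts <- count_transitions(panel)
  rates <- occurrence_exposure_rates(counts, step_length, units)
  structure(list(counts = counts, rates = rates,
                 chain = rates_to_probabilities(rates, time_step = step_length),
                 chain_mle = mle_probabilities(counts)),
            class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, digits = 4, ...) {
  cat("Transition estimate (occurrence-exposure route):\n")
  print(round(x$chain$P, digits))
  cat("Direct MLE:\n")
  print(round(x$chain_mle$P, digits))
  invisible(x)
}

#' Combined expectancy and episode report
#'
#' The standard report of the package: per starting transient state, time
#' spent in each state over the horizon, total (partial life expectancy),
#' and the episode statistics of the target set. Requesting an absorbing
#' state as episode target is refused: once entered it is never left, so
#' episode counting degenerates (use the fundamental matrix directly for
#' absorption probabilities).
#'
#' @param chain a [markov_chain()].
#' @param target episode target set (transient state names).
#' @param horizon `Inf` or a positive integer number of steps.
#' @param step_length,units time scaling, as in [state_expectancies()].
#' @param count_initial_episode as in [episode_summary()].
#' @return List of class `"episode_report"`: `expectancies` (data.frame)
#'   and `episodes` (an [episode_summary()]).
#' @export
episode_report <- function(chain, target, horizon = Inf, step_length = 1,
                           units = "step", count_initial_episode = FALSE) {
  stopifnot(inherits(chain, "markov_chain"))
  target <- as.character(target)
  bad <- intersect(target, absorbing_states(chain$states))
  if (length(bad)) {
    stop("episode target must be transient; refusing absorbing state(s): ",
         paste(bad, collapse = ", "))
  }
  fm <- fundamental_matrix(chain, horizon)
  structure(list(
    expectancies = state_expectancies(fm, step_length, units),
    episodes = episode_summary(chain, target, horizon, step_length, units,
                               count_initial_episode),
    horizon = horizon),
    class = "episode_report")
}

#' @export
print.episode_report <- function(x, digits = 4, ...) {
  cat("Expected time in states:\n")
  print(x$expectancies, digits = digits, row.names = FALSE)
  cat("\n")
  print(x$episodes, digits = digits)
  invisible(x)
}

#' Block-bootstrapped episode analysis of a panel
#'
#' Wires the full pipeline -- estimate the chain from the panel, compute
#' the requested episode quantities -- into a [block_bootstrap()] (or, by
#' flag, a [model_based_bootstrap()]) so every replicate re-runs the whole
#' estimation.
#'
#' @param panel a [panel_data()].
#' @param target,start,horizon,step_length,what,count_initial_episode
#'   passed to [episode_statistic()].
#' @param estimator `"mle"` or `"occurrence_exposure"` (two-step route).
#' @param method `"block"` or `"model_based"`.
#' @param n_replicates,seed,level bootstrap settings.
#' @return A `"bootstrap_estimate"`.
#' @export
bootstrap_episodes <- function(panel, target, start = NULL, horizon = Inf,
                               step_length = 1,
                               what = c("episodes", "occupancy", "avg_length"),
                               count_initial_episode = FALSE,
                               estimator = c("mle", "occurrence_exposure"),
                               method = c("block", "model_based"),
                               n_replicates = 1000, seed = NULL, level = 0.95) {
  method <- match.arg(method)
  stat <- episode_statistic(target, start, horizon, step_length, what,
                            count_initial_episode, match.arg(estimator))
  if (method == "block") {
    block_bootstrap(panel, stat, n_replicates, seed, level)
  } else {
    model_based_bootstrap(count_transitions(panel), stat, n_replicates,
                          seed, level)
  }
}

# ---- interval (event-history) records -------------------------------------

.interval_records <- function(records, states) {
  need <- c("id", "from", "to", "Tstart", "Tstop", "status")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  to_idx <- function(x) {
    if (is.numeric(x)) {
      if (any(x < 1 | x > states$m)) stop("state index outside 1..m")
      as.integer(x)
    } else {
      i <- match(as.character(x), states$labels)
      if (anyNA(i)) stop("unknown state label in records")
      i
    }
  }
  data.frame(id = as.character(records$id),
             from = to_idx(records$from), to = to_idx(records$to),
             dur = as.numeric(records$Tstop) - as.numeric(records$Tstart),
             status = as.integer(records$status))
}

#' Occurrence-exposure rates from transition-structured interval records
#'
#' Computes per-time-unit transition rates from event-history records in
#' the transition-structured ("one row per possible transition per at-risk
#' interval") layout used by multistate survival analyses: `status = 1`
#' marks the transition that actually happened at `Tstop`. The rate for
#' i -> j is the number of observed i -> j events divided by the exposure
#' of state i, where exposure sums `Tstop - Tstart` over *all* rows with
#' `from = i` -- i.e. each at-risk interval contributes once per competing
#' transition out of its origin state. This is the convention of the
#' classical occurrence-exposure analyses of the cirrhosis trial data that
#' this layout comes from; note it differs from naive person-time by a
#' factor equal to the number of competing transitions.
#'
#' @param records data.frame with columns `id`, `from`, `to` (state labels
#'   or indices into `states$labels`), `Tstart`, `Tstop`, `status`.
#' @param states a [state_space()].
#' @param units time unit of `Tstart`/`Tstop` (rates are per this unit).
#' @return List of class `"interval_rate_fit"`: `rates` (a
#'   [rate_matrix()]), `events` (m x m matrix) and `exposure` (per-state
#'   vector).
#' @export
interval_transition_rates <- function(records, states, units = "day") {
  stopifnot(inherits(states, "state_space"))
  r <- .interval_records(records, states)
  m <- states$m
  events <- matrix(0, m, m, dimnames = list(states$labels, states$labels))
  ev <- r[r$status == 1L, ]
  if (nrow(ev)) {
    tab <- tabulate((ev$from - 1L) * m + ev$to, m * m)
    events <- matrix(tab, m, m, byrow = TRUE,
                     dimnames = list(states$labels, states$labels))
  }
  exposure <- setNames(numeric(m), states$labels)
  agg <- tapply(r$dur, factor(r$from, levels = seq_len(m)), sum)
  exposure[!is.na(agg)] <- agg[!is.na(agg)]
  tr <- which(!states$is_absorbing)
  if (any(exposure[tr] == 0)) {
    stop("zero exposure for transient state(s): ",
         paste(states$labels[tr[exposure[tr] == 0]], collapse = ", "))
  }
  Q <- events
  diag(Q) <- 0
  Q[tr, ] <- Q[tr, , drop = FALSE] / exposure[tr]
  Q[states$is_absorbing, ] <- 0
  list_out <- list(rates = rate_matrix(Q, absorbing_states(states), units = units),
                   events = events, exposure = exposure)
  class(list_out) <- "interval_rate_fit"
  list_out
}

#' @export
print.interval_rate_fit <- function(x, digits = 6, ...) {
  print(x$rates, digits = digits)
  cat("events:\n"); print(x$events)
  invisible(x)
}

# ---- case study recipes ----------------------------------------------------

# per-patient event/exposure aggregates for the interval-record block
# bootstrap: one row per patient, columns = m*m event counts then m
# exposures
.interval_patient_matrix <- function(r, m) {
  ids <- unique(r$id)
  f <- factor(r$id, levels = ids)
  ev <- r[r$status == 1L, ]
  E <- matrix(0, length(ids), m * m)
  if (nrow(ev)) {
    code <- (match(ev$id, ids) - 1L) * (m * m) + (ev$from - 1L) * m + ev$to
    tab <- tabulate(code, length(ids) * m * m)
    E <- matrix(tab, length(ids), m * m, byrow = TRUE)
  }
  X <- rowsum(r$dur, f)
  W <- matrix(0, length(ids), m)
  for (j in seq_len(m)) {
    W[, j] <- rowsum(r$dur * (r$from == j), f)[, 1L]
  }
  cbind(E, W)
}

.cirrhosis_table <- function(events, exposure, states, horizon, start,
                             target) {
  tr <- which(!states$is_absorbing)
  Q <- events
  diag(Q) <- 0
  Q[tr, ] <- Q[tr, , drop = FALSE] / exposure[tr]
  Q[states$is_absorbing, ] <- 0
  dimnames(Q) <- list(states$labels, states$labels)
  chain <- rates_to_probabilities(rate_matrix(Q, absorbing_states(states)))
  stats <- .episode_stats_P(chain$P, states$n,
                            match(target, states$labels), horizon,
                            step_length = 1 / 365,
                            count_initial_episode = FALSE,
                            absorbing_idx = which(states$is_absorbing))
  N <- .fundamental(transient_block(chain), horizon) / 365
  i <- match(start, transient_states(states))
  c(life_expectancy = sum(N[i, ]),
    time_low = N[i, match("Low", transient_states(states))],
    time_normal = N[i, match("Normal", transient_states(states))],
    episodes_normal = stats[i, "episodes"],
    episode_length_normal = stats[i, "avg_length"])
}

#' Liver-cirrhosis case study: durations and episodes of normal functioning
#'
#' Reproduces the reversible illness-death analysis of the prednisone
#' trial: states "Normal" and "Low" liver functioning (prothrombin index
#' >= 70% vs below) plus "Death". Day-to-day transition probabilities are
#' estimated in two steps (occurrence-exposure rates from the
#' transition-structured patient records via [interval_transition_rates()],
#' then the rate-to-probability transform), and partial expectancies and
#' episodes of normal functioning are computed over a 10-year (3650 daily
#' steps) horizon starting from low functioning. Confidence intervals come
#' from a block bootstrap over patients: all or none of a patient's
#' exposures and transitions enter a resample.
#'
#' The patient records are user-supplied (e.g. the `prothr` data of the
#' CRAN package mstate, split by treatment arm); they are not bundled.
#'
#' @param records interval records as in [interval_transition_rates()],
#'   with states 1 = Normal, 2 = Low, 3 = Death (or those labels),
#'   times in days.
#' @param horizon analysis horizon in days.
#' @param n_replicates bootstrap replicates; `0` skips the bootstrap.
#' @param seed,level bootstrap settings.
#' @return data.frame with rows `life_expectancy`, `time_low`,
#'   `time_normal`, `episodes_normal`, `episode_length_normal`; columns
#'   `estimate` (years, except a count for episodes), `ci_lower`,
#'   `ci_upper`, `units`.
#' @export
case_study_cirrhosis <- function(records, horizon = 3650,
                                 n_replicates = 1000, seed = NULL,
                                 level = 0.95) {
  states <- state_space(c("Normal", "Low", "Death"), absorbing = "Death")
  r <- .interval_records(records, states)
  m <- states$m
  PM <- .interval_patient_matrix(r, m)
  totals <- colSums(PM)
  events <- matrix(totals[seq_len(m * m)], m, m, byrow = TRUE,
                   dimnames = list(states$labels, states$labels))
  exposure <- totals[m * m + seq_len(m)]
  point <- .cirrhosis_table(events, exposure, states, horizon,
                            start = "Low", target = "Normal")
  quantities <- names(point)
  ci <- matrix(NA_real_, length(point), 2L)
  if (n_replicates > 0) {
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
    set.seed(seed)
    rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
    B <- nrow(PM)
    reps <- matrix(NA_real_, n_replicates, length(point))
    for (rr in seq_len(n_replicates)) {
      set.seed(rep_seeds[rr])
      idx <- sample.int(B, B, replace = TRUE)
      tot <- colSums(PM[idx, , drop = FALSE])
      reps[rr, ] <- tryCatch(
        .cirrhosis_table(matrix(tot[seq_len(m * m)], m, m, byrow = TRUE),
                         tot[m * m + seq_len(m)], states, horizon,
                         "Low", "Normal"),
        error = function(e) rep(NA_real_, length(point)))
    }
    n_failed <- sum(apply(is.na(reps), 1L, all))
    if (n_failed > 0.10 * n_replicates) {
      stop("bootstrap failed: ", n_failed, " of ", n_replicates,
           " replicates unusable (> 10%)")
    }
    ci <- t(apply(reps, 2L, percentile_ci, level = level))
  }
  data.frame(quantity = quantities,
             estimate = unname(point),
             ci_lower = ci[, 1L], ci_upper = ci[, 2L],
             units = c("years", "years", "years", "count", "years"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Frailty/disability case study: time in states and disability episodes
#'
#' The four-state disability model: "no disability", "mild disability",
#' "severe disability" and the absorbing "dead", on monthly steps.
#' Published monthly transition rates (user-supplied as a
#' [rate_matrix()]; the original counts are not bundled) are transformed
#' into monthly transition probabilities, and expected times per state,
#' the expected number of disability episodes (entries into the subset
#' {mild, severe} from no disability) and their average length are
#' computed over a 60-month horizon starting without disability. No
#' resampling is offered here: an aggregated rate table carries no
#' patient-level blocks to resample.
#'
#' @param rates a [rate_matrix()] of monthly rates, or a named list of
#'   them (one per group, e.g. nonfrail/frail).
#' @param target disability subset; defaults to all transient states
#'   except `start`.
#' @param start starting state; defaults to the first transient state.
#' @param horizon analysis horizon in months.
#' @return data.frame with one row per group: expected months per
#'   transient state, number of disability episodes and average episode
#'   length in months.
#' @export
case_study_frailty <- function(rates, target = NULL, start = NULL,
                               horizon = 60) {
  if (inherits(rates, "rate_matrix")) rates <- list(overall = rates)
  if (is.null(names(rates))) names(rates) <- paste0("group", seq_along(rates))
  out <- lapply(names(rates), function(grp) {
    rm <- rates[[grp]]
    stopifnot(inherits(rm, "rate_matrix"))
    chain <- rates_to_probabilities(rm)
    tr <- transient_states(chain$states)
    st <- if (is.null(start)) tr[1L] else start
    tg <- if (is.null(target)) setdiff(tr, st) else target
    rep_ <- episode_report(chain, tg, horizon = horizon, step_length = 1,
                           units = "months")
    i <- match(st, rep_$expectancies$start)
    times <- as.numeric(rep_$expectancies[i, tr])
    epi <- rep_$episodes[match(st, rep_$episodes$start), ]
    df <- data.frame(group = grp, start = st, t(times),
                     episodes = epi$episodes, episode_length = epi$avg_length,
                     stringsAsFactors = FALSE)
    names(df)[2L + seq_along(tr)] <- paste0("months_", gsub("[^[:alnum:]]+", "_", tr))
    df
  })
  do.call(rbind, out)
}
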