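# Sampling-variance estimation for chain-derived statistics: block
# bootstrap (resampling whole individuals, preserving within-individual
# correlation) and model-based multinomial bootstrap (resampling each
# transition-count row, valid only under the Markov/i.i.d. assumption),
# with percentile confidence intervals.
#
# Replicate r uses its own pre-drawn seed, so runs are reproducible and
# independent of evaluation order.

#' Percentile bootstrap confidence interval
#'
#' Empirical alpha/2 and 1 - alpha/2 quantiles of the replicate
#' distribution, using the linear-interpolation quantile definition
#' (`stats::quantile()` type 7).
#'
#' @param replicates numeric vector of bootstrap replicate values (NAs from
#'   failed replicates are dropped).
#' @param level confidence level, strictly between 0 and 1.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' percentile_ci(1:1000, 0.95)  # c(25.975, 975.025)
#' @export
percentile_ci <- function(replicates, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1")
  }
  replicates <- replicates[!is.na(replicates)]
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  alpha <- 1 - level
  q <- quantile(replicates, c(alpha / 2, 1 - alpha / 2), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Wrap a function of a Markov chain as a bootstrap statistic
#'
#' A `chain_statistic` maps an estimated [markov_chain()] to a named
#' numeric vector. Both bootstrap engines understand it: the block
#' bootstrap re-estimates the chain from each resampled panel (by maximum
#' likelihood or by the occurrence-exposure/rate-transform pipeline) and the
#' model-based bootstrap applies it to each resampled transition matrix.
#'
#' @param fn function taking a [markov_chain()] and returning a named
#'   numeric vector.
#' @param name fallback name when `fn` returns an unnamed scalar.
#' @param estimator how a resampled panel's counts are turned into a chain:
#'   direct maximum likelihood, or occurrence-exposure rates followed by
#'   the rate-to-probability transform.
#' @return Object of class `"chain_statistic"`.
#' @seealso [episode_statistic()] for the prewired episode/occupancy
#'   statistics.
#' @export
chain_statistic <- function(fn, name = "statistic",
                            estimator = c("mle", "occurrence_exposure")) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, name = name, estimator = match.arg(estimator)),
            class = "chain_statistic")
}

#' Prewired episode statistics for bootstrapping
#'
#' Builds a [chain_statistic()] that evaluates episode quantities of a
#' target set for chosen starting states: expected episode count,
#' occupancy, average episode length, exit counts and/or total (partial
#' life) expectancy.
#'
#' @inheritParams episode_summary
#' @param target episode target set (state names).
#' @param start starting transient state name(s); `NULL` means all.
#' @param what quantities to report; any of `"episodes"`, `"occupancy"`,
#'   `"avg_length"`, `"exits_all"`, `"exits_recovery"`, `"expectancy"`.
#' @param estimator see [chain_statistic()].
#' @return Object of class `"chain_statistic"`.
#' @export
episode_statistic <- function(target, start = NULL, horizon = Inf,
                              step_length = 1, what = "episodes",
                              count_initial_episode = FALSE,
                              estimator = c("mle", "occurrence_exposure")) {
  what <- match.arg(what, c("episodes", "occupancy", "avg_length",
                            "exits_all", "exits_recovery", "expectancy"),
                    several.ok = TRUE)
  estimator <- match.arg(estimator)
  force(target); force(start); force(horizon); force(step_length)
  force(count_initial_episode)
  fn <- function(chain) {
    labels <- chain$states$labels
    tidx <- match(target, labels)
    if (anyNA(tidx)) stop("unknown target state(s): ",
                          paste(target[is.na(tidx)], collapse = ", "))
    stats <- .episode_stats_P(chain$P, chain$states$n, tidx, horizon,
                              step_length, count_initial_episode,
                              which(chain$states$is_absorbing))
    tr <- transient_states(chain$states)
    rows <- if (is.null(start)) seq_along(tr) else match(start, tr)
    if (anyNA(rows)) stop("unknown starting state(s): ",
                          paste(start[is.na(rows)], collapse = ", "))
    vals <- stats[rows, what, drop = FALSE]
    out <- as.vector(t(vals))
    names(out) <- if (length(rows) == 1L) what
                  else as.vector(t(outer(tr[rows], what, function(a, b) paste(b, a, sep = "_"))))
    out
  }
  structure(list(fn = fn, name = paste(what, collapse = "+"),
                 estimator = estimator),
            class = "chain_statistic")
}

# counts matrix (m x m) -> markov_chain, lean path shared by both bootstraps
.chain_from_counts <- function(C, states, estimator) {
  tr <- which(!states$is_absorbing)
  ci <- rowSums(C)[tr]
  if (any(ci == 0)) {
    stop("state(s) never observed at risk in resample: ",
         paste(states$labels[tr[ci == 0]], collapse = ", "))
  }
  if (estimator == "occurrence_exposure") {
    Q <- C
    diag(Q) <- 0
    Q[tr, ] <- Q[tr, , drop = FALSE] / ci
    Q[states$is_absorbing, ] <- 0
    dimnames(Q) <- list(states$labels, states$labels)
    rates_to_probabilities(rate_matrix(Q, absorbing_states(states)))
  } else {
    P <- C
    P[tr, ] <- P[tr, , drop = FALSE] / ci
    for (i in which(states$is_absorbing)) P[i, ] <- as.numeric(seq_len(states$m) == i)
    dimnames(P) <- list(states$labels, states$labels)
    markov_chain(P, absorbing_states(states))
  }
}

.apply_statistic_counts <- function(C, states, statistic) {
  statistic$fn(.chain_from_counts(C, states, statistic$estimator))
}

# shared replicate loop: draw() returns a named numeric vector or throws
.bootstrap_loop <- function(draw, point, n_replicates, seed, level, method) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  k <- length(point)
  reps <- matrix(NA_real_, n_replicates, k,
                 dimnames = list(NULL, names(point)))
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    val <- tryCatch(draw(), error = function(e) conditionMessage(e))
    if (is.character(val)) {
      failures <- c(failures, val)
    } else {
      reps[r, ] <- val
    }
  }
  n_failed <- length(failures)
  if (n_failed > 0.10 * n_replicates) {
    tab <- sort(table(failures), decreasing = TRUE)
    stop("bootstrap failed: ", n_failed, " of ", n_replicates,
         " replicates unusable (> 10%). Most common reason: ",
         names(tab)[1])
  }
  ok <- !apply(is.na(reps), 1L, all)
  variance <- apply(reps, 2L, var, na.rm = TRUE)
  ci <- t(apply(reps, 2L, percentile_ci, level = level))
  structure(list(statistic = names(point), point = point,
                 replicates = reps[ok, , drop = FALSE],
                 variance = variance,
                 ci_lower = setNames(ci[, 1L], names(point)),
                 ci_upper = setNames(ci[, 2L], names(point)),
                 n_replicates = n_replicates, n_failed = n_failed,
                 method = method, seed = seed, level = level,
                 failure_messages = if (n_failed) table(failures) else NULL),
            class = "bootstrap_estimate")
}

#' Block bootstrap over individuals of a panel
#'
#' Each replicate draws B blocks (whole individuals) with replacement from
#' the panel -- either all or none of an individual's transitions enter a
#' resample -- recomputes the statistic, and summarizes the replicate
#' distribution by its empirical variance and a percentile confidence
#' interval. Because whole trajectories are resampled, within-individual
#' correlation is preserved, so the variance estimate remains valid when
#' the pooled data violate the Markov (row-wise i.i.d.) assumption.
#'
#' Replicates on which the statistic is not computable (for example a
#' resample in which some transient state is never at risk) are skipped and
#' counted; if more than 10% fail, the run aborts with the most common
#' failure reason.
#'
#' @param panel a [panel_data()].
#' @param statistic a [chain_statistic()] / [episode_statistic()] (fast
#'   path: the chain is re-estimated from each resample's transition
#'   counts), or any function mapping a [panel_data()] to a named numeric
#'   vector.
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer seed; drawn (and recorded) if `NULL`.
#' @param level confidence level for the percentile interval.
#' @return Object of class `"bootstrap_estimate"` with fields `statistic`,
#'   `point`, `replicates`, `variance`, `ci_lower`, `ci_upper`,
#'   `n_replicates`, `n_failed`, `method`, `seed`, `level`.
#' @export
block_bootstrap <- function(panel, statistic, n_replicates = 1000,
                            seed = NULL, level = 0.95) {
  stopifnot(inherits(panel, "panel_data"))
  if (panel$B < 2L) {
    warning("only one block: all resamples are identical, variance is zero")
  }
  B <- panel$B
  m <- panel$states$m
  if (inherits(statistic, "chain_statistic")) {
    M <- .block_count_matrix(panel)
    point <- .apply_statistic_counts(.counts_from_vec(colSums(M), m),
                                     panel$states, statistic)
    draw <- function() {
      idx <- sample.int(B, B, replace = TRUE)
      C <- .counts_from_vec(colSums(M[idx, , drop = FALSE]), m)
      .apply_statistic_counts(C, panel$states, statistic)
    }
  } else if (is.function(statistic)) {
    point <- statistic(panel)
    draw <- function() {
      idx <- sample.int(B, B, replace = TRUE)
      statistic(.new_panel(paste0(panel$ids[idx], ".", seq_len(B)),
                           panel$state_seqs[idx], panel$time_seqs[idx],
                           panel$states, panel$allow_gaps))
    }
  } else {
    stop("`statistic` must be a chain_statistic or a function of a panel")
  }
  if (is.null(names(point))) {
    names(point) <- rep(if (inherits(statistic, "chain_statistic"))
      statistic$name else "statistic", length(point))
  }
  .bootstrap_loop(draw, point, n_replicates, seed, level, method = "block")
}

#' Model-based (multinomial) bootstrap of transition counts
#'
#' Each replicate redraws every transient row of the transition-count
#' matrix from a multinomial distribution with size c_i and probabilities
#' c_ij / c_i, rebuilds the transition matrix, and recomputes the
#' statistic. This assumes the observed transitions are row-wise i.i.d.
#' (the Markov property holds in the data); with correlated longitudinal
#' data, prefer [block_bootstrap()].
#'
#' @param counts a [count_transitions()] result.
#' @param statistic a [chain_statistic()] / [episode_statistic()], or a
#'   function mapping a [markov_chain()] to a named numeric vector.
#' @inheritParams block_bootstrap
#' @return A `"bootstrap_estimate"`, as for [block_bootstrap()].
#' @export
model_based_bootstrap <- function(counts, statistic, n_replicates = 1000,
                                  seed = NULL, level = 0.95) {
  stopifnot(inherits(counts, "transition_counts"))
  states <- counts$states
  m <- states$m
  tr <- which(!states$is_absorbing)
  ci <- counts$at_risk[tr]
  if (any(ci == 0)) {
    stop("state(s) never observed at risk: ",
         paste(states$labels[tr[ci == 0]], collapse = ", "))
  }
  probs <- counts$counts[tr, , drop = FALSE] / ci
  if (inherits(statistic, "chain_statistic")) {
    stat_fn <- function(chain) statistic$fn(chain)
    estimator <- statistic$estimator
  } else if (is.function(statistic)) {
    stat_fn <- statistic
    estimator <- "mle"
  } else {
    stop("`statistic` must be a chain_statistic or a function of a markov_chain")
  }
  base_chain <- .chain_from_counts(counts$counts, states, estimator)
  point <- stat_fn(base_chain)
  if (is.null(names(point))) {
    names(point) <- rep(if (inherits(statistic, "chain_statistic"))
      statistic$name else "statistic", length(point))
  }
  draw <- function() {
    C <- matrix(0, m, m)
    for (j in seq_along(tr)) {
      C[tr[j], ] <- rmultinom(1L, ci[j], probs[j, ])[, 1L]
    }
    stat_fn(.chain_from_counts(C, states, estimator))
  }
  .bootstrap_loop(draw, point, n_replicates, seed, level, method = "model_based")
}

#' @export
print.bootstrap_estimate <- function(x, digits = 4, ...) {
  cat(x$method, "bootstrap,", x$n_replicates, "replicates (",
      x$n_failed, "failed ), seed", x$seed, "\n")
  print(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.bootstrap_estimate <- function(x, ...) {
  data.frame(statistic = x$statistic,
             point = unname(x$point),
             variance = unname(x$variance),
             ci_lower = unname(x$ci_lower),
             ci_upper = unname(x$ci_upper),
             method = x$method,
             n_replicates = x$n_replicates,
             n_failed = x$n_failed,
             seed = x$seed,
             level = x$level,
             stringsAsFactors = FALSE)
}

#' Write a bootstrap estimate to CSV
#'
#' Columns `statistic`, `point`, `variance`, `ci_lower`, `ci_upper`,
#' `method`, `n_replicates`, `n_failed`, `seed`, `level`.
#'
#' @param x a `"bootstrap_estimate"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_csv <- function(x, path) {
  stopifnot(inherits(x, "bootstrap_estimate"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
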