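# Markov chains with rewards: reward-matrix constructors for episode
# counting and the expected-reward vector e = N Z (P o R) 1_m (row-to-column
# orientation). Entry rewards count transitions into a target state or set
# from outside it; exit rewards are their transpose and count departures.

.match_target <- function(chain, target, warn_absorbing = TRUE) {
  target <- as.character(target)
  if (length(target) == 0L) stop("target set must not be empty")
  unknown <- setdiff(target, chain$states$labels)
  if (length(unknown)) stop("unknown target state(s): ", paste(unknown, collapse = ", "))
  target <- unique(target)
  if (warn_absorbing && any(target %in% absorbing_states(chain$states))) {
    warning("target set contains absorbing state(s); episode semantics ",
            "(entries and exits) are intended for transient targets")
  }
  target
}

# 0/1 entry-reward matrix: r_ij = 1 iff i outside the target set and j inside
.entry_reward_values <- function(labels, target) {
  inT <- labels %in% target
  R <- outer(!inT, inT, `&`) * 1
  dimnames(R) <- list(labels, labels)
  R
}

#' Reward matrix counting entries into a target state or set
#'
#' Builds the 0/1 reward matrix whose expected accumulated reward equals the
#' expected number of episodes of the target: a reward of 1 is collected on
#' every transition from a state outside the target set to a state inside
#' it; all other transitions (including moves within the set) earn 0. With a
#' single target state this is the classical single-state episode count.
#'
#' @param chain a [markov_chain()].
#' @param target state name, or character vector of state names, defining
#'   the episode set.
#'
#' @return Object of class `"reward_matrix"` (fields `R`, `target`,
#'   `direction = "entries"`).
#' @seealso [exit_rewards()], [expected_rewards()], [episode_summary()]
#' @export
entry_rewards <- function(chain, target) {
  stopifnot(inherits(chain, "markov_chain"))
  target <- .match_target(chain, target)
  structure(list(states = chain$states,
                 R = .entry_reward_values(chain$states$labels, target),
                 target = target, direction = "entries"),
            class = "reward_matrix")
}

#' Reward matrix counting exits from a target state or set
#'
#' The transpose of [entry_rewards()]: a reward of 1 for each transition
#' from inside the target set to a state outside it. With
#' `include_absorbing_destinations = FALSE`, departures into absorbing
#' states earn no reward, so the expected reward counts recoveries only
#' (exits by death are dropped).
#'
#' @inheritParams entry_rewards
#' @param include_absorbing_destinations logical; count exits that end in an
#'   absorbing state?
#' @return Object of class `"reward_matrix"` (fields `R`, `target`,
#'   `direction = "exits"`).
#' @export
exit_rewards <- function(chain, target, include_absorbing_destinations = TRUE) {
  stopifnot(inherits(chain, "markov_chain"))
  target <- .match_target(chain, target)
  R <- t(.entry_reward_values(chain$states$labels, target))
  if (!include_absorbing_destinations) {
    R[, absorbing_states(chain$states)] <- 0
  }
  structure(list(states = chain$states, R = R, target = target,
                 direction = "exits"),
            class = "reward_matrix")
}

#' @export
print.reward_matrix <- function(x, ...) {
  cat("Reward matrix (", x$direction, ") for target {",
      paste(x$target, collapse = ", "), "}\n", sep = "")
  print(x$R)
  invisible(x)
}

# expected one-step reward per transient state: transient part of (P o R) 1_m
.reward_rho <- function(P, R, n) {
  rowSums(P * R)[seq_len(n)]
}

#' Expected accumulated rewards per starting state
#'
#' Computes `e = N Z (P o R) 1_m`: the expected total reward accumulated
#' before absorption (or within a finite horizon), starting from each
#' transient state. `o` is the elementwise (Hadamard) product and
#' `Z = (I_n | 0)` selects the transient rows; with a finite horizon T the
#' fundamental matrix is replaced by the partial sum `I + U + ... +
#' U^{T-1}`, i.e. rewards are collected on the first T transitions.
#' Any real-valued reward matrix is accepted; the 0/1 constructors
#' [entry_rewards()] and [exit_rewards()] cover episode counting.
#'
#' @param chain a [markov_chain()].
#' @param rewards a `"reward_matrix"` or a plain numeric m x m matrix in the
#'   chain's canonical state order.
#' @param horizon `Inf`, or a non-negative integer number of steps
#'   (`horizon = 0` returns zeros).
#'
#' @return Named numeric vector of length n (the transient states).
#' @examples
#' P <- rbind(H = c(0.6, 0.3, 0.1), I = c(0.2, 0.5, 0.3), D = c(0, 0, 1))
#' colnames(P) <- rownames(P)
#' ch <- markov_chain(P, "D")
#' expected_rewards(ch, entry_rewards(ch, "I"))  # c(H = 1.0714, I = 0.4286)
#' @export
expected_rewards <- function(chain, rewards, horizon = Inf) {
  stopifnot(inherits(chain, "markov_chain"))
  R <- if (inherits(rewards, "reward_matrix")) rewards$R else as.matrix(rewards)
  if (!all(dim(R) == dim(chain$P))) {
    stop("dimension mismatch: rewards must be ", nrow(chain$P), " x ", ncol(chain$P))
  }
  n <- chain$states$n
  labels <- transient_states(chain$states)
  if (!is.infinite(horizon)) {
    if (!(is.numeric(horizon) && length(horizon) == 1L && horizon >= 0 &&
          horizon == floor(horizon))) {
      stop("`horizon` must be Inf or a non-negative integer")
    }
    if (horizon == 0) return(setNames(numeric(n), labels))
  }
  rho <- .reward_rho(chain$P, R, n)
  N <- .fundamental(transient_block(chain), horizon)
  setNames(as.vector(N %*% rho), labels)
}

# core episode computation on a raw transition matrix in canonical order;
# used by episode_summary() and (for speed) by the bootstrap machinery.
# target_idx indexes states, start rows are all transient states.
.episode_stats_P <- function(P, n, target_idx, horizon, step_length,
                             count_initial_episode, absorbing_idx) {
  m <- nrow(P)
  inT <- seq_len(m) %in% target_idx
  Rent <- outer(!inT, inT, `&`) * 1
  Rex_all <- t(Rent)
  Rex_rec <- Rex_all
  Rex_rec[, absorbing_idx] <- 0

  U <- P[seq_len(n), seq_len(n), drop = FALSE]
  N <- .fundamental(U, horizon)
  episodes <- as.vector(N %*% rowSums(P * Rent)[seq_len(n)])
  if (count_initial_episode) episodes <- episodes + as.numeric(inT[seq_len(n)])
  occupancy <- rowSums(N[, which(inT[seq_len(n)]), drop = FALSE]) * step_length
  avg <- ifelse(episodes > 0, occupancy / episodes, NA_real_)
  cbind(episodes = episodes,
        occupancy = occupancy,
        avg_length = avg,
        exits_all = as.vector(N %*% rowSums(P * Rex_all)[seq_len(n)]),
        exits_recovery = as.vector(N %*% rowSums(P * Rex_rec)[seq_len(n)]),
        expectancy = rowSums(N) * step_length)
}

#' Expected episode counts, lengths and exits for a target set
#'
#' Per starting transient state: the expected number of episodes of the
#' target set (entries from outside), the expected time spent in the set
#' (occupancy, in time units), the average episode length (occupancy
#' divided by the episode count), and the expected number of exits from the
#' set -- both counting all departures and counting recoveries only
#' (departures into absorbing states excluded).
#'
#' An episode is a maximal consecutive run in the target set initiated by an
#' entry from outside. Occupancy of the set at the very first step is
#' therefore *not* an episode by default; `count_initial_episode = TRUE`
#' adds one episode for starting states inside the set. At an infinite
#' horizon, entries balance exits-including-absorption for starting states
#' outside the set, and exceed them by exactly one for starting states
#' inside it.
#'
#' Starting states from which the target is unreachable have zero episodes;
#' their average length is reported as `NA` (undefined) with a warning, not
#' as zero or infinity.
#'
#' @inheritParams entry_rewards
#' @param horizon `Inf` or a positive integer number of steps.
#' @param step_length length of one step in `units`.
#' @param units time unit for occupancy and average length.
#' @param count_initial_episode logical; count occupancy of the target at
#'   the starting step as an episode for starting states inside the set?
#'
#' @return Object of class `"episode_summary"`: a data.frame with columns
#'   `start`, `episodes`, `occupancy`, `avg_length`, `exits_all`,
#'   `exits_recovery`, `horizon`, `units`.
#' @examples
#' P <- rbind(H = c(0.6, 0.3, 0.1), I = c(0.2, 0.5, 0.3), D = c(0, 0, 1))
#' colnames(P) <- rownames(P)
#' episode_summary(markov_chain(P, "D"), target = "I")
#' @export
episode_summary <- function(chain, target, horizon = Inf, step_length = 1,
                            units = "step", count_initial_episode = FALSE) {
  stopifnot(inherits(chain, "markov_chain"))
  target <- .match_target(chain, target)
  if (!is.numeric(step_length) || length(step_length) != 1L || step_length <= 0) {
    stop("`step_length` must be a positive scalar")
  }
  labels <- chain$states$labels
  stats <- .episode_stats_P(chain$P, chain$states$n,
                            target_idx = match(target, labels),
                            horizon = horizon, step_length = step_length,
                            count_initial_episode = count_initial_episode,
                            absorbing_idx = which(chain$states$is_absorbing))
  if (anyNA(stats[, "avg_length"])) {
    und <- transient_states(chain$states)[is.na(stats[, "avg_length"])]
    warning("average episode length undefined (zero expected episodes) for ",
            "starting state(s): ", paste(und, collapse = ", "))
  }
  out <- data.frame(start = transient_states(chain$states),
                    stats[, c("episodes", "occupancy", "avg_length",
                              "exits_all", "exits_recovery"), drop = FALSE],
                    horizon = if (is.infinite(horizon)) Inf else horizon,
                    units = units, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "target") <- target
  attr(out, "count_initial_episode") <- count_initial_episode
  class(out) <- c("episode_summary", "data.frame")
  out
}

#' @export
print.episode_summary <- function(x, digits = 4, ...) {
  cat("Episode summary for target {",
      paste(attr(x, "target"), collapse = ", "), "}\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write an episode summary to CSV
#'
#' One row per starting state; columns `start`, `target`, `episodes`,
#' `occupancy`, `avg_length`, `exits_all`, `exits_recovery`, `horizon`,
#' `units`.
#'
#' @param x an [episode_summary()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_episode_csv <- function(x, path) {
  stopifnot(inherits(x, "episode_summary"))
  out <- cbind(start = x$start,
               target = paste(attr(x, "target"), collapse = "+"),
               x[, setdiff(names(x), "start"), drop = FALSE])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
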