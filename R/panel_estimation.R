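# Estimation from long-format longitudinal panels: individual trajectory
# blocks, one-step transition counts, maximum-likelihood transition
# probabilities and occurrence-exposure rates. A block (one individual's
# ordered state sequence) is the resampling unit of the block bootstrap.

#' Construct panel data from a long-format table
#'
#' Groups observations into one block per individual, sorted by time.
#' Observations must be equally spaced (time step 1); with
#' `allow_gaps = TRUE` missing waves are tolerated and only adjacent
#' observations one step apart contribute transitions. Observations after
#' an absorbing state, duplicate (id, time) pairs and states outside the
#' declared state space are rejected with the offending id/time named.
#'
#' @param x data.frame with columns `id`, `time` (integer-valued) and
#'   `state` (labels from `states`).
#' @param states a [state_space()] or [markov_chain()] declaring the
#'   states.
#' @param allow_gaps logical; tolerate missing waves?
#'
#' @return Object of class `"panel_data"`: individual blocks (`ids`,
#'   `state_seqs` as integer sequences, `time_seqs`), the state space and
#'   `B`, the number of blocks.
#' @export
panel_data <- function(x, states, allow_gaps = FALSE) {
  if (inherits(states, "markov_chain")) states <- states$states
  stopifnot(inherits(states, "state_space"))
  x <- as.data.frame(x)
  need <- c("id", "time", "state")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) stop("panel is empty")
  if (any(!is.finite(x$time)) || any(x$time != floor(x$time))) {
    stop("`time` must be integer-valued")
  }

  sidx <- match(as.character(x$state), states$labels)
  if (anyNA(sidx)) {
    bad <- which(is.na(sidx))[1]
    stop("unknown state '", x$state[bad], "' for id ", x$id[bad],
         " at time ", x$time[bad])
  }
  key <- paste(x$id, x$time, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicate observation for id ", x$id[bad], " at time ", x$time[bad])
  }

  ord <- order(as.character(x$id), x$time, method = "radix")
  id <- as.character(x$id)[ord]
  time <- as.integer(x$time)[ord]
  sidx <- sidx[ord]

  ids <- unique(id)
  f <- factor(id, levels = ids)
  state_seqs <- split(sidx, f)
  time_seqs <- split(time, f)

  is_abs <- states$is_absorbing
  for (k in seq_along(ids)) {
    s <- state_seqs[[k]]
    absorbed <- which(is_abs[s])
    if (length(absorbed) && absorbed[1] < length(s)) {
      stop("observation after absorbing state for id ", ids[k],
           " at time ", time_seqs[[k]][absorbed[1] + 1L])
    }
    if (!allow_gaps && length(s) > 1L && any(diff(time_seqs[[k]]) != 1L)) {
      stop("gap in observation times for id ", ids[k],
           " (set `allow_gaps = TRUE` to skip non-adjacent pairs)")
    }
  }
  .new_panel(ids, unname(state_seqs), unname(time_seqs), states, allow_gaps)
}

# internal constructor for already-validated blocks
.new_panel <- function(ids, state_seqs, time_seqs, states, allow_gaps = FALSE) {
  structure(list(ids = ids, state_seqs = state_seqs, time_seqs = time_seqs,
                 states = states, B = length(ids), allow_gaps = allow_gaps),
            class = "panel_data")
}

#' Read a long-format panel CSV
#'
#' @param path CSV file with header columns `id`, `time`, `state`.
#' @inheritParams panel_data
#' @return A [panel_data()] object.
#' @export
read_panel <- function(path, states, allow_gaps = FALSE) {
  panel_data(read.csv(path, stringsAsFactors = FALSE), states, allow_gaps)
}

#' @export
print.panel_data <- function(x, ...) {
  nobs <- sum(lengths(x$state_seqs))
  cat("Panel data:", x$B, "individuals,", nobs, "observations,",
      x$states$m, "states\n")
  invisible(x)
}

#' @export
as.data.frame.panel_data <- function(x, ...) {
  data.frame(id = rep(x$ids, lengths(x$state_seqs)),
             time = unlist(x$time_seqs),
             state = x$states$labels[unlist(x$state_seqs)],
             stringsAsFactors = FALSE)
}

#' Write panel data to a long-format CSV
#'
#' @param x a [panel_data()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(x, path) {
  stopifnot(inherits(x, "panel_data"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# per-block m^2 transition-count matrix (row-major codes), B x m^2;
# the fast kernel behind both count_transitions() and the block bootstrap
.block_count_matrix <- function(panel) {
  m <- panel$states$m
  t(vapply(seq_len(panel$B), function(k) {
    s <- panel$state_seqs[[k]]
    tm <- panel$time_seqs[[k]]
    n <- length(s)
    if (n < 2L) return(numeric(m * m))
    from <- s[-n]; to <- s[-1L]
    adj <- diff(tm) == 1L
    tabulate(((from - 1L) * m + to)[adj], m * m)
  }, numeric(m * m)))
}

.counts_from_vec <- function(cv, m) {
  matrix(cv, m, m, byrow = TRUE)
}

#' Count observed one-step transitions in a panel
#'
#' Counts adjacent same-individual observation pairs one time step apart.
#' `at_risk[i]` (the classical c_i) is the number of observed one-step
#' transitions out of state i, which under the origin-state exposure
#' convention also equals the exposure in steps: each observed transition
#' contributes one step of exposure to its origin state.
#'
#' @param panel a [panel_data()].
#' @return Object of class `"transition_counts"`: `counts` (m x m matrix
#'   c_ij), `at_risk` (c_i), `exposure` (steps, equal to `at_risk`), and
#'   the state space.
#' @export
count_transitions <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  m <- panel$states$m
  C <- .counts_from_vec(colSums(.block_count_matrix(panel)), m)
  dimnames(C) <- list(panel$states$labels, panel$states$labels)
  structure(list(counts = C,
                 at_risk = rowSums(C),
                 exposure = rowSums(C),
                 states = panel$states),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Observed one-step transition counts:\n")
  print(x$counts)
  invisible(x)
}

#' Maximum-likelihood transition probabilities from counts
#'
#' The MLE of p_ij is c_ij / c_i. Absorbing rows are never estimated; they
#' are set to identity rows. Transient states never observed at risk make
#' the MLE undefined and are reported as an error.
#'
#' @param counts a [count_transitions()] result.
#' @return A validated [markov_chain()].
#' @export
mle_probabilities <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  states <- counts$states
  tr <- which(!states$is_absorbing)
  zero <- tr[counts$at_risk[tr] == 0]
  if (length(zero)) {
    stop("state(s) never observed at risk: ",
         paste(states$labels[zero], collapse = ", "))
  }
  P <- counts$counts
  P[tr, ] <- P[tr, , drop = FALSE] / counts$at_risk[tr]
  for (i in which(states$is_absorbing)) {
    P[i, ] <- as.numeric(seq_len(states$m) == i)
  }
  markov_chain(P, absorbing = absorbing_states(states))
}

#' Occurrence-exposure transition rates from counts
#'
#' Off-diagonal rate (i, j) is the number of observed i -> j transitions
#' divided by the exposure in state i, with exposure measured under the
#' origin-state convention (one step per observed transition out of i,
#' scaled by `step_length`). Diagonals follow the generator convention.
#' Combined with [rates_to_probabilities()], this is the classical two-step
#' occurrence-exposure estimation of a transition matrix.
#'
#' @param counts a [count_transitions()] result.
#' @param step_length length of one panel step in `units`.
#' @param units time unit of the exposure (rates are per `units`).
#' @return A [rate_matrix()].
#' @export
occurrence_exposure_rates <- function(counts, step_length = 1, units = "step") {
  stopifnot(inherits(counts, "transition_counts"))
  states <- counts$states
  tr <- which(!states$is_absorbing)
  expo <- counts$exposure * step_length
  zero <- tr[expo[tr] == 0]
  if (length(zero)) {
    stop("zero exposure for transient state(s): ",
         paste(states$labels[zero], collapse = ", "))
  }
  Q <- counts$counts
  diag(Q) <- 0
  Q[tr, ] <- Q[tr, , drop = FALSE] / expo[tr]
  Q[states$is_absorbing, ] <- 0
  rate_matrix(Q, absorbing = absorbing_states(states), units = units)
}
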