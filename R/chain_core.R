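# Core representation of absorbing Markov chains: state spaces, transition
# matrices (row-to-column orientation), rate matrices and the fundamental
# matrix. All chains are stored in canonical order: transient states first,
# then absorbing states, so the transient-to-transient block U is always the
# leading n x n submatrix and the selector Z = (I_n | 0) is a plain column
# subset.

# stochasticity tolerances: rows further than .row_reject from 1 are data
# errors and rejected; smaller deviations are treated as float noise and
# renormalized.
.row_reject <- 1e-8
.entry_tol <- 1e-12

#' Define a labelled state space with a transient/absorbing partition
#'
#' @param labels character vector of unique, non-empty state names.
#' @param absorbing character vector naming the absorbing states; must be a
#'   non-empty proper subset of `labels` (at least one transient state must
#'   remain).
#'
#' @return An object of class `"state_space"` with the states reordered
#'   canonically (all transient states before all absorbing states,
#'   preserving relative order), and fields `labels`, `is_absorbing`, `m`
#'   (number of states), `n` (transient) and `q` (absorbing).
#' @export
state_space <- function(labels, absorbing) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a state space needs at least 2 states")
  if (anyDuplicated(labels)) {
    stop("duplicate state labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!nzchar(labels))) stop("state labels must be non-empty")
  absorbing <- as.character(absorbing)
  if (length(absorbing) == 0L) stop("at least one absorbing state is required")
  unknown <- setdiff(absorbing, labels)
  if (length(unknown)) {
    stop("absorbing states not in state space: ", paste(unknown, collapse = ", "))
  }
  flag <- labels %in% absorbing
  if (all(flag)) stop("at least one transient state is required")
  ord <- order(flag)  # stable: transient first
  labels <- labels[ord]
  flag <- flag[ord]
  structure(
    list(labels = labels, is_absorbing = flag,
         m = length(labels), n = sum(!flag), q = sum(flag)),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space:", x$m, "states (", x$n, "transient,", x$q, "absorbing )\n")
  cat("  transient:", paste(x$labels[!x$is_absorbing], collapse = ", "), "\n")
  cat("  absorbing:", paste(x$labels[x$is_absorbing], collapse = ", "), "\n")
  invisible(x)
}

transient_states <- function(states) states$labels[!states$is_absorbing]
absorbing_states <- function(states) states$labels[states$is_absorbing]

# backward reachability: which states can reach an absorbing state through
# edges with positive probability/rate
.can_reach_absorbing <- function(M, is_absorbing) {
  reach <- is_absorbing
  repeat {
    new <- reach | (M %*% reach > 0)
    if (all(new == reach)) break
    reach <- new
  }
  as.vector(reach)
}

#' Build a validated absorbing Markov chain
#'
#' Constructs a discrete-time Markov chain from a row-stochastic transition
#' matrix in row-to-column orientation: entry (i, j) is the probability of
#' moving from state i to state j in one step. States are reordered into
#' canonical order (transient first); rows and columns keep their label
#' association.
#'
#' Validation enforces: rows sum to 1 (deviations below `1e-8` are treated
#' as floating-point noise and renormalized, larger ones are rejected);
#' entries in \[0, 1\]; each absorbing row is an identity row; and every
#' transient state can reach at least one absorbing state.
#'
#' @param probabilities numeric m x m matrix of one-step transition
#'   probabilities. Row/column names are used as state labels unless
#'   `labels` is given.
#' @param absorbing character vector of absorbing state names.
#' @param labels optional character vector of state labels (row order of
#'   `probabilities`).
#'
#' @param .check_reachable internal: skip the reachability check (used by
#'   [rates_to_probabilities()] for degenerate zero-rate inputs, which
#'   legitimately map to the identity matrix).
#' @return An object of class `"markov_chain"`: list with elements `states`
#'   (a [state_space()]) and `P` (the reordered transition matrix).
#' @examples
#' P <- rbind(H = c(0.6, 0.3, 0.1), I = c(0.2, 0.5, 0.3), D = c(0, 0, 1))
#' colnames(P) <- rownames(P)
#' markov_chain(P, absorbing = "D")
#' @export
markov_chain <- function(probabilities, absorbing, labels = NULL,
                         .check_reachable = TRUE) {
  P <- as.matrix(probabilities)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (is.null(labels)) labels <- rownames(P)
  if (is.null(labels)) stop("state labels required (rownames or `labels`)")
  if (length(labels) != nrow(P)) {
    stop("dimension mismatch: ", length(labels), " labels for a ",
         nrow(P), " x ", ncol(P), " matrix")
  }
  if (!is.null(colnames(P)) && !identical(colnames(P), as.character(labels))) {
    # allow permuted column order when fully labelled
    if (setequal(colnames(P), labels)) P <- P[, as.character(labels), drop = FALSE]
    else stop("column labels do not match row labels")
  }
  states <- state_space(labels, absorbing)
  dimnames(P) <- list(labels, labels)
  P <- P[states$labels, states$labels, drop = FALSE]

  if (any(!is.finite(P))) stop("non-finite transition probabilities")
  P[P < 0 & P > -.entry_tol] <- 0
  bad <- which(P < 0 | P > 1 + .entry_tol, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("transition probability outside [0, 1] for ",
         states$labels[bad[1, 1]], " -> ", states$labels[bad[1, 2]],
         " (", format(P[bad[1, , drop = FALSE]]), ")")
  }
  P[P > 1] <- 1
  dev <- rowSums(P) - 1
  off <- which(abs(dev) > .row_reject)
  if (length(off)) {
    stop("row does not sum to 1 for state(s): ",
         paste(sprintf("%s (sum %.10g)", states$labels[off], 1 + dev[off]),
               collapse = ", "))
  }
  P <- P / rowSums(P)

  for (i in which(states$is_absorbing)) {
    ident <- as.numeric(states$labels == states$labels[i])
    if (max(abs(P[i, ] - ident)) > .row_reject) {
      stop("absorbing state '", states$labels[i], "' does not have an identity row")
    }
    P[i, ] <- ident
  }

  if (.check_reachable) {
    reach <- .can_reach_absorbing(P, states$is_absorbing)
    if (!all(reach)) {
      stop("no absorbing state is reachable from transient state(s): ",
           paste(states$labels[!reach], collapse = ", "))
    }
  }
  structure(list(states = states, P = P), class = "markov_chain")
}

#' @export
print.markov_chain <- function(x, digits = 4, ...) {
  cat("Absorbing Markov chain (", x$states$n, "transient +",
      x$states$q, "absorbing states )\n")
  print(round(x$P, digits))
  invisible(x)
}

# transient-to-transient block U of a validated chain
transient_block <- function(chain) {
  n <- chain$states$n
  chain$P[seq_len(n), seq_len(n), drop = FALSE]
}

#' Build a validated transition-rate matrix (generator convention)
#'
#' Per-step transition rates with non-negative off-diagonal entries. The
#' diagonal follows the generator convention (minus the row sum of the
#' off-diagonals, so rows sum to zero); if all transient diagonal entries of
#' `values` are zero -- the usual shape of a published rate table -- the
#' diagonal is filled in automatically. Absorbing rows must be identically
#' zero.
#'
#' @param values numeric m x m matrix of rates.
#' @param absorbing character vector of absorbing state names.
#' @param labels optional state labels (defaults to rownames).
#' @param units time unit of the rates (e.g. `"day"`, `"month"`); metadata
#'   carried into downstream output.
#'
#' @return Object of class `"rate_matrix"` with elements `states`, `Q`
#'   (canonical order) and `units`.
#' @seealso [rates_to_probabilities()]
#' @export
rate_matrix <- function(values, absorbing, labels = NULL, units = "step") {
  Q <- as.matrix(values)
  if (nrow(Q) != ncol(Q)) stop("rate matrix must be square")
  if (is.null(labels)) labels <- rownames(Q)
  if (is.null(labels)) stop("state labels required (rownames or `labels`)")
  if (length(labels) != nrow(Q)) stop("dimension mismatch between labels and matrix")
  states <- state_space(labels, absorbing)
  dimnames(Q) <- list(labels, labels)
  Q <- Q[states$labels, states$labels, drop = FALSE]
  if (any(!is.finite(Q))) stop("non-finite rates")

  offdiag <- Q; diag(offdiag) <- 0
  if (any(offdiag < 0)) {
    bad <- which(offdiag < 0, arr.ind = TRUE)[1, ]
    stop("negative off-diagonal rate for ", states$labels[bad[1]], " -> ",
         states$labels[bad[2]])
  }
  for (i in which(states$is_absorbing)) {
    if (any(Q[i, ] != 0)) {
      stop("absorbing state '", states$labels[i], "' must have an all-zero rate row")
    }
  }
  tr <- which(!states$is_absorbing)
  if (all(diag(Q)[tr] == 0)) {
    diag(Q)[tr] <- -rowSums(offdiag)[tr]
  } else {
    tol <- 1e-12 * max(1, max(abs(Q)))
    off <- abs(rowSums(Q)) > tol
    if (any(off)) {
      stop("rate rows must sum to 0 (generator convention); offending state(s): ",
           paste(states$labels[off], collapse = ", "))
    }
  }
  structure(list(states = states, Q = Q, units = units), class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, digits = 6, ...) {
  cat("Transition-rate matrix (per ", x$units, ")\n", sep = "")
  print(round(x$Q, digits))
  invisible(x)
}

#' Convert transition rates to one-step transition probabilities
#'
#' Applies the rational (Pade) approximation of the matrix exponential,
#' `P = (I + Q/2) (I - Q/2)^{-1}` for a generator-convention rate matrix Q
#' (non-negative off-diagonals, diagonal minus the row sums). For small
#' rates this agrees with `expm(Q)` to second order; rows of the result sum
#' to one exactly. Rates large relative to the step size can push entries
#' outside \[0, 1\], which is rejected with advice to use a smaller step.
#'
#' @param rates a [rate_matrix()].
#' @param time_step scalar step length in the same time unit as the rates
#'   (rates per day and a one-day step give `time_step = 1`).
#'
#' @return A validated [markov_chain()] of one-step transition
#'   probabilities.
#' @examples
#' Q <- rbind(alive = c(0, 0.5), dead = c(0, 0))
#' colnames(Q) <- rownames(Q)
#' r <- rate_matrix(Q, absorbing = "dead")
#' rates_to_probabilities(r)$P  # p11 = 0.6, p12 = 0.4
#' @export
rates_to_probabilities <- function(rates, time_step = 1) {
  stopifnot(inherits(rates, "rate_matrix"))
  if (!is.numeric(time_step) || length(time_step) != 1L || time_step <= 0) {
    stop("`time_step` must be a positive scalar")
  }
  Q <- rates$Q * time_step
  m <- nrow(Q)
  fac <- tryCatch(solve(diag(m) - Q / 2),
                  error = function(e) stop("(I - Q/2) is singular; rates too large for this step size"))
  P <- (diag(m) + Q / 2) %*% fac
  if (any(P < -1e-9) || any(P > 1 + 1e-9)) {
    stop("rate-to-probability transform produced entries outside [0, 1]; ",
         "use a smaller time step (or rescale the rates)")
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  absorbing <- absorbing_states(rates$states)
  tryCatch(markov_chain(P, absorbing = absorbing),
           error = function(e) {
             if (!grepl("no absorbing state is reachable", conditionMessage(e))) stop(e)
             # degenerate (e.g. all-zero) rates: algebraically fine, but the
             # resulting chain never absorbs from some state
             warning("degenerate rates: ", conditionMessage(e),
                     "; occupancy over an infinite horizon is undefined")
             markov_chain(P, absorbing = absorbing, .check_reachable = FALSE)
           })
}

# matrix power by repeated squaring
.matpow <- function(M, k) {
  R <- diag(nrow(M))
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  R
}

# N for the transient block U: (I-U)^{-1}, or the partial sum
# sum_{t=0}^{T-1} U^t for finite T (the state at t = 0 is counted).
.fundamental <- function(U, horizon) {
  n <- nrow(U)
  IU <- diag(n) - U
  if (is.infinite(horizon)) {
    N <- tryCatch(solve(IU),
                  error = function(e) stop("internal error: (I - U) singular for a validated absorbing chain"))
  } else {
    N <- tryCatch(solve(IU, diag(n) - .matpow(U, horizon)),
                  error = function(e) stop("internal error: (I - U) singular for a validated absorbing chain"))
  }
  N[N < 0] <- 0  # clamp float noise
  N
}

#' Fundamental matrix: expected time in each transient state
#'
#' For an absorbing chain with transient-to-transient block U, the
#' fundamental matrix `N = (I - U)^{-1}` holds in entry (i, j) the expected
#' number of steps spent in transient state j when starting from transient
#' state i, counting the starting step. Its row sums are the (remaining)
#' life expectancy in steps. With a finite `horizon` T the partial sum
#' `I + U + ... + U^{T-1}` is returned instead: occupancy of steps
#' t = 0, ..., T-1, so `horizon = 1` gives the identity matrix.
#'
#' @param chain a [markov_chain()].
#' @param horizon `Inf` (default) or a positive integer number of steps.
#'
#' @return Object of class `"fundamental_matrix"`: list with `N` (n x n,
#'   labelled), `labels` (transient states) and `horizon`.
#' @examples
#' P <- rbind(H = c(0.6, 0.3, 0.1), I = c(0.2, 0.5, 0.3), D = c(0, 0, 1))
#' colnames(P) <- rownames(P)
#' fundamental_matrix(markov_chain(P, "D"))$N
#' @export
fundamental_matrix <- function(chain, horizon = Inf) {
  stopifnot(inherits(chain, "markov_chain"))
  if (!(is.infinite(horizon) || (is.numeric(horizon) && length(horizon) == 1L &&
                                 horizon >= 1 && horizon == floor(horizon)))) {
    stop("`horizon` must be Inf or a positive integer")
  }
  N <- .fundamental(transient_block(chain), horizon)
  labels <- transient_states(chain$states)
  dimnames(N) <- list(labels, labels)
  structure(list(N = N, labels = labels, horizon = horizon),
            class = "fundamental_matrix")
}

#' @export
print.fundamental_matrix <- function(x, digits = 4, ...) {
  cat("Fundamental matrix, horizon =",
      if (is.infinite(x$horizon)) "infinite" else paste(x$horizon, "steps"), "\n")
  print(round(x$N, digits))
  invisible(x)
}

#' Expected times in state, per starting state
#'
#' Scales fundamental-matrix occupancies into declared time units: time
#' spent in each transient state and the total (partial life expectancy)
#' for every starting transient state.
#'
#' @param fm a [fundamental_matrix()].
#' @param step_length length of one step in `units` (e.g. `1/365` with
#'   `units = "years"` for a daily chain).
#' @param units time unit of the output.
#'
#' @return A data.frame with one row per starting state: `start`, one
#'   column per transient state, `total`, and `units`.
#' @export
state_expectancies <- function(fm, step_length = 1, units = "step") {
  stopifnot(inherits(fm, "fundamental_matrix"))
  if (!is.numeric(step_length) || length(step_length) != 1L || step_length <= 0) {
    stop("`step_length` must be a positive scalar")
  }
  M <- fm$N * step_length
  out <- data.frame(start = fm$labels, M, total = rowSums(M),
                    units = units, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
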