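# Monte-Carlo machinery: trajectory simulation (the independent oracle for
# the analytical occupancy/episode results), synthetic panel generators --
# homogeneous and with between-individual heterogeneity -- and the bootstrap
# variance bias/coverage harness.

# vectorized simulation core: n trajectories from given start indices;
# returns integer matrix n x (steps+1) with column t+1 = state at time t.
# If steps is NULL, runs until every trajectory is absorbed (up to
# max_steps).
.simulate_matrix <- function(P, is_absorbing, start_idx, steps = NULL,
                             max_steps = 10000L) {
  m <- nrow(P)
  n <- length(start_idx)
  cur <- as.integer(start_idx)
  cols <- vector("list", 64L)
  cols[[1L]] <- cur
  t <- 0L
  until_absorbed <- is.null(steps)
  limit <- if (until_absorbed) max_steps else steps
  while (t < limit) {
    active <- !is_absorbing[cur]
    if (until_absorbed && !any(active)) break
    if (any(active)) {
      nxt <- cur
      for (s in unique(cur[active])) {
        idx <- which(cur == s)
        nxt[idx] <- sample.int(m, length(idx), replace = TRUE, prob = P[s, ])
      }
      cur <- nxt
    }
    t <- t + 1L
    if (t + 1L > length(cols)) cols <- c(cols, vector("list", length(cols)))
    cols[[t + 1L]] <- cur
  }
  truncated <- until_absorbed && any(!is_absorbing[cur])
  X <- matrix(unlist(cols[seq_len(t + 1L)], use.names = FALSE), nrow = n)
  list(states = X, truncated = truncated)
}

#' Simulate i.i.d. trajectories of an absorbing Markov chain
#'
#' Sequential categorical draws from the rows of the transition matrix.
#' With `horizon = NULL` the simulation runs until every trajectory is
#' absorbed (capped at `max_steps`; hitting the cap sets the `truncated`
#' flag). Trajectories are constant after absorption.
#'
#' @param chain a [markov_chain()].
#' @param start_state starting state name.
#' @param n_trajectories number of independent trajectories.
#' @param horizon number of steps to simulate, or `NULL` to run to
#'   absorption.
#' @param seed integer seed (optional).
#' @param max_steps safety cap when `horizon = NULL`.
#' @return Object of class `"trajectory_set"`: integer state matrix
#'   (`states`, one row per trajectory, column t+1 = state at time t),
#'   `labels`, the generating chain's state space, `start_state`, `seed`
#'   and `truncated`.
#' @export
simulate_trajectories <- function(chain, start_state, n_trajectories,
                                  horizon = NULL, seed = NULL,
                                  max_steps = 10000L) {
  stopifnot(inherits(chain, "markov_chain"))
  sidx <- match(start_state, chain$states$labels)
  if (is.na(sidx)) stop("unknown start state: ", start_state)
  if (n_trajectories < 1L) stop("need at least one trajectory")
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulate_matrix(chain$P, chain$states$is_absorbing,
                          rep.int(sidx, n_trajectories), horizon, max_steps)
  structure(list(states = sim$states, labels = chain$states$labels,
                 state_space = chain$states, start_state = start_state,
                 horizon = horizon, seed = seed, truncated = sim$truncated),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set:", nrow(x$states), "trajectories from '",
      x$start_state, "', ", ncol(x$states) - 1L, "steps",
      if (x$truncated) "(truncated before absorption)" else "", "\n")
  invisible(x)
}

#' Empirical episode statistics from simulated trajectories
#'
#' The Monte-Carlo counterpart of [episode_summary()]: per trajectory,
#' counts maximal runs in the target set that begin with an entry from
#' outside the set (a run already in progress at t = 0 is not an entry
#' unless `count_initial_episode = TRUE`), the occupancy (time points
#' t = 0, ..., T-1 spent in the set), and exits out of the set -- all
#' departures, and recoveries only (departures into absorbing states
#' dropped). Means come with Monte-Carlo standard errors; the mean episode
#' length is the ratio of mean occupancy to mean episode count, with a
#' delta-method standard error.
#'
#' @param trajectories a [simulate_trajectories()] result, or a plain
#'   matrix of state labels (rows = trajectories, column t+1 = state at
#'   time t) together with `states`.
#' @param target state name(s) of the episode set.
#' @param count_initial_episode logical, as in [episode_summary()].
#' @param states a [state_space()]; only needed when `trajectories` is a
#'   plain matrix.
#' @return A list with components `episodes`, `occupancy`, `avg_length`,
#'   `exits_all`, `exits_recovery` (each `c(mean, se)`) and
#'   `n_trajectories`.
#' @export
empirical_episode_stats <- function(trajectories, target,
                                    count_initial_episode = FALSE,
                                    states = NULL) {
  if (inherits(trajectories, "trajectory_set")) {
    X <- trajectories$states
    states <- trajectories$state_space
  } else {
    if (is.null(states)) stop("`states` required for a plain matrix input")
    X <- trajectories
    if (is.character(X)) {
      X <- matrix(match(X, states$labels), nrow = nrow(trajectories))
      if (anyNA(X)) stop("matrix contains states outside the state space")
    }
  }
  target <- as.character(target)
  tidx <- match(target, states$labels)
  if (anyNA(tidx)) stop("unknown target state(s): ",
                        paste(target[is.na(tidx)], collapse = ", "))
  ntraj <- nrow(X)
  Tn <- ncol(X) - 1L
  inT <- matrix(X %in% tidx, nrow = ntraj)
  inA <- matrix(states$is_absorbing[X], nrow = ntraj)

  if (Tn == 0L) {
    epi <- occ <- exa <- exr <- numeric(ntraj)
    if (count_initial_episode) epi <- as.numeric(inT[, 1L])
  } else {
    before <- inT[, seq_len(Tn), drop = FALSE]
    after <- inT[, seq_len(Tn) + 1L, drop = FALSE]
    epi <- rowSums(after & !before)
    if (count_initial_episode) epi <- epi + as.numeric(inT[, 1L])
    occ <- rowSums(before)
    exa <- rowSums(before & !after)
    exr <- rowSums(before & !after & !inA[, seq_len(Tn) + 1L, drop = FALSE])
  }

  msd <- function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(ntraj))
  me <- mean(epi); mo <- mean(occ)
  if (me > 0) {
    ve <- var(epi); vo <- var(occ); cv <- stats::cov(occ, epi)
    ratio <- mo / me
    se_ratio <- sqrt(pmax(0, vo / me^2 - 2 * cv * mo / me^3 + ve * mo^2 / me^4) / ntraj)
    avg <- c(mean = ratio, se = se_ratio)
  } else {
    avg <- c(mean = NA_real_, se = NA_real_)
  }
  list(episodes = msd(epi), occupancy = msd(occ), avg_length = avg,
       exits_all = msd(exa), exits_recovery = msd(exr),
       n_trajectories = ntraj)
}

#' Generate a synthetic homogeneous panel
#'
#' Simulates independent individual trajectories from one chain, observes
#' them at every step, truncates each block at its first absorbing
#' observation (the absorbing state itself is kept as the final
#' observation), and returns the result as [panel_data()].
#'
#' @param chain a [markov_chain()].
#' @param n_individuals number of individuals (blocks).
#' @param n_steps number of observed transitions per individual (each block
#'   has up to `n_steps + 1` observations).
#' @param initial_distribution named probability vector over transient
#'   states; default: everyone starts in the first transient state.
#' @param seed integer seed (optional).
#' @return A [panel_data()] object.
#' @export
generate_panel <- function(chain, n_individuals, n_steps,
                           initial_distribution = NULL, seed = NULL) {
  stopifnot(inherits(chain, "markov_chain"))
  if (!is.null(seed)) set.seed(seed)
  start_idx <- .draw_initial(chain$states, n_individuals, initial_distribution)
  sim <- .simulate_matrix(chain$P, chain$states$is_absorbing, start_idx,
                          steps = n_steps)
  # zero-padded ids keep block order stable under character sorting
  .panel_from_matrix(sim$states, chain$states,
                     ids = sprintf("ind%05d", seq_len(n_individuals)))
}

.draw_initial <- function(states, n, initial_distribution) {
  tr <- which(!states$is_absorbing)
  if (is.null(initial_distribution)) return(rep.int(tr[1L], n))
  p <- initial_distribution
  if (is.null(names(p)) && length(p) == length(tr)) {
    names(p) <- states$labels[tr]
  }
  idx <- match(names(p), states$labels[tr])
  if (anyNA(idx) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("`initial_distribution` must be a probability vector over the transient states")
  }
  tr[idx][sample.int(length(p), n, replace = TRUE, prob = p)]
}

# truncate padded trajectories at first absorbing observation, build panel
.panel_from_matrix <- function(X, states, ids) {
  n <- nrow(X)
  inA <- matrix(states$is_absorbing[X], nrow = n)
  first_abs <- apply(inA, 1L, function(z) if (any(z)) which.max(z) else ncol(X))
  state_seqs <- lapply(seq_len(n), function(k) X[k, seq_len(first_abs[k])])
  time_seqs <- lapply(first_abs, function(len) seq_len(len) - 1L)
  .new_panel(ids, state_seqs, time_seqs, states)
}

#' Configuration for panels with between-individual heterogeneity
#'
#' Describes a data-generating process in which each individual follows a
#' private transition matrix, so the pooled data are not Markov: repeated
#' transitions of the same individual are correlated through the shared
#' private matrix, violating the row-wise i.i.d. assumption behind the
#' model-based bootstrap. Two schemes are supported: a finite mixture of
#' chains (individuals drawn from components with given weights; the
#' default, easiest to interpret), and a logit-normal row perturbation of a
#' base chain (each individual's positive row entries receive Gaussian
#' noise of scale `sigma` on the log scale and are renormalized; zero
#' entries stay zero, so reachability is preserved).
#'
#' @param n_individuals,n_steps panel dimensions, as in [generate_panel()].
#' @param components list of [markov_chain()]s over a common state space
#'   (mixture scheme).
#' @param weights mixing weights, one per component (normalized to sum 1).
#' @param base_chain a [markov_chain()] (logit-normal scheme).
#' @param sigma perturbation scale on the log scale (logit-normal scheme).
#' @param scheme `"mixture"` or `"logit_normal"`.
#' @param initial_distribution as in [generate_panel()].
#' @param seed integer seed (optional).
#' @param max_retries retry cap for degenerate perturbed rows.
#' @return Object of class `"heterogeneous_config"`.
#' @export
heterogeneous_config <- function(n_individuals, n_steps, components = NULL,
                                 weights = NULL, base_chain = NULL,
                                 sigma = 0, scheme = c("mixture", "logit_normal"),
                                 initial_distribution = NULL, seed = NULL,
                                 max_retries = 20L) {
  scheme <- match.arg(scheme)
  if (scheme == "mixture") {
    if (is.null(components) || !length(components)) {
      stop("mixture scheme needs a non-empty `components` list")
    }
    lapply(components, function(ch) stopifnot(inherits(ch, "markov_chain")))
    ref <- components[[1L]]$states$labels
    for (ch in components) {
      if (!identical(ch$states$labels, ref)) {
        stop("all mixture components must share one state space")
      }
    }
    if (is.null(weights)) weights <- rep(1, length(components))
    if (length(weights) != length(components) || any(weights < 0) || sum(weights) <= 0) {
      stop("`weights` must be non-negative, one per component")
    }
    weights <- weights / sum(weights)
  } else {
    if (!inherits(base_chain, "markov_chain")) {
      stop("logit_normal scheme needs a `base_chain`")
    }
    if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  }
  structure(list(scheme = scheme, components = components, weights = weights,
                 base_chain = base_chain, sigma = sigma,
                 n_individuals = n_individuals, n_steps = n_steps,
                 initial_distribution = initial_distribution, seed = seed,
                 max_retries = max_retries),
            class = "heterogeneous_config")
}

# logit-normal perturbation of one chain's transient rows
.perturb_chain <- function(chain, sigma, max_retries) {
  P <- chain$P
  n <- chain$states$n
  for (i in seq_len(n)) {
    pos <- which(P[i, ] > 0)
    if (length(pos) < 2L || sigma == 0) next
    for (attempt in seq_len(max_retries)) {
      w <- log(P[i, pos]) + rnorm(length(pos), 0, sigma)
      w <- exp(w - max(w))
      row <- w / sum(w)
      if (all(is.finite(row)) && all(row > 0)) break
      if (attempt == max_retries) stop("perturbation failed to produce a valid row")
    }
    P[i, pos] <- row
  }
  P
}

#' Generate a synthetic panel with between-individual heterogeneity
#'
#' Each individual draws a private transition matrix from the scheme in
#' `config` and contributes one simulated block; the pooled panel is
#' non-Markov at the population level. With a single mixture component or
#' `sigma = 0` this reduces to the homogeneous generator.
#'
#' @param config a [heterogeneous_config()].
#' @return A [panel_data()] object.
#' @export
generate_heterogeneous_panel <- function(config) {
  stopifnot(inherits(config, "heterogeneous_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  B <- config$n_individuals
  if (config$scheme == "mixture") {
    states <- config$components[[1L]]$states
    comp <- sample.int(length(config$components), B, replace = TRUE,
                       prob = config$weights)
    start_idx <- .draw_initial(states, B, config$initial_distribution)
    X <- matrix(NA_integer_, B, config$n_steps + 1L)
    for (c_id in unique(comp)) {
      rows <- which(comp == c_id)
      sim <- .simulate_matrix(config$components[[c_id]]$P, states$is_absorbing,
                              start_idx[rows], steps = config$n_steps)
      X[rows, ] <- sim$states
    }
  } else {
    states <- config$base_chain$states
    start_idx <- .draw_initial(states, B, config$initial_distribution)
    X <- matrix(NA_integer_, B, config$n_steps + 1L)
    for (k in seq_len(B)) {
      Pk <- .perturb_chain(config$base_chain, config$sigma, config$max_retries)
      sim <- .simulate_matrix(Pk, states$is_absorbing, start_idx[k],
                              steps = config$n_steps)
      X[k, ] <- sim$states
    }
  }
  .panel_from_matrix(X, states, ids = sprintf("ind%05d", seq_len(B)))
}

#' Random absorbing chain generator
#'
#' Draws a valid absorbing chain with labelled states `T1, ..., Tn` and
#' `A1, ..., Aq`: transient rows allocate a total mass between
#' `min_absorbing` and `2 * min_absorbing` to the absorbing states and
#' spread the rest over all transient states (Dirichlet-style), which
#' guarantees reachability and keeps expected absorption times moderate.
#' Uses the current RNG state (seed with `set.seed()`).
#'
#' @param n_transient number of transient states (>= 1).
#' @param n_absorbing number of absorbing states (>= 1).
#' @param min_absorbing minimum per-row total absorbing mass.
#' @return A [markov_chain()].
#' @export
random_absorbing_chain <- function(n_transient, n_absorbing = 1,
                                   min_absorbing = 0.05) {
  stopifnot(n_transient >= 1, n_absorbing >= 1,
            min_absorbing > 0, 2 * min_absorbing < 1)
  labels <- c(paste0("T", seq_len(n_transient)),
              paste0("A", seq_len(n_absorbing)))
  m <- n_transient + n_absorbing
  P <- matrix(0, m, m, dimnames = list(labels, labels))
  for (i in seq_len(n_transient)) {
    a <- runif(1, min_absorbing, 2 * min_absorbing)
    wa <- -log(runif(n_absorbing))
    wt <- -log(runif(n_transient))
    P[i, ] <- c((1 - a) * wt / sum(wt), a * wa / sum(wa))
  }
  for (j in seq_len(n_absorbing)) P[n_transient + j, n_transient + j] <- 1
  markov_chain(P, absorbing = labels[(n_transient + 1):m])
}

#' Describe one scenario for the bootstrap bias harness
#'
#' @param name scenario label.
#' @param generate function of a single integer seed returning a
#'   [panel_data()] dataset.
#' @param statistic a [chain_statistic()] returning a single value.
#' @param true_value optional true value of the statistic under the
#'   data-generating process, used for confidence-interval coverage; when
#'   `NULL`, the across-dataset mean of the point estimates is used as a
#'   pseudo-truth (reported in `truth_source`).
#' @return A list of class `"harness_scenario"`.
#' @export
harness_scenario <- function(name, generate, statistic, true_value = NULL) {
  stopifnot(is.character(name), is.function(generate),
            inherits(statistic, "chain_statistic"))
  structure(list(name = name, generate = generate, statistic = statistic,
                 true_value = true_value),
            class = "harness_scenario")
}

#' Relative bias and coverage of bootstrap variance estimators
#'
#' For each scenario: simulates `n_datasets` independent panels, computes
#' the statistic's point estimate on each, runs both the block and the
#' model-based bootstrap, and compares the mean estimated variance against
#' the truth -- the across-dataset empirical variance of the point
#' estimates. Also reports the empirical coverage of the 95% (or `level`)
#' percentile confidence intervals, and flags scenarios with fewer than 50
#' blocks per dataset, where resampling is known to be unreliable.
#'
#' @param scenarios list of [harness_scenario()]s.
#' @param n_datasets simulated datasets per scenario.
#' @param n_replicates bootstrap replicates per dataset and method.
#' @param seed integer seed for the whole harness.
#' @param level confidence level.
#' @return data.frame with one row per scenario x method: `rel_bias`
#'   (relative bias of the mean estimated variance), `coverage`,
#'   `mean_variance`, `truth_variance`, failure counts and a
#'   `small_sample` flag.
#' @export
variance_bias_harness <- function(scenarios, n_datasets = 200,
                                  n_replicates = 500, seed = NULL,
                                  level = 0.95) {
  if (inherits(scenarios, "harness_scenario")) scenarios <- list(scenarios)
  if (!length(scenarios)) stop("scenario list must not be empty")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  scen_seeds <- matrix(sample.int(.Machine$integer.max, 3L * n_datasets * length(scenarios)),
                       ncol = 3L)
  out <- list()
  row <- 0L
  for (sc_i in seq_along(scenarios)) {
    sc <- scenarios[[sc_i]]
    pts <- numeric(n_datasets)
    vb <- vm <- numeric(n_datasets)
    cib <- cim <- matrix(NA_real_, n_datasets, 2L)
    fb <- fm <- 0L
    small <- FALSE
    for (d in seq_len(n_datasets)) {
      sd3 <- scen_seeds[(sc_i - 1L) * n_datasets + d, ]
      panel <- sc$generate(sd3[1L])
      if (panel$B < 50L) small <- TRUE
      bb <- block_bootstrap(panel, sc$statistic, n_replicates,
                            seed = sd3[2L], level = level)
      mb <- model_based_bootstrap(count_transitions(panel), sc$statistic,
                                  n_replicates, seed = sd3[3L], level = level)
      pts[d] <- bb$point[1L]
      vb[d] <- bb$variance[1L]; vm[d] <- mb$variance[1L]
      fb <- fb + bb$n_failed; fm <- fm + mb$n_failed
      cib[d, ] <- c(bb$ci_lower[1L], bb$ci_upper[1L])
      cim[d, ] <- c(mb$ci_lower[1L], mb$ci_upper[1L])
    }
    truth_var <- var(pts)
    if (is.null(sc$true_value)) {
      truth <- mean(pts)  # pseudo-truth when no analytic value is available
      truth_source <- "across-dataset mean (pseudo-truth)"
    } else {
      truth <- sc$true_value
      truth_source <- "analytic true value"
    }
    covb <- cib[, 1L] <= truth & truth <= cib[, 2L]
    covm <- cim[, 1L] <= truth & truth <= cim[, 2L]
    for (meth in c("block", "model_based")) {
      row <- row + 1L
      out[[row]] <- data.frame(
        scenario = sc$name, method = meth,
        rel_bias = (mean(if (meth == "block") vb else vm) - truth_var) / truth_var,
        coverage = mean(if (meth == "block") covb else covm),
        mean_variance = mean(if (meth == "block") vb else vm),
        truth_variance = truth_var,
        n_datasets = n_datasets, n_replicates = n_replicates,
        n_failed = if (meth == "block") fb else fm,
        small_sample = small,
        truth_source = truth_source,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Frozen scenarios of the bootstrap calibration study
#'
#' The two default scenarios used throughout the package's bootstrap
#' calibration: a monthly illness-death chain with recovery (healthy,
#' ill, dead), observed as panels of `n_individuals` individuals over
#' `n_steps` monthly steps, all starting healthy; the statistic is the
#' expected number of illness episodes over a 60-month horizon starting
#' healthy.
#'
#' * `homogeneous`: every individual follows
#'   `H = (0.88, 0.10, 0.02)`, `I = (0.25, 0.71, 0.04)` -- the Markov
#'   assumption holds, and the analytic episode count is supplied as the
#'   coverage truth.
#' * `heterogeneous`: a 50/50 mixture of two sub-populations differing
#'   only in illness incidence (`p(H -> I)` = 0.04 vs 0.16, identical
#'   recovery and mortality), so repeated transitions of one individual
#'   are correlated through the private matrix and the pooled panel
#'   violates the row-wise i.i.d. assumption.
#'
#' @param n_individuals,n_steps panel dimensions.
#' @return Named list of two [harness_scenario()]s, `homogeneous` and
#'   `heterogeneous`.
#' @export
default_bias_scenarios <- function(n_individuals = 150, n_steps = 60) {
  lab <- c("healthy", "ill", "dead")
  mk <- function(p_hi) {
    P <- rbind(c(0.98 - p_hi, p_hi, 0.02),
               c(0.25, 0.71, 0.04),
               c(0, 0, 1))
    dimnames(P) <- list(lab, lab)
    markov_chain(P, absorbing = "dead")
  }
  hom_chain <- mk(0.10)
  comp_low <- mk(0.04)
  comp_high <- mk(0.16)
  stat <- episode_statistic(target = "ill", start = "healthy", horizon = 60,
                            what = "episodes")
  truth <- unname(stat$fn(hom_chain))
  list(
    homogeneous = harness_scenario(
      "homogeneous",
      generate = function(seed) generate_panel(hom_chain, n_individuals,
                                               n_steps, seed = seed),
      statistic = stat, true_value = truth),
    heterogeneous = harness_scenario(
      "heterogeneous",
      generate = local({
        cfg_tmpl <- list(comp_low, comp_high)
        function(seed) generate_heterogeneous_panel(
          heterogeneous_config(n_individuals, n_steps,
                               components = cfg_tmpl, weights = c(0.5, 0.5),
                               seed = seed))
      }),
      statistic = stat)
  )
}
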