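# shared fixtures: small chains with hand-checkable algebra and a toy panel

# reversible illness-death chain; (I - U) inverts by hand:
# det = 0.4*0.5 - 0.3*0.2 = 0.14
illness_death_chain <- function() {
  P <- rbind(H = c(0.6, 0.3, 0.1),
             I = c(0.2, 0.5, 0.3),
             D = c(0, 0, 1))
  colnames(P) <- rownames(P)
  markov_chain(P, absorbing = "D")
}

# illness without recovery: I can only be left through death, so the
# episode count from H is a first-passage probability
no_recovery_chain <- function() {
  P <- rbind(H = c(0.5, 0.3, 0.2),
             I = c(0, 0.7, 0.3),
             D = c(0, 0, 1))
  colnames(P) <- rownames(P)
  markov_chain(P, absorbing = "D")
}

# 4-state disability model (synthetic monthly rates, for recipe tests only)
synthetic_frailty_rates <- function() {
  lab <- c("none", "mild", "severe", "dead")
  Q <- matrix(0, 4, 4, dimnames = list(lab, lab))
  Q["none", c("mild", "severe", "dead")] <- c(0.040, 0.005, 0.010)
  Q["mild", c("none", "severe", "dead")] <- c(0.150, 0.060, 0.030)
  Q["severe", c("none", "mild", "dead")] <- c(0.030, 0.120, 0.080)
  rate_matrix(Q, absorbing = "dead", units = "month")
}

# two-individual panel with hand-countable transitions:
# id1 = H,H,I,D; id2 = H,I,I
toy_panel_df <- function() {
  data.frame(id = c(1, 1, 1, 1, 2, 2, 2),
             time = c(0:3, 0:2),
             state = c("H", "H", "I", "D", "H", "I", "I"),
             stringsAsFactors = FALSE)
}

hid_states <- function() state_space(c("H", "I", "D"), absorbing = "D")

# independent first-passage oracle: probability of ever entering the target
# before absorption, by first-step analysis on the non-target transient states
transient_labels <- function(chain) {
  chain$states$labels[!chain$states$is_absorbing]
}

first_passage_oracle <- function(chain, target) {
  labels <- chain$states$labels
  tr <- transient_labels(chain)
  out <- setdiff(tr, target)
  P <- chain$P
  A <- P[out, out, drop = FALSE]
  b <- rowSums(P[out, intersect(labels, target), drop = FALSE])
  setNames(as.vector(solve(diag(length(out)) - A, b)), out)
}
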