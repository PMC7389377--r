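# mcepisodes

Episode counts and lengths for discrete-time absorbing Markov chains,
for health-expectancy research: epidemiologists, demographers and
biostatisticians who model transitions between health states (healthy /
ill / dead, disability grades, organ-function classes) and want to know
not just *how long* is spent in a state but *how often it is entered
and how long each episode lasts*.

## The method

For an absorbing chain with transition matrix `P` (row-to-column
orientation) and transient-to-transient block `U`, the fundamental
matrix

    N = (I − U)⁻¹

holds expected times in each transient state. Attaching a reward
`r_ij` to each transition, the expected accumulated reward per starting
state is the Markov-chains-with-rewards identity

    e = N Z (P ∘ R) 1ₘ ,     Z = (Iₙ | 0)

Setting `r_ij = 1` exactly for transitions *into* a target state (or
set) from outside makes `e` the expected number of episodes; the
average episode length is the ratio `a_ij = n_ij / e_i`; the transposed
rewards count exits (all departures, or recoveries only). Finite
horizons replace `N` by the partial sum `I + U + … + U^(T−1)`.
Occurrence-exposure rates `Q` convert to probabilities with
`P = (I + Q/2)(I − Q/2)⁻¹`. Sampling uncertainty comes from a block
bootstrap (resampling whole individuals of a longitudinal panel, which
survives violations of the Markov assumption) or the classical
model-based multinomial bootstrap, with percentile intervals.

## Worked example

The reversible illness-death model with healthy (H), ill (I), dead (D):

```r
library(mcepisodes)
P <- rbind(H = c(0.6, 0.3, 0.1),
           I = c(0.2, 0.5, 0.3),
           D = c(0,   0,   1))
colnames(P) <- rownames(P)
chain <- markov_chain(P, absorbing = "D")

fundamental_matrix(chain)$N
#>          H        I
#> H 3.571429 2.142857
#> I 1.428571 2.857143

episode_summary(chain, target = "I")
#> Episode summary for target {I}
#>  start episodes occupancy avg_length exits_all exits_recovery horizon units
#>      H   1.0714     2.143      2.000     1.071         0.4286     Inf  step
#>      I   0.4286     2.857      6.667     1.429         0.5714     Inf  step
```

Reading the `H` row: a healthy individual can expect to live 5.71 more
steps, 2.14 of them ill; the illness time splits into 1.07 expected
episodes of illness averaging 2.0 steps each; entries balance exits
(1.07), of which 0.43 end in recovery and the rest in death. From a
panel you would instead start with

```r
pan <- read_panel("panel.csv", state_space(c("H","I","D"), "D"))
est <- estimate_transitions(pan)                      # rates + MLE routes
boot <- bootstrap_episodes(pan, target = "I", start = "H",
                           n_replicates = 1000, seed = 1)
```

A thin command-line wrapper over these functions ships in
`inst/cli/mcepisodes.R` (subcommands `estimate`, `episodes`,
`bootstrap`, `simulate`, `casestudy`; see
`inst/extdata/example_config.yaml`).

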