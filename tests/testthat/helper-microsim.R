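# Individual-level microsimulation used as an independent oracle for the
# cohort engine: N women are walked through the same age-, arm- and
# cycle-dependent transition matrices one at a time (vectorised over
# individuals), and the empirical state distribution is compared with the
# deterministic cohort trace.
microsimulate <- function(model, arm, n_individuals, n_cycles, seed = 1) {
  set.seed(seed)
  s <- model$settings
  values <- parameter_means(model$parameters)
  state <- rep(1L, n_individuals) # everyone starts in the early state
  occ <- matrix(NA_real_, n_cycles, 5)
  for (t in seq_len(n_cycles) - 1) {
    m <- build_transition_matrix(model, arm, s$start_age + t, t, values)
    new_state <- state
    for (from in 1:3) {
      idx <- which(state == from)
      if (length(idx) == 0) next
      cum <- cumsum(m[from, ])
      new_state[idx] <- findInterval(runif(length(idx)), cum) + 1L
    }
    state <- new_state
    occ[t + 1, ] <- tabulate(state, nbins = 5) / n_individuals
  }
  colnames(occ) <- health_states()
  occ
}
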