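# Individual-level microsimulation: the independent oracle for the
# cohort-propagation engine. Each simulated miner follows the same
# per-cycle transition probabilities; occupancy proportions converge to
# the cohort trace by the law of large numbers.
microsimulate_cohort <- function(schedule, n, seed) {
  set.seed(seed)
  state <- rep(1L, n) # 1 health, 2 cwp, 3 death
  trace <- matrix(0, nrow(schedule) + 1L, 3L,
                  dimnames = list(NULL, c("health", "cwp", "death")))
  trace[1L, ] <- c(1, 0, 0)
  for (t in seq_len(nrow(schedule))) {
    lambda <- schedule$p_health_to_cwp[t]
    q_h <- schedule$p_health_to_death[t]
    q_c <- schedule$p_cwp_to_death[t]
    u <- stats::runif(n)
    healthy <- state == 1L
    sick <- state == 2L
    new_state <- state
    new_state[healthy & u < lambda] <- 2L
    new_state[healthy & u >= lambda & u < lambda + q_h] <- 3L
    new_state[sick & u < q_c] <- 3L
    state <- new_state
    trace[t + 1L, ] <- tabulate(state, 3L) / n
  }
  trace
}
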