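# Shared fixtures, generated once per test run.

paper_interventions <- list(
  engineering = list(list(coverage = 0.95, efficiency = 0.95)),
  individual = list(list(coverage = 0.70, efficiency = 0.70)),
  comprehensive = list(list(coverage = 0.95, efficiency = 0.95),
                       list(coverage = 0.70, efficiency = 0.70)))

# Published base-case per-arm discounted costs and QALYs (model outputs
# reported by the source analysis, used as inputs to the CEA layer).
published_outcomes <- data.frame(
  arm = c("null", "engineering", "individual", "comprehensive"),
  cost_rmb = c(36262.67, 71448.94, 78869.35, 116918.13),
  qaly = c(16.36, 17.50, 16.85, 17.60))

base_config <- default_config()
synthetic_schedule <- generate_schedule(synthetic_schedule_spec(seed = 1))

# Small constant schedule for hand-checkable dynamics.
toy_schedule <- function(n = 3, lambda = 0.001, q_h = 0.002, q_c = 0.05,
                         entry_age = 20) {
  transition_schedule(seq_len(n) - 1L, entry_age + seq_len(n) - 1L,
                      rep(lambda, n), rep(q_h, n), rep(q_c, n))
}

# Trace pinned at a fixed occupancy for accrual closed forms.
constant_trace <- function(n_rows, occ) {
  matrix(rep(occ, each = n_rows), nrow = n_rows,
         dimnames = list(NULL, c("health", "cwp", "death")))
}
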