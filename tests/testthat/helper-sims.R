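# Simulation helpers shared by the goodness-of-fit and fitting tests.

# Adult-marked cohorts only: detection-collapsed histories from such a design
# are a clean single-state null for the contingency components (gosling
# cohorts would add structural transience through delayed recruitment).
sim_adults <- function(seed, p_A, p_B, n = 1500, T = 12, phiA = 0.85) {
  params <- parameter_set(T, piA = 0.5,
    phiJ = list(intercept = qlogis(0.6)), phiA = phiA,
    a = c(A = 0.4, B = 0.4),
    p = list(intercept = qlogis(p_A), groupB = qlogis(p_A) - qlogis(p_B)))
  design <- simulation_design(T, integer(T),
                              brantmix:::.split_cohorts(n, seq_len(T - 2L), T),
                              params, seed)
  simulate_histories(design)
}
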