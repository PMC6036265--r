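# shared fixtures: small deterministic objects used across test files

default_prior <- prior_spec()
two_sided_prior <- prior_spec(side = "two_sided")
default_thresholds <- evidence_thresholds()

# one small simulated cell reused by the curve/separation tests
small_cell <- function(n = 10L, dz = 0.2, reps = 150L, seed = 2024L) {
  run_replicates(n, dz, reps = reps, seed = seed)
}
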