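# Shared fixtures built in code.

# exactly normalised table with quantum interference structure and known
# ground-truth phases (all three columns sum to 1)
exact_quantum_table <- function(n = 12, seed = 1) {
  gen_quantum_table(n, seed = seed, balanced = TRUE)
}

# classical average table: disjunction equals the component mean everywhere
mean_table <- function(n = 6, seed = 2) {
  set.seed(seed)
  mu_A <- stats::rgamma(n, 2); mu_A <- mu_A / sum(mu_A)
  mu_B <- stats::rgamma(n, 2); mu_B <- mu_B / sum(mu_B)
  membership_table(sprintf("item%02d", 1:n), mu_A, mu_B, (mu_A + mu_B) / 2)
}
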