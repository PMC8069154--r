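# Random generators for property-style tests. All tests seed explicitly
# before using these.

rand_belief <- function(n) {
  x <- stats::rgamma(n, shape = 1)
  x / sum(x)
}

# a smooth random free-energy context (log-likelihood evidence drawn from a
# Gaussian on the log scale, prior from a random simplex point)
rand_ctx <- function(n, scale = 2) {
  fe_context(stats::rnorm(n, 0, scale), log(rand_belief(n)))
}

# a random categorical observation model: likelihood matrix, prior, and the
# enumeration posterior for outcome o, computed from the raw joint table
# (the independent oracle used against exact_posterior / free_energy)
rand_obs_model <- function(n_states, n_outcomes) {
  A <- matrix(stats::rgamma(n_states * n_outcomes, 1), n_outcomes, n_states)
  A <- sweep(A, 2, colSums(A), "/")
  p <- rand_belief(n_states)
  list(A = A, prior = p)
}

enumeration_posterior <- function(mod, o) {
  joint <- mod$A[o, ] * mod$prior          # P(o, s) row of the joint table
  list(posterior = joint / sum(joint), evidence = sum(joint))
}

total_variation <- function(a, b) 0.5 * sum(abs(a - b))
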