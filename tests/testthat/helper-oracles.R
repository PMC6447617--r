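# Independent oracles used across the suite.

# Central-difference Jacobian of a vector field.
num_jacobian <- function(f, x, h = 1e-7) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

# Warshall transitive closure: strong connectivity of the graph of
# positive entries, independent of igraph.
warshall_strongly_connected <- function(M) {
  S <- nrow(M)
  R <- (M > 0) | diag(S) > 0
  for (k in seq_len(S)) R <- R | (outer(R[, k], R[k, ]))
  all(R)
}

# Brute-force diffusion matrix: explicit sum over all (die, born) events.
bruteforce_diffusion <- function(com, m) {
  w <- replacement_rates(m, com)
  S <- length(m)
  D <- matrix(0, S, S)
  for (a in seq_len(S)) for (b in seq_len(S)) {
    jump <- rep(0, S)
    jump[b] <- jump[b] + 1
    jump[a] <- jump[a] - 1
    D <- D + w[b] * m[a] * outer(jump, jump)
  }
  D
}

# A small dense cooperative community with an interior equilibrium.
random_coop_community <- function(S, c_M = 1, mu = 1, sigma = 0.2, eps1 = 1,
                                  c_L = 0, eps2 = 0) {
  spec <- ensemble_spec(S, c_M = c_M, c_L = c_L, family = "abs-normal",
                        mu = mu, sigma = sigma)
  com <- sample_community(spec, eps1 = eps1, eps2 = eps2, eps3 = 0)
  while (!is_irreducible(com$M))
    com <- sample_community(spec, eps1 = eps1, eps2 = eps2, eps3 = 0)
  com
}
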