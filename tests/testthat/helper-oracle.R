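# Independent oracles used across the suite.
#
# oracle_rhs expands the occupancy dynamics term by term with scalar loops,
# deliberately avoiding the vectorized cumulative-sum formulation used by the
# package, so the two routes share no code.
oracle_rhs <- function(p, f, q, m, eps = 0) {
  n <- length(p)
  dp <- numeric(n)
  for (i in seq_len(n)) {
    open <- 1 - sum(p[seq_len(i)])
    colonize <- q * f[i] * p[i] * open
    displaced <- if (i > 1) q * sum(f[seq_len(i - 1)] * p[seq_len(i - 1)]) * p[i]
                 else 0
    dp[i] <- colonize - displaced - m * p[i] + eps
  }
  dp
}

# Brute-force stationary state: long integration from a strictly positive
# initial state, independent of the package's simulate_community().
oracle_equilibrium <- function(f, q, m, t_end = 1e7) {
  out <- deSolve::ode(y = rep(1e-2, length(f)), times = c(0, t_end),
                      func = function(t, p, parms) list(oracle_rhs(p, f, q, m)),
                      method = "lsoda", rtol = 1e-11, atol = 1e-14,
                      maxsteps = 1e6)
  pmax(out[2, -1], 0)
}

# Random small community instance. Fecundities are redrawn if any species
# sits within 0.05 of the persistence floor m/q: such borderline species have
# near-zero decay rates and no finite integration horizon resolves them.
random_instance <- function(n_max = 6) {
  n <- sample(2:n_max, 1)
  q <- stats::runif(1, 0.2, 1)
  m <- stats::runif(1, 0.05, 0.5)
  repeat {
    f <- stats::runif(n, 0.1, 3)
    if (all(abs(f - m / q) > 0.05)) break
  }
  list(f = f, q = q, m = m)
}

paper_params <- function(immigration = 0) {
  community_params(q = 0.3, m = 0.2, immigration = immigration)
}
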