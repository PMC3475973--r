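# Independent stationary-state oracle: the inter-class recursion written
# out directly, closed by a bracketing root search on
# g(N) = sum(classes(N)) - N. Deliberately shares no code with the
# package's damped fixed-point solver.
oracle_stationary <- function(b, d, delta_c, N) {
  l <- length(d)
  r <- delta_c / N
  out <- numeric(l)
  out[1] <- b / (d[1] + (1 - d[1]) * r)
  for (i in 2:l)
    out[i] <- (1 - d[i - 1]) * r * out[i - 1] / (d[i] + (1 - d[i]) * r)
  out
}

oracle_equilibrium <- function(b, d, delta_c) {
  if (delta_c == 0) return(c(b / d[1], rep(0, length(d) - 1)))
  g <- function(N) sum(oracle_stationary(b, d, delta_c, N)) - N
  Nstar <- stats::uniroot(g, c(1e-9, b / d[1]), tol = 1e-14)$root
  oracle_stationary(b, d, delta_c, Nstar)
}

ref_b <- 10
ref_d <- c(0.1, 0.11, 0.2, 0.9, 1)
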