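# shared small fixtures, built in code

# a two-source Laplacian mixture for ICA tests
laplacian_sources <- function(n, k = 2, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(k), function(i) {
    u <- stats::runif(n) - 0.5
    -sign(u) * log(1 - 2 * abs(u))
  }, numeric(n)))
}

# simulate a stationary VAR from coefficient blocks
simulate_var <- function(A, N, seed = 1, sd = 1) {
  set.seed(seed)
  M <- dim(A)[1]; p <- dim(A)[3]
  X <- matrix(0, M, N + 100)
  E <- matrix(stats::rnorm(M * (N + 100), 0, sd), M)
  for (t in (p + 1):(N + 100)) {
    x <- E[, t]
    for (k in seq_len(p)) x <- x + A[, , k] %*% X[, t - k]
    X[, t] <- x
  }
  X[, 101:(N + 100), drop = FALSE]
}

# small default-network dataset at the connectivity rate (cheap)
small_network_128 <- function(duration_s = 60, seed = 1) {
  spec <- source_network_spec()
  ev <- generate_events(spec$cadence, duration_s, limb_labels(),
                        phase_jitter_sd = 0.02, seed = seed)
  ss <- simulate_source_network(spec, ev, fs = 128,
                                duration_s = duration_s, seed = seed + 1)
  list(spec = spec, events = ev, ss = ss)
}
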