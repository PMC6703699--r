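# Independent measurement oracles: extract phenomenological quantities from
# long noise-free simulations, to cross-check the closed-form solutions.

# Smallest signed angular difference (radians).
angle_diff <- function(a, b) {
  ((a - b + pi) %% (2 * pi)) - pi
}

# Steady-state amplitude and lag by least-squares sinusoid regression on
# the post-transient half of a long run driven by sin(omega * n).
oracle_periodic <- function(K, A, D, f, N = 384, n_total = 6000) {
  omega <- 2 * pi * f / N
  n <- seq_len(n_total)
  x <- simulate_state(sin(omega * n), K = K, A = A, m = 0, D = D, G = 0)
  post <- (n_total / 2 + 1):n_total
  cf <- stats::.lm.fit(cbind(sin(omega * post), cos(omega * post)),
                       x[post])$coefficients
  list(a = sqrt(sum(cf^2)), lag = atan2(-cf[2], cf[1]))
}

# Asymptote (long-run value) and dominant decay rate (log-linear
# regression on |x - B0| after the fast alternating mode has died) from a
# zero-stimulus run started away from the fixed point.
oracle_baseline <- function(K, A, m, D, n_total = 10000) {
  x <- simulate_state(rep(0, n_total), K = K, A = A, m = m, D = D, G = 1)
  B0 <- x[n_total]
  dev <- abs(x - B0)
  start <- if (D == 0) 5L else 60L
  win <- seq.int(start, min(2000L, n_total))
  win <- win[dev[win] > 1e-11]
  stopifnot(length(win) > 20)
  fit <- stats::lm(log(dev[win]) ~ win)
  list(B0 = B0, lambda = -unname(stats::coef(fit)[2]))
}

# Parameter grid of clearly stable generative settings (margin away from
# the unit circle) crossed with the session frequencies.
stable_param_grid <- function() {
  grid <- expand.grid(
    K = c(0.005, 0.01, 0.02, 0.035, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
    A = c(0.97, 0.99, 1),
    D = c(-0.25, -0.13, -0.05, 0)
  )
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    r <- characteristic_roots(grid$K[i], grid$A[i], grid$D[i])
    max(Mod(r)) < 0.999
  }, logical(1))
  grid <- grid[keep, ]
  freqs <- c(1, 3, 6, 12, 24)
  grid$f <- freqs[(seq_len(nrow(grid)) - 1) %% length(freqs) + 1]
  grid$m <- -0.004
  grid
}

# Explicit convolution solution of the single-error (D = 0) recursion:
# x(n) = (A-K)^(n-1) G + sum_{j<n} (A-K)^(n-1-j) (K s(j) + m).
conv_solution <- function(K, A, m, s, G) {
  n <- length(s)
  x <- numeric(n)
  x[1] <- G
  r <- A - K
  for (t in 2:n) {
    j <- 1:(t - 1)
    x[t] <- r^(t - 1) * G + sum(r^(t - 1 - j) * (K * s[j] + m))
  }
  x
}
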