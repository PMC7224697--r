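# Reference implementations used as oracles: plain R loops mirroring the
# model definitions, independent of the compiled path.

# One full composite step (dynamics + plasticity + clip) in scalar R.
# Mirrors the contract: transmission uses g(y); plasticity consumes the
# rectified state of the step being integrated; dynamics see pre-update
# weights; clipping last.
reference_step <- function(y, W, H, alpha, cfg) {
  n <- length(y)
  n_exc <- length(alpha)
  r <- transfer_rate(y, cfg$r0, cfg$rmax, cfg$baseline_shift)
  rl <- if (identical(cfg$plasticity_activity, "linear")) pmax(y, 0) else r
  y_new <- y + (cfg$dt / cfg$tau_m) * (-y + as.vector(W %*% r) + H)
  dts <- cfg$dt / 1000
  W_new <- W
  for (i in seq_len(n_exc)) {
    rs <- sum(W[i, seq_len(n_exc)])
    for (j in seq_len(n_exc)) {
      if (i == j) next
      w <- W[i, j] + dts * (alpha[i] * rl[i] * rl[j] -
                              cfg$zeta * (rs - cfg$w_total_ee))
      W_new[i, j] <- min(max(w, 0), cfg$wmax)
    }
  }
  for (k in seq_len(n - n_exc)) {
    jj <- n_exc + k
    for (i in seq_len(n_exc)) {
      w <- W[i, jj] - dts * cfg$eta * rl[jj] * (rl[i] - cfg$y0)
      W_new[i, jj] <- min(max(w, -cfg$wmax_inh), 0)
    }
  }
  list(y = y_new, W = W_new)
}

# Scalar-loop Pearson correlation
reference_pearson <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Scalar-loop Spearman with average ranks
reference_spearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  reference_pearson(rank(x), rank(y))
}

# Scalar-loop connection specificity / selectivity
reference_specificity <- function(W, prefs) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- c(); ns <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      if (prefs[j] == prefs[i]) s <- c(s, W[i, j]) else ns <- c(ns, W[i, j])
    }
    out[i] <- mean(s) / mean(ns)
  }
  out
}

reference_selectivity <- function(W, prefs) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- c(); ns <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      if (prefs[j] == prefs[i]) s <- c(s, W[i, j]) else ns <- c(ns, W[i, j])
    }
    out[i] <- mean(s) - mean(ns)
  }
  out
}

# small deterministic network for composite-step tests
make_test_net <- function(n_exc = 4, n_stimuli = 2, cfg = network_config(),
                          alpha = 1e-4) {
  fc_network(n_exc, n_stimuli, rep(alpha, n_exc), cfg)
}
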