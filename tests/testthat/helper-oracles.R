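# Independent reference implementations used as oracles. Deliberately
# naive (explicit loops, expand.grid enumeration) and kept separate from
# the package's vectorised code paths.

# Plain FCM iteration (no spatial step) with explicit loops.
fcm_oracle_iterate <- function(x, centroids, p, iterations) {
  x <- as.numeric(x)
  N <- length(x)
  C <- length(centroids)
  v <- centroids
  history <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    u <- matrix(0, C, N)
    for (n in seq_len(N)) {
      dn <- abs(x[n] - v)
      if (any(dn == 0)) {
        u[, n] <- as.numeric(dn == 0) / sum(dn == 0)
      } else {
        w <- dn^(-2 / (p - 1))
        u[, n] <- w / sum(w)
      }
    }
    v_new <- numeric(C)
    for (m in seq_len(C)) {
      num <- 0; den <- 0
      for (n in seq_len(N)) {
        num <- num + u[m, n]^p * x[n]
        den <- den + u[m, n]^p
      }
      v_new[m] <- num / den
    }
    J <- 0
    for (m in seq_len(C)) for (n in seq_len(N))
      J <- J + u[m, n]^p * (x[n] - v_new[m])^2
    v <- v_new
    history[[it]] <- list(memberships = u, centroids = v, cost = J)
  }
  history
}

# Exact two-tailed signed-rank p-value by direct enumeration of every
# sign assignment (expand.grid; independent of the bit-mask path).
signed_rank_p_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Small, fast acquisition geometry used across end-to-end tests: 10 Hz
# frame rate, 8 s quiet windows, ~4.9 mm record.
reduced_acquisition <- function(seed = 42L) {
  acquisition_config(aline_rate = 10, num_samples = 640, rng_seed = seed)
}

reduced_scenario <- function(plateau_mm = 2.0, duration = 20, ...) {
  ablation_scenario(laser_duration = duration, pre_window = 8,
                    post_window = 8, surface_depth = 1.2,
                    max_lesion_depth = plateau_mm,
                    growth_time_constant = 6, ...)
}
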