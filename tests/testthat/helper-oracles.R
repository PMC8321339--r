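# Independent brute-force oracles and small clip builders used across tests.
# These deliberately avoid the package's own code paths.

# Plateau-aware local-minima scan: walk runs of equal values and report the
# first index of every interior run lower than both neighboring runs.
oracle_local_minima <- function(v) {
  n <- length(v)
  out <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (i > 1L && j < n && v[i] < v[i - 1L] && v[i] < v[j + 1L]) {
      out <- c(out, i)
    }
    i <- j + 1L
  }
  out
}

# Two-pass per-frame spatial standard deviation with explicit loops.
oracle_spatial_std <- function(frames) {
  tt <- dim(frames)[3]
  vapply(seq_len(tt), function(t) {
    fr <- frames[, , t]
    mu <- sum(fr) / length(fr)
    sqrt(sum((fr - mu)^2) / length(fr))
  }, numeric(1))
}

# Single-pass exhaustive run splitting for instability removal: group
# consecutive minima while both closeness conditions hold, then replace
# multi-member groups by their rounded midpoint.
oracle_merge_once <- function(t, sigma, sig_values, sig_t, d, tau_abs) {
  stopifnot(!is.unsorted(t))
  groups <- list(); cur <- 1L
  for (i in seq_along(t)[-1]) {
    if (t[i] - t[i - 1L] <= d && abs(sigma[i] - sigma[i - 1L]) <= tau_abs) {
      cur <- c(cur, i)
    } else {
      groups <- c(groups, list(cur)); cur <- i
    }
  }
  groups <- c(groups, list(cur))
  res_t <- numeric(); res_s <- numeric()
  for (g in groups) {
    if (length(g) == 1L) {
      res_t <- c(res_t, t[g]); res_s <- c(res_s, sigma[g])
    } else {
      th <- floor((min(t[g]) + max(t[g])) / 2 + 0.5)
      res_t <- c(res_t, th)
      res_s <- c(res_s, sig_values[match(th, sig_t)])
    }
  }
  o <- order(res_t)
  data.frame(t = res_t[o], sigma = res_s[o])
}

# Gaussian-smoothed unit-variance noise (independent of the package's
# internal generator helpers).
helper_smooth_noise <- function(n, std = 3) {
  pad <- ceiling(3 * std)
  z <- stats::rnorm(n + 2 * pad)
  k <- exp(-seq(-pad, pad)^2 / (2 * std^2)); k <- k / sum(k)
  s <- stats::convolve(z, rev(k), type = "filter")[seq_len(n)]
  s / stats::sd(s)
}

# Band-limited smooth clip for the derivative-pair (stillness) oracle suite:
# static blob plus a single interior pattern whose amplitude a(t) is smooth
# and strictly positive (a = 0.2 + s(t)^2), so stillness corresponds to
# stationary points of a, never to signed zero-crossings.
make_smooth_clip <- function(seed, T = 80L, H = 32L, W = 32L) {
  set.seed(seed)
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  cy <- H / 2; cx <- W / 2
  blob <- 100 + 70 * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * 6^2))
  py <- cy - 3; px <- cx + 2
  patt <- 25 * exp(-((yy - py)^2 + (xx - px)^2) / (2 * 2.5^2))
  a <- 0.2 + helper_smooth_noise(T, std = 6)^2
  frames <- array(0, dim = c(H, W, T))
  for (t in seq_len(T)) frames[, , t] <- blob + a[t] * patt
  frame_stack(frames, fps = 25)
}

# Integer-valued random stack (exactly representable in 8-bit PNG).
make_integer_stack <- function(seed, H = 8L, W = 8L, T = 4L, fps = 25) {
  set.seed(seed)
  frame_stack(array(sample(0:255, H * W * T, replace = TRUE),
                    dim = c(H, W, T)), fps = fps)
}

# strict minima: v[t] < both neighbors
strict_local_minima <- function(v) {
  n <- length(v)
  which(vapply(seq_len(n), function(t) {
    t > 1L && t < n && v[t] < v[t - 1L] && v[t] < v[t + 1L]
  }, logical(1)))
}
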