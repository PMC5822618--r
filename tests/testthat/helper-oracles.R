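# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Literal Bloch-style simulation of a saturation-prepared spoiled-GRE pulse
# train: longitudinal relaxation integrated by fine-step Euler updates
# (10x finer bookkeeping than the closed-form recurrence), pulses as
# instantaneous cos-alpha scalings.
oracle_sr_signal <- function(t1_ms, sr_ms, tr_ms, fa_deg, n_center,
                             from_equilibrium = FALSE, n_sub = 2000) {
  a <- fa_deg * pi / 180
  relax <- function(mz, dur) {
    dt <- dur / n_sub
    for (i in seq_len(n_sub)) mz <- mz + (1 - mz) * dt / t1_ms
    mz
  }
  mz <- if (from_equilibrium) 1 else relax(0, sr_ms)
  if (n_center > 1) {
    for (p in seq_len(n_center - 1)) mz <- relax(mz * cos(a), tr_ms)
  }
  mz * sin(a)
}

# O(n^2) double-loop trapezoid convolution, 1-indexed
oracle_conv_trapz <- function(a, b, dt) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(i)) {
      w <- if (j == 1 || j == i) 0.5 else 1
      s <- s + w * a[j] * b[i - j + 1]
    }
    out[i] <- dt * s
  }
  out
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n, n1) group assignments of the combined sample (tie-free data).
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  w <- apply(splits, 2, function(ix) sum(r[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w - mu) >= abs(obs - mu) - 1e-9)
}

# Two-sided Fisher exact p by enumeration of the hypergeometric tables with
# the observed margins (sum of probabilities <= observed's, R convention).
oracle_fisher_p <- function(tab) {
  m <- rowSums(tab); k <- colSums(tab)[1]
  support <- max(0, k - m[2]):min(k, m[1])
  probs <- stats::dhyper(support, m[1], m[2], k)
  p_obs <- stats::dhyper(tab[1, 1], m[1], m[2], k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form OLS slope via explicit summation
oracle_ols_slope <- function(x, y) {
  (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
}

# uniform myocardial phantom pushed through the full synthetic image chain
chain_phantom <- function(mbf, nx = 3, snr = Inf, seed = NULL) {
  sim <- gen_dynamic_series(matrix(mbf, nx, nx), snr = snr, seed = seed)
  q <- quantify_perfusion(sim$imaging, sim$aif,
                          myo_mask = array(TRUE, c(nx, nx, 1)))
  list(sim = sim, q = q)
}
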