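# Independent oracles used across the suite. None of these share code with
# the package implementation: the pmf oracle extracts power-series
# coefficients of the composed probability generating function by numerical
# Cauchy integration (FFT on a circle), and the MLE oracle is a plain
# two-stage grid search over that oracle's log-likelihood.

# Coefficients of H(z) = exp(m * (1-w) log(1-w) / w), w = 1 - eps + eps*z,
# via the Cauchy integral p_k = (1/2*pi) int H(r e^{i t}) e^{-i k t} / r^k dt.
oracle_lc_pmf <- function(m, epsilon, k_max) {
  r <- if (k_max <= 50) 0.9 else exp(-10 / k_max)
  n_fft <- 2^ceiling(log2(max(16 * (k_max + 1), 512)))
  z <- r * exp(2i * pi * (0:(n_fft - 1)) / n_fft)
  w <- 1 - epsilon + epsilon * z
  f <- ifelse(Mod(w) < 1e-9, -1 + 0i, (1 - w) * log(1 - w) / w)
  coefs <- Re(fft(exp(m * f))) / n_fft
  coefs[1:(k_max + 1)] / r^(0:k_max)
}

oracle_loglik <- function(m, counts, epsilon) {
  p <- oracle_lc_pmf(m, epsilon, max(counts))
  sum(log(p[counts + 1]))
}

# Exhaustive two-stage grid search of the oracle log-likelihood over
# m in [lo, hi]: coarse step, then 1e-5 steps around the coarse optimum.
oracle_grid_mle <- function(counts, epsilon, lo = 1e-4, hi = 5) {
  coarse <- seq(lo, hi, by = 1e-2)
  v <- vapply(coarse, oracle_loglik, numeric(1), counts = counts,
              epsilon = epsilon)
  m0 <- coarse[which.max(v)]
  fine <- seq(max(lo, m0 - 2e-2), m0 + 2e-2, by = 1e-5)
  v <- vapply(fine, oracle_loglik, numeric(1), counts = counts,
              epsilon = epsilon)
  fine[which.max(v)]
}

# Pearson chi-square computed the textbook way.
oracle_pearson <- function(obs, prop) {
  expd <- sum(obs) * prop / sum(prop)
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat,
       p_value = pchisq(stat, length(obs) - 1, lower.tail = FALSE))
}

# Chi-square GOF of observed integer samples against a pmf, pooling the tail
# so that expected cell counts stay above `min_exp`.
gof_pvalue <- function(counts, pmf_fun, k_pool, min_exp = 10) {
  n <- length(counts)
  p <- pmf_fun(k_pool)
  expd <- c(n * p, n * (1 - sum(p)))
  obs <- c(tabulate(pmin(counts, k_pool + 1) + 1, nbins = k_pool + 2))
  # pool sparse upper cells
  while (length(expd) > 2 && expd[length(expd)] < min_exp) {
    k <- length(expd)
    expd[k - 1] <- expd[k - 1] + expd[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    expd <- expd[-k]; obs <- obs[-k]
  }
  stat <- sum((obs - expd)^2 / expd)
  pchisq(stat, length(obs) - 1, lower.tail = FALSE)
}
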