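#' Construct a fluctuation experiment
#'
#' Bundles the per-culture resistant-colony counts of a Luria-Delbruck
#' fluctuation test together with the culture size and plating fraction, the
#' quantities needed for Lea-Coulson mutation-rate inference.
#'
#' Plates that were uncountable ("burst") are flagged with `censored_high`;
#' such cultures carry no count value. By default they are excluded from the
#' likelihood (the convention used when rates are computed "without counting
#' plates that contained too many colonies"); alternatively they can be
#' treated as right-censored at a known colony ceiling, in which case each
#' censored culture contributes the upper-tail probability `P(X >= ceiling)`.
#'
#' @param counts numeric vector of resistant colonies per culture. Entries
#'   flagged in `censored_high` must be `NA`.
#' @param n_total_cells final number of cells per culture (Nt), a positive
#'   number.
#' @param plating_fraction fraction of each culture plated (epsilon), in
#'   (0, 1].
#' @param environment_label optional label for the plating environment.
#' @param censored_high logical vector marking uncountable plates.
#' @param censor_mode how censored plates enter the likelihood: `"exclude"`
#'   drops them, `"ceiling"` treats them as right-censored at `ceiling`.
#' @param ceiling smallest colony count regarded as uncountable; required when
#'   `censor_mode = "ceiling"` and any plate is censored.
#' @return An object of class `fluctuation_experiment`.
#' @seealso [estimate_rate()], [compare_rates()], [lc_loglik()]
#' @export
fluctuation_experiment <- function(counts,
                                   n_total_cells,
                                   plating_fraction = 1,
                                   environment_label = "",
                                   censored_high = NULL,
                                   censor_mode = c("exclude", "ceiling"),
                                   ceiling = NULL) {
  censor_mode <- match.arg(censor_mode)
  if (is.null(censored_high)) censored_high <- rep(FALSE, length(counts))
  if (length(censored_high) != length(counts)) {
    stop("`censored_high` must have one entry per culture")
  }
  if (!is.numeric(n_total_cells) || length(n_total_cells) != 1L ||
      !is.finite(n_total_cells) || n_total_cells <= 0) {
    stop("`n_total_cells` (Nt) must be a positive number")
  }
  if (!is.numeric(plating_fraction) || length(plating_fraction) != 1L ||
      plating_fraction <= 0 || plating_fraction > 1) {
    stop("`plating_fraction` (epsilon) must lie in (0, 1]")
  }
  if (any(!is.na(counts[censored_high]))) {
    stop("censored cultures must not carry a count value (use NA)")
  }
  obs <- counts[!censored_high]
  if (anyNA(obs)) stop("non-censored cultures must have a count")
  if (any(obs < 0) || any(obs != floor(obs))) {
    stop("counts must be non-negative integers")
  }
  n_censored <- sum(censored_high)
  if (censor_mode == "ceiling" && n_censored > 0) {
    if (is.null(ceiling) || !is.numeric(ceiling) || ceiling < 1 ||
        ceiling != floor(ceiling)) {
      stop("`ceiling` must be a positive integer when censor_mode = \"ceiling\"")
    }
    if (length(obs) > 0 && max(obs) >= ceiling) {
      stop("observed counts must be below the censoring ceiling")
    }
  }
  if (length(obs) + (censor_mode == "ceiling") * n_censored < 1L) {
    stop("at least one usable culture is required")
  }
  structure(
    list(
      counts = as.integer(obs),
      n_censored = as.integer(n_censored),
      censor_mode = censor_mode,
      ceiling = if (censor_mode == "ceiling") ceiling else NULL,
      n_total_cells = as.numeric(n_total_cells),
      plating_fraction = as.numeric(plating_fraction),
      environment_label = environment_label
    ),
    class = "fluctuation_experiment"
  )
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat("Fluctuation experiment",
      if (nzchar(x$environment_label)) paste0("[", x$environment_label, "]"),
      "\n")
  cat("  cultures:", length(x$counts),
      if (x$n_censored > 0) sprintf("(+%d censored, mode = %s)",
                                    x$n_censored, x$censor_mode), "\n")
  cat("  Nt =", format(x$n_total_cells), " epsilon =", x$plating_fraction, "\n")
  invisible(x)
}

# Series coefficients gamma_k such that the cumulant series of the observed
# mutant-count distribution is g_k = m * gamma_k. Derived from the
# compound-Poisson representation of the Lea-Coulson distribution (clone-size
# law q_j = 1/(j(j+1))) under per-cell binomial thinning with probability
# epsilon: a clone of j cells shows Binomial(j, epsilon) colonies, so
#   g_k = m * epsilon^k * sum_{j>=k} C(j,k) (1-epsilon)^(j-k) / (j (j+1)),
# a negative-binomial expectation with all-positive terms (numerically stable
# for every epsilon, unlike partial-fraction expansions of the composed pgf).
# gamma_0 = epsilon*log(epsilon)/(1-epsilon) gives the closed-form P(0).
lc_coef <- function(epsilon, k_max) {
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]")
  if (k_max < 0) stop("k_max must be >= 0")
  if (epsilon == 1) {
    if (k_max == 0) return(-1)
    k <- seq_len(k_max)
    return(c(-1, 1 / (k * (k + 1))))
  }
  g0 <- epsilon * log(epsilon) / (1 - epsilon)
  if (k_max == 0) return(g0)
  # gamma_k = 1/k - M_k / epsilon with M_k = int_0^1 v^k / (1 + c v) dv and
  # c = (1 - epsilon)/epsilon (equivalent to the negative-binomial form via
  # 1/(j+1) = int_0^1 t^j dt). M_k obeys M_k = (1/k - M_{k-1})/c; the forward
  # recursion damps errors iff c > 1, so for c <= 1 (epsilon >= 1/2) M_k is
  # instead summed as a beta-function series in r = c/(1+c) <= 1/2.
  k <- seq_len(k_max)
  c0 <- (1 - epsilon) / epsilon
  if (c0 > 1) {
    M <- numeric(k_max + 1)
    M[1] <- log1p(c0) / c0
    for (kk in k) M[kk + 1] <- (1 / kk - M[kk]) / c0
    M <- M[-1]
  } else {
    r <- c0 / (1 + c0)
    term <- 1 / (k + 1)
    M <- term
    n <- 0
    repeat {
      n <- n + 1
      term <- term * r * n / (k + 1 + n)
      M <- M + term
      if (max(term) < 1e-18) break
    }
    M <- M / (1 + c0)
  }
  c(g0, 1 / k - M / epsilon)
}

#' Lea-Coulson mutant-count distribution with partial plating
#'
#' Probability mass function of the number of resistant colonies observed when
#' a fraction `epsilon` of a single-cell-founded culture carrying on average
#' `m` mutations is plated. Mutant clones are assumed to grow at the wild-type
#' rate; observed counts are binomial thinnings of the culture's mutant
#' counts, so the probability generating function is `H(z) = G(1 - epsilon +
#' epsilon * z)` with `G` the Lea-Coulson pgf
#' `exp(m * (1 - z) * log(1 - z) / z)`. In particular
#' `P(0) = exp(m * epsilon * log(epsilon) / (1 - epsilon))` for `epsilon < 1`
#' and `exp(-m)` for `epsilon = 1`.
#'
#' @param m expected number of mutations per culture (non-negative).
#' @param epsilon plating fraction in (0, 1].
#' @param k_max largest count for which the probability is returned.
#' @return Numeric vector of probabilities for counts `0:k_max`.
#' @examples
#' lc_pmf(1, 1, 3)        # e^-1, e^-1/2, ...
#' lc_pmf(1, 0.5, 0)      # P(0) = 0.5
#' @export
lc_pmf <- function(m, epsilon, k_max) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0) {
    stop("`m` must be a finite non-negative number")
  }
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]")
  k_max <- as.integer(k_max)
  if (k_max < 0) stop("k_max must be >= 0")
  .lc_pmf_series(m * lc_coef(epsilon, k_max))
}

# Build a fast log-likelihood closure for an experiment; the series
# coefficients are computed once and reused across calls with different m.
.loglik_factory <- function(experiment) {
  counts <- experiment$counts
  eps <- experiment$plating_fraction
  censored <- experiment$censor_mode == "ceiling" && experiment$n_censored > 0
  k_need <- if (length(counts) > 0) max(counts) else 0L
  if (censored) k_need <- max(k_need, experiment$ceiling - 1L)
  coef <- lc_coef(eps, k_need)
  tab <- tabulate(counts + 1L, nbins = k_need + 1L)
  idx <- which(tab > 0)
  n_cens <- if (censored) experiment$n_censored else 0L
  ceiling_k <- experiment$ceiling
  function(m) {
    if (m < 0) return(-Inf)
    if (m == 0) {
      # only zero counts have positive probability
      if (any(idx > 1L) || n_cens > 0) return(-Inf)
      return(0)
    }
    p <- .lc_pmf_series(m * coef)
    ll <- sum(tab[idx] * log(p[idx]))
    if (n_cens > 0) {
      tail <- max(1 - sum(p[seq_len(ceiling_k)]), 1e-300)
      ll <- ll + n_cens * log(tail)
    }
    ll
  }
}

#' Log-likelihood of a fluctuation experiment under the Lea-Coulson model
#'
#' Sum over cultures of the log probability of the observed colony count given
#' `m` expected mutations per culture, under partial plating. Cultures flagged
#' as censored (`censor_mode = "ceiling"`) contribute the log upper-tail
#' probability beyond the colony ceiling; with the default `"exclude"` mode
#' they were already dropped at construction.
#'
#' @param m expected mutations per culture.
#' @param experiment a [fluctuation_experiment()].
#' @return The log-likelihood value.
#' @export
lc_loglik <- function(m, experiment) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  if (length(experiment$counts) == 0 &&
      !(experiment$censor_mode == "ceiling" && experiment$n_censored > 0)) {
    stop("experiment has no usable cultures")
  }
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0) {
    stop("`m` must be a finite non-negative number")
  }
  .loglik_factory(experiment)(m)
}

# Maximize a 1-D log-likelihood in m: log-spaced scan to bracket, then Brent
# on log m (scale-free, so rates of order 1e-8 converge as well as order 1).
.maximize_m <- function(ll, m_hint, tol = 1e-10) {
  lo <- max(m_hint * 1e-4, m_hint / 1e4, 1e-12)
  hi <- max(m_hint * 20, lo * 1e5)
  repeat {
    grid <- exp(seq(log(lo), log(hi), length.out = 60))
    vals <- vapply(grid, ll, numeric(1))
    best <- which.max(vals)
    if (best == length(grid) && hi < grid[1] * 1e20) {
      hi <- hi * 100
    } else if (best == 1L) {
      lo <- lo / 100
      if (lo < grid[length(grid)] * 1e-25) break
    } else break
  }
  lower <- log(grid[max(best - 1L, 1L)])
  upper <- log(grid[min(best + 1L, length(grid))])
  opt <- optimize(function(t) ll(exp(t)), c(lower, upper),
                  maximum = TRUE, tol = tol)
  list(m = exp(opt$maximum), loglik = opt$objective)
}

#' Estimate the mutation rate from a fluctuation experiment
#'
#' Maximum-likelihood estimation of `m` (expected mutations per culture) under
#' the Lea-Coulson model with partial plating, following Foster's convention
#' for the per-cell-division rate, `mu = m / Nt`. Confidence intervals are
#' profile-likelihood intervals at the chi-square cutoff
#' `2 * (logL(m_hat) - logL(m)) = qchisq(conf_level, 1)` (3.84 for 95%). When
#' every culture shows zero colonies the MLE sits on the boundary `m_hat = 0`
#' and the lower confidence limit is 0.
#'
#' @param experiment a [fluctuation_experiment()].
#' @param conf_level confidence level for the profile interval.
#' @param ci compute the profile-likelihood interval (set to `FALSE` to save
#'   time in large simulation studies; the interval is then `NA`).
#' @return An object of class `rate_estimate` with elements `m_hat`, `mu_hat`,
#'   `ci95_m`, `ci95_mu`, `loglik_at_mle`, and bookkeeping fields.
#' @export
estimate_rate <- function(experiment, conf_level = 0.95, ci = TRUE) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  counts <- experiment$counts
  usable <- length(counts) +
    (experiment$censor_mode == "ceiling") * experiment$n_censored
  if (length(counts) == 0) stop("no non-censored cultures available")
  if (usable < 1L) stop("no usable cultures")
  nt <- experiment$n_total_cells
  cutoff <- qchisq(conf_level, df = 1)
  ll <- .loglik_factory(experiment)

  if (max(counts) == 0 && experiment$n_censored == 0) {
    # boundary MLE: logL(m) = n * gamma0 * m, decreasing in m
    g0 <- lc_coef(experiment$plating_fraction, 0)
    m_up <- cutoff / (-2 * length(counts) * g0)
    est <- list(m_hat = 0, loglik = 0, ci_m = c(0, m_up))
  } else {
    # crude scale hint: zero fraction if informative, else typical count
    g0 <- lc_coef(experiment$plating_fraction, 0)
    p0 <- mean(counts == 0)
    m_hint <- if (p0 > 0 && p0 < 1) log(p0) / g0 else
      max(median(counts) / experiment$plating_fraction, 0.5)
    fit <- .maximize_m(ll, m_hint)
    if (ci) {
      dev <- function(m) 2 * (fit$loglik - ll(m)) - cutoff
      # lower limit
      lower <- if (dev(1e-12) < 0) 0 else
        uniroot(dev, c(1e-12, fit$m), tol = 1e-10)$root
      # upper limit: expand until the deviance crosses the cutoff
      hi <- fit$m * 2 + 0.5
      while (dev(hi) < 0) hi <- hi * 2
      upper <- uniroot(dev, c(fit$m, hi), tol = 1e-10)$root
      ci_m <- c(lower, upper)
    } else {
      ci_m <- c(NA_real_, NA_real_)
    }
    est <- list(m_hat = fit$m, loglik = fit$loglik, ci_m = ci_m)
  }

  structure(
    list(
      m_hat = est$m_hat,
      mu_hat = est$m_hat / nt,
      ci95_m = est$ci_m,
      ci95_mu = est$ci_m / nt,
      loglik_at_mle = est$loglik,
      conf_level = conf_level,
      n_cultures = length(counts),
      n_censored = experiment$n_censored,
      n_total_cells = nt,
      plating_fraction = experiment$plating_fraction,
      environment_label = experiment$environment_label
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Lea-Coulson rate estimate",
      if (nzchar(x$environment_label)) paste0("[", x$environment_label, "]"),
      "\n")
  cat(sprintf("  m_hat  = %.6g  (%d%% CI %.6g - %.6g)\n",
              x$m_hat, round(100 * x$conf_level), x$ci95_m[1], x$ci95_m[2]))
  cat(sprintf("  mu_hat = %.6g per cell division (%d%% CI %.6g - %.6g)\n",
              x$mu_hat, round(100 * x$conf_level), x$ci95_mu[1], x$ci95_mu[2]))
  invisible(x)
}

#' Compare mutation rates between two plating environments
#'
#' Likelihood-ratio test of equal per-cell-division mutation rates between an
#' environment and a reference, under the Lea-Coulson model with partial
#' plating. The null model shares a single rate `mu`, with environment-specific
#' `m = mu * Nt` and plating fraction; the alternative fits each environment
#' separately. The test statistic `2 * (logL_a + logL_ref - logL_null)` is
#' referred to a chi-square distribution with 1 degree of freedom. The
#' reported ratio is `mu_hat_a / mu_hat_ref` with a profile-likelihood
#' confidence interval on the ratio parameter.
#'
#' @param experiment_a,experiment_ref [fluctuation_experiment()] objects.
#' @param conf_level confidence level for the ratio interval.
#' @param ratio_ci compute the profile-likelihood interval for the ratio
#'   (set to `FALSE` to save time in large simulation studies).
#' @return An object of class `rate_comparison`.
#' @export
compare_rates <- function(experiment_a, experiment_ref, conf_level = 0.95,
                          ratio_ci = TRUE) {
  stopifnot(inherits(experiment_a, "fluctuation_experiment"),
            inherits(experiment_ref, "fluctuation_experiment"))
  fit_a <- estimate_rate(experiment_a, conf_level, ci = ratio_ci)
  fit_r <- estimate_rate(experiment_ref, conf_level, ci = ratio_ci)
  ll_a <- .loglik_factory(experiment_a)
  ll_r <- .loglik_factory(experiment_ref)
  nt_a <- experiment_a$n_total_cells
  nt_r <- experiment_ref$n_total_cells

  ll_null <- function(mu) ll_a(mu * nt_a) + ll_r(mu * nt_r)
  mu_hint <- max((fit_a$mu_hat + fit_r$mu_hat) / 2, 1e-12)
  if (fit_a$m_hat == 0 && fit_r$m_hat == 0) {
    null_fit <- list(m = 0, loglik = 0)
  } else {
    null_fit <- .maximize_m(ll_null, mu_hint)
  }
  ll_unres <- fit_a$loglik_at_mle + fit_r$loglik_at_mle
  lrt <- max(0, 2 * (ll_unres - null_fit$loglik))
  if (lrt < 1e-8) lrt <- 0   # numerically indistinguishable from the null
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  ratio <- if (fit_r$mu_hat > 0) fit_a$mu_hat / fit_r$mu_hat else
    if (fit_a$mu_hat == 0) NA_real_ else Inf

  ci <- c(NA_real_, NA_real_)
  if (ratio_ci && is.finite(ratio)) {
    cutoff <- qchisq(conf_level, df = 1)
    # profile the ratio rho, maximizing over the reference rate
    prof <- function(rho) {
      f <- function(mu) ll_a(rho * mu * nt_a) + ll_r(mu * nt_r)
      .maximize_m(f, max(fit_r$mu_hat, 1e-12))$loglik
    }
    devr <- function(rho) 2 * (ll_unres - prof(rho)) - cutoff
    if (ratio == 0 || devr(max(ratio * 1e-6, 1e-12)) < 0) {
      lo <- 0
    } else {
      lo <- uniroot(devr, c(max(ratio * 1e-6, 1e-12), ratio), tol = 1e-8)$root
    }
    hi <- max(ratio * 2, 0.5)
    while (devr(hi) < 0 && hi < 1e6) hi <- hi * 2
    up <- if (hi >= 1e6) Inf else
      uniroot(devr, c(max(ratio, 1e-12), hi), tol = 1e-8)$root
    ci <- c(lo, up)
  }

  structure(
    list(
      ratio = ratio,
      ci95_ratio = ci,
      lrt_statistic = lrt,
      p_value = p,
      estimate_a = fit_a,
      estimate_ref = fit_r,
      conf_level = conf_level
    ),
    class = "rate_comparison"
  )
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("Rate comparison (Lea-Coulson LRT)\n")
  cat(sprintf("  ratio = %.4g", x$ratio))
  if (!anyNA(x$ci95_ratio)) {
    cat(sprintf("  (%d%% CI %.4g - %.4g)",
                round(100 * x$conf_level), x$ci95_ratio[1], x$ci95_ratio[2]))
  }
  cat(sprintf("\n  LRT = %.4g, p = %.4g\n", x$lrt_statistic, x$p_value))
  invisible(x)
}
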