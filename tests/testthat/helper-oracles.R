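# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force log densities, hypergeometric
# enumeration, generic-optimizer likelihood fits.

# Diagonal-Gaussian log-density discriminant scores, computed sample by
# sample with scalar loops.
dlda_oracle_scores <- function(x, means, vars, priors) {
  n <- nrow(x)
  scores <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (c in 1:2) {
      s <- 0
      for (k in seq_len(ncol(x)))
        s <- s - (x[i, k] - means[c, k])^2 / (2 * vars[k])
      scores[i, c] <- s + log(priors[c])
    }
  }
  scores
}

# Fisher p-values by explicit enumeration of the hypergeometric support of
# the [1,1] cell given the margins (same table convention as fisher.test:
# rows = groups, cols = outcomes).
fisher_oracle <- function(tab, alternative) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  supp <- max(0, k - n):min(k, m)
  d <- dhyper(supp, m, n, k)
  obs <- tab[1, 1]
  dobs <- dhyper(obs, m, n, k)
  switch(alternative,
         less = sum(d[supp <= obs]),
         greater = sum(d[supp >= obs]),
         two.sided = sum(d[d <= dobs * (1 + 1e-7)]))
}

# Logistic interaction-model fit by direct maximization of the likelihood
# with a generic optimizer (no IRLS).
logit_interaction_oracle <- function(y, arm, z) {
  nll <- function(b) {
    eta <- b[1] + b[2] * arm + b[3] * z * arm
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  setNames(fit$par, c("beta0", "beta2", "beta3"))
}

# Cox partial log-likelihood for a single covariate (Breslow ties), and
# the Breslow baseline cumulative hazard at the fitted coefficient.
cox_partial_oracle <- function(time, event, x, beta_grid = NULL) {
  pll <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  bhat <- optimize(function(b) -pll(b), c(-20, 20))$minimum
  list(beta = bhat, pll = pll)
}

breslow_oracle <- function(time, event, lp) {
  ev_times <- sort(unique(time[event == 1]))
  H <- cumsum(vapply(ev_times, function(t) {
    d <- sum(event == 1 & time == t)
    d / sum(exp(lp[time >= t]))
  }, numeric(1)))
  data.frame(time = ev_times, hazard = H)
}

# small test cohorts -------------------------------------------------------

small_binary_scenario <- function(pi = 0.3, u11 = 0.9, u01 = 0.1,
                                  n_per_arm = 60, n_probes = 40,
                                  n_predictive = 5, alpha = 0.01) {
  scenario(pi = pi, u00 = u01, u01 = u01, u10 = u01, u11 = u11,
           n_per_arm = n_per_arm, n_probes = n_probes,
           n_predictive = n_predictive, alpha_screen = alpha)
}
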