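# Shared fixtures: tiny cohorts built in code.

# Dense-matrix multivariate normal log-density (independent oracle for the
# package's low-dimensional evidence computation).
dense_mvn_logpdf <- function(y, mu, V) {
  R <- chol(V)
  w <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(w^2))
}

dense_marginal_logpdf <- function(Y, Q, m, Sigma, sigma2) {
  dense_mvn_logpdf(Y, drop(Q %*% m),
                   Q %*% Sigma %*% t(Q) + diag(sigma2, nrow(Q)))
}

# A small deterministic mixed cohort: n_mono patients on one line, n_bi
# patients with a change after k_true visits, Gaussian noise sd `noise`.
toy_cohort <- function(n_mono = 3, n_bi = 3, times = seq(0, 140, by = 20),
                       k_true = 4, noise = 2, seed = 42) {
  set.seed(seed)
  pats <- list()
  for (i in seq_len(n_mono)) {
    y <- 80 - 0.2 * times + rnorm(length(times), 0, noise)
    pats[[length(pats) + 1]] <- patient_series(paste0("m", i), times, y)
  }
  tk <- times[k_true]
  for (i in seq_len(n_bi)) {
    mu <- ifelse(times <= tk, 85 - 0.5 * times,
                 (85 - 0.5 * tk) + 0.1 * tk - 0.1 * times)
    y <- mu + rnorm(length(times), 0, noise)
    pats[[length(pats) + 1]] <- patient_series(paste0("b", i), times, y)
  }
  cohort(pats)
}

# Default small population-parameter set compatible with toy_cohort.
toy_params <- function(cohort = NULL, lam = 0.5) {
  pw <- if (is.null(cohort)) NULL else
    lapply(cohort, function(p) rep(1 / (length(p$times) - 1),
                                   length(p$times) - 1))
  population_parameters(
    mono_params(c(80, -0.2), diag(c(4, 1e-4))),
    bi_params(c(85, -0.5, 61, -0.1), diag(c(4, 1e-4, 4, 1e-4))),
    sigma2 = 4, lam = lam, pi_weights = pw)
}

# Expected complete-data penalized log-posterior, written densely and
# independently of the package's M-step algebra. Latent weights and
# individual posterior moments are held fixed (as in the M-step); the priors
# are those whose MAP the closed-form updates implement: (sigma2)^-1,
# |Sigma_S|^-1, |Sigma_B|^-1, Beta(1,1) on lambda.
expected_complete_objective <- function(cohort, es, S, SigS, B, SigB,
                                        sigma2, lam) {
  z <- es$latent$z
  zeta <- es$latent$zeta
  ind <- es$individuals
  val <- -log(sigma2) - determinant(SigS)$modulus[1] -
    determinant(SigB)$modulus[1]
  iSS <- solve(SigS)
  iSB <- solve(SigB)
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    M <- length(p$times)
    Qs <- build_mono_design(p$times)
    sh <- ind$shat[, i]
    Ps <- ind$SigShat[, , i]
    lik_s <- -M / 2 * log(2 * pi * sigma2) -
      (sum((p$values - Qs %*% sh)^2) + sum(diag(Qs %*% Ps %*% t(Qs)))) /
        (2 * sigma2)
    pri_s <- -log(2 * pi) - 0.5 * determinant(SigS)$modulus[1] -
      0.5 * (drop(t(sh - S) %*% iSS %*% (sh - S)) + sum(diag(iSS %*% Ps)))
    val <- val + (1 - z[i]) * (lik_s + pri_s)
    for (j in seq_along(zeta[[i]])) {
      w <- z[i] * zeta[[i]][j]
      if (w == 0) next
      Qb <- build_biphasic_design(p$times, j)
      bh <- ind$bhat[[i]][, j]
      Pb <- ind$SigBhat[[i]][, , j]
      lik_b <- -M / 2 * log(2 * pi * sigma2) -
        (sum((p$values - Qb %*% bh)^2) + sum(diag(Qb %*% Pb %*% t(Qb)))) /
          (2 * sigma2)
      pri_b <- -2 * log(2 * pi) - 0.5 * determinant(SigB)$modulus[1] -
        0.5 * (drop(t(bh - B) %*% iSB %*% (bh - B)) + sum(diag(iSB %*% Pb)))
      val <- val + w * (lik_b + pri_b)
    }
    if (lam > 0 && lam < 1)
      val <- val + z[i] * log(lam) + (1 - z[i]) * log1p(-lam)
  }
  val
}
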