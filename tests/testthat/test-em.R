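test_that("design posteriors are symmetric under equal weights and respect zero priors", {
  tt <- seq(0, 100, by = 20)
  s <- patient_series("p", tt, rep(50, 6))
  # both population lines are the same flat line with no between-patient
  # variability, so every candidate design has exactly the same evidence
  bi <- bi_params(c(50, 0, 50, 0), matrix(0, 4, 4))
  zt <- e_step_zeta(s, bi, 1, rep(1 / 5, 5))
  expect_equal(zt, rep(1 / 5, 5), tolerance = 1e-12)
  pi0 <- c(0, 0.5, 0, 0.5, 0)
  zt0 <- e_step_zeta(s, bi, 1, pi0)
  expect_equal(zt0[c(1, 3, 5)], rep(0, 3))
  expect_equal(sum(zt0), 1, tolerance = 1e-12)
})

test_that("design posterior concentrates near the generating change point", {
  # The two population lines intersect at the transition, so observations
  # near t* sit close to both lines and adjacent change points are only
  # weakly distinguished; the posterior mode should still fall close to the
  # generating k for essentially every bi-phasic patient.
  sim <- simulate_cohort(make_scenario(1, seed = 302))
  bi_true <- bi_params(c(91, -0.35, 55, -0.15), matrix(0, 4, 4))
  bi_idx <- which(sim$truth$eta == 1 & sim$truth$k >= 2 &
                    sim$truth$k <= 16)
  dev <- vapply(bi_idx, function(i) {
    zt <- e_step_zeta(sim$cohort[[i]], bi_true, 25, rep(1 / 17, 17))
    abs(which.max(zt) - sim$truth$k[i])
  }, numeric(1))
  expect_gte(mean(dev <= 2), 0.7)
  expect_lte(mean(dev), 1.8)
  # and an individual patient whose mode hits the truth exactly
  exact <- bi_idx[dev == 0]
  expect_gt(length(exact), 5)
  i <- exact[1]
  zt <- e_step_zeta(sim$cohort[[i]], bi_true, 25, rep(1 / 17, 17))
  expect_identical(which.max(zt), as.integer(sim$truth$k[i]))
})

test_that("phasicity posterior handles degenerate mixing weights and the BIC gap", {
  sim <- simulate_cohort(make_scenario(1, seed = 303, n_patients = 5))
  p <- sim$cohort[[1]]
  mono <- mono_params(c(90, -0.25), matrix(0, 2, 2))
  bi <- bi_params(c(91, -0.35, 55, -0.15), matrix(0, 4, 4))
  pi_i <- rep(1 / 17, 17)
  expect_identical(e_step_z(p, mono, bi, 25, 0, pi_i), 0)
  expect_identical(e_step_z(p, mono, bi, 25, 1, pi_i), 1)
  z <- e_step_z(p, mono, bi, 25, 0.6, pi_i)
  expect_gte(z, 0)
  expect_lte(z, 1)
  # the penalty gap: twice the penalized-evidence gap minus twice the raw
  # evidence gap is -2 log(M) = -2 log(18) ~ -5.780
  params <- population_parameters(mono, bi, 25, 0.6,
                                  lapply(sim$cohort, function(q)
                                    rep(1 / 17, 17)))
  es <- e_step(sim$cohort, params, detail = TRUE)
  lsum <- function(lw) {
    m <- max(lw)
    m + log(sum(exp(lw - m)))
  }
  i <- 1
  lse <- lsum(log(pi_i) + es$individuals$lb[[i]])
  gap <- 2 * (es$individuals$gb2[i] - es$individuals$gs2[i]) -
    2 * (lse - es$individuals$ls[i])
  expect_equal(gap, -2 * log(18), tolerance = 1e-10)
  expect_equal(-2 * log(18), -5.780744, tolerance = 1e-6)
})

test_that("batched E-step matches the per-patient reference computations", {
  ch <- toy_cohort()
  par <- toy_params(ch, lam = 0.4)
  es <- e_step(ch, par, detail = TRUE)
  for (i in c(1, 4, 6)) {
    zt_ref <- e_step_zeta(ch[[i]], par$bi, par$sigma2, par$pi_weights[[i]])
    expect_equal(es$latent$zeta[[i]], zt_ref, tolerance = 1e-10)
    z_ref <- e_step_z(ch[[i]], par$mono, par$bi, par$sigma2, par$lam,
                      par$pi_weights[[i]])
    expect_equal(es$latent$z[i], z_ref, tolerance = 1e-10)
    # empirical-Bayes moments for a couple of designs
    for (j in c(1, 3)) {
      eb <- empirical_bayes(ch[[i]], build_biphasic_design(ch[[i]]$times, j),
                            par$bi$B, par$bi$Sigma_B, par$sigma2)
      expect_equal(es$individuals$bhat[[i]][, j], eb$mean, tolerance = 1e-10)
      expect_equal(es$individuals$SigBhat[[i]][, , j], eb$cov,
                   tolerance = 1e-10)
    }
  }
})

test_that("M-step closed forms maximize the expected complete-data objective", {
  ch <- toy_cohort(n_mono = 2, n_bi = 3, times = seq(0, 100, by = 20))
  par <- toy_params(ch, lam = 0.5)
  es <- e_step(ch, par, detail = TRUE)
  up <- m_step(ch, es$latent, es$individuals)
  obj_S <- function(v)
    expected_complete_objective(ch, es, v, up$mono$Sigma_S, up$bi$B,
                                up$bi$Sigma_B, up$sigma2, up$lam)
  o <- optim(up$mono$S * 1.05 + 0.1, obj_S, method = "BFGS",
             control = list(fnscale = -1, reltol = 1e-14))
  expect_equal(o$par, up$mono$S, tolerance = 1e-4)
  obj_B <- function(v)
    expected_complete_objective(ch, es, up$mono$S, up$mono$Sigma_S, v,
                                up$bi$Sigma_B, up$sigma2, up$lam)
  o <- optim(up$bi$B * 1.05 + 0.1, obj_B, method = "BFGS",
             control = list(fnscale = -1, reltol = 1e-14))
  expect_equal(o$par, up$bi$B, tolerance = 1e-4)
  # sigma2 and lambda: 1-d maximizers
  obj_s2 <- function(v)
    expected_complete_objective(ch, es, up$mono$S, up$mono$Sigma_S, up$bi$B,
                                up$bi$Sigma_B, v, up$lam)
  o <- optimize(obj_s2, c(up$sigma2 / 5, up$sigma2 * 5), maximum = TRUE,
                tol = 1e-10)
  expect_equal(o$maximum, up$sigma2, tolerance = 1e-4)
  obj_lam <- function(v)
    expected_complete_objective(ch, es, up$mono$S, up$mono$Sigma_S, up$bi$B,
                                up$bi$Sigma_B, up$sigma2, v)
  o <- optimize(obj_lam, c(0.01, 0.99), maximum = TRUE, tol = 1e-10)
  expect_equal(o$maximum, up$lam, tolerance = 1e-4)
  # Sigma_S via its Cholesky parameterization: the closed-form update must
  # match the numerical maximum to 1e-4 relative error in the objective,
  # and be at least as good
  obj_SS <- function(th) {
    L <- matrix(0, 2, 2)
    L[lower.tri(L, diag = TRUE)] <- th
    expected_complete_objective(ch, es, up$mono$S, tcrossprod(L), up$bi$B,
                                up$bi$Sigma_B, up$sigma2, up$lam)
  }
  L0 <- t(chol(up$mono$Sigma_S))
  th0 <- L0[lower.tri(L0, diag = TRUE)]
  o <- optim(th0 * 1.1, obj_SS, method = "BFGS",
             control = list(fnscale = -1, reltol = 1e-14, maxit = 1000,
                            parscale = abs(th0) + 1e-4))
  expect_gte(obj_SS(th0) + 1e-9, o$value)
  expect_equal(obj_SS(th0), o$value, tolerance = 1e-4)
  # Sigma_B likewise (10 free parameters)
  obj_SB <- function(th) {
    L <- matrix(0, 4, 4)
    L[lower.tri(L, diag = TRUE)] <- th
    expected_complete_objective(ch, es, up$mono$S, up$mono$Sigma_S, up$bi$B,
                                tcrossprod(L), up$sigma2, up$lam)
  }
  L0 <- t(chol(up$bi$Sigma_B))
  th0 <- L0[lower.tri(L0, diag = TRUE)]
  o <- optim(th0 * 1.1, obj_SB, method = "BFGS",
             control = list(fnscale = -1, reltol = 1e-14, maxit = 2000,
                            parscale = abs(th0) + 1e-4))
  expect_gte(obj_SB(th0) + 1e-9, o$value)
  expect_equal(obj_SB(th0), o$value, tolerance = 1e-4)
})

test_that("M-step weight identities hold", {
  ch <- toy_cohort(n_mono = 2, n_bi = 2)
  par <- toy_params(ch)
  es <- e_step(ch, par)
  lat <- es$latent
  lat$z <- c(1, 0, 1, 0)
  up <- m_step(ch, lat, es$individuals)
  expect_equal(up$lam, 0.5)
  # all-mono weights: S is the plain mean of the shat and the Sigma_S
  # denominator is N + 2
  lat$z <- rep(0, 4)
  expect_error(m_step(ch, lat, es$individuals), "component collapse")
  lat$z <- rep(1e-9, 4) # effectively mono, bi side kept alive numerically
  up <- m_step(ch, lat, es$individuals)
  expect_equal(up$mono$S, rowMeans(es$individuals$shat), tolerance = 1e-6)
  sc <- matrix(0, 2, 2)
  for (i in 1:4) {
    d <- es$individuals$shat[, i] - up$mono$S
    sc <- sc + es$individuals$SigShat[, , i] + tcrossprod(d)
  }
  expect_equal(up$mono$Sigma_S, sc / (4 + 2), tolerance = 1e-6)
})

test_that("transition density integrates to one and pools patients correctly", {
  tt <- c(0, 21, 42, 63)
  p1 <- patient_series("a", tt, c(4, 3, 2, 1))
  ch1 <- cohort(list(p1))
  lat1 <- list(z = 1, zeta = list(c(0, 1, 0)))
  d1 <- update_transition_density(ch1, lat1)
  on <- d1$breakpoints[-1] > 21 & d1$breakpoints[-1] <= 42
  expect_equal(d1$density[on], rep(1 / 21, sum(on)))
  expect_equal(d1$density[!on], rep(0, sum(!on)))
  # random weights still integrate to 1
  set.seed(5)
  ch <- toy_cohort()
  zt <- lapply(ch, function(p) {
    w <- runif(length(p$times) - 1)
    w / sum(w)
  })
  lat <- list(z = runif(length(ch)), zeta = zt)
  d <- update_transition_density(ch, lat)
  expect_equal(sum(d$density * diff(d$breakpoints)), 1, tolerance = 1e-8)
  # duplicating a patient leaves the density unchanged
  ch2 <- cohort(list(p1, patient_series("b", tt, c(4, 3, 2, 1))))
  lat2 <- list(z = c(1, 1), zeta = list(c(0, 1, 0), c(0, 1, 0)))
  d2 <- update_transition_density(ch2, lat2)
  expect_equal(d2$density, d1$density)
  # no bi-phasic mass: flat fallback with a warning
  expect_warning(update_transition_density(ch1, list(z = 0,
                                                     zeta = list(c(0, 1, 0)))),
                 "flat")
})

test_that("pi weights integrate the density over each patient's intervals", {
  tt <- seq(0, 357, by = 21)
  p <- patient_series("a", tt, rev(seq_along(tt)))
  flat <- structure(list(breakpoints = c(0, 357), density = 1 / 357),
                    class = "transition_density")
  expect_equal(update_pi(flat, p), rep(1 / 17, 17), tolerance = 1e-12)
  conc <- structure(list(breakpoints = c(0, 42, 63, 357),
                         density = c(0, 1 / 21, 0)),
                    class = "transition_density")
  pi_c <- update_pi(conc, p)
  expect_equal(pi_c[3], 1)
  expect_equal(sum(pi_c), 1)
  # misaligned visit: integral checked against numerical quadrature
  tt2 <- tt
  tt2[4] <- tt2[4] + 7  # one visit a week late
  p2 <- patient_series("b", tt2, rev(seq_along(tt2)))
  set.seed(8)
  dens_v <- runif(3)
  bp <- c(0, 100, 200, 357)
  dens_v <- dens_v / sum(dens_v * diff(bp))
  dens <- structure(list(breakpoints = bp, density = dens_v),
                    class = "transition_density")
  pi2 <- update_pi(dens, p2)
  grid <- seq(0, 357, by = 0.01)
  theta <- dens_v[findInterval(grid, bp, rightmost.closed = TRUE)]
  quad <- vapply(seq_len(17), function(j) {
    sel <- grid > tt2[j] & grid <= tt2[j + 1]
    sum(theta[sel]) * 0.01
  }, numeric(1))
  expect_equal(pi2, quad / sum(quad), tolerance = 1e-3)
})

test_that("grid-search initialization lands near the generating parameters", {
  sim <- simulate_cohort(make_scenario(1, seed = 304))
  init <- grid_search_init(sim$cohort)
  # per-patient two-line OLS overfits noise, so the initial lambda leans
  # liberal; EM prunes it (see the recovery tests). Assert a usable start.
  expect_lt(abs(init$lam - 0.6), 0.35)
  expect_gt(init$lam, 0.4)
  expect_lt(abs(init$mono$S[1] - 90), 3)
  expect_lt(abs(init$bi$B[2] + 0.35), 0.1)
  # identical straight lines: lambda initialized at its lower clamp
  tt <- seq(0, 140, by = 20)
  ch <- cohort(lapply(1:6, function(i)
    patient_series(i, tt, 70 - 0.3 * tt)))
  init2 <- grid_search_init(ch)
  expect_equal(init2$lam, 0.02)
  expect_equal(init2$mono$S, c(70, -0.3), tolerance = 1e-8)
  # single-candidate passthrough
  par <- toy_params()
  out <- grid_search_init(ch, list(candidates = list(par)))
  expect_equal(out$mono$S, par$mono$S)
  expect_equal(out$lam, par$lam)
})

test_that("EM on an all-mono cohort reduces to a linear mixed-effects fit", {
  set.seed(99)
  tt <- seq(0, 357, by = 21)
  ch <- cohort(lapply(1:40, function(i) {
    a <- rnorm(1, 85, 2)
    b <- rnorm(1, -0.3, 0.02)
    patient_series(i, tt, a + b * tt + rnorm(18, 0, 3))
  }))
  fit <- fit_em(ch, em_options(tol = 1e-6, max_iter = 300))
  expect_lt(fit$params$lam, 0.05)
  expect_equal(fit$params$mono$S, c(85, -0.3), tolerance = 0.05)
  expect_equal(sqrt(fit$params$sigma2), 3, tolerance = 0.15)
  expect_lte(mean(classify(fit) == "bi"), 0.05)
})

test_that("EM objective trace is finite and its decreases are flagged, not hidden", {
  sim <- simulate_cohort(make_scenario(1, seed = 305, n_patients = 40))
  fit <- fit_em(sim$cohort, em_options(tol = 1e-6, max_iter = 150))
  expect_true(all(is.finite(fit$trace)))
  expect_length(fit$trace, fit$n_iter)
  expect_true(is.integer(fit$objective_decreases))
  # over the first iterations from the grid start the objective climbs
  expect_gt(fit$trace[min(5, fit$n_iter)], fit$trace[1] - 1e-6)
})
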