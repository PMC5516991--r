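test_that("conjugate samplers match their closed-form moments", {
  set.seed(21)
  # inverse-Wishart: mean = Psi / (df - p - 1); R and compiled routes
  Psi <- matrix(c(4, 1, 1, 3), 2, 2)
  df <- 12
  mR <- Reduce(`+`, replicate(4000, phasemix:::rinvwishart_r(df, Psi),
                              simplify = FALSE)) / 4000
  expect_equal(mR, Psi / (df - 2 - 1), tolerance = 0.08)
  mC <- Reduce(`+`, replicate(4000, phasemix:::rinvwishart1_cpp(df, Psi),
                              simplify = FALSE)) / 4000
  expect_equal(mC, Psi / (df - 2 - 1), tolerance = 0.08)
  # scaled inverse-chi-square: quantiles df*s2/qchisq(1-p, df)
  x <- phasemix:::rscaled_invchisq(40000, df = 50, s2 = 2)
  p <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_equal(quantile(x, p, names = FALSE), 50 * 2 / qchisq(1 - p, 50),
               tolerance = 0.02)
  expect_equal(mean(x), 50 * 2 / (50 - 2), tolerance = 0.02)
  # Beta conditional for lambda on fixed indicators
  eta <- c(rep(1, 14), rep(0, 6))
  lams <- replicate(40000, phasemix:::draw_lambda(eta))
  expect_equal(mean(lams), 15 / 22, tolerance = 0.01)
  expect_equal(var(lams), 15 * 7 / (22^2 * 23), tolerance = 0.05)
  # Dirichlet draw for pi on a frozen density: mean = concentration / total
  tt <- c(0, 30, 60, 90)
  s <- patient_series("p", tt, c(3, 2, 1, 0))
  dens <- structure(list(breakpoints = c(0, 30, 90),
                         density = c(1 / 45, 1 / 180)),
                    class = "transition_density")
  conc <- diff(phasemix:::density_cdf(dens)(tt)) + 1
  pis <- replicate(20000, phasemix:::draw_pi_patient(dens, s))
  expect_equal(rowMeans(pis), conc / sum(conc), tolerance = 0.02)
})

test_that("a single Gibbs sweep returns a coherent state and honors the df guard", {
  ch <- toy_cohort(n_mono = 8, n_bi = 12, noise = 2, seed = 31)
  par <- toy_params(ch, lam = 0.6)
  set.seed(1)
  st <- gibbs_step(list(params = par), ch)
  expect_s3_class(st$params, "population_parameters")
  expect_true(all(st$latent$eta %in% 0:1))
  expect_true(all(st$latent$xi_k >= 1 &
                    st$latent$xi_k <= length(ch[[1]]$times) - 1))
  expect_true(all(vapply(st$params$pi_weights, function(p)
    abs(sum(p) - 1) < 1e-10, logical(1))))
  expect_gt(st$params$sigma2, 0)
  # all-mono occupancy leaves too few bi patients for the Sigma_B df
  ch2 <- toy_cohort(n_mono = 6, n_bi = 0, noise = 1, seed = 32)
  par2 <- toy_params(ch2, lam = 1e-6)
  set.seed(2)
  expect_error(gibbs_step(list(params = par2), ch2), "inverse-Wishart guard")
  set.seed(2)
  st2 <- gibbs_step(list(params = par2), ch2, on_collapse = "skip")
  expect_true(st2$guard)
  expect_equal(st2$params$bi$Sigma_B, par2$bi$Sigma_B)
})

test_that("chains are bit-reproducible under a fixed seed", {
  sim <- simulate_cohort(make_scenario(1, seed = 33, n_patients = 20,
                                       n_followup = 7))
  fit <- fit_em(sim$cohort, em_options(tol = 1e-4, max_iter = 100))
  go <- gibbs_options(n_iter = 300, burn_in = 50, seed = 77, init = fit)
  c1 <- run_chain(sim$cohort, go)
  c2 <- run_chain(sim$cohort, go)
  expect_identical(c1$draws, c2$draws)
  c3 <- run_chain(sim$cohort, gibbs_options(n_iter = 300, burn_in = 50,
                                            seed = 78, init = fit))
  expect_false(identical(c1$draws, c3$draws))
})

test_that("reference R sweep and compiled chain agree in distribution", {
  sim <- simulate_cohort(make_scenario(1, seed = 34, n_patients = 50))
  fit <- fit_em(sim$cohort, em_options(tol = 1e-4, max_iter = 150))
  cc <- run_chain(sim$cohort, gibbs_options(n_iter = 200L, burn_in = 50,
                                            seed = 7, init = fit))
  cr <- run_chain(sim$cohort, gibbs_options(n_iter = 200L, burn_in = 50,
                                            seed = 8, init = fit,
                                            engine = "r"))
  for (pn in c("S0", "S1", "B0", "sigma", "lambda")) {
    se <- sd(cc$draws[, pn]) + sd(cr$draws[, pn])
    expect_lt(abs(mean(cc$draws[, pn]) - mean(cr$draws[, pn])),
              4 * se / sqrt(10) + 1e-8)
  }
})

test_that("posterior for a pooled mono cohort tracks the OLS line", {
  # one shared line, tight noise; lambda pinned small so the chain treats
  # everyone as mono-phasic
  set.seed(41)
  tt <- seq(0, 140, by = 20)
  ch <- cohort(lapply(1:30, function(i)
    patient_series(i, tt, 75 - 0.4 * tt + rnorm(8, 0, 2))))
  par <- population_parameters(
    mono_params(c(75, -0.4), diag(c(0.5, 1e-5))),
    bi_params(c(80, -0.6, 40, -0.2), diag(c(1, 1e-4, 1, 1e-4))),
    sigma2 = 4, lam = 1e-4)
   chn <- run_chain(ch, gibbs_options(n_iter = 1500, burn_in = 500, seed = 9,
                                     init = par))
  Y <- unlist(lapply(ch, `[[`, "values"))
  X <- cbind(1, rep(tt, 30))
  ols <- drop(solve(crossprod(X), crossprod(X, Y)))
  expect_lt(abs(mean(chn$draws[, "S0"]) - ols[1]),
            2 * sd(chn$draws[, "S0"]))
  expect_lt(abs(mean(chn$draws[, "S1"]) - ols[2]),
            2 * sd(chn$draws[, "S1"]))
  expect_lt(mean(chn$draws[, "lambda"]), 0.15)
  # the bi-phasic covariance guard fires but the chain still runs
  expect_gt(chn$guard_frac[["bi"]], 0.5)
  expect_lt(chn$guard_frac[["mono"]], 0.01)
})

test_that("simultaneous region reduces to the equal-tailed interval in 1-D", {
  set.seed(51)
  x <- matrix(rnorm(20000), ncol = 1)
  reg <- simultaneous_credible_region(x, 0.95)
  expect_equal(reg$lower, quantile(x, 0.025, names = FALSE),
               tolerance = 0.01)
  expect_equal(reg$upper, quantile(x, 0.975, names = FALSE),
               tolerance = 0.01)
  expect_gte(reg$coverage, 0.95)
})

test_that("simultaneous region matches a brute-force search in 2-D", {
  set.seed(52)
  draws <- cbind(rnorm(20000), rnorm(20000, 5, 2))
  reg <- simultaneous_credible_region(draws, 0.9)
  # brute force over pointwise tail levels
  alphas <- seq(1e-4, 0.1, by = 1e-4)
  cov_at <- vapply(alphas, function(a) {
    lo <- apply(draws, 2, quantile, a / 2)
    hi <- apply(draws, 2, quantile, 1 - a / 2)
    mean(draws[, 1] >= lo[1] & draws[, 1] <= hi[1] &
           draws[, 2] >= lo[2] & draws[, 2] <= hi[2])
  }, numeric(1))
  a_star <- alphas[max(which(cov_at >= 0.9))]
  expect_lt(abs((1 - reg$pointwise) - a_star), 1e-3 + 1e-12)
  expect_gte(reg$coverage, 0.9)
  # defining property on its own draws
  inside <- draws[, 1] >= reg$lower[1] & draws[, 1] <= reg$upper[1] &
    draws[, 2] >= reg$lower[2] & draws[, 2] <= reg$upper[2]
  expect_gte(mean(inside), 0.9)
})

test_that("credible region construction from an exact conjugate posterior attains nominal coverage", {
  # Normal mean with known variance and flat prior: the posterior is
  # N(ybar, s2/n); regions built from exact posterior draws must cover the
  # generating mean at the nominal rate within binomial error.
  set.seed(53)
  n_rep <- 400
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    mu <- 3
    y <- rnorm(25, mu, 2)
    draws <- matrix(rnorm(800, mean(y), 2 / sqrt(25)), ncol = 1)
    reg <- simultaneous_credible_region(draws, 0.95)
    hits[r] <- mu >= reg$lower && mu <= reg$upper
  }
  expect_gt(mean(hits), 0.95 - 3 * sqrt(0.95 * 0.05 / n_rep))
  expect_lt(mean(hits), 1)
})
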