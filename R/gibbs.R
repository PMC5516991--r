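#' Gibbs sampler options
#'
#' Defaults follow the convention of a 30,000-iteration chain with a 3,000
#' iteration burn-in and no thinning.
#'
#' @param n_iter total iterations.
#' @param burn_in discarded prefix, `< n_iter`.
#' @param thin keep-every stride, `>= 1`.
#' @param seed integer seed (one root seed drives every draw in the chain).
#' @param init a [population_parameters] or `em_result` used as the starting
#'   state (typically the EM mode); `NULL` runs [fit_em] first.
#' @param engine `"cpp"` (fast path) or `"r"` (reference implementation
#'   looping [gibbs_step]; used for cross-checking).
#' @return List of class `gibbs_options`.
#' @export
gibbs_options <- function(n_iter = 30000L, burn_in = 3000L, thin = 1L,
                          seed = 1L, init = NULL,
                          engine = c("cpp", "r")) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 init = init, engine = match.arg(engine)),
            class = "gibbs_options")
}

# --- conjugate-draw helpers (R reference implementations) ------------------

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# scaled inverse-chi-square(df, s2): df * s2 / chisq(df)
rscaled_invchisq <- function(n, df, s2) {
  df * s2 / rchisq(n, df)
}

# Inverse-Wishart(df, Psi) via the Bartlett decomposition: with Psi = LL'
# and A the Bartlett factor, (L^-T A A' L^-1)^-1 = L A^-T A^-1 L', computed
# with triangular solves only (no explicit inverse of Psi, so near-singular
# scatter matrices are handled gracefully).
rinvwishart_r <- function(df, Psi) {
  p <- nrow(Psi)
  stopifnot(df >= p)
  L <- t(chol(Psi))
  A <- matrix(0, p, p)
  diag(A) <- sqrt(rchisq(p, df - seq_len(p) + 1))
  A[lower.tri(A)] <- rnorm(p * (p - 1) / 2)
  M <- t(forwardsolve(A, t(L)))
  tcrossprod(M)
}

draw_lambda <- function(eta) rbeta(1, sum(eta) + 1, sum(1 - eta) + 1)

draw_pi_patient <- function(density, series) {
  Fc <- density_cdf(density)
  conc <- diff(Fc(series$times)) + 1
  rdirichlet1(conc)
}

# --- single Gibbs step (reference R implementation) ------------------------

#' One full sweep of the Gibbs sampler
#'
#' Executes the eleven conditional-sampling steps in order: design posteriors
#' `zeta` and a hard design draw `xi` per patient; the BIC-penalized
#' phasicity probability for the selected design and a hard `eta` draw; the
#' transition density and per-patient Dirichlet draws of `pi`; Beta draw of
#' `lambda`; individual parameters from their empirical-Bayes posteriors;
#' population means from their normal conditionals; covariances from
#' inverse-Wishart conditionals (degrees of freedom `sum(1-eta) - 1` and
#' `sum(eta) - 3` as printed, with a guard when they fall below the matrix
#' dimension); and the residual variance from a scaled inverse-chi-square.
#' No pseudoprior is used for the between-model move; this is the heuristic
#' sampler as specified, not a strict Carlin-Chib sampler.
#'
#' This is the reference implementation; [run_chain] uses an equivalent
#' compiled loop by default.
#'
#' @param state list with `params` (a [population_parameters] including
#'   `pi_weights`) and optionally previous `latent`/`individuals` draws.
#' @param cohort a [cohort].
#' @param on_collapse `"error"` (default) raises when an inverse-Wishart
#'   degrees-of-freedom guard trips; `"skip"` keeps the previous covariance.
#' @return Updated state: `params`, `latent` (`eta`, `xi_k`), `individuals`
#'   (`s` 2 x N, `b` 4 x N), `guard` (logical, guard tripped).
#' @export
gibbs_step <- function(state, cohort, on_collapse = c("error", "skip")) {
  on_collapse <- match.arg(on_collapse)
  par <- state$params
  N <- length(cohort)
  Msizes <- vapply(cohort, function(p) length(p$times), integer(1))
  pw <- par$pi_weights
  if (is.null(pw))
    pw <- lapply(cohort, function(p) rep(1 / (length(p$times) - 1),
                                         length(p$times) - 1))
  eta <- integer(N)
  jsel <- integer(N)
  s_i <- matrix(0, 2, N)
  b_i <- matrix(0, 4, N)
  zeta_hard <- vector("list", N)
  eb_s <- vector("list", N)
  eb_b <- vector("list", N)
  for (i in seq_len(N)) {
    p <- cohort[[i]]
    M <- Msizes[i]
    zt <- e_step_zeta(p, par$bi, par$sigma2, pw[[i]])
    j <- sample.int(M - 1L, 1L, prob = zt)
    jsel[i] <- j
    Qb <- build_biphasic_design(p$times, j)
    Qs <- build_mono_design(p$times)
    ls <- log_marginal_gaussian(p$values, Qs, par$mono$S, par$mono$Sigma_S,
                                par$sigma2)
    lbj <- log_marginal_gaussian(p$values, Qb, par$bi$B, par$bi$Sigma_B,
                                 par$sigma2)
    gs2 <- ls - log(M)
    gb2 <- lbj - 2 * log(M)
    zi <- if (par$lam <= 0) 0 else if (par$lam >= 1) 1 else
      1 / (1 + exp(log1p(-par$lam) + gs2 - log(par$lam) - gb2))
    eta[i] <- rbinom(1, 1, zi)
    oh <- rep(0, M - 1L)
    oh[j] <- 1
    zeta_hard[[i]] <- oh
    eb_s[[i]] <- empirical_bayes(p, Qs, par$mono$S, par$mono$Sigma_S,
                                 par$sigma2)
    eb_b[[i]] <- empirical_bayes(p, Qb, par$bi$B, par$bi$Sigma_B, par$sigma2)
  }
  dens <- suppressWarnings(
    update_transition_density(cohort, list(z = as.numeric(eta),
                                           zeta = zeta_hard)))
  pi_new <- lapply(cohort, function(p) draw_pi_patient(dens, p))
  lam <- draw_lambda(eta)
  for (i in seq_len(N)) {
    s_i[, i] <- MASS::mvrnorm(1, eb_s[[i]]$mean, eb_s[[i]]$cov,
                              tol = 1e-10)
    b_i[, i] <- MASS::mvrnorm(1, eb_b[[i]]$mean, eb_b[[i]]$cov,
                              tol = 1e-10)
  }
  nS <- sum(eta == 0)
  nB <- sum(eta == 1)
  S <- par$mono$S
  B <- par$bi$B
  SigS <- par$mono$Sigma_S
  SigB <- par$bi$Sigma_B
  guard <- FALSE
  if (nS > 0)
    S <- MASS::mvrnorm(1, rowMeans(s_i[, eta == 0, drop = FALSE]),
                       SigS / nS, tol = 1e-10)
  if (nB > 0)
    B <- MASS::mvrnorm(1, rowMeans(b_i[, eta == 1, drop = FALSE]),
                       SigB / nB, tol = 1e-10)
  guard_msg <- function(which, df, need)
    sprintf(paste0("inverse-Wishart guard for %s: df = %g < dimension %d ",
                   "(component occupancy: %d mono, %d bi)"),
            which, df, need, nS, nB)
  if (nS - 1 >= 2) {
    sc <- matrix(0, 2, 2)
    for (i in which(eta == 0)) sc <- sc + tcrossprod(s_i[, i] - S)
    SigS <- rinvwishart_r(nS - 1, sc)
  } else {
    guard <- TRUE
    if (on_collapse == "error") stop(guard_msg("Sigma_S", nS - 1, 2))
  }
  if (nB - 3 >= 4) {
    sc <- matrix(0, 4, 4)
    for (i in which(eta == 1)) sc <- sc + tcrossprod(b_i[, i] - B)
    SigB <- rinvwishart_r(nB - 3, sc)
  } else {
    guard <- TRUE
    if (on_collapse == "error") stop(guard_msg("Sigma_B", nB - 3, 4))
  }
  sse <- 0
  for (i in seq_len(N)) {
    p <- cohort[[i]]
    if (eta[i] == 0) {
      sse <- sse + sum((p$values - s_i[1, i] - s_i[2, i] * p$times)^2)
    } else {
      k <- jsel[i]
      first <- seq_len(k)
      mu <- numeric(Msizes[i])
      mu[first] <- b_i[1, i] + b_i[2, i] * p$times[first]
      mu[-first] <- b_i[3, i] + b_i[4, i] * p$times[-first]
      sse <- sse + sum((p$values - mu)^2)
    }
  }
  sigma2 <- drop(rscaled_invchisq(1, sum(Msizes), sse / sum(Msizes)))
  params <- population_parameters(mono_params(S, SigS), bi_params(B, SigB),
                                  sigma2, lam, pi_new)
  list(params = params,
       latent = list(eta = eta, xi_k = jsel),
       individuals = list(s = s_i, b = b_i),
       guard = guard)
}

# --- chain runner ----------------------------------------------------------

#' Run the Gibbs sampler
#'
#' Simulates the joint posterior from an EM-mode start, recording the 21
#' scalar parameters (see [flatten_params] for the fixed ordering) for every
#' kept draw. A covariance conditional whose inverse-Wishart degrees of
#' freedom fall below the matrix dimension (component collapse) is skipped
#' for that iteration and counted; the run aborts only when both components'
#' guards trip in more than half of the iterations, since a chain on e.g. an
#' all-mono cohort legitimately never updates the bi-phasic covariance.
#'
#' @param cohort a [cohort].
#' @param options a [gibbs_options].
#' @return Object of class `chain_summary`: `draws` (kept x 21 matrix with
#'   parameter names), `eta_mean` (posterior bi-phasic probability per
#'   patient), `guard_frac` (per-component guard rates), `options`.
#' @export
run_chain <- function(cohort, options = gibbs_options()) {
  stopifnot(inherits(cohort, "cohort"), inherits(options, "gibbs_options"))
  init <- options$init
  if (is.null(init)) init <- fit_em(cohort)
  if (inherits(init, "em_result")) init <- init$params
  stopifnot(inherits(init, "population_parameters"))
  pw <- init$pi_weights
  if (is.null(pw))
    pw <- lapply(cohort, function(p) rep(1 / (length(p$times) - 1),
                                         length(p$times) - 1))
  set.seed(options$seed)
  if (options$engine == "cpp") {
    tl <- lapply(cohort, `[[`, "times")
    yl <- lapply(cohort, `[[`, "values")
    bp <- sort(unique(unlist(tl)))
    idx <- lapply(tl, function(t) match(t, bp) - 1L)
    out <- gibbs_chain_cpp(tl, yl, init$mono$S, init$mono$Sigma_S,
                           init$bi$B, init$bi$Sigma_B, init$sigma2,
                           init$lam, pw, options$n_iter, options$burn_in,
                           options$thin, bp, idx)
    draws <- out$draws
    eta_mean <- as.numeric(out$eta_mean)
    guard_frac <- c(mono = out$guard_S / options$n_iter,
                    bi = out$guard_B / options$n_iter)
  } else {
    state <- list(params = init)
    state$params$pi_weights <- pw
    keep <- seq(options$burn_in + 1L, options$n_iter, by = options$thin)
    draws <- matrix(NA_real_, length(keep), 21)
    eta_sum <- numeric(length(cohort))
    guards <- 0L
    kept <- 0L
    for (it in seq_len(options$n_iter)) {
      state <- gibbs_step(state, cohort, on_collapse = "skip")
      if (state$guard) guards <- guards + 1L
      if (it %in% keep) {
        kept <- kept + 1L
        draws[kept, ] <- flatten_params(state$params)
        eta_sum <- eta_sum + state$latent$eta
      }
    }
    eta_mean <- eta_sum / kept
    guard_frac <- c(mono = guards / options$n_iter,
                    bi = guards / options$n_iter)
  }
  if (all(guard_frac > 0.5))
    stop("persistent component collapse: covariance updates skipped in ",
         round(100 * max(guard_frac)), "% of iterations")
  colnames(draws) <- param_names_21()
  structure(list(draws = draws, eta_mean = eta_mean,
                 guard_frac = guard_frac, options = options),
            class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, ...) {
  cat(sprintf("<chain_summary> %d kept draws x %d parameters\n",
              nrow(x$draws), ncol(x$draws)))
  pm <- colMeans(x$draws[, 1:8, drop = FALSE])
  cat("  posterior means:",
      paste(sprintf("%s=%.3g", names(pm), pm), collapse = " "), "\n")
  invisible(x)
}

#' Simultaneous rectangular credible region
#'
#' Finds, by bisection on the pointwise tail probability, the smallest
#' pointwise level whose per-parameter equal-tailed quantile hyperrectangle
#' contains at least `level` of the joint posterior draws, and returns its
#' bounds. In one dimension this reduces to the ordinary equal-tailed
#' interval.
#'
#' @param chain a `chain_summary`, or a draws matrix (one column per
#'   parameter).
#' @param level nominal joint coverage, e.g. 0.95.
#' @param params optional column subset (names or indices).
#' @return Object of class `credible_region` with `lower`, `upper`,
#'   `level`, `pointwise` (the pointwise level used) and `coverage` (the
#'   achieved empirical joint coverage, `>= level`).
#' @export
simultaneous_credible_region <- function(chain, level = 0.95,
                                         params = NULL) {
  draws <- if (inherits(chain, "chain_summary")) chain$draws else
    as.matrix(chain)
  if (!is.null(params)) draws <- draws[, params, drop = FALSE]
  n <- nrow(draws)
  if (n < 100) stop("need at least 100 kept draws (have ", n, ")")
  if (n * (1 - level) < 1)
    stop("too few draws to resolve level ", level)
  region_at <- function(alpha) {
    lo <- apply(draws, 2, quantile, probs = alpha / 2, names = FALSE)
    hi <- apply(draws, 2, quantile, probs = 1 - alpha / 2, names = FALSE)
    inside <- rep(TRUE, n)
    for (j in seq_len(ncol(draws)))
      inside <- inside & draws[, j] >= lo[j] & draws[, j] <= hi[j]
    list(frac = mean(inside), lo = lo, hi = hi)
  }
  lo_a <- 0
  hi_a <- 1 - level
  if (region_at(hi_a)$frac >= level) {
    lo_a <- hi_a
  } else {
    for (i in 1:40) {
      mid <- (lo_a + hi_a) / 2
      if (region_at(mid)$frac >= level) lo_a <- mid else hi_a <- mid
    }
  }
  res <- region_at(lo_a)
  structure(list(level = level, pointwise = 1 - lo_a, lower = res$lo,
                 upper = res$hi, coverage = res$frac,
                 param_names = colnames(draws)),
            class = "credible_region")
}

#' @export
print.credible_region <- function(x, ...) {
  cat(sprintf(
    "<credible_region> joint level %.2f (pointwise %.4f, empirical %.3f)\n",
    x$level, x$pointwise, x$coverage))
  df <- data.frame(lower = x$lower, upper = x$upper)
  rownames(df) <- x$param_names
  print(df)
  invisible(x)
}
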